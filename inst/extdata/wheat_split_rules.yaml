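# Subgenome split rules for common polyploid wheat annotations:
# gene-id regular expression -> subgenome label, per polyploid genome.
# CS = hexaploid bread wheat (AABBDD), WEW = wild emmer wheat (AABB).
CS:
  "^TraesCS\\dA": CS_A
  "^TraesCS\\dB": CS_B
  "^TraesCS\\dD": CS_D
  "^TraesCSU": CS_U
WEW:
  "^TRIDC\\dA": WEW_A
  "^TRIDC\\dB": WEW_B
  "^TRIDCU": WEW_U
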