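Package: haploblocks
Title: Haploblock Detection and Comparative Gene-Content Analysis for
    Wheat Wild-Relative Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects haplotype blocks (haploblocks) between chromosome-scale
    genome assemblies from pairwise whole-genome alignment coordinates, by
    binning per-alignment percent identity in fixed-width chromosomal bins,
    merging adjacent bins with matching median identity, and applying
    per-genome-pair identity cutoffs. Companion tools implement rule-based
    high/low-confidence gene classification from homology-search evidence,
    consensus calling of NLR disease-resistance loci by positional
    intersection of de novo predictions with function-annotated genes,
    and orthogroup set algebra (exclusive sharing, upset counts,
    single-copy orthogroups) across a genome panel, together with seeded
    synthetic-data generators that produce alignment, evidence, locus and
    orthogroup inputs with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
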