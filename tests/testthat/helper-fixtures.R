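# small constructors used across test files

mkAln <- function(chrom, start, end, idy, query_chrom = chrom,
                  strand = "+", mapq = NA_real_) {
    AlignmentSet(data.frame(
        ref_chrom = chrom, ref_start = start, ref_end = end,
        query_chrom = query_chrom, query_start = start, query_end = end,
        strand = strand, pct_identity = idy, mapq = mapq,
        stringsAsFactors = FALSE))
}

# GRanges from 0-based half-open coordinates
mkGr <- function(chrom, start0, end0, ids = NULL) {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start0 + 1, end0))
    if (!is.null(ids)) names(gr) <- ids
    gr
}

# an AlignmentSet whose bins (given bin_size) get exactly the requested
# medians: one alignment per non-NA bin, centred in the bin
alnFromBinMedians <- function(medians, bin_size = 1e6, chrom = "chr1",
                              aln_len = 2e5) {
    idx <- which(!is.na(medians)) - 1
    if (!length(idx)) return(AlignmentSet())
    centre <- idx * bin_size + bin_size / 2
    mkAln(chrom, centre - aln_len / 2, centre + aln_len / 2,
          medians[idx + 1])
}
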