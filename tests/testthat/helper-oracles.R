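# Brute-force oracles, written independently of the package internals.
# Coordinates here are 0-based half-open throughout.

o_round <- function(x, d = 2) floor(x * 10^d + 0.5 + 1e-9) / 10^d

# sort-based median (mean of central pair for even counts)
o_median <- function(v) {
    s <- sort(v)
    n <- length(s)
    if (n == 0L) return(NA_real_)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# midpoint-histogram binning: identity lists per bin for one chromosome
o_bin <- function(starts, ends, idents, bin_size, chrom_len) {
    n_bins <- ceiling(chrom_len / bin_size)
    out <- vector("list", n_bins)
    for (k in seq_along(starts)) {
        mid <- floor((starts[k] + ends[k]) / 2)
        idx <- floor(mid / bin_size) + 1
        out[[idx]] <- c(out[[idx]], idents[k])
    }
    out
}

# explicit run enumeration over one chromosome's bin medians.
# med: vector of rounded medians (NA = empty bin). Returns data.frame of
# blocks with 0-based half-open coordinates.
o_enumerate_runs <- function(med, bin_size, chrom_len, cutoff,
                             mode = c("identical_median", "threshold"),
                             strict = TRUE, min_bins = 1, rounding = 2) {
    mode <- match.arg(mode)
    pass <- function(m) !is.na(m) &&
        (if (strict) m > cutoff else m >= cutoff)
    n <- length(med)
    res <- list()
    i <- 1
    while (i <= n) {
        if (is.na(med[i])) { i <- i + 1; next }
        if (mode == "identical_median") {
            j <- i
            while (j + 1 <= n && !is.na(med[j + 1]) &&
                   med[j + 1] == med[i]) j <- j + 1
            bm <- med[i]
        } else {
            if (!pass(med[i])) { i <- i + 1; next }
            j <- i
            while (j + 1 <= n && !is.na(med[j + 1]) &&
                   pass(med[j + 1])) j <- j + 1
            bm <- o_round(o_median(med[i:j]), rounding)
        }
        if (pass(bm) && (j - i + 1) >= min_bins)
            res[[length(res) + 1L]] <- data.frame(
                start = (i - 1) * bin_size,
                end = min(j * bin_size, chrom_len),
                median = bm, n_bins = j - i + 1)
        i <- j + 1
    }
    if (!length(res))
        return(data.frame(start = numeric(0), end = numeric(0),
                          median = numeric(0), n_bins = integer(0)))
    do.call(rbind, res)
}

# full haploblock oracle for single-chromosome alignment tables
o_call_blocks <- function(aln_df, bin_size, chrom_len, min_aln_len,
                          cutoff, mode, strict = TRUE, min_bins = 1,
                          rounding = 2) {
    keep <- (aln_df$ref_end - aln_df$ref_start) >= min_aln_len
    aln_df <- aln_df[keep, , drop = FALSE]
    bins <- o_bin(aln_df$ref_start, aln_df$ref_end, aln_df$pct_identity,
                  bin_size, chrom_len)
    med <- vapply(bins, function(v)
        if (is.null(v)) NA_real_ else o_round(o_median(v), rounding),
        numeric(1))
    o_enumerate_runs(med, bin_size, chrom_len, cutoff, mode, strict,
                     min_bins, rounding)
}

# quadratic overlap scan: for each feature, the 0-based half-open overlap
# in bases with each block; returns, per feature, the index of the block
# with the largest overlap (ties -> leftmost by (chrom, start)), or NA.
o_best_overlap <- function(f_chrom, f_start, f_end,
                           b_chrom, b_start, b_end) {
    n <- length(f_start)
    best <- rep(NA_integer_, n)
    ord <- order(b_chrom, b_start)
    for (i in seq_len(n)) {
        best_ov <- 0
        for (j in ord) {
            if (b_chrom[j] != f_chrom[i]) next
            ov <- min(f_end[i], b_end[j]) - max(f_start[i], b_start[j])
            if (ov > best_ov) { best_ov <- ov; best[i] <- j }
        }
    }
    best
}

# quadratic scan for >= min_overlap bp overlap with any interval in the
# other track (same chromosome); returns a logical per 'a' interval
o_any_overlap <- function(a_chrom, a_start, a_end,
                          b_chrom, b_start, b_end, min_overlap = 1) {
    vapply(seq_along(a_start), function(i) {
        any(b_chrom == a_chrom[i] &
            pmin(a_end[i], b_end) - pmax(a_start[i], b_start) >=
                min_overlap)
    }, logical(1))
}

# per-base bitmap over one chromosome; intervals 0-based half-open
o_bitmap <- function(starts, ends, chrom_len) {
    bm <- logical(chrom_len)
    for (k in seq_along(starts))
        if (ends[k] > starts[k])
            bm[(starts[k] + 1):ends[k]] <- TRUE
    bm
}

# hand-written classifier truth table, one row per (C, M, P, T)
# combination, derived clause by clause from the confidence rules; M is a
# UniMag hit qualifying on both subject and query coverage.
o_truth_table <- function() {
    rows <- list(
        c(0, 0, 0, 0, "UNCLASSIFIED"),
        c(0, 0, 0, 1, "UNCLASSIFIED"),
        c(0, 0, 1, 0, "LC"),
        c(0, 0, 1, 1, "UNCLASSIFIED"),
        c(0, 1, 0, 0, "LC"),
        c(0, 1, 0, 1, "UNCLASSIFIED"),
        c(0, 1, 1, 0, "LC"),
        c(0, 1, 1, 1, "UNCLASSIFIED"),
        c(1, 0, 0, 0, "LC"),
        c(1, 0, 0, 1, "REP"),
        c(1, 0, 1, 0, "HC"),
        c(1, 0, 1, 1, "REP"),
        c(1, 1, 0, 0, "HC"),
        c(1, 1, 0, 1, "HC"),
        c(1, 1, 1, 0, "HC"),
        c(1, 1, 1, 1, "HC"))
    d <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    colnames(d) <- c("C", "M", "P", "T", "label")
    for (col in c("C", "M", "P", "T")) d[[col]] <- d[[col]] == "1"
    d
}

# evidence row realizing one (C, M, P, T) combination with metrics well
# inside the qualified/disqualified regions
o_evidence_row <- function(id, C, M, P, T) {
    data.frame(
        protein_id = id, complete = C,
        unimag_evalue = if (M) 1e-30 else NA_real_,
        unimag_subject_coverage = if (M) 99 else NA_real_,
        unimag_query_coverage = if (M) 99 else NA_real_,
        unipoa_evalue = if (P) 1e-30 else NA_real_,
        unipoa_subject_coverage = if (P) 99 else NA_real_,
        ptrep_evalue = if (T) 1e-30 else NA_real_,
        ptrep_query_coverage = if (T) 99 else NA_real_,
        stringsAsFactors = FALSE)
}

# brute-force exclusive-sharing count from a presence list
# memb: list group -> character vector of genomes with >= 1 gene
o_exclusive_count <- function(memb, genome_set, panel) {
    sum(vapply(memb, function(g)
        all(genome_set %in% g) && !any(setdiff(panel, genome_set) %in% g),
        logical(1)))
}

# random disjoint 0-based half-open blocks on [0, chrom_len)
r_disjoint_blocks <- function(n, chrom_len) {
    cuts <- sort(sample.int(chrom_len - 1, 2 * n))
    data.frame(start = cuts[seq(1, 2 * n, 2)],
               end = cuts[seq(2, 2 * n, 2)])
}
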