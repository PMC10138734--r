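#' Bin alignments by reference chromosomal position
#'
#' Lays a fixed-width bin grid anchored at position 0 over every reference
#' chromosome and assigns each alignment's percent identity to exactly one
#' bin: the bin containing its reference midpoint
#' \code{floor((ref_start + ref_end) / 2)}. All bins of every chromosome
#' are returned, empty ones included; the terminal bin of a chromosome is
#' truncated at the chromosome length.
#'
#' @param x An \linkS4class{AlignmentSet} (already filtered as desired).
#' @param binSize bin width in bases (default 5e6).
#' @param chromLengths named numeric vector of reference chromosome
#'   lengths; an alignment midpoint beyond its chromosome length (or a
#'   chromosome absent from the table) is an error.
#' @return A data.frame with one row per bin: \code{chrom}, \code{index}
#'   (0-based), \code{start}, \code{end} (0-based half-open), \code{n}
#'   (alignments assigned) and a list-column \code{identities}.
#' @seealso \code{\link{callHaploblocks}}
#' @export
binAlignments <- function(x, binSize = 5e6, chromLengths) {
    stopifnot(binSize > 0, length(chromLengths) > 0,
              !is.null(names(chromLengths)))
    r <- x@records
    if (nrow(r) > 0) {
        unknown <- setdiff(unique(r$ref_chrom), names(chromLengths))
        if (length(unknown))
            stop("alignment chromosomes missing from length table: ",
                 paste(unknown, collapse = ", "))
        mid <- floor((r$ref_start + r$ref_end) / 2)
        beyond <- mid >= chromLengths[r$ref_chrom]
        if (any(beyond))
            stop("alignment midpoint beyond chromosome length for ",
                 sum(beyond), " record(s) on ",
                 paste(unique(r$ref_chrom[beyond]), collapse = ", "),
                 " (length table inconsistent with alignments)")
        bin_idx <- floor(mid / binSize)
        key <- paste(r$ref_chrom, bin_idx, sep = "\r")
    } else {
        key <- character(0)
    }
    out <- lapply(names(chromLengths), function(chrom) {
        n_bins <- ceiling(chromLengths[[chrom]] / binSize)
        idx <- seq_len(n_bins) - 1L
        data.frame(chrom = chrom, index = idx,
                   start = idx * binSize,
                   end = pmin((idx + 1) * binSize, chromLengths[[chrom]]),
                   stringsAsFactors = FALSE)
    })
    bins <- do.call(rbind, out)
    rownames(bins) <- NULL
    assigned <- if (length(key)) split(r$pct_identity, key) else list()
    bkey <- paste(bins$chrom, bins$index, sep = "\r")
    bins$identities <- I(lapply(bkey, function(k) {
        v <- assigned[[k]]
        if (is.null(v)) numeric(0) else v
    }))
    bins$n <- lengths(bins$identities)
    attr(bins, "bin_size") <- binSize
    bins
}

#' Median percent identity of a bin
#'
#' Unweighted median of the identities assigned to a bin (mean of the
#' central pair for even counts), rounded half-up to \code{rounding}
#' decimal places. Empty bins have no median (NA).
#'
#' @param identities numeric vector of percent identities (possibly empty).
#' @param rounding decimal places (default 2).
#' @return The rounded median, or \code{NA_real_} for an empty bin.
#' @examples
#' binMedian(c(99.1, 99.3, 99.5))  # 99.3
#' binMedian(numeric(0))           # NA
#' @export
binMedian <- function(identities, rounding = 2) {
    if (length(identities) == 0L) return(NA_real_)
    roundHalfUp(stats::median(identities), rounding)
}

# per-chromosome run merging over bin medians; returns a data.frame of
# blocks (0-based half-open) before the cutoff/minBins filter
.mergeBins <- function(bins, med, params) {
    passes <- function(m) {
        !is.na(m) & if (params@cutoffStrict) m > params@identityCutoff
                    else m >= params@identityCutoff
    }
    res <- list()
    for (chrom in unique(bins$chrom)) {
        sel <- bins$chrom == chrom
        b <- bins[sel, , drop = FALSE]
        m <- med[sel]
        if (params@mergeMode == "identical_median") {
            # runs of adjacent non-empty bins with equal rounded medians;
            # empty bins terminate runs
            grp <- cumsum(c(TRUE, (m[-1] != m[-length(m)]) |
                                   is.na(m[-1]) != is.na(m[-length(m)]) |
                                   is.na(m[-1])))
        } else {
            ok <- passes(m)
            grp <- cumsum(c(TRUE, ok[-1] != ok[-length(ok)] | !ok[-1]))
            grp[!ok] <- NA
        }
        grp[is.na(m)] <- NA
        for (g in unique(grp[!is.na(grp)])) {
            i <- which(!is.na(grp) & grp == g)
            block_med <- if (params@mergeMode == "identical_median") m[i[1]]
                         else roundHalfUp(stats::median(m[i]),
                                          params@medianRounding)
            res[[length(res) + 1L]] <- data.frame(
                chrom = chrom, start = b$start[i[1]], end = b$end[i[length(i)]],
                median_identity = block_med, n_bins = length(i),
                n_alignments = sum(b$n[i]), stringsAsFactors = FALSE)
        }
    }
    if (!length(res))
        return(data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), median_identity = numeric(0),
                          n_bins = integer(0), n_alignments = integer(0)))
    blocks <- do.call(rbind, res)
    keep <- passes(blocks$median_identity) & blocks$n_bins >= params@minBins
    blocks[keep, , drop = FALSE]
}

#' Call haploblocks from pairwise alignments
#'
#' Full haploblock construction for one genome pair: alignments shorter
#' than \code{minAlnLen} on the reference are discarded, the remainder are
#' binned by reference midpoint into \code{binSize} bins, each bin's median
#' percent identity is computed and rounded, adjacent bins are merged into
#' blocks, and blocks failing the identity cutoff or the minimum bin count
#' are dropped.
#'
#' Two merge modes are available. \code{"identical_median"} (default)
#' merges maximal runs of adjacent non-empty bins whose rounded medians are
#' equal; the block median is that shared value. \code{"threshold"} merges
#' maximal runs of adjacent non-empty bins that each pass the identity
#' cutoff; the block median is the median of the constituent bin medians.
#' In both modes an empty bin (no alignments) terminates a run: absence of
#' alignment is absence of evidence for shared ancestry.
#'
#' @param x An \linkS4class{AlignmentSet} holding one genome pair's
#'   alignments.
#' @param params A \linkS4class{HaploblockParams}.
#' @param chromLengths named numeric vector of reference chromosome
#'   lengths.
#' @param referenceGenome,queryGenome genome labels recorded in the result.
#' @return A \linkS4class{HaploblockSet}; an empty alignment set yields a
#'   valid empty block set.
#' @examples
#' cl <- c(chr1 = 2e7)
#' aln <- AlignmentSet(data.frame(
#'     ref_chrom = "chr1", ref_start = c(0, 5e6), ref_end = c(4e6, 9e6),
#'     query_chrom = "chr1", query_start = c(0, 5e6),
#'     query_end = c(4e6, 9e6), strand = "+",
#'     pct_identity = c(99.2, 99.2)))
#' callHaploblocks(aln, HaploblockParams(identityCutoff = 99), cl)
#' @export
callHaploblocks <- function(x, params = HaploblockParams(), chromLengths,
                            referenceGenome = "reference",
                            queryGenome = "query") {
    validObject(params)
    filt <- filterAlignments(x, minRefSpan = params@minAlnLen)
    bins <- binAlignments(filt, params@binSize, chromLengths)
    med <- vapply(bins$identities, binMedian, numeric(1),
                  rounding = params@medianRounding)
    blk <- .mergeBins(bins, med, params)
    gr <- GRanges(blk$chrom,
                  IRanges(start = blk$start + 1, end = blk$end),
                  median_identity = blk$median_identity,
                  n_bins = as.integer(blk$n_bins),
                  n_alignments = as.integer(blk$n_alignments))
    gr <- gr[order(as.character(GenomeInfoDb::seqnames(gr)),
                   BiocGenerics::start(gr))]
    HaploblockSet(blocks = gr, referenceGenome = referenceGenome,
                  queryGenome = queryGenome, params = params,
                  chromLengths = chromLengths)
}

#' Fraction of the genome covered by haploblocks
#'
#' @param x A \linkS4class{HaploblockSet} (blocks are disjoint by
#'   construction).
#' @param chromLengths optional named numeric vector; defaults to the
#'   lengths stored in \code{x}. A block extending beyond its chromosome
#'   length is an error.
#' @return Percent of total genome length covered, in [0, 100].
#' @export
genomeCoverage <- function(x, chromLengths = NULL) {
    if (is.null(chromLengths)) chromLengths <- x@chromLengths
    stopifnot(length(chromLengths) > 0)
    b <- x@blocks
    if (length(b)) {
        lens <- chromLengths[as.character(GenomeInfoDb::seqnames(b))]
        if (any(is.na(lens)) || any(BiocGenerics::end(b) > lens))
            stop("block beyond chromosome length")
    }
    100 * sum(as.numeric(BiocGenerics::width(b))) / sum(chromLengths)
}

#' Summarize a haploblock set
#'
#' @param x A \linkS4class{HaploblockSet}.
#' @return A list with \code{count}, \code{meanLength}, \code{minLength},
#'   \code{maxLength} (bases; NA when there are no blocks) and
#'   \code{perChromosome}, a data.frame of block counts per chromosome.
#' @export
blockSummary <- function(x) {
    b <- x@blocks
    w <- as.numeric(BiocGenerics::width(b))
    per <- if (length(b)) {
        t <- table(as.character(GenomeInfoDb::seqnames(b)))
        data.frame(chrom = names(t), count = as.integer(t),
                   stringsAsFactors = FALSE)
    } else data.frame(chrom = character(0), count = integer(0))
    list(count = length(b),
         meanLength = if (length(b)) mean(w) else NA_real_,
         minLength = if (length(b)) min(w) else NA_real_,
         maxLength = if (length(b)) max(w) else NA_real_,
         perChromosome = per)
}

#' Intersect haploblock sets sharing a reference genome
#'
#' Computes the maximal reference intervals covered by at least one block
#' in \emph{every} input set — the multi-genome shared regions of a panel
#' of pairwise comparisons against a common reference. The result is a
#' disjoint, sorted GRanges; for each interval, one metadata column per
#' query genome records the median identity of that set's overlapping
#' block(s) (comma-joined if the interval is spanned by adjacent blocks).
#'
#' @param sets list of >= 2 \linkS4class{HaploblockSet} objects with the
#'   same \code{referenceGenome}.
#' @return A GRanges of shared intervals (empty if any set is empty).
#' @export
intersectHaploblockSets <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 2)
    refs <- vapply(sets, referenceGenome, character(1))
    if (length(unique(refs)) != 1L)
        stop("all sets must share the same reference genome (got: ",
             paste(unique(refs), collapse = ", "), ")")
    grl <- lapply(sets, blocks)
    common <- Reduce(function(a, b)
        GenomicRanges::intersect(a, b, ignore.strand = TRUE),
        lapply(grl, function(g) { mcols(g) <- NULL; GenomicRanges::reduce(g) }))
    if (length(common) == 0L) return(GRanges())
    common <- BiocGenerics::sort(common)
    for (i in seq_along(sets)) {
        hits <- findOverlaps(common, grl[[i]])
        meds <- vapply(seq_along(common), function(j) {
            m <- mcols(grl[[i]])$median_identity[
                S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == j]]
            paste(m, collapse = ",")
        }, character(1))
        mcols(common)[[paste0("median.", queryGenome(sets[[i]]))]] <- meds
    }
    common
}

#' Associate features with haploblocks
#'
#' Maps each feature (gene, NLR locus, ...) to the haploblock it overlaps
#' by at least one base, or to none. A feature spanning several blocks is
#' assigned to the block with the larger overlap; exact ties go to the
#' leftmost block.
#'
#' @param x A \linkS4class{HaploblockSet}.
#' @param features GRanges on the reference genome's coordinates; feature
#'   ids are taken from \code{names()} or an \code{id} metadata column.
#' @return A data.frame with one row per feature: \code{feature_id},
#'   \code{block_chrom}, \code{block_start}, \code{block_end} (0-based
#'   half-open), \code{block_median}, \code{overlap_bp} (NA row when the
#'   feature overlaps no block).
#' @export
associateIntervals <- function(x, features) {
    b <- x@blocks
    ids <- .featureIds(features)
    out <- data.frame(feature_id = ids,
                      block_chrom = NA_character_, block_start = NA_real_,
                      block_end = NA_real_, block_median = NA_real_,
                      overlap_bp = NA_real_, stringsAsFactors = FALSE)
    if (length(features) == 0L || length(b) == 0L) return(out)
    hits <- findOverlaps(features, b, ignore.strand = TRUE)
    if (length(hits) == 0L) return(out)
    ov <- BiocGenerics::width(pintersect(
        features[S4Vectors::queryHits(hits)], b[S4Vectors::subjectHits(hits)],
        ignore.strand = TRUE))
    for (q in unique(S4Vectors::queryHits(hits))) {
        sel <- which(S4Vectors::queryHits(hits) == q)
        sj <- S4Vectors::subjectHits(hits)[sel]
        o <- ov[sel]
        # largest overlap wins; ties to the leftmost block (blocks are
        # sorted, and subjectHits ascend within a query)
        best <- sj[which.max(o)]
        out$block_chrom[q] <- as.character(GenomeInfoDb::seqnames(b))[best]
        out$block_start[q] <- BiocGenerics::start(b)[best] - 1
        out$block_end[q] <- BiocGenerics::end(b)[best]
        out$block_median[q] <- mcols(b)$median_identity[best]
        out$overlap_bp[q] <- max(o)
    }
    out
}

#' Write a haploblock set as TSV
#'
#' One row per block with columns reference, query, chrom, start, end
#' (0-based half-open), n_bins, n_alignments, median_identity.
#'
#' @param x A \linkS4class{HaploblockSet}.
#' @param path output path.
#' @param header optional comment line (without trailing newline) written
#'   before the column header.
#' @return \code{path}, invisibly.
#' @export
writeHaploblockTsv <- function(x, path, header = NULL) {
    b <- x@blocks
    d <- data.frame(reference = x@referenceGenome, query = x@queryGenome,
                    chrom = as.character(GenomeInfoDb::seqnames(b)),
                    start = BiocGenerics::start(b) - 1,
                    end = BiocGenerics::end(b),
                    n_bins = mcols(b)$n_bins,
                    n_alignments = mcols(b)$n_alignments,
                    median_identity = mcols(b)$median_identity)
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(header, con)
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
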