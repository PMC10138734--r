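#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- isSorted
#' @importFrom GenomicRanges GRanges findOverlaps pintersect
#' @importFrom IRanges IRanges
NULL

.ALN_COLS <- c("ref_chrom", "ref_start", "ref_end", "query_chrom",
               "query_start", "query_end", "strand", "pct_identity",
               "ref_span", "mapq")

#' Pairwise whole-genome alignment records
#'
#' Container for local alignments between a reference and a query genome,
#' as produced by whole-genome aligners (nucmer/show-coords, minimap2/PAF).
#' Coordinates are stored 0-based half-open on the forward strand of both
#' sequences; reverse-strand alignments carry \code{strand == "-"} with
#' forward-normalized query coordinates.
#'
#' @slot records data.frame with columns \code{ref_chrom}, \code{ref_start},
#'   \code{ref_end}, \code{query_chrom}, \code{query_start},
#'   \code{query_end}, \code{strand}, \code{pct_identity}, \code{ref_span},
#'   \code{mapq} (NA when the source dialect has no mapping quality).
#'
#' @export
setClass("AlignmentSet", representation(records = "data.frame"))

setValidity("AlignmentSet", function(object) {
    r <- object@records
    if (!all(.ALN_COLS %in% colnames(r)))
        return(paste("missing columns:",
                     paste(setdiff(.ALN_COLS, colnames(r)), collapse = ", ")))
    if (nrow(r) == 0L) return(TRUE)
    if (any(r$ref_start >= r$ref_end))
        return("ref_start must be < ref_end for every record")
    if (any(r$ref_start < 0) || any(r$query_start < 0))
        return("negative coordinates")
    if (any(r$pct_identity < 0 | r$pct_identity > 100))
        return("pct_identity outside [0, 100]")
    if (any(r$ref_span != r$ref_end - r$ref_start))
        return("ref_span inconsistent with ref_end - ref_start")
    if (!all(r$strand %in% c("+", "-")))
        return("strand must be '+' or '-'")
    TRUE
})

#' Construct an AlignmentSet
#'
#' @param records data.frame of alignment records; \code{ref_span} and
#'   \code{mapq} are filled in when absent.
#' @return An \linkS4class{AlignmentSet}.
#' @export
AlignmentSet <- function(records = NULL) {
    if (is.null(records)) {
        records <- as.data.frame(
            setNames(rep(list(numeric(0)), length(.ALN_COLS)), .ALN_COLS))
        records$ref_chrom <- character(0)
        records$query_chrom <- character(0)
        records$strand <- character(0)
    }
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    if (is.null(records$ref_span))
        records$ref_span <- records$ref_end - records$ref_start
    if (is.null(records$mapq)) records$mapq <- NA_real_
    records <- records[, .ALN_COLS]
    rownames(records) <- NULL
    new("AlignmentSet", records = records)
}

#' @describeIn AlignmentSet number of alignment records
#' @param x An AlignmentSet.
#' @export
setMethod("length", "AlignmentSet", function(x) nrow(x@records))

#' @export
setMethod("show", "AlignmentSet", function(object) {
    r <- object@records
    cat("AlignmentSet with", nrow(r), "records\n")
    if (nrow(r) > 0) {
        cat("  reference chromosomes:",
            paste(unique(r$ref_chrom), collapse = ", "), "\n")
        cat("  ref span: ", min(r$ref_span), "-", max(r$ref_span),
            " bp; identity: ",
            sprintf("%.2f-%.2f", min(r$pct_identity), max(r$pct_identity)),
            "%\n", sep = "")
    }
})

#' @describeIn AlignmentSet extract records as a data.frame
#' @param row.names,optional,... passed on for S3 compatibility (unused).
#' @export
as.data.frame.AlignmentSet <- function(x, row.names = NULL,
                                       optional = FALSE, ...) x@records

setMethod("[", "AlignmentSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, records = x@records[i, , drop = FALSE])
})

#' Parameters of the haploblock caller
#'
#' Holds the tunable parameters of haploblock construction: bin width,
#' minimum alignment length, per-pair identity cutoff, merge mode and the
#' rounding precision at which bin medians are compared.
#'
#' @slot binSize bin width in bases (default 5e6, i.e. 5-Mb bins).
#' @slot minAlnLen minimum reference span of an alignment in bases
#'   (default 20000).
#' @slot identityCutoff percent identity cutoff applied to merged blocks
#'   (default 95; use 99 for very close genome pairs).
#' @slot mergeMode \code{"identical_median"} (adjacent bins sharing the same
#'   rounded median merge) or \code{"threshold"} (adjacent bins each passing
#'   the cutoff merge).
#' @slot medianRounding decimal places at which medians are rounded and
#'   compared (default 2).
#' @slot minBins minimum number of non-empty bins per block (default 1).
#' @slot cutoffStrict when TRUE (default) a block must exceed the cutoff
#'   strictly (median > cutoff); when FALSE, median >= cutoff suffices.
#'
#' @export
setClass("HaploblockParams",
    representation(binSize = "numeric", minAlnLen = "numeric",
                   identityCutoff = "numeric", mergeMode = "character",
                   medianRounding = "numeric", minBins = "numeric",
                   cutoffStrict = "logical"))

setValidity("HaploblockParams", function(object) {
    if (object@binSize <= 0) return("binSize must be > 0")
    if (object@minAlnLen < 0) return("minAlnLen must be >= 0")
    if (object@identityCutoff < 0 || object@identityCutoff > 100)
        return("identityCutoff must lie in [0, 100]")
    if (!object@mergeMode %in% c("identical_median", "threshold"))
        return(sprintf("unknown merge mode '%s'", object@mergeMode))
    if (object@minBins < 1) return("minBins must be >= 1")
    if (object@medianRounding < 0) return("medianRounding must be >= 0")
    TRUE
})

#' Construct haploblock-caller parameters
#'
#' @param binSize,minAlnLen,identityCutoff,mergeMode,medianRounding,minBins,cutoffStrict
#'   see the slot documentation of \linkS4class{HaploblockParams}.
#' @return A \linkS4class{HaploblockParams} object.
#' @examples
#' HaploblockParams(identityCutoff = 99)
#' @export
HaploblockParams <- function(binSize = 5e6, minAlnLen = 20000,
                             identityCutoff = 95,
                             mergeMode = "identical_median",
                             medianRounding = 2, minBins = 1,
                             cutoffStrict = TRUE) {
    new("HaploblockParams", binSize = binSize, minAlnLen = minAlnLen,
        identityCutoff = identityCutoff, mergeMode = mergeMode,
        medianRounding = medianRounding, minBins = minBins,
        cutoffStrict = cutoffStrict)
}

#' @export
setMethod("show", "HaploblockParams", function(object) {
    cat("HaploblockParams: bin", object@binSize / 1e6, "Mb; min alignment",
        object@minAlnLen, "bp; cutoff",
        paste0(if (object@cutoffStrict) ">" else ">=", object@identityCutoff,
               "%"),
        "; merge", object@mergeMode,
        "; rounding", object@medianRounding, "dp\n")
})

#' A set of haploblocks for one genome pair
#'
#' The haploblocks called between one reference genome and one query genome:
#' merged runs of fixed-width bins whose alignments share a median percent
#' identity above the pair's cutoff. Blocks are stored as a sorted, disjoint
#' \link[GenomicRanges]{GRanges} on the reference genome with metadata
#' columns \code{median_identity}, \code{n_bins} and \code{n_alignments}.
#'
#' @slot referenceGenome label of the reference genome.
#' @slot queryGenome label of the query genome.
#' @slot params the \linkS4class{HaploblockParams} used.
#' @slot blocks GRanges of blocks (1-based closed, as is standard for
#'   GRanges; exported BED is 0-based half-open).
#' @slot chromLengths named numeric vector of reference chromosome lengths.
#'
#' @export
setClass("HaploblockSet",
    representation(referenceGenome = "character", queryGenome = "character",
                   params = "HaploblockParams", blocks = "GRanges",
                   chromLengths = "numeric"))

setValidity("HaploblockSet", function(object) {
    b <- object@blocks
    cl <- object@chromLengths
    if (length(cl) && (is.null(names(cl)) || any(cl <= 0)))
        return("chromLengths must be a named vector of positive lengths")
    if (length(b) == 0L) return(TRUE)
    need <- c("median_identity", "n_bins", "n_alignments")
    if (!all(need %in% colnames(mcols(b))))
        return("blocks must carry median_identity, n_bins, n_alignments")
    if (any(mcols(b)$n_bins < 1) || any(mcols(b)$n_alignments < 1))
        return("n_bins and n_alignments must be >= 1")
    if (!identical(order(as.character(GenomeInfoDb::seqnames(b)),
                         BiocGenerics::start(b)), seq_along(b)))
        return("blocks must be sorted by (chrom, start)")
    ends <- cl[as.character(GenomeInfoDb::seqnames(b))]
    if (any(is.na(ends)))
        return("block chromosome missing from chromLengths")
    if (any(BiocGenerics::end(b) > ends))
        return("block extends beyond chromosome length")
    sp <- split(b, GenomeInfoDb::seqnames(b))
    for (g in sp) {
        if (length(g) > 1 &&
            any(BiocGenerics::start(g)[-1] <=
                BiocGenerics::end(g)[-length(g)]))
            return("blocks must be pairwise disjoint")
    }
    TRUE
})

#' Construct a HaploblockSet
#'
#' @param blocks GRanges of blocks with metadata columns
#'   \code{median_identity}, \code{n_bins}, \code{n_alignments}.
#' @param referenceGenome,queryGenome genome labels.
#' @param params a \linkS4class{HaploblockParams}.
#' @param chromLengths named numeric vector of reference chromosome lengths.
#' @return A \linkS4class{HaploblockSet}.
#' @export
HaploblockSet <- function(blocks = GRanges(), referenceGenome = "reference",
                          queryGenome = "query",
                          params = HaploblockParams(),
                          chromLengths = numeric(0)) {
    new("HaploblockSet", referenceGenome = referenceGenome,
        queryGenome = queryGenome, params = params, blocks = blocks,
        chromLengths = chromLengths)
}

#' @export
setMethod("show", "HaploblockSet", function(object) {
    b <- object@blocks
    cat("HaploblockSet:", object@referenceGenome, "vs",
        object@queryGenome, "\n")
    cat(" ", length(b), "blocks")
    if (length(b))
        cat(sprintf(" (mean %.2f Mb, median identity %.2f-%.2f%%)",
                    mean(BiocGenerics::width(b)) / 1e6,
                    min(mcols(b)$median_identity),
                    max(mcols(b)$median_identity)))
    cat("\n")
    show(object@params)
})

#' @describeIn HaploblockSet number of blocks
#' @param x A HaploblockSet.
#' @export
setMethod("length", "HaploblockSet", function(x) length(x@blocks))

#' Orthogroup membership across a genome panel
#'
#' An orthogroup table in the layout emitted by orthology-inference tools:
#' one row per orthogroup, one column per genome, each cell the list of the
#' genome's gene ids in that group. Every gene id belongs to exactly one
#' group.
#'
#' @slot panel ordered character vector of genome labels.
#' @slot groups named list (group id -> named list genome -> character
#'   vector of gene ids); genomes with no member may be absent or empty.
#'
#' @export
setClass("OrthogroupTable",
    representation(panel = "character", groups = "list"))

setValidity("OrthogroupTable", function(object) {
    if (anyDuplicated(object@panel)) return("duplicated panel labels")
    if (length(object@groups) == 0L) return(TRUE)
    if (is.null(names(object@groups)) || anyDuplicated(names(object@groups)))
        return("groups must be uniquely named by group id")
    labs <- unique(unlist(lapply(object@groups, names), use.names = FALSE))
    if (!all(labs %in% object@panel))
        return(paste("genome labels outside panel:",
                     paste(setdiff(labs, object@panel), collapse = ", ")))
    genes <- unlist(object@groups, use.names = FALSE)
    if (anyDuplicated(genes))
        return(paste("gene ids present in more than one group, e.g.",
                     genes[anyDuplicated(genes)]))
    TRUE
})

#' Construct an OrthogroupTable
#'
#' @param groups named list: group id -> named list (genome -> character
#'   vector of gene ids).
#' @param panel genome panel labels; defaults to the labels observed in
#'   \code{groups}.
#' @return An \linkS4class{OrthogroupTable}.
#' @examples
#' OrthogroupTable(list(OG1 = list(A = "a1", B = "b1"), OG2 = list(A = "a2")))
#' @export
OrthogroupTable <- function(groups = list(), panel = NULL) {
    if (is.null(panel))
        panel <- unique(unlist(lapply(groups, names), use.names = FALSE))
    if (is.null(panel)) panel <- character(0)
    new("OrthogroupTable", panel = panel, groups = groups)
}

#' @describeIn OrthogroupTable number of orthogroups
#' @param x An OrthogroupTable.
#' @export
setMethod("length", "OrthogroupTable", function(x) length(x@groups))

#' @export
setMethod("show", "OrthogroupTable", function(object) {
    cat("OrthogroupTable:", length(object@groups), "groups over",
        length(object@panel), "genomes\n")
    cat("  panel:", paste(object@panel, collapse = ", "), "\n")
})
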