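#' Read pairwise whole-genome alignment coordinates
#'
#' Parses alignment coordinate files in either the MUMmer
#' \code{show-coords -T} tab dialect or PAF (minimap2). Records are
#' normalized to 0-based half-open reference coordinates; reverse-strand
#' alignments are stored with forward-normalized query coordinates and a
#' \code{"-"} strand flag. File order is preserved.
#'
#' The show-coords tab dialect carries the 1-based inclusive columns
#' \code{S1 E1 S2 E2 LEN1 LEN2 \%IDY REFNAME QRYNAME}; header and banner
#' lines are skipped. For PAF, percent identity is computed as
#' 100 x matches (column 10) / alignment block length (column 11), and the
#' mapping quality column is retained.
#'
#' @param path path to the coordinate file.
#' @param dialect \code{"showcoords_tab"} or \code{"paf"}.
#' @return An \linkS4class{AlignmentSet}.
#' @examples
#' f <- tempfile()
#' writeLines("1\t20000\t1\t19990\t20000\t19990\t99.5\tchr1S\tchr1S", f)
#' readAlignments(f, "showcoords_tab")
#' @seealso \code{\link{writeAlignments}}, \code{\link{filterAlignments}}
#' @export
readAlignments <- function(path, dialect = c("showcoords_tab", "paf")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    switch(dialect,
           showcoords_tab = .parseShowCoords(lines, path),
           paf = .parsePaf(lines, path))
}

.isShowCoordsHeader <- function(line) {
    line == "" || grepl("^\\[", line) || grepl("^NUCMER", line) ||
        grepl("^=+$", line) || grepl("^/", line)
}

.parseShowCoords <- function(lines, path) {
    keep <- !vapply(lines, .isShowCoordsHeader, logical(1), USE.NAMES = FALSE)
    idx <- which(keep)
    rows <- lapply(idx, function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) == 1L) f <- strsplit(lines[i], "[[:space:]]+")[[1]]
        if (length(f) < 9L)
            stop("malformed show-coords line ", i, " in ", path,
                 ": expected 9 tab-separated fields, got ", length(f))
        num <- suppressWarnings(as.numeric(f[1:7]))
        if (anyNA(num))
            stop("malformed show-coords line ", i, " in ", path,
                 ": non-numeric coordinate field")
        list(num = num, ref = f[8], qry = f[9])
    })
    if (length(rows) == 0L) return(AlignmentSet())
    m <- do.call(rbind, lapply(rows, `[[`, "num"))
    s1 <- m[, 1]; e1 <- m[, 2]; s2 <- m[, 3]; e2 <- m[, 4]; idy <- m[, 7]
    if (any(s1 < 1) || any(s1 > e1))
        stop("malformed show-coords line ",
             idx[which(s1 < 1 | s1 > e1)[1]], " in ", path,
             ": negative or inverted reference coordinates")
    if (any(idy < 0 | idy > 100))
        stop("malformed show-coords line ",
             idx[which(idy < 0 | idy > 100)[1]], " in ", path,
             ": percent identity outside [0, 100]")
    rev <- s2 > e2
    AlignmentSet(data.frame(
        ref_chrom = vapply(rows, `[[`, character(1), "ref"),
        ref_start = s1 - 1, ref_end = e1,
        query_chrom = vapply(rows, `[[`, character(1), "qry"),
        query_start = ifelse(rev, e2 - 1, s2 - 1),
        query_end = ifelse(rev, s2, e2),
        strand = ifelse(rev, "-", "+"),
        pct_identity = idy,
        mapq = NA_real_,
        stringsAsFactors = FALSE))
}

.parsePaf <- function(lines, path) {
    lines <- lines[lines != ""]
    if (length(lines) == 0L) return(AlignmentSet())
    rows <- lapply(seq_along(lines), function(i) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 12L)
            stop("malformed PAF line ", i, " in ", path,
                 ": expected >= 12 fields, got ", length(f))
        num <- suppressWarnings(as.numeric(f[c(3, 4, 8, 9, 10, 11, 12)]))
        if (anyNA(num))
            stop("malformed PAF line ", i, " in ", path,
                 ": non-numeric coordinate field")
        if (num[3] < 0 || num[3] >= num[4])
            stop("malformed PAF line ", i, " in ", path,
                 ": negative or inverted reference coordinates")
        if (!f[5] %in% c("+", "-"))
            stop("malformed PAF line ", i, " in ", path,
                 ": strand must be '+' or '-'")
        list(q = f[1], s = f[5], t = f[6], num = num)
    })
    num <- do.call(rbind, lapply(rows, `[[`, "num"))
    AlignmentSet(data.frame(
        ref_chrom = vapply(rows, `[[`, character(1), "t"),
        ref_start = num[, 3], ref_end = num[, 4],
        query_chrom = vapply(rows, `[[`, character(1), "q"),
        query_start = num[, 1], query_end = num[, 2],
        strand = vapply(rows, `[[`, character(1), "s"),
        pct_identity = 100 * num[, 5] / num[, 6],
        mapq = num[, 7],
        stringsAsFactors = FALSE))
}

#' Write alignment records back to a coordinate dialect
#'
#' Inverse of \code{\link{readAlignments}}: emits show-coords tab lines
#' (1-based inclusive, reverse-strand query coordinates swapped back) or
#' PAF lines. PAF output encodes identity as
#' \code{matches = round(identity/100 x ref_span)} over a block length of
#' \code{ref_span}, so PAF identity round-trips only to that resolution;
#' the show-coords dialect round-trips all fields exactly.
#'
#' @param x An \linkS4class{AlignmentSet}.
#' @param path output path.
#' @param dialect \code{"showcoords_tab"} or \code{"paf"}.
#' @return \code{path}, invisibly.
#' @export
writeAlignments <- function(x, path, dialect = c("showcoords_tab", "paf")) {
    dialect <- match.arg(dialect)
    r <- x@records
    lines <- if (nrow(r) == 0L) character(0) else if (dialect == "showcoords_tab") {
        rev <- r$strand == "-"
        s2 <- ifelse(rev, r$query_end, r$query_start + 1)
        e2 <- ifelse(rev, r$query_start + 1, r$query_end)
        paste(format(r$ref_start + 1, scientific = FALSE, trim = TRUE),
              format(r$ref_end, scientific = FALSE, trim = TRUE),
              format(s2, scientific = FALSE, trim = TRUE),
              format(e2, scientific = FALSE, trim = TRUE),
              format(r$ref_span, scientific = FALSE, trim = TRUE),
              format(r$query_end - r$query_start, scientific = FALSE,
                     trim = TRUE),
              sprintf("%.17g", r$pct_identity),
              r$ref_chrom, r$query_chrom, sep = "\t")
    } else {
        mapq <- ifelse(is.na(r$mapq), 60, r$mapq)
        blk <- r$ref_span
        paste(r$query_chrom,
              format(r$query_end, scientific = FALSE, trim = TRUE),
              format(r$query_start, scientific = FALSE, trim = TRUE),
              format(r$query_end, scientific = FALSE, trim = TRUE),
              r$strand, r$ref_chrom,
              format(r$ref_end, scientific = FALSE, trim = TRUE),
              format(r$ref_start, scientific = FALSE, trim = TRUE),
              format(r$ref_end, scientific = FALSE, trim = TRUE),
              format(round(r$pct_identity / 100 * blk), scientific = FALSE,
                     trim = TRUE),
              format(blk, scientific = FALSE, trim = TRUE),
              format(mapq, scientific = FALSE, trim = TRUE), sep = "\t")
    }
    writeLines(lines, path)
    invisible(path)
}

#' Filter alignment records by reference span and mapping quality
#'
#' Keeps records whose reference span is at least \code{minRefSpan} bases
#' and, when \code{minMapq} is given, whose mapping quality is at least
#' \code{minMapq}. Short spurious alignments are removed before haploblock
#' binning with \code{minRefSpan = 20000}; 1-kb window alignments against a
#' reference are typically filtered at \code{minRefSpan = 750, minMapq = 60}.
#' An optional chromosome pairing map drops records whose reference and
#' query chromosomes are not the homologous pair.
#'
#' @param x An \linkS4class{AlignmentSet}.
#' @param minRefSpan minimum reference span in bases (>= 0).
#' @param minMapq minimum mapping quality, or NULL to skip; an error is
#'   raised if requested on records without mapping quality (show-coords
#'   input).
#' @param pairing optional named character vector mapping each reference
#'   chromosome to its expected query chromosome; records on other
#'   chromosome pairs are dropped.
#' @return A filtered \linkS4class{AlignmentSet}, input order preserved.
#' @export
filterAlignments <- function(x, minRefSpan = 0, minMapq = NULL,
                             pairing = NULL) {
    stopifnot(minRefSpan >= 0)
    r <- x@records
    keep <- r$ref_span >= minRefSpan
    if (!is.null(minMapq)) {
        if (anyNA(r$mapq) && nrow(r) > 0)
            stop("minMapq requested but records carry no mapping quality ",
                 "(dialect mismatch)")
        keep <- keep & r$mapq >= minMapq
    }
    if (!is.null(pairing)) {
        expected <- pairing[r$ref_chrom]
        keep <- keep & !is.na(expected) & expected == r$query_chrom
    }
    initialize(x, records = r[keep, , drop = FALSE])
}

#' Write intervals or haploblocks as BED6
#'
#' Writes 0-based half-open BED6 sorted by (chrom, start). For a
#' \linkS4class{HaploblockSet} the score column carries the block median
#' identity times ten, rounded (99.2\% -> 992). For a GRanges the name is
#' taken from \code{names()} or an \code{id}/\code{name} metadata column
#' and the score from a \code{score} column (else 0).
#'
#' @param x A GRanges or \linkS4class{HaploblockSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(x, path) {
    if (is(x, "HaploblockSet")) {
        gr <- x@blocks
        nm <- rep(".", length(gr))
        score <- as.integer(roundHalfUp(mcols(gr)$median_identity * 10))
    } else if (is(x, "GRanges")) {
        gr <- x
        nm <- .featureIds(gr, default_prefix = "")
        nm[nm == ""] <- "."
        score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score
                 else rep(0L, length(gr))
    } else stop("writeBed expects a GRanges or HaploblockSet")
    o <- order(as.character(GenomeInfoDb::seqnames(gr)),
               BiocGenerics::start(gr))
    gr <- gr[o]; nm <- nm[o]; score <- score[o]
    strand <- as.character(BiocGenerics::strand(gr))
    strand[strand == "*"] <- "."
    lines <- paste(as.character(GenomeInfoDb::seqnames(gr)),
                   format(BiocGenerics::start(gr) - 1, scientific = FALSE,
                          trim = TRUE),
                   format(BiocGenerics::end(gr), scientific = FALSE,
                          trim = TRUE),
                   nm, score, strand, sep = "\t")
    tryCatch(writeLines(lines, path),
             error = function(e) stop("cannot write BED to ", path, ": ",
                                      conditionMessage(e)))
    invisible(path)
}

#' Read a BED file as GRanges
#'
#' Thin wrapper over \code{rtracklayer::import} returning a GRanges with
#' BED names carried as \code{names()}.
#'
#' @param path BED3/BED6 file.
#' @return A GRanges.
#' @export
readBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(mcols(gr)$name)) names(gr) <- mcols(gr)$name
    gr
}

#' Read gene features from GFF3
#'
#' Imports a GFF3 file via \code{rtracklayer} and returns the requested
#' feature type with gene ids as \code{names()}.
#'
#' @param path GFF3 file.
#' @param featureType feature type to keep (default \code{"gene"}); NULL
#'   keeps everything.
#' @return A GRanges.
#' @export
readGff3 <- function(path, featureType = "gene") {
    gr <- rtracklayer::import(path, format = "GFF3")
    if (!is.null(featureType))
        gr <- gr[!is.na(mcols(gr)$type) & mcols(gr)$type == featureType]
    if (!is.null(mcols(gr)$ID)) names(gr) <- mcols(gr)$ID
    gr
}

#' Read a chromosome-length table
#'
#' Reads a two-column TSV (chromosome name, length in bases; no header)
#' into a named numeric vector.
#'
#' @param path TSV file.
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromLengths <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           stringsAsFactors = FALSE)
    if (any(d$length <= 0)) stop("chromosome lengths must be positive")
    stats::setNames(as.numeric(d$length), d$chrom)
}

#' Write a chromosome-length table
#'
#' @param lengths named numeric vector.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeChromLengths <- function(lengths, path) {
    writeLines(paste(names(lengths),
                     format(lengths, scientific = FALSE, trim = TRUE),
                     sep = "\t"), path)
    invisible(path)
}
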