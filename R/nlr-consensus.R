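#' Select genes by functional-annotation keywords
#'
#' Returns the genes whose functional description contains any of the
#' keywords as a case-insensitive substring. The default keywords —
#' "Disease", "NBS-LRR", "NB-ARC" — pick out annotated NLR
#' (nucleotide-binding leucine-rich repeat) disease-resistance gene
#' candidates. Duplicate gene ids are removed (first occurrence kept);
#' selection is invariant to input order and description case.
#'
#' @param genes GRanges of gene models; ids from \code{names()} or an
#'   \code{id} metadata column.
#' @param functions functional descriptions: either a named character
#'   vector (gene id -> description) or NULL to use a
#'   \code{description} (or \code{func}) metadata column on \code{genes}.
#'   Genes without a description are never selected.
#' @param keywords character vector of keywords.
#' @return The selected genes as a GRanges with a \code{source =
#'   "annotation"} metadata column.
#' @export
selectFunctionalGenes <- function(genes, functions = NULL,
                                  keywords = c("Disease", "NBS-LRR",
                                               "NB-ARC")) {
    ids <- .featureIds(genes, "gene")
    desc <- if (!is.null(functions)) {
        unname(functions[ids])
    } else if (!is.null(mcols(genes)$description)) {
        mcols(genes)$description
    } else if (!is.null(mcols(genes)$func)) {
        mcols(genes)$func
    } else stop("no functional descriptions: pass `functions` or provide ",
                "a 'description' metadata column")
    desc_lc <- tolower(ifelse(is.na(desc), "", desc))
    hit <- Reduce(`|`, lapply(tolower(keywords), function(k)
        grepl(k, desc_lc, fixed = TRUE)))
    sel <- genes[hit & !duplicated(ids)]
    names(sel) <- ids[hit & !duplicated(ids)]
    mcols(sel)$source <- if (length(sel)) "annotation" else character(0)
    sel
}

#' Consensus NLR loci supported by both prediction routes
#'
#' Keeps the annotated NLR gene models that are confirmed by position:
#' each must overlap at least \code{minOverlap} bases with at least one
#' de novo predicted NLR locus on the same chromosome. Coordinates are
#' half-open at the BED level, so book-ended loci (one ending where the
#' other starts) do not overlap. Strand is ignored by default, since
#' de novo locus strand calls need not agree with gene models.
#'
#' @param denovo GRanges of de novo NLR locus predictions.
#' @param annotated GRanges of annotation-derived NLR gene models (e.g.
#'   from \code{\link{selectFunctionalGenes}}).
#' @param minOverlap minimum overlap in bases (default 1).
#' @param ignoreStrand default TRUE; set FALSE for strict-strand matching.
#' @return The confirmed annotated loci, sorted, each reported once, with
#'   a \code{source = "consensus"} metadata column. A warning is issued
#'   when the two inputs share no chromosome names (likely mixed naming
#'   schemes).
#' @export
consensusNlrs <- function(denovo, annotated, minOverlap = 1,
                          ignoreStrand = TRUE) {
    stopifnot(minOverlap >= 1)
    if (length(denovo) && length(annotated)) {
        shared <- intersect(
            unique(as.character(GenomeInfoDb::seqnames(denovo))),
            unique(as.character(GenomeInfoDb::seqnames(annotated))))
        if (length(shared) == 0L)
            warning("no chromosome names shared between de novo and ",
                    "annotated loci; mixed naming schemes?")
    }
    # our own naming-scheme warning above is the informative one;
    # findOverlaps would repeat it as a seqlevel warning
    hits <- suppressWarnings(
        findOverlaps(annotated, denovo, minoverlap = minOverlap,
                     ignore.strand = ignoreStrand))
    keep <- sort(unique(S4Vectors::queryHits(hits)))
    out <- annotated[keep]
    out <- out[order(as.character(GenomeInfoDb::seqnames(out)),
                     BiocGenerics::start(out))]
    mcols(out)$source <- if (length(out)) "consensus" else character(0)
    out
}

#' Count consensus NLRs per genome and per chromosome
#'
#' @param consensusSets named list (genome label -> GRanges of consensus
#'   NLR loci). Unplaced-scaffold pseudo-chromosomes (chrUn) appear as
#'   their own chromosome rows.
#' @return A list with \code{perGenome} (named integer) and
#'   \code{perChromosome} (data.frame genome, chrom, count).
#' @export
nlrCensus <- function(consensusSets) {
    stopifnot(is.list(consensusSets), !is.null(names(consensusSets)))
    perGenome <- vapply(consensusSets, length, integer(1))
    rows <- lapply(names(consensusSets), function(g) {
        gr <- consensusSets[[g]]
        if (length(gr) == 0L)
            return(data.frame(genome = character(0), chrom = character(0),
                              count = integer(0)))
        t <- table(as.character(GenomeInfoDb::seqnames(gr)))
        data.frame(genome = g, chrom = names(t),
                   count = as.integer(t), stringsAsFactors = FALSE)
    })
    perChromosome <- do.call(rbind, rows)
    rownames(perChromosome) <- NULL
    list(perGenome = perGenome, perChromosome = perChromosome)
}
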