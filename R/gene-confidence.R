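#' Does a best hit qualify as significant evidence?
#'
#' A hit qualifies when its E-value is strictly below \code{evalueMax} and
#' the database-appropriate coverage strictly exceeds \code{covMin}:
#' subject coverage for the protein reference databases (UniMag, UniPoa),
#' query coverage for the transposon database (PTREP). In strict mode
#' (used for the UniMag clause of the high-confidence rule) both subject
#' and query coverage must exceed \code{covMin}.
#'
#' Boundary values fall on the excluded side: an E-value of exactly
#' \code{evalueMax} or a coverage of exactly \code{covMin} does not
#' qualify.
#'
#' @param db \code{"UniMag"}, \code{"UniPoa"} or \code{"PTREP"} (the alias
#'   \code{"TREP"} is accepted for PTREP).
#' @param evalue hit E-value (>= 0); NA means no hit.
#' @param subjectCoverage,queryCoverage percent coverages in [0, 100].
#' @param evalueMax E-value threshold (default 1e-10).
#' @param covMin coverage threshold in percent (default 95).
#' @param strict require both coverages (UniMag high-confidence clause).
#' @return logical.
#' @examples
#' qualifyHit("UniPoa", 1e-12, subjectCoverage = 96)   # TRUE
#' qualifyHit("PTREP", 1e-12, queryCoverage = 94)      # FALSE
#' @export
qualifyHit <- function(db, evalue, subjectCoverage = NA_real_,
                       queryCoverage = NA_real_, evalueMax = 1e-10,
                       covMin = 95, strict = FALSE) {
    db <- match.arg(db, c("UniMag", "UniPoa", "PTREP", "TREP"))
    if (is.na(evalue)) return(FALSE)
    if (!(evalue < evalueMax)) return(FALSE)
    cov_ok <- function(v) !is.na(v) && v > covMin
    if (strict) return(cov_ok(subjectCoverage) && cov_ok(queryCoverage))
    if (db %in% c("PTREP", "TREP")) cov_ok(queryCoverage)
    else cov_ok(subjectCoverage)
}

# vectorized qualified-hit flags from a wide evidence data.frame
.qualFlags <- function(ev, evalueMax, covMin) {
    q <- function(e, cov) !is.na(e) & e < evalueMax & !is.na(cov) &
        cov > covMin
    list(
        M = q(ev$unimag_evalue, ev$unimag_subject_coverage),
        Mstrict = q(ev$unimag_evalue, ev$unimag_subject_coverage) &
            !is.na(ev$unimag_query_coverage) &
            ev$unimag_query_coverage > covMin,
        P = q(ev$unipoa_evalue, ev$unipoa_subject_coverage),
        T = q(ev$ptrep_evalue, ev$ptrep_query_coverage))
}

.classifyFlags <- function(C, M, Mstrict, P, T, hc2RequiresComplete = TRUE) {
    hc2_c <- if (hc2RequiresComplete) C else TRUE
    label <- rep("UNCLASSIFIED", length(C))
    lc <- (!C & (M | P) & !T) | (C & !M & !P & !T)
    label[lc] <- "LC"
    label[!M & C & T] <- "REP"
    label[(C & Mstrict) | (hc2_c & !M & P & !T)] <- "HC"
    label
}

#' Classify one predicted protein into HC/LC/REP/UNCLASSIFIED
#'
#' Rule-based confidence classification from best-hit evidence against
#' three databases. With C = protein complete (start and stop codon
#' present), M = qualified UniMag hit, P = qualified UniPoa hit, T =
#' qualified PTREP hit, the label is, in precedence order:
#' \itemize{
#'   \item HC if (C and a UniMag hit qualifying on \emph{both} subject and
#'     query coverage) or (C and no UniMag hit but a UniPoa hit and no
#'     PTREP hit);
#'   \item REP if no UniMag hit, complete, and a PTREP hit;
#'   \item LC if (incomplete with a UniMag or UniPoa hit and no PTREP hit)
#'     or (complete with no hit in any database);
#'   \item UNCLASSIFIED otherwise.
#' }
#' Unqualified hits count as no hit.
#'
#' @param complete logical: start and stop codon present.
#' @param uniMag,uniPoa,ptrep each NULL (no hit) or a list with elements
#'   \code{evalue}, \code{subject_coverage}, \code{query_coverage}
#'   (missing coverages may be NA).
#' @param evalueMax,covMin qualification thresholds (defaults 1e-10, 95).
#' @param hc2RequiresComplete whether the UniPoa high-confidence clause
#'   also requires completeness (default TRUE).
#' @return \code{"HC"}, \code{"LC"}, \code{"REP"} or \code{"UNCLASSIFIED"}.
#' @export
classifyProtein <- function(complete, uniMag = NULL, uniPoa = NULL,
                            ptrep = NULL, evalueMax = 1e-10, covMin = 95,
                            hc2RequiresComplete = TRUE) {
    g <- function(h, f) if (is.null(h) || is.null(h[[f]])) NA_real_
                        else h[[f]]
    ev <- data.frame(
        unimag_evalue = g(uniMag, "evalue"),
        unimag_subject_coverage = g(uniMag, "subject_coverage"),
        unimag_query_coverage = g(uniMag, "query_coverage"),
        unipoa_evalue = g(uniPoa, "evalue"),
        unipoa_subject_coverage = g(uniPoa, "subject_coverage"),
        ptrep_evalue = g(ptrep, "evalue"),
        ptrep_query_coverage = g(ptrep, "query_coverage"))
    f <- .qualFlags(ev, evalueMax, covMin)
    .classifyFlags(complete, f$M, f$Mstrict, f$P, f$T, hc2RequiresComplete)
}

#' Classify a table of protein evidence
#'
#' Batch wrapper over the confidence rules. The evidence table has one row
#' per protein with columns \code{protein_id}, \code{complete} and, per
#' database, best-hit metrics (\code{unimag_evalue},
#' \code{unimag_subject_coverage}, \code{unimag_query_coverage},
#' \code{unipoa_evalue}, \code{unipoa_subject_coverage},
#' \code{ptrep_evalue}, \code{ptrep_query_coverage}); NA marks an absent
#' hit. Labels are independent of row order.
#'
#' @param evidence the evidence data.frame (see above); duplicate protein
#'   ids are an error.
#' @param evalueMax,covMin,hc2RequiresComplete as in
#'   \code{\link{classifyProtein}}.
#' @return A list with \code{labels} (data.frame \code{protein_id},
#'   \code{label}) and \code{counts} (named integer over HC, LC, REP,
#'   UNCLASSIFIED, summing to the number of proteins).
#' @export
classifyAll <- function(evidence, evalueMax = 1e-10, covMin = 95,
                        hc2RequiresComplete = TRUE) {
    if (anyDuplicated(evidence$protein_id))
        stop("duplicate protein ids: ",
             paste(unique(evidence$protein_id[
                 duplicated(evidence$protein_id)]), collapse = ", "))
    for (col in c("unimag_evalue", "unimag_subject_coverage",
                  "unimag_query_coverage", "unipoa_evalue",
                  "unipoa_subject_coverage", "ptrep_evalue",
                  "ptrep_query_coverage"))
        if (is.null(evidence[[col]])) evidence[[col]] <- NA_real_
    f <- .qualFlags(evidence, evalueMax, covMin)
    label <- .classifyFlags(as.logical(evidence$complete), f$M, f$Mstrict,
                            f$P, f$T, hc2RequiresComplete)
    lv <- c("HC", "LC", "REP", "UNCLASSIFIED")
    counts <- table(factor(label, levels = lv))
    list(labels = data.frame(protein_id = evidence$protein_id,
                             label = label, stringsAsFactors = FALSE),
         counts = stats::setNames(as.integer(counts), lv))
}

#' Read a merged protein-evidence TSV
#'
#' Reads the wide evidence layout consumed by \code{\link{classifyAll}}:
#' tab-separated with a header, columns \code{protein_id},
#' \code{complete} (TRUE/FALSE or 1/0) and the seven per-database hit
#' metric columns; empty fields or NA mark absent hits.
#'
#' @param path TSV file.
#' @return The evidence data.frame.
#' @export
readProteinEvidence <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
    d$complete <- as.logical(d$complete)
    d
}

#' Write protein confidence labels
#'
#' @param labels the \code{labels} data.frame from
#'   \code{\link{classifyAll}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeConfidenceLabels <- function(labels, path) {
    utils::write.table(labels, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
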