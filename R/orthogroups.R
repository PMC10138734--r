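#' Read an orthogroup membership table
#'
#' Reads the tab-separated layout emitted by orthology-inference tools:
#' header row with the group-id column followed by one column per genome,
#' one row per orthogroup, cells holding comma(-space)-separated gene ids
#' (empty cell = no member).
#'
#' @param path TSV file.
#' @return An \linkS4class{OrthogroupTable} whose panel is the header's
#'   genome columns in order.
#' @export
readOrthogroupTable <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "", na.strings = NULL)
    if (ncol(d) < 2) stop("orthogroup table needs a group-id column plus ",
                          "at least one genome column")
    panel <- colnames(d)[-1]
    groups <- lapply(seq_len(nrow(d)), function(i) {
        row <- lapply(panel, function(g) {
            cell <- d[i, g]
            if (is.na(cell) || cell == "") character(0)
            else strsplit(cell, ",[[:space:]]*")[[1]]
        })
        names(row) <- panel
        row[lengths(row) > 0]
    })
    names(groups) <- d[[1]]
    OrthogroupTable(groups = groups, panel = panel)
}

#' Write an orthogroup table
#'
#' Inverse of \code{\link{readOrthogroupTable}} (gene lists joined with
#' ", ").
#'
#' @param x An \linkS4class{OrthogroupTable}.
#' @param path output TSV path.
#' @param idColumn name of the group-id column (default "Orthogroup").
#' @return \code{path}, invisibly.
#' @export
writeOrthogroupTable <- function(x, path, idColumn = "Orthogroup") {
    panel <- x@panel
    body <- vapply(names(x@groups), function(gid) {
        cells <- vapply(panel, function(g) {
            v <- x@groups[[gid]][[g]]
            if (is.null(v)) "" else paste(v, collapse = ", ")
        }, character(1))
        paste(c(gid, cells), collapse = "\t")
    }, character(1))
    writeLines(c(paste(c(idColumn, panel), collapse = "\t"), body), path)
    invisible(path)
}

# groups x panel gene-count matrix
.countMatrix <- function(x) {
    panel <- x@panel
    m <- matrix(0L, nrow = length(x@groups), ncol = length(panel),
                dimnames = list(names(x@groups), panel))
    for (i in seq_along(x@groups)) {
        g <- x@groups[[i]]
        if (length(g)) m[i, names(g)] <- lengths(g)
    }
    m
}

#' Split polyploid genomes of an orthogroup table into subgenomes
#'
#' Reassigns the genes of designated polyploid panel members to subgenome
#' labels according to gene-id patterns, so that each subgenome can be
#' treated as a separate panel member downstream (e.g. bread wheat ABD ->
#' three diploid-like columns). Gene counts are conserved.
#'
#' @param x An \linkS4class{OrthogroupTable}.
#' @param rules named list: genome label to split -> named character
#'   vector whose names are regular expressions matched against gene ids
#'   and whose values are the replacement subgenome labels. Every gene of
#'   a split genome must match exactly one pattern; offenders are listed
#'   in the error.
#' @return A new \linkS4class{OrthogroupTable} with the expanded panel
#'   (subgenome labels replace the split genome, in rule order).
#' @examples
#' tbl <- OrthogroupTable(list(OG1 = list(
#'     CS = c("TraesCS2B02G046000.1", "TraesCS2D02G045000.1"))),
#'     panel = "CS")
#' splitSubgenomes(tbl, list(CS = c(
#'     "^TraesCS\\dA" = "CS_A", "^TraesCS\\dB" = "CS_B",
#'     "^TraesCS\\dD" = "CS_D")))
#' @export
splitSubgenomes <- function(x, rules) {
    stopifnot(is.list(rules), !is.null(names(rules)))
    unknown <- setdiff(names(rules), x@panel)
    if (length(unknown))
        stop("rules name genomes outside the panel: ",
             paste(unknown, collapse = ", "))
    newPanel <- unlist(lapply(x@panel, function(g) {
        if (g %in% names(rules)) unique(unname(rules[[g]])) else g
    }), use.names = FALSE)
    offenders <- character(0)
    groups <- lapply(x@groups, function(grp) {
        out <- list()
        for (g in names(grp)) {
            if (!g %in% names(rules)) {
                out[[g]] <- c(out[[g]], grp[[g]])
                next
            }
            pats <- names(rules[[g]])
            for (gene in grp[[g]]) {
                m <- vapply(pats, function(p) grepl(p, gene), logical(1))
                if (sum(m) != 1L) {
                    offenders <<- c(offenders, gene)
                    next
                }
                lab <- rules[[g]][[which(m)]]
                out[[lab]] <- c(out[[lab]], gene)
            }
        }
        out
    })
    if (length(offenders))
        stop("gene ids not matching exactly one split rule: ",
             paste(utils::head(offenders, 10), collapse = ", "),
             if (length(offenders) > 10) sprintf(" (and %d more)",
                                                 length(offenders) - 10))
    OrthogroupTable(groups = groups, panel = newPanel)
}

#' Count orthogroups shared exclusively by a genome set
#'
#' Number of orthogroups with at least one gene in \emph{every} genome of
#' \code{genomeSet} and no gene in any other panel genome — the bar
#' heights of an upset plot.
#'
#' @param x An \linkS4class{OrthogroupTable}.
#' @param genomeSet character vector of panel labels.
#' @return Integer count.
#' @export
exclusiveSharedCount <- function(x, genomeSet) {
    unknown <- setdiff(genomeSet, x@panel)
    if (length(unknown))
        stop("unknown genome label(s): ", paste(unknown, collapse = ", "))
    m <- .countMatrix(x) > 0
    inset <- colnames(m) %in% genomeSet
    sum(apply(m, 1, function(r) all(r[inset]) && !any(r[!inset])))
}

#' Exclusive-sharing (upset) counts over all realized combinations
#'
#' For every genome combination that occurs in the table, the number of
#' orthogroups whose members come from exactly that combination.
#' Combinations are keyed by their labels in panel order joined with
#' \code{"+"}; zero-count combinations are omitted, and the counts sum to
#' the number of orthogroups.
#'
#' @param x An \linkS4class{OrthogroupTable}.
#' @return Named integer vector (combination -> count).
#' @export
upsetCounts <- function(x) {
    m <- .countMatrix(x) > 0
    if (nrow(m) == 0L) return(stats::setNames(integer(0), character(0)))
    keys <- apply(m, 1, function(r) paste(colnames(m)[r], collapse = "+"))
    t <- table(keys[keys != ""])
    stats::setNames(as.integer(t), names(t))
}

#' Single-copy orthogroups over a panel
#'
#' Orthogroups with exactly one gene in every genome of \code{panel}. In
#' strict mode (default) a gene in any non-panel genome disqualifies the
#' group; with \code{strict = FALSE} non-panel membership is ignored.
#'
#' @param x An \linkS4class{OrthogroupTable}.
#' @param panel character vector of panel labels (default: the table's
#'   whole panel).
#' @param strict disallow genes outside \code{panel} (default TRUE).
#' @return Character vector of group ids.
#' @export
singleCopyGroups <- function(x, panel = genomePanel(x), strict = TRUE) {
    unknown <- setdiff(panel, x@panel)
    if (length(unknown))
        stop("unknown genome label(s): ", paste(unknown, collapse = ", "))
    m <- .countMatrix(x)
    inset <- colnames(m) %in% panel
    ok <- apply(m, 1, function(r)
        all(r[inset] == 1L) && (!strict || all(r[!inset] == 0L)))
    rownames(m)[ok]
}

#' Species-specific orthogroup counts
#'
#' Per panel genome, the number of orthogroups whose genes come from that
#' genome alone (the singleton exclusive-sharing counts).
#'
#' @param x An \linkS4class{OrthogroupTable}.
#' @return Named integer vector over the full panel (zeros included).
#' @export
speciesSpecificGroups <- function(x) {
    m <- .countMatrix(x) > 0
    if (nrow(m) == 0L)
        return(stats::setNames(integer(length(x@panel)), x@panel))
    single <- rowSums(m) == 1L
    counts <- colSums(m[single, , drop = FALSE])
    stats::setNames(as.integer(counts), colnames(m))[x@panel]
}
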