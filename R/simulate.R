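#' Configuration for the alignment simulator
#'
#' Builds the configuration consumed by \code{\link{simulateAlignments}}
#' and \code{\link{simulateGenomePair}}. Defaults describe a desk-scale
#' version of a chromosome-level nucmer comparison between two closely
#' related diploid genomes: alignments of ~40 kb tiling each chromosome
#' with small gaps, identities set by planted haplotype tracts plus
#' Gaussian noise, and a fraction of short decoy alignments below the
#' 20-kb length filter.
#'
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param tracts data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{target_identity} (percent),
#'   optional \code{label}; tracts on a chromosome must be disjoint.
#' @param alnMeanLen mean alignment length in bases (default 40000).
#' @param alnLenJitter half-width of the uniform length jitter (default
#'   10000).
#' @param alnGap mean gap between successive alignments (default 5000).
#' @param noiseSd standard deviation of the Gaussian identity noise, in
#'   percent (default 0.1).
#' @param decoyFrac fraction of additional sub-filter-length decoy
#'   alignments (default 0.1).
#' @param decoyMaxLen maximum decoy length (default 19999, i.e. strictly
#'   below the default length filter).
#' @param backgroundIdentity identity assigned outside any tract (default
#'   90).
#' @param seed integer seed.
#' @return A list of class \code{"simConfig"}.
#' @export
simConfig <- function(chromLengths, tracts,
                      alnMeanLen = 40000, alnLenJitter = 10000,
                      alnGap = 5000, noiseSd = 0.1, decoyFrac = 0.1,
                      decoyMaxLen = 19999, backgroundIdentity = 90,
                      seed = 1L) {
    stopifnot(is.numeric(chromLengths), !is.null(names(chromLengths)),
              all(chromLengths > 0), is.data.frame(tracts))
    need <- c("chrom", "start", "end", "target_identity")
    if (!all(need %in% colnames(tracts)))
        stop("tracts need columns: ", paste(need, collapse = ", "))
    if (any(tracts$target_identity < 0 | tracts$target_identity > 100))
        stop("target_identity outside [0, 100]")
    for (chrom in unique(tracts$chrom)) {
        t <- tracts[tracts$chrom == chrom, , drop = FALSE]
        t <- t[order(t$start), , drop = FALSE]
        if (any(t$start >= t$end) ||
            (nrow(t) > 1 && any(t$start[-1] < t$end[-nrow(t)])))
            stop("tracts on ", chrom, " must be disjoint, non-empty ",
                 "intervals")
    }
    structure(list(chromLengths = chromLengths, tracts = tracts,
                   alnMeanLen = alnMeanLen, alnLenJitter = alnLenJitter,
                   alnGap = alnGap, noiseSd = noiseSd,
                   decoyFrac = decoyFrac, decoyMaxLen = decoyMaxLen,
                   backgroundIdentity = backgroundIdentity,
                   seed = as.integer(seed)),
              class = "simConfig")
}

.tractIdentity <- function(config, chrom, mid) {
    t <- config$tracts
    hit <- t$chrom == chrom & t$start <= mid & mid < t$end
    if (any(hit)) t$target_identity[which(hit)[1]]
    else config$backgroundIdentity
}

#' Simulate whole-genome alignment records with known tract truth
#'
#' Tiles each chromosome left to right with alignments of configured mean
#' length and gap; each alignment's percent identity is the target
#' identity of the tract containing its reference midpoint (or the
#' background identity outside all tracts) plus Gaussian noise, clipped to
#' [0, 100]. A configured fraction of decoy alignments shorter than the
#' length filter is appended. Deterministic under the config's seed; the
#' surrounding RNG state is left untouched.
#'
#' @param config a \code{\link{simConfig}}.
#' @return A list with \code{alignments} (an
#'   \linkS4class{AlignmentSet}) and \code{truth} (the tract data.frame).
#' @export
simulateAlignments <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    withStream(config$seed, "alignments", {
        rows <- list()
        for (chrom in names(config$chromLengths)) {
            L <- config$chromLengths[[chrom]]
            pos <- 0
            while (pos < L - 1) {
                len <- round(stats::runif(1,
                                          config$alnMeanLen - config$alnLenJitter,
                                          config$alnMeanLen + config$alnLenJitter))
                len <- max(2, min(len, L - pos))
                end <- pos + len
                mid <- floor((pos + end) / 2)
                idy <- .tractIdentity(config, chrom, mid) +
                    stats::rnorm(1, 0, config$noiseSd)
                rows[[length(rows) + 1L]] <- data.frame(
                    ref_chrom = chrom, ref_start = pos, ref_end = end,
                    query_chrom = chrom, query_start = pos,
                    query_end = end, strand = "+",
                    pct_identity = min(100, max(0, idy)),
                    mapq = NA_real_, stringsAsFactors = FALSE)
                pos <- end + round(stats::runif(1, 0, 2 * config$alnGap))
            }
        }
        n_main <- length(rows)
        n_decoy <- round(config$decoyFrac * n_main)
        for (k in seq_len(n_decoy)) {
            chrom <- sample(names(config$chromLengths), 1)
            L <- config$chromLengths[[chrom]]
            len <- round(stats::runif(1, 500, config$decoyMaxLen))
            start <- floor(stats::runif(1, 0, L - len))
            rows[[length(rows) + 1L]] <- data.frame(
                ref_chrom = chrom, ref_start = start,
                ref_end = start + len, query_chrom = chrom,
                query_start = start, query_end = start + len,
                strand = "+",
                pct_identity = stats::runif(1, 80, 100), mapq = NA_real_,
                stringsAsFactors = FALSE)
        }
        aln <- if (length(rows)) AlignmentSet(do.call(rbind, rows))
               else AlignmentSet()
        list(alignments = aln, truth = config$tracts)
    })
}

#' Simulate a diverged genome pair as sequences
#'
#' Generates a random reference genome at the configured chromosome
#' lengths and a query genome that is the reference with, inside each
#' tract, substitutions applied at rate (100 - target_identity)/100 at
#' uniformly random positions (sequence outside tracts is untouched).
#' Intended as a small end-to-end fixture into which an external aligner
#' can be slotted; chromosome lengths should stay at desk scale (<= 1e7).
#'
#' @param config a \code{\link{simConfig}}.
#' @return A list with \code{reference} and \code{query}
#'   (\link[Biostrings]{DNAStringSet}) and \code{truth} (GRanges of the
#'   tracts with a \code{target_identity} column).
#' @export
simulateGenomePair <- function(config) {
    stopifnot(inherits(config, "simConfig"),
              all(config$chromLengths <= 1e7))
    withStream(config$seed, "genomes", {
        bases <- c("A", "C", "G", "T")
        ref <- lapply(config$chromLengths, function(L)
            paste(sample(bases, L, replace = TRUE), collapse = ""))
        qry <- ref
        t <- config$tracts
        for (i in seq_len(nrow(t))) {
            chrom <- t$chrom[i]
            s <- t$start[i]; e <- t$end[i]
            p <- (100 - t$target_identity[i]) / 100
            width <- e - s
            n_sub <- stats::rbinom(1, width, p)
            if (n_sub == 0) next
            pos <- sample.int(width, n_sub) + s   # 1-based positions s+1..e
            chars <- strsplit(substr(qry[[chrom]], s + 1, e), "")[[1]]
            idx <- pos - s
            chars[idx] <- vapply(chars[idx], function(b)
                sample(setdiff(bases, b), 1), character(1))
            qry[[chrom]] <- paste0(substr(qry[[chrom]], 1, s),
                                   paste(chars, collapse = ""),
                                   substr(qry[[chrom]], e + 1,
                                          nchar(qry[[chrom]])))
        }
        truth <- GRanges(t$chrom, IRanges(t$start + 1, t$end),
                         target_identity = t$target_identity)
        list(reference = Biostrings::DNAStringSet(unlist(ref)),
             query = Biostrings::DNAStringSet(unlist(qry)),
             truth = truth)
    })
}

#' Simulate an orthogroup table with planted sharing structure
#'
#' Generates orthogroups whose exclusive genome combinations and counts
#' are given exactly, so that downstream set algebra has a known truth.
#'
#' @param panel character vector of genome labels.
#' @param combos data.frame with columns \code{genomes} (labels joined
#'   with "+"), \code{n} (number of groups to plant), and optional
#'   \code{minCopies}/\code{maxCopies} (per-genome gene-copy range,
#'   default 1-2; use 1-1 to plant single-copy groups).
#' @param seed integer seed.
#' @return A list with \code{table} (an \linkS4class{OrthogroupTable})
#'   and \code{truth} (the combos data.frame).
#' @examples
#' sim <- simulateOrthogroupTable(c("A", "B", "C"),
#'     data.frame(genomes = c("A+B", "A"), n = c(5, 2)), seed = 7)
#' exclusiveSharedCount(sim$table, c("A", "B"))  # 5
#' @export
simulateOrthogroupTable <- function(panel, combos, seed = 1L) {
    stopifnot(is.character(panel), is.data.frame(combos))
    if (nrow(combos) == 0L)
        return(list(table = OrthogroupTable(panel = panel), truth = combos))
    if (is.null(combos$minCopies)) combos$minCopies <- 1L
    if (is.null(combos$maxCopies)) combos$maxCopies <- 2L
    withStream(seed, "orthogroups", {
        groups <- list()
        counter <- 0L
        gene_counter <- stats::setNames(integer(length(panel)), panel)
        for (i in seq_len(nrow(combos))) {
            members <- strsplit(combos$genomes[i], "+", fixed = TRUE)[[1]]
            if (!all(members %in% panel))
                stop("combination references genomes outside the panel: ",
                     combos$genomes[i])
            for (k in seq_len(combos$n[i])) {
                counter <- counter + 1L
                grp <- lapply(members, function(g) {
                    rng <- combos$minCopies[i]:combos$maxCopies[i]
                    nc <- rng[sample.int(length(rng), 1)]
                    ids <- sprintf("%s_g%06d", g,
                                   gene_counter[[g]] + seq_len(nc))
                    gene_counter[[g]] <<- gene_counter[[g]] + nc
                    ids
                })
                names(grp) <- members
                groups[[sprintf("OG%07d", counter)]] <- grp
            }
        }
        list(table = OrthogroupTable(groups = groups, panel = panel),
             truth = combos)
    })
}

# the 16 (complete, M, P, T) combinations and their labels under the
# default rules; M means a UniMag hit qualifying on both coverages
.truthTable <- function(hc2RequiresComplete = TRUE) {
    g <- expand.grid(C = c(FALSE, TRUE), M = c(FALSE, TRUE),
                     P = c(FALSE, TRUE), T = c(FALSE, TRUE))
    g$label <- .classifyFlags(g$C, g$M, g$M, g$P, g$T, hc2RequiresComplete)
    g
}

#' Simulate protein hit evidence with known confidence labels
#'
#' Samples truth labels from \code{labelMix}, picks for each protein a
#' (complete, UniMag, UniPoa, PTREP) qualified-hit combination consistent
#' with its label, and draws hit metrics on the correct side of the
#' thresholds: qualified hits get E-values well below 1e-10 and coverages
#' strictly above 95; disqualified evidence is either an absent hit or a
#' hit failing on E-value or coverage (for UniMag, both coverages fail
#' together, keeping the four-flag truth table exact).
#'
#' @param n number of proteins.
#' @param labelMix named numeric vector of label proportions over HC, LC,
#'   REP, UNCLASSIFIED (default roughly the mix seen in annotation runs,
#'   HC-heavy).
#' @param seed integer seed.
#' @return A list with \code{evidence} (wide data.frame for
#'   \code{\link{classifyAll}}) and \code{truth} (data.frame
#'   \code{protein_id}, \code{label}).
#' @export
simulateProteinEvidence <- function(n,
                                    labelMix = c(HC = 0.45, LC = 0.3,
                                                 REP = 0.15,
                                                 UNCLASSIFIED = 0.1),
                                    seed = 1L) {
    tt <- .truthTable()
    lv <- c("HC", "LC", "REP", "UNCLASSIFIED")
    stopifnot(all(names(labelMix) %in% lv))
    if (n == 0L)
        return(list(evidence = data.frame(protein_id = character(0),
                                          complete = logical(0)),
                    truth = data.frame(protein_id = character(0),
                                       label = character(0))))
    withStream(seed, "evidence", {
        labels <- sample(names(labelMix), n, replace = TRUE,
                         prob = labelMix)
        combo <- vapply(labels, function(l) {
            rows <- which(tt$label == l)
            rows[sample.int(length(rows), 1)]
        }, integer(1))
        good_e <- function(k) 10^stats::runif(k, -50, -15)
        good_c <- function(k) stats::runif(k, 95.5, 100)
        # disqualified: absent hit, or present with bad evalue/coverage
        badHit <- function() {
            if (stats::runif(1) < 0.5) return(c(NA, NA, NA))
            if (stats::runif(1) < 0.5)
                c(10^stats::runif(1, -9, -1), good_c(1), good_c(1))
            else c(good_e(1), stats::runif(1, 40, 94.5),
                   stats::runif(1, 40, 94.5))
        }
        mk <- function(flag) t(vapply(flag, function(f) {
            if (f) c(good_e(1), good_c(1), good_c(1)) else badHit()
        }, numeric(3)))
        M <- mk(tt$M[combo]); P <- mk(tt$P[combo]); T <- mk(tt$T[combo])
        ev <- data.frame(
            protein_id = sprintf("prot%06d", seq_len(n)),
            complete = tt$C[combo],
            unimag_evalue = M[, 1], unimag_subject_coverage = M[, 2],
            unimag_query_coverage = M[, 3],
            unipoa_evalue = P[, 1], unipoa_subject_coverage = P[, 2],
            ptrep_evalue = T[, 1], ptrep_query_coverage = T[, 3],
            stringsAsFactors = FALSE)
        list(evidence = ev,
             truth = data.frame(protein_id = ev$protein_id, label = labels,
                                stringsAsFactors = FALSE))
    })
}

#' Simulate paired NLR prediction tracks with planted overlap
#'
#' Places annotated NLR gene models in evenly spaced slots along each
#' chromosome; a configured fraction receive an overlapping de novo
#' locus, and decoy de novo loci are placed in the inter-slot gaps so
#' they are guaranteed not to touch any gene model. The truth is the set
#' of gene ids with a planted overlap.
#'
#' @param nAnnotated number of annotated gene models (default 200).
#' @param overlapFraction fraction with a planted de novo overlap
#'   (default 0.5).
#' @param decoyFraction de novo decoys as a fraction of
#'   \code{nAnnotated} (default 0.3).
#' @param chromLengths named numeric vector (default one 1e7 chromosome).
#' @param seed integer seed.
#' @return A list with \code{denovo} (GRanges), \code{annotated}
#'   (GRanges, named by gene id) and \code{truth} (character vector of
#'   overlapped gene ids).
#' @export
simulateNlrTracks <- function(nAnnotated = 200, overlapFraction = 0.5,
                              decoyFraction = 0.3,
                              chromLengths = c(chr1S = 1e7), seed = 1L) {
    stopifnot(nAnnotated >= 0, overlapFraction >= 0, overlapFraction <= 1)
    withStream(seed, "nlr", {
        chroms <- rep(names(chromLengths), length.out = max(nAnnotated, 1))
        slot <- floor(min(chromLengths) /
                      (ceiling(nAnnotated / length(chromLengths)) + 1))
        slot <- max(slot, 40L)
        ann <- list(); dn <- list(); truth <- character(0)
        idx_on <- stats::setNames(integer(length(chromLengths)),
                                  names(chromLengths))
        overlapped <- if (nAnnotated)
            sample(c(rep(TRUE, round(overlapFraction * nAnnotated)),
                     rep(FALSE, nAnnotated -
                             round(overlapFraction * nAnnotated))))
            else logical(0)
        for (i in seq_len(nAnnotated)) {
            chrom <- chroms[i]
            idx_on[[chrom]] <- idx_on[[chrom]] + 1L
            base <- (idx_on[[chrom]] - 1L) * slot
            gene_w <- round(stats::runif(1, slot * 0.2, slot * 0.4))
            gs <- base + round(slot * 0.1)
            id <- sprintf("gene%05d", i)
            ann[[i]] <- data.frame(chrom = chrom, start = gs,
                                   end = gs + gene_w, id = id)
            if (overlapped[i]) {
                # de novo locus overlapping the gene by >= 1 bp
                off <- round(stats::runif(1, -gene_w * 0.5, gene_w * 0.5))
                ds <- max(base, gs + off)
                de <- min(base + slot - 1, ds + gene_w)
                dn[[length(dn) + 1L]] <- data.frame(chrom = chrom,
                                                    start = ds, end = de)
                truth <- c(truth, id)
            } else if (stats::runif(1) < decoyFraction) {
                # decoy strictly inside the slot's tail gap, book-ended at
                # worst (half-open: zero overlap)
                gap_s <- gs + gene_w
                gap_e <- base + slot
                if (gap_e - gap_s >= 20) {
                    ds <- gap_s + round(stats::runif(1, 0,
                                                     (gap_e - gap_s) / 2))
                    dn[[length(dn) + 1L]] <- data.frame(
                        chrom = chrom, start = ds,
                        end = min(gap_e, ds + 100))
                }
            }
        }
        mkGr <- function(rows, withId = FALSE) {
            if (!length(rows)) return(GRanges())
            d <- do.call(rbind, rows)
            gr <- GRanges(d$chrom, IRanges(d$start + 1, d$end))
            if (withId) names(gr) <- d$id
            gr
        }
        list(denovo = mkGr(dn), annotated = mkGr(ann, withId = TRUE),
             truth = sort(truth))
    })
}
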