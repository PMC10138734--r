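test_that("alignments land in the bin containing their reference midpoint", {
    cl <- c(chr1 = 5e7)
    a <- mkAln("chr1", c(0, 4999000), c(20000, 5021000), c(99, 98))
    bins <- binAlignments(a, 5e6, cl)
    expect_equal(nrow(bins), 10)            # all bins present
    expect_equal(bins$identities[[1]], 99)  # midpoint 10,000 -> bin 0
    expect_equal(bins$identities[[2]], 98)  # midpoint 5,010,000 -> bin 1
    expect_equal(sum(bins$n), 2)
    # a midpoint beyond the chromosome length is a table inconsistency
    bad <- mkAln("chr1", 4.9e7, 5.2e7, 99)
    expect_error(binAlignments(bad, 5e6, cl), "beyond chromosome length")
})

test_that("per-bin identity counts equal a brute-force midpoint histogram", {
    withr::local_seed(23)
    cl <- c(chr1 = 5e7)
    n <- 500
    start <- floor(runif(n, 0, 4.9e7))
    len <- floor(runif(n, 1000, 1e6))
    end <- pmin(start + len, 5e7)
    idy <- runif(n, 85, 100)
    a <- mkAln("chr1", start, end, idy)
    bins <- binAlignments(a, 5e6, cl)
    ob <- o_bin(start, end, idy, 5e6, 5e7)
    for (i in seq_len(nrow(bins))) {
        expect_equal(sort(bins$identities[[i]]),
                     sort(if (is.null(ob[[i]])) numeric(0) else ob[[i]]))
    }
})

test_that("bin medians are unweighted, half-up rounded, NA when empty", {
    expect_equal(binMedian(c(99.1, 99.3, 99.5)), 99.3)
    expect_equal(binMedian(numeric(0)), NA_real_)
    expect_equal(binMedian(c(99.124, 99.126)), 99.13)  # mean of pair, half-up
    expect_equal(binMedian(c(1.005), 2), 1.01)         # half-up, not banker's
    withr::local_seed(7)
    for (k in seq_len(10000)) {
        v <- runif(sample.int(9, 1), 80, 100)
        expect_identical(binMedian(v, 2), o_round(o_median(v), 2))
    }
})

test_that("the documented bin-median pattern yields the documented blocks", {
    # medians [99.2, 99.2, 98.7, NA, 99.2], identical-median mode, cutoff 99
    a <- alnFromBinMedians(c(99.2, 99.2, 98.7, NA, 99.2))
    p <- HaploblockParams(binSize = 1e6, minAlnLen = 1e5,
                          identityCutoff = 99)
    hb <- callHaploblocks(a, p, c(chr1 = 5e6))
    b <- blocks(hb)
    expect_equal(length(b), 2)
    expect_equal(BiocGenerics::start(b) - 1, c(0, 4e6))
    expect_equal(BiocGenerics::end(b), c(2e6, 5e6))
    expect_equal(S4Vectors::mcols(b)$median_identity, c(99.2, 99.2))
    expect_equal(S4Vectors::mcols(b)$n_bins, c(2L, 1L))
    # no alignments -> a valid empty set, not an error
    empty <- callHaploblocks(AlignmentSet(), p, c(chr1 = 5e6))
    expect_s4_class(empty, "HaploblockSet")
    expect_equal(length(empty), 0)
    expect_error(HaploblockParams(mergeMode = "no_such_mode"),
                 "unknown merge mode")
})

test_that("both merge modes equal explicit run enumeration on random instances", {
    withr::local_seed(41)
    bin_size <- 1e6
    for (rep in seq_len(60)) {
        n_bins <- sample.int(20, 1)
        chrom_len <- n_bins * bin_size - sample(c(0, 12345), 1)
        n <- sample.int(120, 1)
        start <- floor(runif(n, 0, chrom_len - 30000))
        end <- start + floor(runif(n, 5000, 30000))
        end <- pmin(end, chrom_len)
        df <- data.frame(ref_start = start, ref_end = end,
                         pct_identity = round(runif(n, 90, 100),
                                              sample(0:2, 1)))
        a <- mkAln("chr1", df$ref_start, df$ref_end, df$pct_identity)
        for (mode in c("identical_median", "threshold")) {
            cutoff <- sample(c(92, 95, 99), 1)
            p <- HaploblockParams(binSize = bin_size, minAlnLen = 20000,
                                  identityCutoff = cutoff,
                                  mergeMode = mode)
            got <- blocks(callHaploblocks(a, p,
                                          c(chr1 = chrom_len)))
            want <- o_call_blocks(df, bin_size, chrom_len, 20000,
                                  cutoff, mode)
            expect_equal(length(got), nrow(want),
                         info = sprintf("rep %d mode %s", rep, mode))
            if (nrow(want)) {
                expect_equal(BiocGenerics::start(got) - 1, want$start)
                expect_equal(BiocGenerics::end(got), want$end)
                expect_equal(S4Vectors::mcols(got)$median_identity,
                             want$median)
                expect_equal(S4Vectors::mcols(got)$n_bins, want$n_bins)
            }
        }
    }
})

test_that("genome coverage is block length over genome length", {
    p <- HaploblockParams()
    gr <- mkGr("chr1", 0, 5e6)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        median_identity = 99, n_bins = 1L, n_alignments = 1L)
    hb <- HaploblockSet(gr, params = p, chromLengths = c(chr1 = 5e7))
    expect_equal(genomeCoverage(hb), 10.0)
    expect_equal(genomeCoverage(
        HaploblockSet(chromLengths = c(chr1 = 5e7))), 0.0)
    expect_error(genomeCoverage(hb, c(chr1 = 4e6)), "beyond")
})

test_that("random disjoint blocks cover what a base bitmap counts", {
    withr::local_seed(3)
    chrom_len <- 1e5
    for (rep in 1:20) {
        bl <- r_disjoint_blocks(sample.int(15, 1), chrom_len)
        gr <- mkGr("chr1", bl$start, bl$end)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            median_identity = 99, n_bins = 1L,
            n_alignments = 1L)
        hb <- HaploblockSet(gr, params = HaploblockParams(),
                            chromLengths = c(chr1 = chrom_len))
        bm <- o_bitmap(bl$start, bl$end, chrom_len)
        expect_equal(genomeCoverage(hb), 100 * sum(bm) / chrom_len)
        # a partition (blocks plus complement) covers 100%
        comp <- GenomicRanges::setdiff(
            mkGr("chr1", 0, chrom_len), gr)
        expect_equal(genomeCoverage(hb) +
                     100 * sum(BiocGenerics::width(comp)) / chrom_len,
                     100)
    }
})

test_that("block summaries recompute count and length statistics", {
    p <- HaploblockParams()
    gr <- mkGr(c("chr1", "chr2"), c(0, 0), c(5e6, 15e6))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        median_identity = c(99, 98), n_bins = c(1L, 3L),
        n_alignments = c(5L, 9L))
    hb <- HaploblockSet(gr, params = p,
                        chromLengths = c(chr1 = 2e7, chr2 = 2e7))
    s <- blockSummary(hb)
    expect_equal(s$count, 2)
    expect_equal(s$meanLength, 1e7)
    expect_equal(s$minLength, 5e6)
    expect_equal(s$maxLength, 1.5e7)
    empty <- blockSummary(HaploblockSet(chromLengths = c(chr1 = 1e6)))
    expect_equal(empty$count, 0)
    expect_true(is.na(empty$meanLength))
    withr::local_seed(17)
    bl <- r_disjoint_blocks(100, 1e7)
    gr2 <- mkGr("chr1", bl$start, bl$end)
    S4Vectors::mcols(gr2) <- S4Vectors::DataFrame(
        median_identity = 99, n_bins = 1L, n_alignments = 1L)
    s2 <- blockSummary(HaploblockSet(gr2, params = p,
                                     chromLengths = c(chr1 = 1e7)))
    expect_equal(s2$meanLength, mean(bl$end - bl$start))
})

test_that("multi-set intersection equals a per-base AND over a bitmap", {
    mkSet <- function(bl, qry, chrom_len) {
        gr <- mkGr("chr1", bl$start, bl$end)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            median_identity = round(runif(nrow(bl), 95, 100), 2),
            n_bins = 1L, n_alignments = 1L)
        HaploblockSet(gr, "refG", qry, HaploblockParams(),
                      c(chr1 = chrom_len))
    }
    # documented two-set example
    a <- mkSet(data.frame(start = 0, end = 10e6), "A", 2e7)
    b <- mkSet(data.frame(start = 5e6, end = 15e6), "B", 2e7)
    got <- intersectHaploblockSets(list(a, b))
    expect_equal(BiocGenerics::start(got) - 1, 5e6)
    expect_equal(BiocGenerics::end(got), 10e6)
    # any empty set -> empty intersection
    e <- HaploblockSet(referenceGenome = "refG",
                       chromLengths = c(chr1 = 2e7))
    expect_equal(length(intersectHaploblockSets(list(a, e))), 0)
    # mismatched reference labels are an error
    c2 <- mkSet(data.frame(start = 0, end = 1e6), "C", 2e7)
    c2@referenceGenome <- "otherRef"
    expect_error(intersectHaploblockSets(list(a, c2)), "reference")
    # three random sets against the bitmap oracle
    withr::local_seed(29)
    chrom_len <- 1e5
    for (rep in 1:10) {
        sets <- lapply(1:3, function(i)
            mkSet(r_disjoint_blocks(sample.int(12, 1), chrom_len),
                  paste0("q", i), chrom_len))
        got <- intersectHaploblockSets(sets)
        bms <- lapply(sets, function(s) {
            b <- blocks(s)
            o_bitmap(BiocGenerics::start(b) - 1, BiocGenerics::end(b),
                     chrom_len)
        })
        want <- Reduce(`&`, bms)
        gotbm <- if (length(got))
            o_bitmap(BiocGenerics::start(got) - 1,
                     BiocGenerics::end(got), chrom_len)
            else logical(chrom_len)
        expect_identical(gotbm, want)
    }
})

test_that("features associate with the block of largest overlap, ties leftmost", {
    p <- HaploblockParams()
    gr <- mkGr("chr1", c(0, 5e6), c(5e6, 9e6))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        median_identity = c(99.2, 98.5), n_bins = 1L, n_alignments = 1L)
    hb <- HaploblockSet(gr, params = p, chromLengths = c(chr1 = 1e7))
    feats <- mkGr("chr1", c(4.9e6, 9.5e6, 4.8e6), c(5.1e6, 9.9e6, 5.2e6),
                  ids = c("fA", "fB", "fTie"))
    got <- associateIntervals(hb, feats)
    expect_equal(got$block_start[got$feature_id == "fA"], 0)   # 0.1 Mb each
    expect_true(is.na(got$block_chrom[got$feature_id == "fB"]))
    # fTie overlaps both blocks 0.2 Mb -> leftmost wins
    expect_equal(got$block_start[got$feature_id == "fTie"], 0)
})

test_that("association agrees with a quadratic overlap scan", {
    withr::local_seed(67)
    chrom_len <- 1e6
    bl <- r_disjoint_blocks(40, chrom_len)
    gr <- mkGr("chr1", bl$start, bl$end)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        median_identity = round(runif(40, 95, 100), 2),
        n_bins = 1L, n_alignments = 1L)
    hb <- HaploblockSet(gr, params = HaploblockParams(),
                        chromLengths = c(chr1 = chrom_len))
    n <- 200
    fs <- floor(runif(n, 0, chrom_len - 5000))
    fe <- fs + floor(runif(n, 1, 5000))
    feats <- mkGr("chr1", fs, fe, ids = sprintf("f%03d", seq_len(n)))
    got <- associateIntervals(hb, feats)
    best <- o_best_overlap(rep("chr1", n), fs, fe,
                           rep("chr1", 40), bl$start, bl$end)
    expect_equal(is.na(got$block_chrom), is.na(best))
    hit <- !is.na(best)
    expect_equal(got$block_start[hit], bl$start[best[hit]])
    expect_equal(got$block_end[hit], bl$end[best[hit]])
})

test_that("called blocks stay disjoint, sorted, bin-aligned and in bounds", {
    withr::local_seed(59)
    for (rep in 1:15) {
        cl <- c(chrA = 37e6, chrB = 24e6)
        n <- 300
        chrom <- sample(names(cl), n, replace = TRUE)
        start <- floor(runif(n, 0, cl[chrom] - 50000))
        end <- start + floor(runif(n, 10000, 50000))
        a <- mkAln(chrom, start, pmin(end, cl[chrom]),
                   round(runif(n, 93, 100), 1))
        p <- HaploblockParams(identityCutoff = sample(c(94, 96), 1),
                              mergeMode = sample(c("identical_median",
                                                   "threshold"), 1))
        hb <- callHaploblocks(a, p, cl)
        expect_true(validObject(hb))   # sortedness/disjointness/bounds
        b <- blocks(hb)
        if (length(b)) {
            s0 <- BiocGenerics::start(b) - 1
            expect_true(all(s0 %% p@binSize == 0))
            e0 <- BiocGenerics::end(b)
            lens <- cl[as.character(GenomeInfoDb::seqnames(b))]
            expect_true(all(e0 %% p@binSize == 0 | e0 == lens))
        }
    }
})

test_that("coverage and retention respond monotonically to their parameters", {
    withr::local_seed(101)
    cl <- c(chr1 = 5e7)
    for (rep in 1:10) {
        n <- 400
        start <- floor(runif(n, 0, 4.95e7))
        a <- mkAln("chr1", start,
                   pmin(start + floor(runif(n, 5000, 60000)), 5e7),
                   round(runif(n, 90, 100), 1))
        # retained alignments non-increasing in the length filter
        spans <- c(0, 10000, 20000, 40000)
        kept <- vapply(spans, function(s)
            length(filterAlignments(a, s)), integer(1))
        expect_true(all(diff(kept) <= 0))
        # coverage non-increasing in the identity cutoff (threshold mode)
        covs <- vapply(c(90, 93, 96, 99), function(cut)
            genomeCoverage(callHaploblocks(
                a, HaploblockParams(identityCutoff = cut,
                                    mergeMode = "threshold"), cl)),
            numeric(1))
        expect_true(all(diff(covs) <= 1e-9))
    }
})
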