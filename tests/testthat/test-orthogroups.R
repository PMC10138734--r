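test_that("orthogroup tables round-trip through the standard TSV layout", {
    tbl <- OrthogroupTable(list(
        OG0000001 = list(A = c("A_g1", "A_g2"), B = "B_g1"),
        OG0000002 = list(C = "C_g1"),
        OG0000003 = list(A = "A_g3", B = "B_g2", C = "C_g2")),
        panel = c("A", "B", "C"))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeOrthogroupTable(tbl, f)
    back <- readOrthogroupTable(f)
    expect_identical(genomePanel(back), c("A", "B", "C"))
    expect_identical(orthogroups(back), orthogroups(tbl))
    # gene ids may appear in only one group
    expect_error(OrthogroupTable(list(g1 = list(A = "x"),
                                      g2 = list(B = "x"))),
                 "more than one group")
})

test_that("exclusive sharing counts groups confined to exactly the given set", {
    tbl <- OrthogroupTable(list(g1 = list(A = "x", B = "y"),
                                g2 = list(A = "z")),
                           panel = c("A", "B"))
    expect_equal(exclusiveSharedCount(tbl, c("A", "B")), 1)
    expect_equal(exclusiveSharedCount(tbl, "A"), 1)
    expect_equal(exclusiveSharedCount(tbl, "B"), 0)
    expect_error(exclusiveSharedCount(tbl, "Z"), "unknown")
    # a full-panel set on a table where every group spans all genomes
    all3 <- OrthogroupTable(lapply(setNames(nm = sprintf("og%d", 1:7)),
                                   function(i) list(A = paste0(i, "a"),
                                                    B = paste0(i, "b"))),
                            panel = c("A", "B"))
    expect_equal(exclusiveSharedCount(all3, c("A", "B")), 7)
})

test_that("exclusive counts over all subsets match brute force and sum to total", {
    withr::local_seed(47)
    panel <- LETTERS[1:6]
    for (rep in 1:5) {
        n <- 80
        memb <- lapply(seq_len(n), function(i)
            sort(sample(panel, sample.int(6, 1))))
        groups <- lapply(seq_len(n), function(i) {
            g <- lapply(memb[[i]], function(l)
                sprintf("%s_r%d_%d_%d", l, rep, i,
                        seq_len(sample.int(3, 1))))
            names(g) <- memb[[i]]
            g
        })
        names(groups) <- sprintf("OG%04d", seq_len(n))
        tbl <- OrthogroupTable(groups, panel = panel)
        # all 63 non-empty subsets against independent set algebra
        total <- 0
        for (k in 1:6) {
            for (ss in utils::combn(panel, k, simplify = FALSE)) {
                want <- o_exclusive_count(memb, ss, panel)
                expect_equal(exclusiveSharedCount(tbl, ss), want)
                total <- total + want
            }
        }
        expect_equal(total, n)
        # upset counts cover the same partition
        uc <- upsetCounts(tbl)
        expect_equal(sum(uc), n)
        for (key in names(uc)) {
            expect_equal(uc[[key]],
                         o_exclusive_count(memb,
                                           strsplit(key, "+",
                                                    fixed = TRUE)[[1]],
                                           panel))
        }
    }
})

test_that("upset counts handle degenerate tables", {
    one <- OrthogroupTable(list(g1 = list(A = "a1")), panel = c("A", "B"))
    expect_equal(upsetCounts(one), c(A = 1L))
    two <- OrthogroupTable(list(g1 = list(A = "a1"),
                                g2 = list(B = "b1")),
                           panel = c("A", "B"))
    expect_equal(sort(names(upsetCounts(two))), c("A", "B"))
    expect_equal(unname(upsetCounts(two)), c(1L, 1L))
    expect_equal(length(upsetCounts(OrthogroupTable(panel = "A"))), 0)
})

test_that("single-copy orthogroups require exactly one gene per panel genome", {
    tbl <- OrthogroupTable(list(
        sc = list(A = "a1", B = "b1", C = "c1"),
        multi = list(A = c("a2", "a3"), B = "b2", C = "c2"),
        partial = list(A = "a4", B = "b4"),
        outside = list(A = "a5", B = "b5", C = "c5", D = "d1")),
        panel = c("A", "B", "C", "D"))
    expect_identical(singleCopyGroups(tbl, c("A", "B", "C")), "sc")
    # non-strict mode tolerates genes outside the panel
    expect_setequal(singleCopyGroups(tbl, c("A", "B", "C"),
                                     strict = FALSE),
                    c("sc", "outside"))
})

test_that("planted single-copy groups are recovered exactly", {
    combos <- data.frame(
        genomes = c("A+B+C", "A+B+C", "A+B", "A"),
        n = c(12, 9, 5, 3),
        minCopies = c(1, 2, 1, 1),
        maxCopies = c(1, 3, 1, 2))
    sim <- simulateOrthogroupTable(c("A", "B", "C"), combos, seed = 55)
    got <- singleCopyGroups(sim$table, c("A", "B", "C"))
    expect_equal(length(got), 12)   # only the copies == 1 full-panel combo
    expect_equal(exclusiveSharedCount(sim$table, c("A", "B")), 5)
    expect_equal(sum(upsetCounts(sim$table)), sum(combos$n))
})

test_that("species-specific counts are the singleton exclusive counts", {
    tbl <- OrthogroupTable(list(g1 = list(A = "a1"),
                                g2 = list(A = "a2"),
                                g3 = list(B = "b1"),
                                g4 = list(A = "a3", B = "b2")),
                           panel = c("A", "B", "C"))
    expect_equal(speciesSpecificGroups(tbl),
                 c(A = 2L, B = 1L, C = 0L))
    withr::local_seed(61)
    sim <- simulateOrthogroupTable(
        c("A", "B", "C"),
        data.frame(genomes = c("A", "B", "A+B", "A+B+C"),
                   n = c(7, 4, 3, 2)), seed = 66)
    got <- speciesSpecificGroups(sim$table)
    expect_equal(got, c(A = 7L, B = 4L, C = 0L))
    for (g in c("A", "B", "C"))
        expect_equal(got[[g]], exclusiveSharedCount(sim$table, g))
})

test_that("subgenome splitting reassigns by pattern and conserves genes", {
    tbl <- OrthogroupTable(list(
        OG1 = list(CS = c("TraesCS2B02G046000.1", "TraesCS2D02G045000.1"),
                   lon = "lon_g1"),
        OG2 = list(CS = "TraesCS5A02G001000.1")),
        panel = c("CS", "lon"))
    rules <- list(CS = c("^TraesCS\\dA" = "CS_A", "^TraesCS\\dB" = "CS_B",
                         "^TraesCS\\dD" = "CS_D"))
    out <- splitSubgenomes(tbl, rules)
    expect_setequal(genomePanel(out), c("CS_A", "CS_B", "CS_D", "lon"))
    expect_equal(orthogroups(out)$OG1$CS_B, "TraesCS2B02G046000.1")
    expect_equal(orthogroups(out)$OG1$CS_D, "TraesCS2D02G045000.1")
    expect_equal(orthogroups(out)$OG1$lon, "lon_g1")
    # gene counts conserved
    nGenes <- function(x) length(unlist(orthogroups(x)))
    expect_equal(nGenes(out), nGenes(tbl))
    # unmatched ids are listed
    bad <- OrthogroupTable(list(OG1 = list(CS = "weird.1")), panel = "CS")
    expect_error(splitSubgenomes(bad, rules), "weird.1")
    # empty table passes through
    expect_equal(length(splitSubgenomes(OrthogroupTable(panel = "CS"),
                                        rules)), 0)
    # the shipped wheat rule file covers CS and WEW gene-id grammars
    shipped <- lapply(yaml::read_yaml(
        system.file("extdata", "wheat_split_rules.yaml",
                    package = "haploblocks")), unlist)
    tblW <- OrthogroupTable(list(
        OG1 = list(CS = "TraesCS2B02G046000.1",
                   WEW = "TRIDC2BG001000.1")),
        panel = c("CS", "WEW"))
    outW <- splitSubgenomes(tblW, shipped)
    expect_equal(orthogroups(outW)$OG1$CS_B, "TraesCS2B02G046000.1")
    expect_equal(orthogroups(outW)$OG1$WEW_B, "TRIDC2BG001000.1")
})

test_that("counts are invariant to row and gene-list ordering", {
    sim <- simulateOrthogroupTable(
        c("A", "B", "C", "D"),
        data.frame(genomes = c("A+B", "C+D", "A+B+C+D", "B"),
                   n = c(4, 3, 5, 2)), seed = 99)
    tbl <- sim$table
    g <- orthogroups(tbl)
    perm <- OrthogroupTable(rev(lapply(g, function(x) rev(x))),
                            panel = genomePanel(tbl))
    expect_equal(upsetCounts(perm), upsetCounts(tbl))
    expect_setequal(singleCopyGroups(perm), singleCopyGroups(tbl))
})
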