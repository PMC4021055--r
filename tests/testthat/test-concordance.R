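test_that("venn partition reconciles event counts with constituent call counts", {
    ## three loci, each called once by each of four programs: the four-way
    ## subset holds 3 events but 12 calls
    programs <- c("AGC", "GH", "PC", "PGS")
    sets <- CNVCallSetList(lapply(programs, function(p)
        mkSet("S", p, c(1e4, 5e5, 2e6), c(2e4 - 1, 6e5 - 1, 21e5 - 1))))
    v <- vennPartition(buildEventGroups(sets))
    expect_identical(nrow(v), 1L)
    expect_identical(v$programSet, "AGC+GH+PC+PGS")
    expect_identical(v$eventGroups, 3L)
    expect_identical(v$calls, 12L)
    expect_identical(attr(v, "totalCalls"), 12L)
})

test_that("venn partition is a partition of total post-merge calls", {
    sets <- CNVCallSetList(list(
        mkSet("S", "PC", c(1000, 90000), c(1999, 99999)),
        mkSet("S", "AGC", 1000, 1999),
        mkSet("S", "GH", 500000, 599999)))
    v <- vennPartition(buildEventGroups(sets))
    expect_identical(sum(v$calls), attr(v, "totalCalls"))
    expect_identical(attr(v, "totalCalls"), 4L)
    expect_setequal(v$programSet, c("AGC+PC", "PC", "GH"))
    ## PC participates in two subsets; a singleton group stays its own
    expect_identical(v$eventGroups[v$programSet == "GH"], 1L)
    expect_true(all(v$calls >= v$eventGroups))
})

test_that("empty input yields an empty partition with zero total", {
    v <- vennPartition(buildEventGroups(CNVCallSetList(list())))
    expect_identical(nrow(v), 0L)
    expect_identical(attr(v, "totalCalls"), 0L)
})

test_that("the d statistic counts unshared over total calls", {
    ## A has 3 calls, B has 2, one matched pair -> d = 3/5
    a <- CNVCallSet("A", "P", mkCalls(c(1000, 50000, 200000),
                                      c(1999, 59999, 209999)))
    b <- CNVCallSet("B", "P", mkCalls(c(1000, 800000), c(1999, 809999)))
    st <- pairwiseDifference(a, b)
    expect_identical(st$shared_pairs, 1L)
    expect_identical(st$unshared, 3L)
    expect_identical(st$total, 5L)
    expect_equal(st$d, 0.6)

    ## identical call sets -> d = 0; disjoint -> d = 1
    expect_equal(pairwiseDifference(a, CNVCallSet("B", "P", cnvCalls(a)))$d, 0)
    disjoint <- CNVCallSet("B", "P", mkCalls(9e6, 9e6 + 999))
    expect_equal(pairwiseDifference(a, disjoint)$d, 1)

    ## d is symmetric
    expect_equal(pairwiseDifference(b, a)$d, st$d)

    empty <- CNVCallSet("A", "P")
    expect_error(pairwiseDifference(empty, CNVCallSet("B", "P")),
                 "d is undefined")
})

test_that("d stays within [0, 1] and hits the bounds exactly when expected", {
    set.seed(21)
    for (r in 1:30) {
        a <- randomCallSet(sample.int(15L, 1), "A", "P")
        b <- randomCallSet(sample.int(15L, 1), "B", "P")
        st <- pairwiseDifference(a, b)
        expect_gte(st$d, 0)
        expect_lte(st$d, 1)
        if (st$shared_pairs == 0L) expect_equal(st$d, 1)
        if (st$d == 0) expect_identical(2L * st$shared_pairs, st$total)
    }
})

test_that("group summaries report mean, sample sd and sem per relation and program", {
    pairs <- validatePairs(data.frame(
        sample_a = c("T1a", "T2a", "T3a"),
        sample_b = c("T1b", "T2b", "T3b"),
        relation = "MZ", stringsAsFactors = FALSE))
    stats <- data.frame(sample_a = pairs$sample_a, sample_b = pairs$sample_b,
                        program_id = "PC", d = c(0.1, 0.2, 0.3),
                        stringsAsFactors = FALSE)
    gs <- groupDifferenceSummary(stats, pairs)
    expect_identical(gs$n_pairs, 3L)
    expect_equal(gs$mean_d, 0.2)
    expect_equal(gs$sd_d, 0.1)
    expect_equal(gs$sem_d, 0.1 / sqrt(3), tolerance = 1e-6)

    ## single pair: dispersion undefined, flagged by n_pairs
    solo <- groupDifferenceSummary(stats[1, ], pairs[1, ])
    expect_identical(solo$n_pairs, 1L)
    expect_true(is.na(solo$sd_d))

    ## undeclared pair is an error; empty relation group warns
    expect_error(groupDifferenceSummary(
        data.frame(sample_a = "X", sample_b = "Y", program_id = "PC", d = 0.5),
        pairs), "no declared relation")
    pairs2 <- rbind(pairs, validatePairs(data.frame(
        sample_a = "U1", sample_b = "U2", relation = "unrelated")))
    expect_warning(groupDifferenceSummary(stats, pairs2),
                   "no difference statistics .* unrelated")
})

test_that("size bins are right-closed and counts sum to the input", {
    cs <- CNVCallSet("S", "P", mkCalls(
        c(1e6, 3e6, 5e6, 8e6, 12e6),
        c(1e6 + 49999, 3e6 + 99999, 5e6 + 999999, 8e6 + 1e7 - 1, 12e6 + 500)))
    tab <- sizeDistribution(cs)
    expect_identical(sum(tab), 5L)
    counts <- as.vector(tab[, "P"])
    ## 50 kb and exactly 100 kb both land in (1 kb, 100 kb]; 1 Mb in the
    ## second bin; 10 Mb in the third; 501 bp in the underflow bin
    expect_identical(counts, c(1L, 2L, 1L, 1L, 0L))
    expect_error(sizeDistribution(cs, binEdges = c(1e5, 1e3)),
                 "strictly increasing")
    expect_identical(sum(sizeDistribution(CNVCallSetList(list()))), 0L)
})

test_that("chromosome distribution counts per autosome per program", {
    sets <- CNVCallSetList(list(
        CNVCallSet("S", "P1", mkCalls(c(1, 200, 400, 600, 800),
                                      c(100, 300, 500, 700, 900),
                                      chrom = c("1", "1", "1", "1", "1"))),
        CNVCallSet("S", "P2", mkCalls(c(1, 200, 400), c(100, 300, 500),
                                      chrom = c("2", "2", "2")))))
    tab <- chromosomeDistribution(sets)
    expect_identical(dim(tab), c(22L, 2L))
    expect_identical(tab["1", "P1"], 5L)
    expect_identical(tab["2", "P2"], 3L)
    expect_identical(sum(tab), 8L)
    empty <- chromosomeDistribution(CNVCallSetList(list()))
    expect_identical(nrow(empty), 22L)
})
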