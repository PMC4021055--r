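test_that("overlap length uses inclusive coordinates and respects chromosomes", {
    expect_identical(overlapLength(GRanges("1", IRanges(100, 199)),
                                   GRanges("1", IRanges(150, 249))), 50L)
    expect_identical(overlapLength(GRanges("1", IRanges(100, 199)),
                                   GRanges("1", IRanges(300, 400))), 0L)
    expect_identical(overlapLength(GRanges("1", IRanges(100, 199)),
                                   GRanges("1", IRanges(100, 199))), 100L)
    expect_identical(overlapLength(GRanges("1", IRanges(100, 199)),
                                   GRanges("2", IRanges(100, 199))), 0L)
})

test_that("reciprocal overlap passes at the inclusive 50% boundary with matching status", {
    x <- GRanges("1", IRanges(100, 199), state = 1L)
    y <- GRanges("1", IRanges(150, 249), state = 1L)
    ro <- reciprocalOverlap(x, y)
    expect_equal(ro$oA, 0.5)
    expect_equal(ro$oB, 0.5)
    expect_true(ro$passes)

    ## asymmetric nesting fails: the big call is barely covered
    nest <- reciprocalOverlap(GRanges("1", IRanges(100, 199), state = 1L),
                              GRanges("1", IRanges(1, 1000), state = 1L))
    expect_equal(nest$oA, 1.0)
    expect_equal(nest$oB, 0.1)
    expect_false(nest$passes)

    ## identity passes; status mismatch vetoes even perfect overlap
    expect_true(reciprocalOverlap(x, x)$passes)
    flip <- reciprocalOverlap(GRanges("1", IRanges(100, 199), state = 3L),
                              GRanges("1", IRanges(100, 199), state = 1L))
    expect_equal(c(flip$oA, flip$oB), c(1, 1))
    expect_false(flip$passes)
})

test_that("reciprocal overlap is symmetric with swapped fractions", {
    set.seed(7)
    for (r in 1:50) {
        x <- mkCalls(s <- sample.int(1e5, 1), s + sample.int(1e4, 1),
                     state = sample(c(1L, 3L), 1))
        y <- mkCalls(s2 <- sample.int(1e5, 1), s2 + sample.int(1e4, 1),
                     state = sample(c(1L, 3L), 1))
        a <- reciprocalOverlap(x, y)
        b <- reciprocalOverlap(y, x)
        expect_identical(a$passes, b$passes)
        expect_equal(a$oA, b$oB)
        expect_equal(a$oB, b$oA)
        expect_equal(reciprocalOverlap(x, x)$oA, 1)
    }
})

test_that("indexed candidate generation agrees with the exhaustive oracle", {
    set.seed(11)
    for (r in 1:50) {
        grA <- cnvCalls(randomCallSet())
        grB <- cnvCalls(randomCallSet())
        got <- roPairs(grA, grB)
        expect_true(samePairs(got, roOracle(grA, grB)))
        self <- roPairs(grA)
        expect_true(samePairs(self, roOracle(grA)))
    }
})

test_that("event groups are connected components, not cliques", {
    ## a-b pass, b-c pass, a-c fail -> one group of three
    a <- mkSet("S", "P1", 100, 199)
    b <- mkSet("S", "P2", 150, 249)
    cc <- mkSet("S", "P3", 200, 299)
    eg <- buildEventGroups(CNVCallSetList(list(a, b, cc)))
    expect_identical(nGroups(eg), 1L)
    tab <- eventTable(eg)
    expect_identical(tab$nCalls, 3L)
    expect_identical(tab$programs, "P1+P2+P3")
    ## sanity: a and c alone do not pass
    expect_false(reciprocalOverlap(cnvCalls(a), cnvCalls(cc))$passes)
})

test_that("event grouping partitions calls and handles full agreement and isolates", {
    four <- CNVCallSetList(lapply(paste0("P", 1:4), function(p)
        mkSet("S", p, 10000, 19999)))
    eg <- buildEventGroups(four)
    expect_identical(nGroups(eg), 1L)
    expect_identical(eventTable(eg)$programs, "P1+P2+P3+P4")

    apart <- CNVCallSetList(list(mkSet("S", "P1", 1000, 1999),
                                 mkSet("S", "P2", 50000, 59999)))
    eg2 <- buildEventGroups(apart)
    expect_identical(nGroups(eg2), 2L)
    ## partition property: every call in exactly one group
    expect_identical(sort(unique(mcols(eg2@calls)$groupId)), 1:2)
    expect_identical(length(eg2@calls), 2L)
})

test_that("pairwise matching is one-to-one and maximum cardinality", {
    ## one call against two passing candidates: exactly one pair, the
    ## better min(O_a, O_b)
    a <- mkSet("A", "P", 1000, 1999)
    b <- CNVCallSet("B", "P", mkCalls(c(1000, 1400), c(1999, 2399)))
    m <- matchPairwise(a, b)
    expect_identical(nrow(m), 1L)
    expect_identical(m$bIdx, 1L)   # perfect overlap beats the 60% one

    ## 2x2 with candidates (a1,b1),(a1,b2),(a2,b2): matching of size 2
    a2 <- CNVCallSet("A", "P", mkCalls(c(1000, 1800), c(1999, 2799)))
    b2 <- CNVCallSet("B", "P", mkCalls(c(1000, 1500), c(1999, 2499)))
    cand <- roPairs(cnvCalls(a2), cnvCalls(b2))
    expect_identical(nrow(cand), 3L)
    m2 <- matchPairwise(a2, b2)
    expect_identical(nrow(m2), 2L)
    expect_identical(m2$aIdx, 1:2)
    expect_identical(m2$bIdx, 1:2)
})

test_that("matching cardinality equals the brute-force maximum on small instances", {
    set.seed(13)
    for (r in 1:40) {
        a <- randomCallSet(sample.int(8L, 1L), "A", "P", maxPos = 5e4,
                           chroms = "1")
        b <- randomCallSet(sample.int(8L, 1L), "B", "P", maxPos = 5e4,
                           chroms = "1")
        cand <- roPairs(cnvCalls(a), cnvCalls(b))
        m <- matchPairwise(a, b)
        expect_identical(nrow(m), bruteMaxMatching(cand, length(a)))
        expect_false(anyDuplicated(m$aIdx) > 0)
        expect_false(anyDuplicated(m$bIdx) > 0)
    }
})

test_that("cross-program matching between individuals is refused", {
    expect_error(matchPairwise(mkSet("A", "PC", 1, 100),
                               mkSet("B", "AGC", 1, 100)),
                 "within one program")
})
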