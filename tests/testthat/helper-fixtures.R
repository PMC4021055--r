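suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

## single-chromosome GRanges shorthand for call construction
mkCalls <- function(s, e, state = 1L, chrom = "1", nMarkers = 10L) {
    GRanges(chrom, IRanges(s, e), state = as.integer(state),
            nMarkers = as.integer(nMarkers))
}

mkSet <- function(sample, program, s, e, state = 1L, chrom = "1",
                  nMarkers = 10L) {
    CNVCallSet(sample, program, mkCalls(s, e, state, chrom, nMarkers))
}

## random call set for merge/overlap property tests: sorted construction is
## handled by CNVCallSet itself
randomCallSet <- function(n = NULL, sample = "S", program = "P",
                          maxPos = 1e6, chroms = c("1", "2", "3")) {
    if (is.null(n)) n <- sample.int(30L, 1L)
    s <- sample.int(maxPos, n, replace = TRUE)
    w <- sample(100:50000, n, replace = TRUE)
    CNVCallSet(sample, program,
               GRanges(sample(chroms, n, replace = TRUE),
                       IRanges(s, s + w - 1L),
                       state = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
                       nMarkers = 10L))
}

## exhaustive all-pairs reciprocal-overlap oracle, independent of the
## findOverlaps-based candidate generation: dense outer() arithmetic
roOracle <- function(grA, grB = NULL, threshold = 0.5) {
    self <- is.null(grB)
    if (self) grB <- grA
    sA <- start(grA); eA <- end(grA); sB <- start(grB); eB <- end(grB)
    ov <- outer(eA, eB, pmin) - outer(sA, sB, pmax) + 1L
    chromEq <- outer(as.character(seqnames(grA)),
                     as.character(seqnames(grB)), "==")
    statusEq <- outer(mcols(grA)$status, mcols(grB)$status, "==")
    oA <- ov / width(grA)
    oB <- t(t(ov) / width(grB))
    pass <- chromEq & statusEq & ov > 0 & oA >= threshold & oB >= threshold
    idx <- which(pass, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1L], j = idx[, 2L])
    if (self) df <- df[df$i < df$j, , drop = FALSE]
    df <- df[order(df$i, df$j), , drop = FALSE]
    rownames(df) <- NULL
    df
}

## order-insensitive to row names: same (i, j) pair list?
samePairs <- function(got, want) {
    nrow(got) == nrow(want) && all(got$i == want$i) && all(got$j == want$j)
}

## brute-force maximum-cardinality bipartite matching over candidate pairs
bruteMaxMatching <- function(pairs, nA) {
    best <- 0L
    recurse <- function(ai, usedB, count) {
        if (ai > nA) {
            best <<- max(best, count)
            return(invisible(NULL))
        }
        recurse(ai + 1L, usedB, count)
        for (b in pairs$j[pairs$i == ai])
            if (!b %in% usedB) recurse(ai + 1L, c(usedB, b), count + 1L)
    }
    recurse(1L, integer(), 0L)
    best
}

callTruthFrame <- function(gr) {
    data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
               end = end(gr), status = mcols(gr)$status,
               locusId = mcols(gr)$locusId, stringsAsFactors = FALSE)
}

## pedigree of n independent twin families: two founder parents, one child
## and the child's MZ co-twin each
familyPedigree <- function(n) {
    do.call(rbind, lapply(seq_len(n), function(i) data.frame(
        id = paste0(c("F", "M", "C", "D"), i),
        father = c(NA, NA, paste0("F", i), NA),
        mother = c(NA, NA, paste0("M", i), NA),
        twinOf = c(NA, NA, NA, paste0("C", i)),
        stringsAsFactors = FALSE)))
}

callFrame <- function(cs) {
    gr <- cnvCalls(cs)
    data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
               end = end(gr), state = mcols(gr)$state,
               status = mcols(gr)$status, mergedFrom = mcols(gr)$mergedFrom,
               stringsAsFactors = FALSE)
}

## shared property checks for mergeAdjacent, reused by the acceptance
## suite at larger replicate counts; returns a named logical vector so
## callers can aggregate over many replicates with few expectations
mergePropertyFlags <- function(cs, maxGapFraction = 0.2) {
    m <- mergeAdjacent(cs, maxGapFraction)
    grIn <- cnvCalls(cs); grOut <- cnvCalls(m)
    df <- callFrame(m)
    ## fixed point: consecutive same-status survivors never satisfy the
    ## merge criteria pairwise
    fixedPoint <- TRUE
    if (nrow(df) > 1L) {
        i <- seq_len(nrow(df) - 1L); j <- i + 1L
        samePair <- df$chrom[i] == df$chrom[j] & df$status[i] == df$status[j]
        frac <- (df$start[j] - df$end[i] - 1) / (df$end[j] - df$start[i] + 1)
        fixedPoint <- all(!samePair |
                          (df$end[i] < df$start[j] & frac > maxGapFraction))
    }
    c(conserved = sum(mcols(grOut)$mergedFrom) == sum(mcols(grIn)$mergedFrom),
      covered = all(GenomicRanges::countOverlaps(grIn, grOut, type = "within") >= 1L),
      boundariesFromInput = all(start(grOut) %in% start(grIn)) &&
          all(end(grOut) %in% end(grIn)),
      idempotent = identical(callFrame(mergeAdjacent(m, maxGapFraction)), df),
      fixedPoint = fixedPoint)
}

checkMergeProperties <- function(cs, maxGapFraction = 0.2) {
    flags <- mergePropertyFlags(cs, maxGapFraction)
    expect_true(all(flags), label = paste0(
        "merge properties [", paste(names(flags)[!flags], collapse = ", "),
        " failed]"))
}
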