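#' Base pairs of overlap between two calls
#'
#' On 1-based inclusive coordinates the overlap length is
#' `max(0, min(ends) - max(starts) + 1)` when the calls share a chromosome,
#' and 0 otherwise.
#'
#' @param x,y single-call `GRanges` (length 1).
#' @return integer overlap length in bp.
#' @export
#' @examples
#' overlapLength(GenomicRanges::GRanges("1", IRanges::IRanges(100, 199)),
#'               GenomicRanges::GRanges("1", IRanges::IRanges(150, 249)))
overlapLength <- function(x, y) {
    x <- GRanges(x); y <- GRanges(y)
    if (length(x) != 1L || length(y) != 1L)
        stop("'x' and 'y' must each be a single call")
    if (as.character(seqnames(x)) != as.character(seqnames(y)))
        return(0L)
    max(0L, min(end(x), end(y)) - max(start(x), start(y)) + 1L)
}

#' Reciprocal overlap between two calls
#'
#' Let `L` be the overlap length in bp. The two overlap fractions are
#' `O_a = L / length(x)` and `O_b = L / length(y)`. The pair passes at
#' threshold `t` (default 0.50, inclusive: "at least half of each") when
#' both fractions are `>= t` *and* the gain/loss statuses agree — two
#' perfectly coincident calls of opposite status are different events.
#'
#' @param x,y single-call `GRanges`; a `status` metadata column (or a
#'   `state` column it can be derived from) is required for the pass
#'   decision.
#' @param threshold reciprocal-overlap threshold in (0, 1], default 0.5.
#' @return list with `L`, `oA`, `oB`, `passes`.
#' @export
#' @examples
#' x <- GenomicRanges::GRanges("1", IRanges::IRanges(100, 199), state = 1L)
#' y <- GenomicRanges::GRanges("1", IRanges::IRanges(150, 249), state = 1L)
#' reciprocalOverlap(x, y)   # O_a = O_b = 0.5 -> passes
reciprocalOverlap <- function(x, y, threshold = 0.5) {
    x <- GRanges(x); y <- GRanges(y)
    L <- overlapLength(x, y)
    oA <- L / width(x)
    oB <- L / width(y)
    sx <- .callStatus(x); sy <- .callStatus(y)
    list(L = L, oA = oA, oB = oB,
         passes = oA >= threshold && oB >= threshold && sx == sy)
}

.callStatus <- function(gr) {
    mc <- mcols(gr)
    if ("status" %in% colnames(mc)) as.character(mc$status)
    else if ("state" %in% colnames(mc)) statusFromState(mc$state)
    else stop("call lacks a 'status' (or 'state') metadata column")
}

## Interval-index candidate generation: all (i, j) pairs between grA and
## grB passing reciprocal overlap + status agreement. With grB = NULL,
## self-comparison of grA (unordered pairs, i < j). findOverlaps provides
## the candidates; exact RO arithmetic prunes them.
.roPairs <- function(grA, grB = NULL, threshold = 0.5) {
    self <- is.null(grB)
    hits <- if (self)
        findOverlaps(grA, drop.self = TRUE, drop.redundant = TRUE,
                     ignore.strand = TRUE)
    else findOverlaps(grA, grB, ignore.strand = TRUE)
    i <- S4Vectors::queryHits(hits)
    j <- S4Vectors::subjectHits(hits)
    if (self) grB <- grA
    if (!length(i))
        return(data.frame(i = integer(), j = integer(), L = integer(),
                          oA = numeric(), oB = numeric(), minRO = numeric()))
    L <- pmin(end(grA)[i], end(grB)[j]) - pmax(start(grA)[i], start(grB)[j]) + 1L
    oA <- L / width(grA)[i]
    oB <- L / width(grB)[j]
    keep <- oA >= threshold & oB >= threshold &
        .callStatus(grA)[i] == .callStatus(grB)[j]
    out <- data.frame(i = i[keep], j = j[keep], L = L[keep],
                      oA = oA[keep], oB = oB[keep],
                      minRO = pmin(oA, oB)[keep])
    ## deterministic genomic order of the left-hand call, then right-hand
    out[order(out$i, out$j), , drop = FALSE]
}

#' All pairs of calls passing reciprocal overlap with status agreement
#'
#' Interval-index (accelerated) enumeration of the passing pairs between
#' two call collections, or among one collection when `grB` is `NULL`
#' (unordered pairs, `i < j`). This is the candidate generator behind
#' [buildEventGroups()] and [matchPairwise()], exposed for sensitivity
#' analyses and validation.
#'
#' @param grA,grB `GRanges` with `status` (or `state`) metadata; `grB`
#'   `NULL` for self-comparison.
#' @param threshold reciprocal-overlap threshold, default 0.5.
#' @return data.frame with `i`, `j` (indices into `grA`/`grB`), `L`, `oA`,
#'   `oB`, `minRO`, in genomic (index) order.
#' @export
roPairs <- function(grA, grB = NULL, threshold = 0.5) {
    .roPairs(GRanges(grA), if (is.null(grB)) NULL else GRanges(grB),
             threshold = threshold)
}

#' Group calls into events by reciprocal-overlap connectivity
#'
#' Builds a graph whose nodes are the calls of all supplied call sets and
#' whose edges join pairs passing the reciprocal-overlap criterion (both
#' fractions at or above `threshold`) with matching gain/loss status. The
#' connected components of this graph are the event groups: chains of
#' partially overlapping calls end up in one event even when distal members
#' do not overlap each other directly (transitive closure). Each group
#' records its program and sample membership, which drives the
#' cross-program [vennPartition()].
#'
#' @param callsets a [CNVCallSetList] (or single [CNVCallSet]); typically
#'   post-merge.
#' @param threshold reciprocal-overlap threshold, default 0.5.
#' @return a [CNVEventGroups]; groups are numbered in genomic order of
#'   their spans.
#' @export
buildEventGroups <- function(callsets, threshold = 0.5) {
    gr <- .flattenCalls(callsets)
    if (!length(gr))
        return(new("CNVEventGroups",
                   calls = .emptyGroupCalls(), nGroups = 0L,
                   threshold = threshold))
    pairs <- .roPairs(gr, threshold = threshold)
    g <- igraph::make_empty_graph(n = length(gr), directed = FALSE)
    if (nrow(pairs))
        g <- igraph::add_edges(g, rbind(pairs$i, pairs$j))
    comp <- igraph::components(g)$membership
    ## renumber components by genomic order of their spans
    chrom <- as.integer(as.character(seqnames(gr)))
    minStart <- tapply(start(gr), comp, min)
    maxEnd <- tapply(end(gr), comp, max)
    minChrom <- tapply(chrom, comp, min)
    rank <- order(order(minChrom, minStart, maxEnd))
    mcols(gr)$groupId <- rank[comp]
    new("CNVEventGroups", calls = gr,
        nGroups = max(rank), threshold = threshold)
}

.emptyGroupCalls <- function() {
    gr <- GRanges()
    mcols(gr) <- DataFrame(state = integer(), nMarkers = integer(),
                           status = character(), mergedFrom = integer(),
                           sampleId = character(), programId = character(),
                           groupId = integer())
    gr
}

#' @rdname CNVEventGroups-class
#' @export
setMethod("eventTable", "CNVEventGroups", function(object) {
    gr <- object@calls
    if (!length(gr))
        return(data.frame(groupId = integer(), chrom = character(),
                          start = integer(), end = integer(),
                          nCalls = integer(), status = character(),
                          programs = character(), samples = character(),
                          stringsAsFactors = FALSE))
    gid <- mcols(gr)$groupId
    idx <- split(seq_along(gr), gid)
    do.call(rbind, lapply(names(idx), function(k) {
        i <- idx[[k]]
        data.frame(groupId = as.integer(k),
                   chrom = as.character(seqnames(gr))[i[1L]],
                   start = min(start(gr)[i]), end = max(end(gr)[i]),
                   nCalls = length(i),
                   status = mcols(gr)$status[i[1L]],
                   programs = paste(sort(unique(mcols(gr)$programId[i])),
                                    collapse = "+"),
                   samples = paste(sort(unique(mcols(gr)$sampleId[i])),
                                   collapse = "+"),
                   stringsAsFactors = FALSE)
    }))
})

#' Event groups across programs and individuals
#'
#' `CNVEventGroups` is the result of [buildEventGroups()]: every input call
#' annotated with the id of the reciprocal-overlap connected component
#' (event) it belongs to. `nGroups()` gives the number of events;
#' `eventTable()` a per-event summary (span, call count, program and sample
#' membership).
#'
#' @name CNVEventGroups-class
#' @aliases CNVEventGroups
NULL

#' One-to-one matching of calls between two individuals
#'
#' Compares the call sets of two samples produced by the *same* program and
#' returns a one-to-one matching of their calls: candidate pairs are those
#' passing reciprocal overlap at `threshold` with matching gain/loss
#' status; among candidates a maximum-cardinality matching is selected
#' (so no call is counted as shared more than once), with ties broken in
#' favour of larger `min(O_a, O_b)` and then by genomic order.
#'
#' @param a,b [CNVCallSet]s for two different samples, same program.
#' @param threshold reciprocal-overlap threshold, default 0.5.
#' @return data.frame with one row per matched pair: `aIdx`, `bIdx`
#'   (positions within `a`/`b`), `L`, `oA`, `oB`.
#' @seealso [pairwiseDifference()] which turns the matching into the
#'   d statistic.
#' @export
matchPairwise <- function(a, b, threshold = 0.5) {
    stopifnot(is(a, "CNVCallSet"), is(b, "CNVCallSet"))
    if (a@programId != b@programId)
        stop(sprintf(paste0("between-individual comparison must stay within ",
                            "one program (got '%s' vs '%s')"),
                     a@programId, b@programId))
    grA <- a@calls; grB <- b@calls
    cand <- .roPairs(grA, grB, threshold = threshold)
    empty <- data.frame(aIdx = integer(), bIdx = integer(), L = integer(),
                        oA = numeric(), oB = numeric())
    if (!nrow(cand)) return(empty)
    if (!anyDuplicated(cand$i) && !anyDuplicated(cand$j)) {
        ## candidates already form a partial one-to-one assignment: that
        ## assignment is the unique maximum matching
        out <- data.frame(aIdx = cand$i, bIdx = cand$j, L = cand$L,
                          oA = cand$oA, oB = cand$oB)
        return(out[order(out$aIdx), , drop = FALSE])
    }
    nA <- length(grA); nB <- length(grB)
    g <- igraph::make_empty_graph(n = nA + nB, directed = FALSE)
    g <- igraph::add_edges(g, rbind(cand$i, nA + cand$j))
    ## weight K + minRO with K above the largest possible cardinality makes
    ## the maximum-weight matching a maximum-cardinality one, tie-broken by
    ## total min reciprocal overlap
    K <- min(nA, nB) + 1
    igraph::V(g)$type <- c(rep(FALSE, nA), rep(TRUE, nB))
    m <- igraph::max_bipartite_match(g, weights = K + cand$minRO)
    matchedOf <- m$matching[seq_len(nA)]
    sel <- which(!is.na(matchedOf))
    pairs <- data.frame(aIdx = sel, bIdx = as.integer(matchedOf[sel]) - nA)
    key <- paste(pairs$aIdx, pairs$bIdx)
    candKey <- paste(cand$i, cand$j)
    hit <- match(key, candKey)
    out <- data.frame(aIdx = pairs$aIdx, bIdx = pairs$bIdx,
                      L = cand$L[hit], oA = cand$oA[hit], oB = cand$oB[hit])
    out[order(out$aIdx), , drop = FALSE]
}
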