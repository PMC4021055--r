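#' Gap fraction between two ordered, non-overlapping calls
#'
#' For two same-chromosome calls A (left) and C (right) separated by an
#' unchanged stretch B, computes the length of B divided by the length of
#' the whole A+B+C span, on 1-based inclusive coordinates:
#' `gap = start(C) - end(A) - 1`, `span = end(C) - start(A) + 1`,
#' `fraction = gap / span`. Abutting calls have fraction 0. This is the
#' quantity the adjacent-call merge rule thresholds at 20%.
#'
#' @param a,c single-call `GRanges` (length 1), `a` strictly preceding `c`
#'   (`end(a) < start(c)`) on the same chromosome.
#' @return list with `gapBp`, `spanBp`, `gapFraction`.
#' @seealso [mergeAdjacent()] which applies the rule (cumulatively for
#'   chains of more than two calls).
#' @export
#' @examples
#' library(GenomicRanges)
#' gapFraction(GRanges("1", IRanges::IRanges(1000, 1799)),
#'             GRanges("1", IRanges::IRanges(2000, 2799)))
gapFraction <- function(a, c) {
    a <- GRanges(a); c <- GRanges(c)
    if (length(a) != 1L || length(c) != 1L)
        stop("'a' and 'c' must each be a single call")
    if (as.character(seqnames(a)) != as.character(seqnames(c)))
        stop("calls must lie on the same chromosome")
    if (end(a) >= start(c))
        stop("calls must be ordered and non-overlapping: end(a) < start(c)")
    gap <- start(c) - end(a) - 1L
    span <- end(c) - start(a) + 1L
    list(gapBp = gap, spanBp = span, gapFraction = gap / span)
}

## One cumulative left-to-right merge pass over sorted calls (plain
## vectors; a chromosome change breaks the chain). Returns per-call chain
## ids. A chain is extended to the next call (which, by sort order, is the
## immediately adjacent call: criterion 1) only when statuses agree
## (criterion 2) and the cumulative internal gap stays within
## maxGapFraction of the growing span (criterion 3). Overlapping
## same-status calls contribute no gap and merge unconditionally.
.mergePassChains <- function(chrom, s, e, status, maxGapFraction) {
    n <- length(s)
    chain <- integer(n)
    chain[1L] <- 1L
    chainStart <- s[1L]; chainEnd <- e[1L]; cumGap <- 0
    cur <- 1L
    for (i in seq_len(n)[-1L]) {
        extended <- FALSE
        if (chrom[i] == chrom[i - 1L] && status[i] == status[i - 1L]) {
            gap <- max(0, s[i] - chainEnd - 1)
            newEnd <- max(chainEnd, e[i])
            span <- newEnd - chainStart + 1
            if ((cumGap + gap) / span <= maxGapFraction) {
                cumGap <- cumGap + gap
                chainEnd <- newEnd
                extended <- TRUE
            }
        }
        if (!extended) {
            cur <- cur + 1L
            chainStart <- s[i]; chainEnd <- e[i]; cumGap <- 0
        }
        chain[i] <- cur
    }
    chain
}

## iterate cumulative merge passes to a fixed point on plain vectors
.mergeVectors <- function(chrom, s, e, state, nMarkers, status, mergedFrom,
                          maxGapFraction) {
    changed <- FALSE
    repeat {
        n <- length(s)
        if (n <= 1L) break
        chain <- .mergePassChains(chrom, s, e, status, maxGapFraction)
        if (chain[n] == n) break    # every call its own chain: fixed point
        changed <- TRUE
        idx <- unname(split(seq_len(n), chain))
        first <- vapply(idx, `[`, integer(1), 1L)
        chrom <- chrom[first]
        status <- status[first]
        newS <- s[first]            # sorted input: chain min start leads
        newE <- vapply(idx, function(i) max(e[i]), numeric(1))
        state <- vapply(idx, function(i)
            state[i[which.max(e[i] - s[i])]], integer(1))
        nMarkers <- vapply(idx, function(i)
            if (anyNA(nMarkers[i])) NA_integer_
            else as.integer(sum(nMarkers[i])), integer(1))
        mergedFrom <- vapply(idx, function(i)
            as.integer(sum(mergedFrom[i])), integer(1))
        s <- newS; e <- newE
        ord <- order(chrom, s, e, status)
        chrom <- chrom[ord]; s <- s[ord]; e <- e[ord]
        state <- state[ord]; nMarkers <- nMarkers[ord]
        status <- status[ord]; mergedFrom <- mergedFrom[ord]
    }
    list(chrom = chrom, start = s, end = e, state = state,
         nMarkers = nMarkers, status = status, mergedFrom = mergedFrom,
         changed = changed)
}

#' Merge adjacent same-status calls within one (sample, program)
#'
#' Scans each chromosome left to right and merges runs of calls that
#' (1) are adjacent — no other call of any status between them, (2) share
#' the same gain/loss status, and (3) keep the cumulative internal gap at
#' or below `maxGapFraction` (default 20%) of the total span, re-checked at
#' each chain extension. The scan is repeated until a fixed point: once a
#' run is merged, its internal gaps are part of the call, so a merged call
#' and its right neighbour are re-assessed as a plain pair. The merged call
#' spans the run, keeps the shared status, takes the copy-number state of
#' its largest constituent, sums marker counts, and records the number of
#' original calls in `mergedFrom` (summed across nested merges, so the
#' total over a call set is conserved).
#'
#' @param x a [CNVCallSet] (sorted by construction) or [CNVCallSetList].
#' @param maxGapFraction maximum allowed gap fraction, default 0.20.
#' @return object of the same class with merged calls; idempotent.
#' @export
#' @examples
#' cs <- CNVCallSet("S1", "PC", GenomicRanges::GRanges(
#'     "1", IRanges::IRanges(c(1000, 2000), c(1799, 2799)),
#'     state = 1L, nMarkers = 10L))
#' mergeAdjacent(cs)   # gap 200 / span 1800 = 11.1% -> one call
mergeAdjacent <- function(x, maxGapFraction = 0.20) {
    if (is(x, "CNVCallSetList")) {
        out <- CNVCallSetList(lapply(as.list(x), mergeAdjacent,
                                     maxGapFraction = maxGapFraction))
        metadata(out) <- metadata(x)
        return(out)
    }
    stopifnot(is(x, "CNVCallSet"))
    if (maxGapFraction < 0 || maxGapFraction >= 1)
        stop("'maxGapFraction' must be in [0, 1)")
    gr <- x@calls
    if (length(gr) < 2L) return(x)
    merged <- .mergeVectors(as.integer(as.character(seqnames(gr))),
                            start(gr), end(gr),
                            mcols(gr)$state, mcols(gr)$nMarkers,
                            mcols(gr)$status, mcols(gr)$mergedFrom,
                            maxGapFraction)
    if (!merged$changed) return(x)
    newGr <- GRanges(factor(as.character(merged$chrom), levels = .AUTOSOMES),
                     IRanges(merged$start, merged$end))
    mcols(newGr) <- DataFrame(state = merged$state,
                              nMarkers = merged$nMarkers,
                              status = merged$status,
                              mergedFrom = merged$mergedFrom)
    out <- .newCallSet(x@sampleId, x@programId, newGr)
    metadata(out) <- metadata(x)
    out
}
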