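#' Partition events by the set of programs that called them
#'
#' Assigns every event group to the subset of programs contributing at
#' least one member call, and reports, per subset, both the number of
#' event groups and the number of constituent calls. The two counts differ
#' because one event may contain several calls (even several from one
#' program): an event called once by each of four programs contributes one
#' event but four calls to the four-program subset. Call counts over all
#' subsets sum exactly to the total post-merge call count.
#'
#' @param groups a [CNVEventGroups] from [buildEventGroups()].
#' @param programs optional character vector restricting/ordering the
#'   program universe; defaults to the programs observed.
#' @return data.frame with `programSet` (sorted program ids joined by
#'   `"+"`), `nPrograms`, `eventGroups`, `calls`; attribute `totalCalls`
#'   holds the overall call count.
#' @export
vennPartition <- function(groups, programs = NULL) {
    stopifnot(is(groups, "CNVEventGroups"))
    gr <- groups@calls
    empty <- data.frame(programSet = character(), nPrograms = integer(),
                        eventGroups = integer(), calls = integer(),
                        stringsAsFactors = FALSE)
    if (!length(gr)) {
        attr(empty, "totalCalls") <- 0L
        return(empty)
    }
    if (!is.null(programs)) {
        bad <- setdiff(unique(mcols(gr)$programId), programs)
        if (length(bad))
            stop(sprintf("event groups contain program(s) outside 'programs': %s",
                         paste(bad, collapse = ", ")))
    }
    gid <- mcols(gr)$groupId
    prog <- mcols(gr)$programId
    subsetOf <- vapply(split(prog, gid), function(p)
        paste(sort(unique(p)), collapse = "+"), character(1))
    callsOf <- vapply(split(prog, gid), length, integer(1))
    agg <- data.frame(programSet = subsetOf, calls = callsOf,
                      stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(split(agg, agg$programSet), function(d)
        data.frame(programSet = d$programSet[1L],
                   nPrograms = length(strsplit(d$programSet[1L], "+",
                                               fixed = TRUE)[[1L]]),
                   eventGroups = nrow(d), calls = sum(d$calls),
                   stringsAsFactors = FALSE)))
    out <- out[order(-out$nPrograms, out$programSet), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "totalCalls") <- length(gr)
    out
}

#' Per-sample cross-program Venn partition
#'
#' The cross-program comparison is a within-individual question: events are
#' grouped per sample across that sample's programs, then subset counts are
#' summed over samples. Grouping all samples at once would let calls of
#' different individuals bridge events.
#'
#' @param callsets a [CNVCallSetList] covering one or more samples.
#' @param threshold reciprocal-overlap threshold, default 0.5.
#' @return as [vennPartition()], aggregated over samples.
#' @export
vennAcrossSamples <- function(callsets, threshold = 0.5) {
    bySample <- split(as.list(callsets),
                      vapply(as.list(callsets), sampleId, character(1)))
    parts <- lapply(bySample, function(sets)
        vennPartition(buildEventGroups(CNVCallSetList(sets), threshold)))
    all <- do.call(rbind, parts)
    if (is.null(all) || !nrow(all)) {
        out <- data.frame(programSet = character(), nPrograms = integer(),
                          eventGroups = integer(), calls = integer())
        attr(out, "totalCalls") <- 0L
        return(out)
    }
    out <- do.call(rbind, lapply(split(all, all$programSet), function(d)
        data.frame(programSet = d$programSet[1L], nPrograms = d$nPrograms[1L],
                   eventGroups = sum(d$eventGroups), calls = sum(d$calls),
                   stringsAsFactors = FALSE)))
    out <- out[order(-out$nPrograms, out$programSet), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "totalCalls") <- sum(vapply(parts, attr, integer(1), "totalCalls"))
    out
}

#' The pairwise difference statistic d between two individuals
#'
#' For the call sets of two individuals from one program, `d` is the number
#' of unshared calls across the two individuals divided by the total number
#' of calls across the two individuals. Shared calls are counted via the
#' one-to-one reciprocal-overlap matching of [matchPairwise()]: with `s`
#' matched pairs, `unshared = total - 2 s` and `d = unshared / total`.
#' `d = 0` means identical call sets, `d = 1` fully discordant ones.
#'
#' @param a,b [CNVCallSet]s for the two individuals (same program,
#'   post-merge).
#' @param threshold reciprocal-overlap threshold, default 0.5.
#' @return one-row data.frame: `sample_a`, `sample_b`, `program_id`,
#'   `shared_pairs`, `unshared`, `total`, `d`.
#' @export
#' @examples
#' \dontrun{pairwiseDifference(callsetA, callsetB)}
pairwiseDifference <- function(a, b, threshold = 0.5) {
    total <- length(a) + length(b)
    if (total == 0L)
        stop(sprintf("d is undefined: no calls in either individual (%s, %s)",
                     sampleId(a), sampleId(b)))
    shared <- nrow(matchPairwise(a, b, threshold = threshold))
    unshared <- total - 2L * shared
    data.frame(sample_a = sampleId(a), sample_b = sampleId(b),
               program_id = programId(a), shared_pairs = shared,
               unshared = unshared, total = total, d = unshared / total,
               stringsAsFactors = FALSE)
}

#' Difference statistics for every declared pair and program
#'
#' Runs [pairwiseDifference()] for each relatedness pair and each program
#' for which both samples have a call set. Pairs where a sample lacks calls
#' for a program are skipped with a warning (d would be computed on a
#' one-sided comparison otherwise).
#'
#' @param callsets a [CNVCallSetList] (post-merge).
#' @param pairs validated pairs data.frame from [readPairs()].
#' @param threshold reciprocal-overlap threshold, default 0.5.
#' @return data.frame of per-(pair, program) difference statistics with the
#'   pair's `relation` attached.
#' @export
pairDifferences <- function(callsets, pairs, threshold = 0.5) {
    sets <- as.list(callsets)
    keyOf <- function(s, p) paste(s, p, sep = "|")
    names(sets) <- vapply(sets, function(x)
        keyOf(sampleId(x), programId(x)), character(1))
    programs <- sort(unique(vapply(sets, programId, character(1))))
    rows <- list()
    for (r in seq_len(nrow(pairs))) {
        for (p in programs) {
            ka <- keyOf(pairs$sample_a[r], p)
            kb <- keyOf(pairs$sample_b[r], p)
            if (!ka %in% names(sets) || !kb %in% names(sets)) {
                warning(sprintf("no %s call set for pair (%s, %s); skipped",
                                p, pairs$sample_a[r], pairs$sample_b[r]))
                next
            }
            st <- pairwiseDifference(sets[[ka]], sets[[kb]], threshold)
            st$relation <- pairs$relation[r]
            rows[[length(rows) + 1L]] <- st
        }
    }
    if (!length(rows))
        return(data.frame(sample_a = character(), sample_b = character(),
                          program_id = character(), shared_pairs = integer(),
                          unshared = integer(), total = integer(),
                          d = numeric(), relation = character()))
    do.call(rbind, rows)
}

#' Summarize d by relatedness group and program
#'
#' Averages the pair-level difference statistic within each
#' (relation, program) group, reporting the mean, the sample standard
#' deviation and the standard error of the mean (`sem = sd / sqrt(n)`).
#' Groups with a single pair get `NA` dispersion; relations declared in
#' `pairs` but absent from `stats` are omitted with a warning.
#'
#' @param stats output of [pairDifferences()] (or any data.frame with
#'   `sample_a`, `sample_b`, `program_id`, `d`).
#' @param pairs validated pairs data.frame; every stat's pair must appear
#'   here (unordered).
#' @return data.frame with `relation`, `program_id`, `n_pairs`, `mean_d`,
#'   `sd_d`, `sem_d`, ordered MZ, parent_child, unrelated.
#' @export
groupDifferenceSummary <- function(stats, pairs) {
    pairKey <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
    declared <- pairKey(pairs$sample_a, pairs$sample_b)
    got <- pairKey(stats$sample_a, stats$sample_b)
    if (any(is.na(match(got, declared))))
        stop("difference statistic for a pair with no declared relation")
    stats$relation <- pairs$relation[match(got, declared)]
    stats$relation <- factor(stats$relation,
                             levels = c("MZ", "parent_child", "unrelated"))
    missing <- setdiff(unique(as.character(pairs$relation)),
                       unique(as.character(stats$relation)))
    if (length(missing))
        warning(sprintf("no difference statistics for relation group(s): %s",
                        paste(missing, collapse = ", ")))
    grp <- split(stats, list(stats$relation, stats$program_id), drop = TRUE)
    out <- do.call(rbind, lapply(grp, function(d) {
        n <- nrow(d)
        data.frame(relation = as.character(d$relation[1L]),
                   program_id = d$program_id[1L], n_pairs = n,
                   mean_d = mean(d$d),
                   sd_d = if (n > 1L) stats::sd(d$d) else NA_real_,
                   sem_d = if (n > 1L) stats::sd(d$d) / sqrt(n) else NA_real_,
                   stringsAsFactors = FALSE)
    }))
    out <- out[order(factor(out$relation,
                            levels = c("MZ", "parent_child", "unrelated")),
                     out$program_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Size distribution of calls per program
#'
#' Counts calls per length bin per program. Bins are right-closed,
#' `(lo, hi]`, so a call of exactly 100 kb falls in the 1 kb-100 kb bin;
#' the defaults are (1 kb, 100 kb], (100 kb, 1 Mb], (1 Mb, 10 Mb] and
#' > 10 Mb, plus an underflow bin for anything at or below the first edge
#' so that counts always sum to the input size.
#'
#' @param x a [CNVCallSet] or [CNVCallSetList].
#' @param binEdges strictly increasing bp thresholds,
#'   default `c(1e3, 1e5, 1e6, 1e7)`.
#' @return matrix of counts, bins x programs.
#' @export
sizeDistribution <- function(x, binEdges = c(1e3, 1e5, 1e6, 1e7)) {
    if (is.unsorted(binEdges, strictly = TRUE))
        stop("'binEdges' must be strictly increasing")
    gr <- .flattenCalls(x)
    breaks <- c(0, binEdges, Inf)
    fmt <- function(v) ifelse(v >= 1e6, paste0(v / 1e6, "Mb"),
                       ifelse(v >= 1e3, paste0(v / 1e3, "kb"), paste0(v, "bp")))
    labels <- c(paste0("<=", fmt(binEdges[1L])),
                paste(fmt(binEdges[-length(binEdges)]),
                      fmt(binEdges[-1L]), sep = "-"),
                paste0(">", fmt(binEdges[length(binEdges)])))
    bin <- cut(width(gr), breaks = breaks, labels = labels, right = TRUE)
    prog <- factor(mcols(gr)$programId,
                   levels = sort(unique(mcols(gr)$programId)))
    table(bin = bin, program = prog)
}

#' Chromosomal distribution of calls per program
#'
#' @param x a [CNVCallSet] or [CNVCallSetList] (autosomes only, enforced at
#'   ingestion).
#' @return matrix of counts, 22 autosomes x programs.
#' @export
chromosomeDistribution <- function(x) {
    gr <- .flattenCalls(x)
    chrom <- factor(as.character(seqnames(gr)), levels = .AUTOSOMES)
    prog <- factor(mcols(gr)$programId,
                   levels = sort(unique(mcols(gr)$programId)))
    table(chrom = chrom, program = prog)
}
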