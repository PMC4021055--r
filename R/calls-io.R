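#' Default column mapping for call tables
#'
#' Names on the left are the internal fields; values are the column names
#' expected in the file. Override individual entries to ingest exports whose
#' headers differ (e.g. `callDialect(chrom = "Chromosome")`).
#'
#' @param sample_id,program_id,chrom,start,end,state,n_markers column names
#'   in the input table. `n_markers` may be absent from the file.
#' @return named character vector suitable for the `dialect` argument of
#'   [readCallTable()].
#' @export
callDialect <- function(sample_id = "sample_id", program_id = "program_id",
                        chrom = "chrom", start = "start", end = "end",
                        state = "state", n_markers = "n_markers") {
    c(sample_id = sample_id, program_id = program_id, chrom = chrom,
      start = start, end = end, state = state, n_markers = n_markers)
}

.readTable <- function(file) {
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
    utils::read.table(file, header = TRUE, sep = sep,
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "")
}

.asCount <- function(x, what, rows) {
    suppressWarnings(v <- as.numeric(x))
    bad <- is.na(v) | v != floor(v)
    if (any(bad))
        stop(sprintf("non-integer %s in row(s) %s", what,
                     paste(rows[bad], collapse = ", ")))
    as.integer(v)
}

#' Read a multi-caller CNV call table
#'
#' Reads a TSV/CSV of per-call records (one row per CNV call, 1-based
#' inclusive coordinates) and returns one [CNVCallSet] per observed
#' (sample, program). The gain/loss `status` is derived from the copy-number
#' state. Rows on chromosomes other than the 22 autosomes (e.g. X, Y, MT)
#' are excluded — the analysis is autosome-only — and the number of excluded
#' rows is recorded in `metadata(result)$excludedRows`.
#'
#' @param file path to a tab- (".tsv"/other) or comma- (".csv") separated
#'   table with a header row.
#' @param dialect column mapping from [callDialect()].
#' @return a [CNVCallSetList]; `metadata()` carries `excludedRows`.
#' @details A state written `"4+"` is accepted and stored as integer 4.
#'   Chromosome labels may carry a `"chr"` prefix, which is stripped.
#' @export
readCallTable <- function(file, dialect = callDialect()) {
    df <- .readTable(file)
    mandatory <- c("sample_id", "program_id", "chrom", "start", "end", "state")
    for (f in mandatory)
        if (!dialect[[f]] %in% names(df))
            stop(sprintf("call table lacks mandatory column '%s' (field %s)",
                         dialect[[f]], f))
    n <- nrow(df)
    rows <- seq_len(n) + 1L   # header is line 1
    out <- data.frame(
        sample_id = df[[dialect[["sample_id"]]]],
        program_id = df[[dialect[["program_id"]]]],
        chrom = sub("^chr", "", df[[dialect[["chrom"]]]]),
        stringsAsFactors = FALSE)
    out$start <- .asCount(df[[dialect[["start"]]]], "start coordinate", rows)
    out$end <- .asCount(df[[dialect[["end"]]]], "end coordinate", rows)
    state_raw <- sub("\\+$", "", df[[dialect[["state"]]]])
    out$state <- .asCount(state_raw, "copy-number state", rows)
    if (any(out$state < 0L | out$state > 4L))
        stop(sprintf("invalid copy-number state in row(s) %s: states are 0..4 (4 = \"4+\")",
                     paste(rows[out$state < 0L | out$state > 4L], collapse = ", ")))
    if (any(out$end < out$start))
        stop(sprintf("end < start in row(s) %s",
                     paste(rows[out$end < out$start], collapse = ", ")))
    if (dialect[["n_markers"]] %in% names(df)) {
        nm <- df[[dialect[["n_markers"]]]]
        keepNA <- is.na(nm) | nm == "" | nm == "NA"
        out$n_markers <- NA_integer_
        if (any(!keepNA))
            out$n_markers[!keepNA] <- .asCount(nm[!keepNA], "marker count",
                                               rows[!keepNA])
    } else out$n_markers <- NA_integer_

    onAuto <- out$chrom %in% .AUTOSOMES
    excluded <- sum(!onAuto)
    out <- out[onAuto, , drop = FALSE]

    key <- paste(out$sample_id, out$program_id, sep = "|")
    sets <- lapply(split(seq_len(nrow(out)), factor(key, levels = unique(key))),
                   function(i) {
        d <- out[i, , drop = FALSE]
        CNVCallSet(d$sample_id[1L], d$program_id[1L],
                   GRanges(d$chrom, IRanges(d$start, d$end),
                           state = d$state, nMarkers = d$n_markers))
    })
    res <- CNVCallSetList(sets)
    metadata(res)$excludedRows <- excluded
    res
}

.flattenCalls <- function(x) {
    if (is(x, "CNVCallSet")) x <- CNVCallSetList(list(x))
    grl <- lapply(as.list(x), function(cs) {
        gr <- cs@calls
        mcols(gr)$sampleId <- cs@sampleId
        mcols(gr)$programId <- cs@programId
        gr
    })
    if (!length(grl)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(state = integer(), nMarkers = integer(),
                               status = character(), mergedFrom = integer(),
                               sampleId = character(), programId = character())
        return(gr)
    }
    unname(do.call(c, unname(grl)))
}

#' Write CNV call sets to a plain-text table
#'
#' Writes the canonical tab-separated call-table layout (columns
#' `sample_id`, `program_id`, `chrom`, `start`, `end`, `state`, `n_markers`,
#' `status`, `merged_from`; 1-based inclusive coordinates) that
#' [readCallTable()] reads back losslessly.
#'
#' @param x a [CNVCallSet] or [CNVCallSetList].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeCallTable <- function(x, file) {
    gr <- .flattenCalls(x)
    df <- data.frame(sample_id = mcols(gr)$sampleId,
                     program_id = mcols(gr)$programId,
                     chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr),
                     state = mcols(gr)$state,
                     n_markers = mcols(gr)$nMarkers,
                     status = mcols(gr)$status,
                     merged_from = mcols(gr)$mergedFrom,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Export calls as BED
#'
#' Converts the 1-based inclusive internal coordinates to BED's 0-based
#' half-open convention (via `rtracklayer`). The BED name field packs
#' `sample|program|status|state`; the score carries the marker count.
#'
#' @param x a [CNVCallSet] or [CNVCallSetList].
#' @param file output `.bed` path.
#' @return `file`, invisibly.
#' @export
exportBED <- function(x, file) {
    gr <- .flattenCalls(x)
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
    mcols(out)$name <- paste(mcols(gr)$sampleId, mcols(gr)$programId,
                             mcols(gr)$status, mcols(gr)$state, sep = "|")
    nm <- mcols(gr)$nMarkers
    mcols(out)$score <- ifelse(is.na(nm), 0L, nm)
    rtracklayer::export(out, file, format = "BED")
    invisible(file)
}

#' Import calls from BED written by [exportBED()]
#'
#' @param file a `.bed` path whose name field is `sample|program|status|state`.
#' @return a [CNVCallSetList].
#' @export
importBED <- function(file) {
    gr <- rtracklayer::import(file, format = "BED")
    parts <- strsplit(mcols(gr)$name, "|", fixed = TRUE)
    if (any(lengths(parts) != 4L))
        stop("BED name field must be sample|program|status|state")
    p <- do.call(rbind, parts)
    df <- data.frame(sample_id = p[, 1L], program_id = p[, 2L],
                     chrom = sub("^chr", "", as.character(seqnames(gr))),
                     start = start(gr), end = end(gr),
                     state = as.integer(p[, 4L]),
                     n_markers = ifelse(mcols(gr)$score == 0, NA_integer_,
                                        as.integer(mcols(gr)$score)),
                     stringsAsFactors = FALSE)
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    readCallTable(tmp)
}

#' Apply the standard inclusion filters to a call set
#'
#' Retains calls supported by at least `minMarkers` consecutive array
#' markers, strictly longer than `minLengthBp` (the default keeps variants
#' *greater than* 1 kb) and, by default, non-copy-neutral (state != 2).
#' Dropped calls are tallied by the first filter they fail, in the order
#' markers, length, neutral; the tally is stored in
#' `metadata(result)$filterDrops` together with the retained count, so the
#' counts always sum to the input size.
#'
#' @param x a [CNVCallSet] or [CNVCallSetList].
#' @param minMarkers minimum supporting marker count (inclusive); set to 0
#'   to disable when marker counts are unavailable.
#' @param minLengthBp calls must be strictly longer than this many bp.
#' @param excludeNeutral drop copy-neutral (state 2) calls.
#' @return object of the same class containing the retained calls;
#'   filtering an already-filtered set is a no-op.
#' @export
#' @examples
#' cs <- CNVCallSet("S1", "PC", GenomicRanges::GRanges(
#'     c("1", "1"), IRanges::IRanges(c(1000, 8000), c(1900, 9000)),
#'     state = c(1L, 3L), nMarkers = c(9L, 12L)))
#' filtered <- filterCalls(cs)
#' S4Vectors::metadata(filtered)$filterDrops
filterCalls <- function(x, minMarkers = 10, minLengthBp = 1000,
                        excludeNeutral = TRUE) {
    if (is(x, "CNVCallSetList")) {
        out <- CNVCallSetList(lapply(as.list(x), filterCalls,
                                     minMarkers = minMarkers,
                                     minLengthBp = minLengthBp,
                                     excludeNeutral = excludeNeutral))
        metadata(out) <- metadata(x)
        return(out)
    }
    stopifnot(is(x, "CNVCallSet"))
    gr <- x@calls
    nm <- mcols(gr)$nMarkers
    if (minMarkers > 0 && any(is.na(nm)))
        stop("calls lack marker counts; supply 'n_markers' or set minMarkers = 0")
    failMarkers <- if (minMarkers > 0) nm < minMarkers else rep(FALSE, length(gr))
    failLength <- width(gr) <= minLengthBp
    failNeutral <- if (excludeNeutral) mcols(gr)$status == "NEUTRAL"
                   else rep(FALSE, length(gr))
    reason <- rep(NA_character_, length(gr))
    reason[failNeutral] <- "neutral"
    reason[failLength] <- "length"
    reason[failMarkers] <- "markers"
    keep <- is.na(reason)
    out <- if (all(keep)) x
           else .newCallSet(x@sampleId, x@programId, gr[keep])
    metadata(out) <- metadata(x)
    metadata(out)$filterDrops <- c(
        markers = sum(reason == "markers", na.rm = TRUE),
        length = sum(reason == "length", na.rm = TRUE),
        neutral = sum(reason == "neutral", na.rm = TRUE),
        retained = sum(keep))
    out
}

.RELATION_SHARING <- c(MZ = 1.0, parent_child = 0.5, unrelated = 0.0)

#' Read a relatedness pairs file
#'
#' Reads a TSV with columns `sample_a`, `sample_b`, `relation`, where the
#' relation is one of `MZ` (monozygotic twins, 100% expected genetic
#' sharing), `parent_child` (50%) or `unrelated` (0%). The expected sharing
#' fraction is filled in from the relation.
#'
#' @param file path to the pairs TSV.
#' @return data.frame with columns `sample_a`, `sample_b`, `relation`,
#'   `expected_sharing`.
#' @export
readPairs <- function(file) {
    df <- .readTable(file)
    need <- c("sample_a", "sample_b", "relation")
    if (!all(need %in% names(df)))
        stop("pairs file needs columns sample_a, sample_b, relation")
    validatePairs(data.frame(sample_a = df$sample_a, sample_b = df$sample_b,
                             relation = df$relation, stringsAsFactors = FALSE))
}

#' Validate a relatedness pairs table
#'
#' @param df data.frame with `sample_a`, `sample_b`, `relation`.
#' @return the validated data.frame with `expected_sharing` added.
#' @rdname readPairs
#' @export
validatePairs <- function(df) {
    bad <- !df$relation %in% names(.RELATION_SHARING)
    if (any(bad))
        stop(sprintf("unknown relation '%s'; allowed: %s",
                     df$relation[bad][1L],
                     paste(names(.RELATION_SHARING), collapse = ", ")))
    if (any(df$sample_a == df$sample_b))
        stop("self-pair: sample_a and sample_b must differ")
    key <- ifelse(df$sample_a < df$sample_b,
                  paste(df$sample_a, df$sample_b),
                  paste(df$sample_b, df$sample_a))
    if (anyDuplicated(key))
        stop("duplicate (unordered) sample pair in pairs file")
    df$expected_sharing <- unname(.RELATION_SHARING[df$relation])
    df
}

#' @rdname readPairs
#' @param pairs a validated pairs data.frame.
#' @export
writePairs <- function(pairs, file) {
    utils::write.table(pairs[, c("sample_a", "sample_b", "relation")],
                       file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
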