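#' Run the full multi-caller integration workflow
#'
#' Executes the stages in their canonical order — inclusion filtering
#' (>= `minMarkers` markers, length strictly greater than `minLengthBp`,
#' non-neutral), adjacent-call merging at `maxGapFraction`, within-sample
#' cross-program event grouping at `roThreshold`, and, when a pairs file is
#' given, between-individual difference statistics — and writes all
#' artifacts to `outdir`:
#' \describe{
#'   \item{merged.tsv}{filtered + merged calls, [writeCallTable()] layout}
#'   \item{venn.json}{cross-program partition of events and calls}
#'   \item{dstat.tsv}{per-(pair, program) difference statistics}
#'   \item{group_summary.tsv}{mean/sd/sem of d per relatedness group}
#'   \item{summary.json}{size-bin and chromosome distributions per program}
#'   \item{provenance.json}{package version, full parameter set, input
#'     digests}
#' }
#'
#' @param callsFile path to the raw call table ([readCallTable()] format).
#' @param outdir output directory (created if needed).
#' @param pairsFile optional relatedness pairs TSV; without it the d-statistic
#'   stage is skipped.
#' @param minMarkers,minLengthBp,maxGapFraction,roThreshold stage
#'   thresholds; the defaults (10 markers, > 1 kb, 20% gap, 50% RO) are the
#'   standard operating point of the workflow.
#' @param dialect column mapping for the call table, see [callDialect()].
#' @return invisibly, a list with the in-memory results (`merged`,
#'   `venn`, `dstat`, `groupSummary`, `paths`).
#' @export
runPipeline <- function(callsFile, outdir, pairsFile = NULL,
                        minMarkers = 10, minLengthBp = 1000,
                        maxGapFraction = 0.20, roThreshold = 0.50,
                        dialect = callDialect()) {
    if (!file.exists(callsFile))
        stop(sprintf("[read] cannot read call table: %s", callsFile))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()

    raw <- readCallTable(callsFile, dialect = dialect)
    filtered <- tryCatch(
        filterCalls(raw, minMarkers = minMarkers, minLengthBp = minLengthBp),
        error = function(e) stop(sprintf("[filter] %s", conditionMessage(e))))
    merged <- tryCatch(mergeAdjacent(filtered, maxGapFraction = maxGapFraction),
        error = function(e) stop(sprintf("[merge] %s", conditionMessage(e))))
    paths$merged <- file.path(outdir, "merged.tsv")
    writeCallTable(merged, paths$merged)

    venn <- vennAcrossSamples(merged, threshold = roThreshold)
    paths$venn <- file.path(outdir, "venn.json")
    jsonlite::write_json(
        list(threshold = roThreshold,
             totalCalls = attr(venn, "totalCalls"),
             subsets = venn),
        paths$venn, auto_unbox = TRUE, digits = NA, dataframe = "rows")

    dstat <- NULL; groupSummary <- NULL
    if (!is.null(pairsFile)) {
        if (!file.exists(pairsFile))
            stop(sprintf("[pairs] cannot read pairs file: %s", pairsFile))
        pairs <- readPairs(pairsFile)
        dstat <- pairDifferences(merged, pairs, threshold = roThreshold)
        groupSummary <- groupDifferenceSummary(dstat, pairs)
        paths$dstat <- file.path(outdir, "dstat.tsv")
        utils::write.table(dstat, paths$dstat, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths$groupSummary <- file.path(outdir, "group_summary.tsv")
        utils::write.table(groupSummary, paths$groupSummary, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }

    sizes <- sizeDistribution(raw)
    chroms <- chromosomeDistribution(raw)
    paths$summary <- file.path(outdir, "summary.json")
    jsonlite::write_json(
        list(rawCalls = length(.flattenCalls(raw)),
             excludedRows = metadata(raw)$excludedRows,
             sizeDistribution = .tableToList(sizes),
             chromosomeDistribution = .tableToList(chroms)),
        paths$summary, auto_unbox = TRUE, digits = NA)

    paths$provenance <- file.path(outdir, "provenance.json")
    inputs <- c(calls = callsFile, pairs = pairsFile)
    jsonlite::write_json(
        list(tool = "CNVconcord",
             version = as.character(utils::packageVersion("CNVconcord")),
             parameters = list(minMarkers = minMarkers,
                               minLengthBp = minLengthBp,
                               maxGapFraction = maxGapFraction,
                               roThreshold = roThreshold),
             inputs = as.list(tools::md5sum(unlist(inputs))),
             timestamp = format(Sys.time(), tz = "UTC")),
        paths$provenance, auto_unbox = TRUE, digits = NA)

    invisible(list(merged = merged, venn = venn, dstat = dstat,
                   groupSummary = groupSummary, paths = paths))
}

.tableToList <- function(tab) {
    m <- as.matrix(unclass(tab))
    lapply(stats::setNames(seq_len(ncol(m)), colnames(m)),
           function(j) as.list(stats::setNames(as.integer(m[, j]),
                                               rownames(m))))
}
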