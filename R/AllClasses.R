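#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame SimpleList
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<-
NULL

.AUTOSOMES <- as.character(1:22)

.CALL_MCOLS <- c("state", "nMarkers", "status", "mergedFrom")

#' Derive gain/loss status from an integer copy-number state
#'
#' States 0 and 1 are losses, 2 is copy-neutral, 3 and 4 (where 4 encodes
#' "4 or more copies") are gains. All downstream comparisons operate on this
#' binarized status, not on the exact state.
#'
#' @param state integer vector of copy-number states in 0..4.
#' @return character vector with values `"LOSS"`, `"NEUTRAL"`, `"GAIN"`.
#' @export
#' @examples
#' statusFromState(c(0, 1, 2, 3, 4))
statusFromState <- function(state) {
    state <- as.integer(state)
    if (any(is.na(state)) || any(state < 0L | state > 4L))
        stop("copy-number state must be an integer in 0..4 (4 encodes \"4+\")")
    c("LOSS", "LOSS", "NEUTRAL", "GAIN", "GAIN")[state + 1L]
}

## Canonical sort: numeric chromosome, then start, end, status.
.callOrder <- function(gr) {
    order(as.integer(as.character(seqnames(gr))),
          start(gr), end(gr), mcols(gr)$status)
}

#' @rdname CNVCallSet-class
#' @export
setClass("CNVCallSet",
    contains = "Annotated",
    representation(sampleId = "character",
                   programId = "character",
                   calls = "GRanges"))

.validCNVCallSet <- function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
        !nzchar(object@sampleId))
        msg <- c(msg, "'sampleId' must be a single non-empty string")
    if (length(object@programId) != 1L || is.na(object@programId) ||
        !nzchar(object@programId))
        msg <- c(msg, "'programId' must be a single non-empty string")
    gr <- object@calls
    missing <- setdiff(.CALL_MCOLS, colnames(mcols(gr)))
    if (length(missing))
        return(c(msg, paste0("calls lack metadata column(s): ",
                             paste(missing, collapse = ", "))))
    if (!all(as.character(seqnames(gr)) %in% .AUTOSOMES))
        msg <- c(msg, "calls must lie on autosomes \"1\"..\"22\"")
    if (length(gr)) {
        st <- mcols(gr)$state
        if (!all(st %in% 0:4))
            msg <- c(msg, "copy-number states must be integers in 0..4")
        else if (!all(mcols(gr)$status == statusFromState(st)))
            msg <- c(msg, "status must equal statusFromState(state)")
        if (any(start(gr) < 1L))
            msg <- c(msg, "coordinates are 1-based: start must be >= 1")
        if (any(mcols(gr)$mergedFrom < 1L))
            msg <- c(msg, "mergedFrom must be >= 1")
        nm <- mcols(gr)$nMarkers
        if (!all(is.na(nm) | nm >= 1L))
            msg <- c(msg, "nMarkers must be >= 1 (or NA when unknown)")
        if (is.unsorted(.callOrder(gr)))
            msg <- c(msg, "calls must be sorted by (chrom, start, end)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("CNVCallSet", .validCNVCallSet)

#' Container for the CNV calls of one (sample, program)
#'
#' A `CNVCallSet` holds every copy-number call made by one calling program
#' on one sample, as a [GenomicRanges::GRanges] with 1-based inclusive
#' coordinates on autosomes "1".."22" and metadata columns `state`
#' (integer copy number, 0..4 with 4 meaning "4+"), `nMarkers` (supporting
#' consecutive array markers; may be NA), `status` (`"GAIN"`/`"LOSS"`/
#' `"NEUTRAL"`, derived from `state`) and `mergedFrom` (number of original
#' calls combined into the record; 1 when unmerged). Calls are kept sorted
#' by chromosome (numeric order), start, end.
#'
#' The `CNVCallSet` is the unit on which filtering ([filterCalls()]),
#' adjacent-call merging ([mergeAdjacent()]) and between-individual
#' comparison ([matchPairwise()], [pairwiseDifference()]) operate.
#'
#' @param sampleId,programId single strings identifying the sample and the
#'   calling program.
#' @param calls a `GRanges` (or anything coercible via `GRanges()`); if the
#'   `status` or `mergedFrom` columns are absent they are filled in from
#'   `state` and as 1 respectively. Input order is not required; calls are
#'   sorted on construction.
#' @return a `CNVCallSet`.
#' @seealso [readCallTable()] to build sets from a call table,
#'   [CNVCallSetList] for collections.
#' @export
#' @examples
#' cs <- CNVCallSet("S1", "PC",
#'     GenomicRanges::GRanges("1", IRanges::IRanges(1000, 5999),
#'                            state = 1L, nMarkers = 12L))
#' cs
CNVCallSet <- function(sampleId, programId, calls = GRanges()) {
    gr <- if (is(calls, "GRanges")) calls else GRanges(calls)
    n <- length(gr)
    mc <- mcols(gr)
    if (n && !"state" %in% colnames(mc))
        stop("'calls' must carry a 'state' metadata column")
    state <- as.integer(mc$state)
    nMarkers <- if ("nMarkers" %in% colnames(mc)) as.integer(mc$nMarkers)
                else rep(NA_integer_, n)
    mergedFrom <- if ("mergedFrom" %in% colnames(mc))
                      as.integer(mc$mergedFrom)
                  else rep(1L, n)
    mcols(gr) <- DataFrame(state = state, nMarkers = nMarkers,
                           status = statusFromState(state),
                           mergedFrom = mergedFrom)
    if (!identical(seqlevels(gr), .AUTOSOMES))
        seqlevels(gr) <- intersect(.AUTOSOMES,
                                   union(.AUTOSOMES, seqlevels(gr)))
    ord <- .callOrder(gr)
    if (!identical(ord, seq_len(n))) gr <- gr[ord]
    new("CNVCallSet", sampleId = as.character(sampleId),
        programId = as.character(programId), calls = gr)
}

## trusted internal constructor: 'gr' already canonical (autosome
## seqlevels, canonical metadata columns, sorted); skips revalidation
.newCallSet <- function(sampleId, programId, gr) {
    S4Vectors::new2("CNVCallSet", sampleId = sampleId, programId = programId,
                    calls = gr, check = FALSE)
}

#' @rdname CNVCallSetList-class
#' @export
setClass("CNVCallSetList",
    contains = "SimpleList",
    prototype = prototype(elementType = "CNVCallSet"))

#' List of CNVCallSet objects
#'
#' A [S4Vectors::SimpleList] whose elements are [CNVCallSet] objects, named
#' `"<sample>|<program>"`. This is what [readCallTable()] and the simulator
#' return, and what the pipeline-level summaries consume.
#'
#' @param ... `CNVCallSet` objects, or a single list of them.
#' @return a `CNVCallSetList`.
#' @export
CNVCallSetList <- function(...) {
    elts <- list(...)
    if (length(elts) == 1L && is.list(elts[[1L]]) && !is(elts[[1L]], "CNVCallSet"))
        elts <- elts[[1L]]
    if (!all(vapply(elts, is, logical(1), "CNVCallSet")))
        stop("all elements must be CNVCallSet objects")
    if (is.null(names(elts)) || any(!nzchar(names(elts))))
        names(elts) <- vapply(elts, function(x)
            paste(x@sampleId, x@programId, sep = "|"), character(1))
    new("CNVCallSetList", S4Vectors::SimpleList(elts))
}

#' @rdname CNVEventGroups-class
#' @export
setClass("CNVEventGroups",
    representation(calls = "GRanges",
                   nGroups = "integer",
                   threshold = "numeric"))

.validCNVEventGroups <- function(object) {
    msg <- character()
    need <- c(.CALL_MCOLS, "sampleId", "programId", "groupId")
    missing <- setdiff(need, colnames(mcols(object@calls)))
    if (length(missing))
        msg <- c(msg, paste0("calls lack column(s): ",
                             paste(missing, collapse = ", ")))
    else if (length(object@calls)) {
        gid <- mcols(object@calls)$groupId
        if (!all(gid %in% seq_len(object@nGroups)))
            msg <- c(msg, "groupId values must cover 1..nGroups")
    }
    if (object@threshold < 0 || object@threshold > 1)
        msg <- c(msg, "threshold must be in [0, 1]")
    if (length(msg)) msg else TRUE
}
setValidity("CNVEventGroups", .validCNVEventGroups)

#' @rdname CallerProfile-class
#' @export
setClass("CallerProfile",
    representation(programId = "character",
                   sensitivity = "numeric",
                   fpRate = "numeric",
                   jitterSd = "numeric",
                   fragProb = "numeric",
                   stateFlipProb = "numeric"))

.validCallerProfile <- function(object) {
    msg <- character()
    p <- c(sensitivity = object@sensitivity, fragProb = object@fragProb,
           stateFlipProb = object@stateFlipProb)
    if (any(p < 0 | p > 1))
        msg <- c(msg, "sensitivity, fragProb and stateFlipProb must be in [0, 1]")
    if (object@fpRate < 0) msg <- c(msg, "fpRate must be >= 0")
    if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
    if (length(object@programId) != 1L || !nzchar(object@programId))
        msg <- c(msg, "programId must be a single non-empty string")
    if (length(msg)) msg else TRUE
}
setValidity("CallerProfile", .validCallerProfile)

#' Error model for one simulated CNV caller
#'
#' Describes how a simulated calling program distorts the true CNV
#' complement of an individual: `sensitivity` is the probability a true CNV
#' is detected at all; `fpRate` the expected number of spurious calls per
#' genome (Poisson); `jitterSd` the standard deviation (bp) of Gaussian
#' noise added independently to each breakpoint; `fragProb` the probability
#' a detected CNV is emitted as two fragments separated by a small gap
#' (at most 15% of the original span, so the default merge rule can rejoin
#' them); and `stateFlipProb` the probability the emitted gain/loss status
#' is inverted.
#'
#' @param programId caller name used in the emitted call sets.
#' @param sensitivity,fpRate,jitterSd,fragProb,stateFlipProb numeric scalars,
#'   see description.
#' @return a `CallerProfile`.
#' @seealso [applyCaller()], [defaultCallerProfiles()]
#' @export
#' @examples
#' callerProfile("perfect", sensitivity = 1, fpRate = 0, jitterSd = 0,
#'               fragProb = 0, stateFlipProb = 0)
callerProfile <- function(programId, sensitivity = 0.9, fpRate = 10,
                          jitterSd = 2000, fragProb = 0.1,
                          stateFlipProb = 0.01) {
    new("CallerProfile", programId = as.character(programId),
        sensitivity = sensitivity, fpRate = fpRate, jitterSd = jitterSd,
        fragProb = fragProb, stateFlipProb = stateFlipProb)
}

#' @rdname SimConfig-class
#' @export
setClass("SimConfig",
    representation(genome = "numeric",
                   pedigree = "data.frame",
                   nCnvsPerFounder = "integer",
                   lengthRange = "numeric",
                   populationSharedFraction = "numeric",
                   deNovoPerTwin = "numeric",
                   callerProfiles = "list",
                   seed = "integer"))

.validSimConfig <- function(object) {
    msg <- character()
    g <- object@genome
    if (length(g) != 22L || is.null(names(g)) ||
        !identical(names(g), .AUTOSOMES))
        msg <- c(msg, "genome must be a numeric vector named \"1\"..\"22\"")
    else if (any(g <= 1e7))
        msg <- c(msg, "all autosome lengths must exceed 10 Mb")
    ped <- object@pedigree
    need <- c("id", "father", "mother", "twinOf")
    if (!all(need %in% names(ped)))
        msg <- c(msg, "pedigree needs columns id, father, mother, twinOf")
    else {
        if (anyDuplicated(ped$id))
            msg <- c(msg, "pedigree ids must be unique")
        known <- c(NA, ped$id)
        if (!all(ped$father %in% known & ped$mother %in% known &
                 ped$twinOf %in% known))
            msg <- c(msg, "pedigree parent/twin references must resolve to ids")
        both <- !is.na(ped$twinOf) & (!is.na(ped$father) | !is.na(ped$mother))
        if (any(both))
            msg <- c(msg, "an MZ co-twin lists twinOf only; parents belong on the primary twin")
    }
    if (length(object@lengthRange) != 2L ||
        object@lengthRange[1] < 1000 ||
        object@lengthRange[2] <= object@lengthRange[1])
        msg <- c(msg, "lengthRange must be increasing and start above 1 kb")
    if (object@populationSharedFraction < 0 || object@populationSharedFraction > 1)
        msg <- c(msg, "populationSharedFraction must be in [0, 1]")
    if (object@nCnvsPerFounder < 1L)
        msg <- c(msg, "nCnvsPerFounder must be >= 1")
    if (object@deNovoPerTwin < 0)
        msg <- c(msg, "deNovoPerTwin must be >= 0")
    if (!all(vapply(object@callerProfiles, is, logical(1), "CallerProfile")))
        msg <- c(msg, "callerProfiles must be a list of CallerProfile objects")
    if (length(msg)) msg else TRUE
}
setValidity("SimConfig", .validSimConfig)
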