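#' @rdname CNVCallSet-class
#' @param object,x a `CNVCallSet`.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname CNVCallSet-class
#' @export
setGeneric("programId", function(object) standardGeneric("programId"))

#' @rdname CNVCallSet-class
#' @export
setGeneric("cnvCalls", function(object) standardGeneric("cnvCalls"))

#' @rdname CNVEventGroups-class
#' @export
setGeneric("nGroups", function(object) standardGeneric("nGroups"))

#' @rdname CNVEventGroups-class
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' @rdname CNVCallSet-class
setMethod("sampleId", "CNVCallSet", function(object) object@sampleId)

#' @rdname CNVCallSet-class
setMethod("programId", "CNVCallSet", function(object) object@programId)

#' @rdname CNVCallSet-class
setMethod("cnvCalls", "CNVCallSet", function(object) object@calls)

#' @rdname CNVCallSet-class
setMethod("length", "CNVCallSet", function(x) length(x@calls))

#' @rdname CNVCallSet-class
setMethod("show", "CNVCallSet", function(object) {
    cat("CNVCallSet: sample", object@sampleId,
        "| program", object@programId,
        "|", length(object@calls), "call(s)\n")
    if (length(object@calls)) {
        tab <- table(factor(mcols(object@calls)$status,
                            levels = c("GAIN", "LOSS", "NEUTRAL")))
        cat("  ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
        mf <- mcols(object@calls)$mergedFrom
        if (any(mf > 1L))
            cat("  ", sum(mf > 1L), "merged call(s) combining",
                sum(mf[mf > 1L]), "original calls\n")
    }
    invisible(NULL)
})

#' @rdname CNVEventGroups-class
setMethod("nGroups", "CNVEventGroups", function(object) object@nGroups)

#' @rdname CNVEventGroups-class
#' @param object a `CNVEventGroups`.
setMethod("show", "CNVEventGroups", function(object) {
    cat("CNVEventGroups:", object@nGroups, "event group(s) over",
        length(object@calls), "call(s); RO threshold",
        object@threshold, "\n")
    if (object@nGroups > 0L) {
        sizes <- table(mcols(object@calls)$groupId)
        cat("  group sizes: ", paste(range(sizes), collapse = "-"),
            " (median ", stats::median(sizes), ")\n", sep = "")
    }
    invisible(NULL)
})

#' @rdname CallerProfile-class
#' @param object a `CallerProfile`.
setMethod("show", "CallerProfile", function(object) {
    cat(sprintf(paste0("CallerProfile %s: sensitivity=%.2f fpRate=%.1f ",
                       "jitterSd=%.0fbp fragProb=%.2f stateFlipProb=%.2f\n"),
                object@programId, object@sensitivity, object@fpRate,
                object@jitterSd, object@fragProb, object@stateFlipProb))
    invisible(NULL)
})

#' @rdname SimConfig-class
#' @param object a `SimConfig`.
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", nrow(object@pedigree), "individuals,",
        object@nCnvsPerFounder, "CNVs/founder,",
        length(object@callerProfiles), "caller profile(s), seed",
        object@seed, "\n")
    invisible(NULL)
})
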