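#' @rdname normalizeCounts
#' @export
setGeneric("normalizeCounts", function(x, ...)
    standardGeneric("normalizeCounts"))

#' @rdname buildReference
#' @export
setGeneric("buildReference", function(x, ...)
    standardGeneric("buildReference"))

#' @rdname qcCheck
#' @export
setGeneric("qcCheck", function(x, minReads = 90000L)
    standardGeneric("qcCheck"))

#' Accessors for ControlReference
#'
#' `armMeans()` / `armSds()` return the per-arm mean and (floored) SD of
#' normalized fractions; `nControls()` the control cohort size; `sStats()`
#' the leave-one-out control sum-of-squares mean and SD used to standardize
#' the GWA score; `sdFloor()` the SD floor in force.
#'
#' @param x a [ControlReference-class] object.
#' @return Named numeric vectors (`armMeans`, `armSds`), an integer
#'   (`nControls`), a named numeric of length 2 (`sStats`), or a numeric
#'   (`sdFloor`).
#' @aliases armMeans armSds nControls sStats sdFloor
#' @name reference-accessors
#' @export
setGeneric("armMeans", function(x) standardGeneric("armMeans"))

#' @rdname reference-accessors
#' @export
setGeneric("armSds", function(x) standardGeneric("armSds"))

#' @rdname reference-accessors
#' @export
setGeneric("nControls", function(x) standardGeneric("nControls"))

#' @rdname reference-accessors
#' @export
setGeneric("sStats", function(x) standardGeneric("sStats"))

#' @rdname reference-accessors
#' @export
setGeneric("sdFloor", function(x) standardGeneric("sdFloor"))

#' @rdname fitTable
#' @export
setGeneric("fitTable", function(x) standardGeneric("fitTable"))

setMethod("armMeans", "ControlReference", function(x) x@armMean)
setMethod("armSds", "ControlReference", function(x) x@armSd)
setMethod("nControls", "ControlReference", function(x) x@nControls)
setMethod("sStats", "ControlReference",
          function(x) c(mean = x@sMean, sd = x@sSd))
setMethod("sdFloor", "ControlReference", function(x) x@sdFloor)

#' Tabulate a SurvivalFit
#'
#' @param x a [SurvivalFit-class] object.
#' @return `data.frame` with columns `term`, `coef`, `se`, `hr`, `ciLow`,
#'   `ciHigh`, `p`.
#' @export
setMethod("fitTable", "SurvivalFit", function(x) {
    data.frame(term = x@terms, coef = x@coef, se = x@se, hr = x@hr,
               ciLow = x@ciLow, ciHigh = x@ciHigh, p = x@p,
               row.names = NULL)
})

setMethod("show", "ControlReference", function(object) {
    cat("ControlReference with", length(object@armMean), "included arms,",
        object@nControls, "controls\n")
    cat(sprintf("  S statistics (leave-one-out): mean %.3f, sd %.3f\n",
                object@sMean, object@sSd))
    cat(sprintf("  sd floor: %.3g\n", object@sdFloor))
})

setMethod("show", "SurvivalFit", function(object) {
    cat("Cox proportional-hazards fit:", object@n, "subjects,",
        object@nEvents, "events\n")
    tab <- fitTable(object)
    tab$hr <- sprintf("%.2f", tab$hr)
    tab$ci95 <- sprintf("%.2f-%.2f", object@ciLow, object@ciHigh)
    tab$p <- format.pval(object@p, digits = 3, eps = 1e-4)
    print(tab[, c("term", "hr", "ci95", "p")], row.names = FALSE)
})

setMethod("show", "DPCRWell", function(object) {
    cat(sprintf("DPCRWell '%s': %d / %d partitions positive (%.1f nL)\n",
                object@target, object@nPositive, object@nPartitions,
                object@partitionVolume))
})
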