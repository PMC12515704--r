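#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData rowRanges
#' @importFrom stats sd setNames qnorm pnorm pchisq rgamma rmultinom rnorm
#'   runif rexp rbinom cor.test wilcox.test uniroot complete.cases coef
#'   as.formula
#' @importFrom utils read.table write.table
NULL

#' Arm-level read counts for one or more cfDNA samples
#'
#' `ArmCounts` extends [SummarizedExperiment::RangedSummarizedExperiment] with
#' one row per chromosome arm and one column per sample.  The single `"counts"`
#' assay holds raw reads per arm; `rowRanges()` carries the arm model (label,
#' inclusion flag, relative LINE-1 weight) and `colData()` the per-sample QC
#' metadata (`sample_id`, `timepoint`, `total_reads`, `qc_pass`).
#'
#' `total_reads` is the sum of counts over *included* arms only; counts on
#' excluded arms (acrocentric short arms, chrY) are retained for diagnostics
#' but never enter normalization or scoring.  `qc_pass` is `TRUE` when
#' `total_reads` reaches the configured minimum (default 90,000 reads).
#'
#' @seealso [ArmCounts()], [normalizeCounts()], [buildReference()]
#' @export
setClass("ArmCounts", contains = "RangedSummarizedExperiment")

setValidity("ArmCounts", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0) || any(!is.finite(cnt)))
            msg <- c(msg, "counts must be finite and non-negative")
    }
    need <- c("armName", "arm", "included", "weight")
    if (!all(need %in% names(SummarizedExperiment::rowData(object))))
        msg <- c(msg, paste("rowData must contain:",
                            paste(need, collapse = ", ")))
    needc <- c("sample_id", "timepoint", "total_reads", "qc_pass")
    if (!all(needc %in% names(SummarizedExperiment::colData(object))))
        msg <- c(msg, paste("colData must contain:",
                            paste(needc, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Healthy-control reference for GWA scoring
#'
#' Holds everything needed to score a new sample against a healthy (male)
#' control cohort: the per-arm mean and standard deviation of normalized
#' arm fractions, the number of controls, and the mean/SD of the control
#' sum-of-squares statistic S obtained leave-one-out.  Arm SDs are floored
#' at `sdFloor` to prevent division blow-ups on low-variance arms.
#'
#' @slot armMean named numeric, mean normalized fraction per included arm.
#' @slot armSd named numeric, floored SD of the normalized fraction per arm.
#' @slot nControls integer, number of control samples.
#' @slot sMean,sSd numeric, mean and SD of leave-one-out control S values.
#' @slot sdFloor numeric, the SD floor applied to `armSd`.
#'
#' @seealso [buildReference()], [armZscores()], [gwaScore()]
#' @export
setClass("ControlReference",
    slots = c(armMean = "numeric", armSd = "numeric", nControls = "integer",
              sMean = "numeric", sSd = "numeric", sdFloor = "numeric"))

setValidity("ControlReference", function(object) {
    msg <- NULL
    if (length(object@armMean) != length(object@armSd) ||
        !identical(names(object@armMean), names(object@armSd)))
        msg <- c(msg, "armMean and armSd must be parallel named vectors")
    if (abs(sum(object@armMean) - 1) > 1e-6)
        msg <- c(msg, "armMean must sum to 1 over included arms")
    if (object@nControls < 3L)
        msg <- c(msg, "at least 3 controls are required")
    if (!(object@sdFloor > 0))
        msg <- c(msg, "sdFloor must be positive")
    if (any(object@armSd < object@sdFloor - 1e-12))
        msg <- c(msg, "every armSd must be >= sdFloor")
    if (object@sSd < 0) msg <- c(msg, "sSd must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Cox proportional-hazards fit summary
#'
#' Thin container for a fitted Cox model in the "HR (95% CI), P" reporting
#' shape: per-term log-hazard coefficients, hazard ratios with Wald 95%
#' confidence intervals and p-values, plus the sample and event counts.
#'
#' @slot terms character, covariate names.
#' @slot coef,se numeric, log-hazard estimates and standard errors.
#' @slot hr,ciLow,ciHigh numeric, hazard ratios with 95% CI bounds.
#' @slot p numeric, Wald p-values.
#' @slot n,nEvents integer, subjects and events used in the fit.
#'
#' @seealso [coxFit()], [interactionModel()], [dynamicsAnalysis()],
#'   [fitTable()]
#' @export
setClass("SurvivalFit",
    slots = c(terms = "character", coef = "numeric", se = "numeric",
              hr = "numeric", ciLow = "numeric", ciHigh = "numeric",
              p = "numeric", n = "integer", nEvents = "integer"))

setValidity("SurvivalFit", function(object) {
    k <- length(object@terms)
    if (!all(lengths(list(object@coef, object@se, object@hr,
                          object@ciLow, object@ciHigh, object@p)) == k))
        return("all per-term slots must have one entry per term")
    ok <- is.finite(object@hr) & is.finite(object@ciLow) &
          is.finite(object@ciHigh)
    if (any(object@ciLow[ok] > object@hr[ok] + 1e-8) ||
        any(object@hr[ok] > object@ciHigh[ok] + 1e-8))
        return("CI must bracket the hazard ratio")
    TRUE
})

#' One digital-PCR well (partition summary)
#'
#' Partition-level summary of a dPCR well: how many partitions were read,
#' how many were positive for the target, and the partition volume in
#' nanoliters.  Concentrations are recovered by Poisson correction of the
#' positive fraction.
#'
#' @slot target character, assay target name (e.g. "AR", "AGO1").
#' @slot nPartitions,nPositive integer partition counts.
#' @slot partitionVolume numeric, nanoliters per partition.
#'
#' @seealso [DPCRWell()], [poissonConcentration()], [cnRatio()]
#' @export
setClass("DPCRWell",
    slots = c(target = "character", nPartitions = "integer",
              nPositive = "integer", partitionVolume = "numeric"))

setValidity("DPCRWell", function(object) {
    msg <- NULL
    if (object@nPartitions <= 0L)
        msg <- c(msg, "nPartitions must be positive")
    if (object@nPositive < 0L || object@nPositive > object@nPartitions)
        msg <- c(msg, "nPositive must lie in [0, nPartitions]")
    if (!(object@partitionVolume > 0))
        msg <- c(msg, "partitionVolume must be positive")
    if (is.null(msg)) TRUE else msg
})
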