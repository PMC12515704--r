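## Survival analysis of GWA status: Kaplan-Meier estimates, log-rank tests,
## Cox proportional-hazards fits (Efron ties, Wald CIs), the treatment-by-GWA
## interaction model, and the three-group longitudinal dynamics model.
## Estimators are endpoint-agnostic: FFS (ARSI) and TTNT (taxanes) both enter
## as (time, event) pairs; endpoint semantics live in the records.

.checkRecords <- function(records, need = c("time", "event")) {
    if (!is.data.frame(records) || nrow(records) == 0)
        stop("'records' must be a non-empty data.frame")
    missing <- setdiff(need, names(records))
    if (length(missing))
        stop("records missing column(s): ", paste(missing, collapse = ", "))
    if (any(records$time <= 0)) stop("times must be positive")
    if (!all(records$event %in% c(0, 1, FALSE, TRUE)))
        stop("event must be 0/1")
    invisible(records)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function, optionally stratified,
#' with median survival time (earliest time at which survival drops to 0.5
#' or below; `NA` when never reached).
#'
#' @param records `data.frame` with columns `time` (days) and `event`
#'   (1 = event, 0 = censored), plus the optional grouping column.
#' @param group optional name of a grouping column in `records`.
#' @return List with elements `fit` (a [survival::survfit] object, whose
#'   `time`/`surv` components give the step function) and `median` (named
#'   numeric of median survival times).
#' @examples
#' rec <- data.frame(time = 1:4, event = 1)
#' kmEstimate(rec)$median   # 2
#' @export
kmEstimate <- function(records, group = NULL) {
    .checkRecords(records)
    if (is.null(group)) {
        fit <- survival::survfit(
            survival::Surv(time, event) ~ 1, data = records)
    } else {
        records$.group <- records[[group]]
        fit <- survival::survfit(
            survival::Surv(time, event) ~ .group, data = records)
    }
    # median = earliest time with survival <= 0.5, NA when never reached
    stepMedian <- function(time, surv) {
        i <- which(surv <= 0.5 + 1e-12)
        if (length(i)) time[min(i)] else NA_real_
    }
    if (is.null(fit$strata)) {
        med <- c(all = stepMedian(fit$time, fit$surv))
    } else {
        idx <- rep(seq_along(fit$strata), fit$strata)
        med <- vapply(split(seq_along(idx), idx), function(j)
            stepMedian(fit$time[j], fit$surv[j]), numeric(1))
        names(med) <- sub("^\\.group=", "", names(fit$strata))
    }
    list(fit = fit, median = med)
}

#' Log-rank test
#'
#' Standard log-rank statistic comparing two or more survival curves, with
#' a chi-square reference on (groups - 1) degrees of freedom.
#'
#' @inheritParams kmEstimate
#' @param group name of the grouping column (required; 2 or more levels).
#' @return List with `chisq`, `df`, `pValue`.
#' @export
logrankTest <- function(records, group) {
    .checkRecords(records, c("time", "event", group))
    records$.group <- factor(records[[group]])
    if (nlevels(records$.group) < 2)
        stop("log-rank test needs at least 2 groups")
    if (any(table(records$.group) == 0)) stop("empty group")
    if (sum(records$event) == 0) stop("no events")
    sd <- survival::survdiff(survival::Surv(time, event) ~ .group,
                             data = records)
    df <- length(sd$n) - 1
    list(chisq = unname(sd$chisq), df = df,
         pValue = pchisq(sd$chisq, df, lower.tail = FALSE))
}

.separationGuard <- function(fit) {
    beta <- stats::coef(fit)
    se <- sqrt(diag(fit$var))
    if (any(!is.finite(beta)) || any(abs(beta) > 10) ||
        any(!is.finite(se)) || any(se > 100))
        stop("complete separation suspected (|log-HR| diverging); ",
             "consider an exact or penalized fit")
    invisible(fit)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood with the Efron approximation for tied event
#' times; hazard ratios with Wald 95% confidence intervals and p-values.
#'
#' @inheritParams kmEstimate
#' @param covariates character vector naming covariate columns of
#'   `records` (binary indicators or factors).
#' @return A [SurvivalFit-class] object.
#' @export
coxFit <- function(records, covariates) {
    .checkRecords(records, c("time", "event", covariates))
    fml <- stats::as.formula(paste(
        "survival::Surv(time, event) ~",
        paste(sprintf("`%s`", covariates), collapse = " + ")))
    environment(fml) <- environment()
    nonconv <- FALSE
    fit <- withCallingHandlers(
        survival::coxph(fml, data = records, ties = "efron"),
        warning = function(w) {
            if (grepl("Ran out of iterations", conditionMessage(w)))
                nonconv <<- TRUE
            invokeRestart("muffleWarning")
        })
    .separationGuard(fit)
    if (nonconv)
        stop("Cox fit did not converge after ", fit$iter, " iterations")
    beta <- stats::coef(fit)
    se <- sqrt(diag(fit$var))
    zq <- qnorm(0.975)
    new("SurvivalFit",
        terms = names(beta), coef = unname(beta), se = unname(se),
        hr = unname(exp(beta)),
        ciLow = unname(exp(beta - zq * se)),
        ciHigh = unname(exp(beta + zq * se)),
        p = unname(2 * pnorm(-abs(beta / se))),
        n = as.integer(fit$n), nEvents = as.integer(fit$nevent))
}

#' Treatment-by-GWA interaction model
#'
#' Cox fit with three terms — an ARSI treatment indicator, a GWA-high
#' indicator, and their product — mirroring the "treatment type, GWA
#' status, interaction" reporting rows.  The reference category is a
#' taxane-treated GWA-low patient.  All four treatment-by-status cells must
#' be populated.
#'
#' @param records `data.frame` with columns `time`, `event`, `treatment`
#'   (`"ARSI"`/`"taxane"`) and the status column.
#' @param status which dichotomized status to use: `"status_bl"`
#'   (baseline, default) or `"status_et"` (early timepoint), or any other
#'   column of low/high labels.
#' @return A [SurvivalFit-class] object with terms `treatmentARSI`,
#'   `gwaHigh`, `interaction`.
#' @export
interactionModel <- function(records, status = "status_bl") {
    .checkRecords(records, c("time", "event", "treatment", status))
    st <- records[[status]]
    if (anyNA(st)) stop("missing GWA status in column ", status)
    cells <- table(records$treatment, st)
    for (trt in c("ARSI", "taxane")) for (s in c("low", "high"))
        if (!trt %in% rownames(cells) || !s %in% colnames(cells) ||
            cells[trt, s] == 0)
            stop("empty stratum: treatment=", trt, ", status=", s)
    records$treatmentARSI <- as.integer(records$treatment == "ARSI")
    records$gwaHigh <- as.integer(st == "high")
    records$interaction <- records$treatmentARSI * records$gwaHigh
    coxFit(records, c("treatmentARSI", "gwaHigh", "interaction"))
}

#' Longitudinal GWA dynamics model
#'
#' Cox fit of the three-group dynamics classification with `GWAlow` as the
#' reference: dummy covariates for `GWAswitch` (discordant between
#' baseline and early timepoint) and `GWAhigh` (high at both).
#'
#' @param records `data.frame` with columns `time`, `event` and either a
#'   `dynamics` column (labels `GWAlow`/`GWAswitch`/`GWAhigh`) or both
#'   `status_bl` and `status_et` from which dynamics are derived via
#'   [classifyDynamics()].  All three groups must be present; groups with a
#'   single record yield an unstable fit and trigger a warning.
#' @return A [SurvivalFit-class] object with terms `GWAswitch`, `GWAhigh`.
#' @export
dynamicsAnalysis <- function(records) {
    .checkRecords(records)
    if (!"dynamics" %in% names(records)) {
        if (!all(c("status_bl", "status_et") %in% names(records)))
            stop("records need a 'dynamics' column or both ",
                 "'status_bl' and 'status_et'")
        records$dynamics <- classifyDynamics(records$status_bl,
                                             records$status_et)
    }
    tab <- table(records$dynamics)
    need <- c("GWAlow", "GWAswitch", "GWAhigh")
    missing <- setdiff(need, names(tab)[tab > 0])
    if (length(missing))
        stop("missing dynamics group(s): ", paste(missing, collapse = ", "))
    if (any(tab[need] == 1))
        warning("dynamics group with a single record; fit may be unstable")
    records$GWAswitch <- as.integer(records$dynamics == "GWAswitch")
    records$GWAhigh <- as.integer(records$dynamics == "GWAhigh")
    coxFit(records, c("GWAswitch", "GWAhigh"))
}

#' Read a clinical records CSV
#'
#' @param path CSV with columns `patient_id`, `treatment`, `endpoint`,
#'   `time_days`, `event` and optionally `status_bl`, `status_et`.
#' @return `data.frame` with a `time` column in days, validated for the
#'   endpoint/treatment pairing (FFS with ARSI, TTNT with taxanes).
#' @export
readClinical <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if ("time_days" %in% names(df)) df$time <- df$time_days
    .checkRecords(df, c("time", "event", "treatment", "endpoint"))
    bad <- (df$treatment == "ARSI" & df$endpoint != "FFS") |
           (df$treatment == "taxane" & df$endpoint != "TTNT")
    if (any(bad))
        stop("endpoint must be FFS for ARSI and TTNT for taxanes (row ",
             which(bad)[1], ")")
    df
}
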