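## Digital PCR: Poisson correction of partition counts and the
## target/reference (AR vs AGO1) copy-number ratio with a delta-method CI
## on the log ratio, plus the correlation of ratios with GWA scores.
##
## Baseline note: AGO1 is a single-copy autosomal reference (1p34.3) while
## AR sits on chrX, so an unamplified male sample has an expected AR/AGO1
## ratio of ~0.5 at the DNA level (one X vs two autosomes).  The ratio
## reported here is the raw lambda ratio, not renormalized to that
## baseline.

#' Construct a dPCR well
#'
#' @param target assay target name (e.g. `"AR"`, `"AGO1"`).
#' @param nPartitions total partitions read.
#' @param nPositive positive partitions.
#' @param partitionVolume partition volume in nanoliters (default 0.85 nL).
#' @return A [DPCRWell-class] object.
#' @export
DPCRWell <- function(target, nPartitions, nPositive,
                     partitionVolume = 0.85) {
    new("DPCRWell", target = as.character(target),
        nPartitions = as.integer(nPartitions),
        nPositive = as.integer(nPositive),
        partitionVolume = as.numeric(partitionVolume))
}

#' Poisson-corrected mean copies per partition
#'
#' `lambda = -ln(1 - nPositive/nPartitions)`.  A fully positive
#' (saturated) well carries no concentration information and is an error;
#' an all-negative well gives `lambda = 0` (valid).
#'
#' @param well a [DPCRWell-class] object.
#' @return Mean copies per partition (numeric).
#' @examples
#' poissonLambda(DPCRWell("AR", 20000, 10000))  # log(2)
#' @export
poissonLambda <- function(well) {
    stopifnot(is(well, "DPCRWell"))
    if (well@nPositive == well@nPartitions)
        stop("saturated well: all partitions positive")
    -log(1 - well@nPositive / well@nPartitions)
}

#' Poisson-corrected concentration
#'
#' @inheritParams poissonLambda
#' @return Copies per nanoliter.
#' @export
poissonConcentration <- function(well) {
    poissonLambda(well) / well@partitionVolume
}

# Delta-method variance of log(lambda-hat): Var(p-hat) = p(1-p)/n,
# dlambda/dp = 1/(1-p), so Var(log lambda) = p / ((1-p) n lambda^2).
.logLambdaVar <- function(well) {
    p <- well@nPositive / well@nPartitions
    lam <- poissonLambda(well)
    p / ((1 - p) * well@nPartitions * lam^2)
}

#' Target/reference copy-number ratio
#'
#' Ratio of Poisson-corrected concentrations (equal partition volumes
#' reduce to the lambda ratio), with a 95% CI from the delta method on the
#' log ratio, propagating the binomial uncertainty of each well's positive
#' fraction.
#'
#' @param target,reference [DPCRWell-class] objects.
#' @param conf confidence level (default 0.95).
#' @return `data.frame` with columns `ratio`, `ciLow`, `ciHigh`.  A target
#'   with no positive partitions yields ratio 0 with an undefined CI.
#' @export
cnRatio <- function(target, reference, conf = 0.95) {
    lamT <- poissonLambda(target)
    lamR <- poissonLambda(reference)
    if (lamR == 0) stop("reference not detected (lambda = 0)")
    concT <- lamT / target@partitionVolume
    concR <- lamR / reference@partitionVolume
    ratio <- concT / concR
    if (lamT == 0)
        return(data.frame(ratio = 0, ciLow = 0, ciHigh = NA_real_))
    v <- .logLambdaVar(target) + .logLambdaVar(reference)
    zq <- qnorm(1 - (1 - conf) / 2)
    data.frame(ratio = ratio,
               ciLow = ratio * exp(-zq * sqrt(v)),
               ciHigh = ratio * exp(zq * sqrt(v)))
}

#' Relate dPCR ratios to GWA scores
#'
#' Pearson correlation (and R^2) between per-sample AR/AGO1 ratios and GWA
#' scores, a rank-sum comparison of ratios between GWA-high and GWA-low
#' samples, and optionally the Pearson correlation with Xq Z-scores.
#'
#' @param ratio numeric vector of per-sample CN ratios.
#' @param gwa numeric vector of per-sample GWA scores (same order).
#' @param status optional character vector of `"low"`/`"high"` GWA
#'   statuses for the rank-sum comparison.
#' @param xqZ optional numeric vector of per-sample Xq Z-scores.
#' @return List with `pearsonR`, `rSquared`, `pValue`, and when available
#'   `rankSumP` (Wilcoxon) and `xqPearsonR`.
#' @export
ratioVsGwa <- function(ratio, gwa, status = NULL, xqZ = NULL) {
    ok <- complete.cases(ratio, gwa)
    if (sum(ok) < 10)
        stop("need at least 10 paired samples, got ", sum(ok))
    ct <- cor.test(ratio[ok], gwa[ok], method = "pearson")
    out <- list(pearsonR = unname(ct$estimate),
                rSquared = unname(ct$estimate)^2,
                pValue = ct$p.value)
    if (!is.null(status)) {
        g <- factor(status[ok], levels = c("low", "high"))
        if (nlevels(droplevels(g)) == 2)
            out$rankSumP <- wilcox.test(ratio[ok] ~ g)$p.value
    }
    if (!is.null(xqZ))
        out$xqPearsonR <- unname(cor.test(ratio[ok], xqZ[ok])$estimate)
    out
}

#' Read a dPCR well table
#'
#' @param path CSV with columns `sample_id`, `target`, `n_partitions`,
#'   `n_positive`, `partition_volume_nl`.
#' @return `data.frame` as read, validated.
#' @export
readDpcrWells <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "target", "n_partitions", "n_positive",
              "partition_volume_nl")
    if (!all(need %in% names(df)))
        stop("well table needs columns: ", paste(need, collapse = ", "))
    if (any(df$n_positive > df$n_partitions) || any(df$n_partitions <= 0))
        stop("invalid partition counts")
    df
}
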