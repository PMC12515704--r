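## Genome-wide aneuploidy (GWA) scoring: library-size normalization, per-arm
## Z-scores against a healthy-control reference, the summed-square GWA score
## standardized against the control S distribution, dichotomization at 5,
## and longitudinal dynamics labels.

#' Normalize arm counts to library size
#'
#' Converts raw per-arm counts to fractions of the total read count over
#' *included* arms.  Excluded arms are absent from the output; fractions
#' over included arms sum to 1 per sample.
#'
#' @param x an [ArmCounts-class] object.
#' @param ... unused.
#' @return Numeric matrix (included arms x samples) of fractions.
#' @export
setMethod("normalizeCounts", "ArmCounts", function(x, ...) {
    inc <- SummarizedExperiment::rowData(x)$included
    cnt <- SummarizedExperiment::assay(x, "counts")[inc, , drop = FALSE]
    tot <- colSums(cnt)
    if (any(tot == 0))
        stop("empty profile: no included-arm reads for sample(s) ",
             paste(colnames(cnt)[tot == 0], collapse = ", "))
    sweep(cnt, 2, tot, "/")
})

#' Build a healthy-control reference
#'
#' Estimates the per-arm mean and SD (denominator n-1) of normalized
#' fractions across a control cohort, and the null distribution of the
#' sum-of-squares statistic S = sum of squared per-arm Z-scores.  Each
#' control's S is computed *leave-one-out* — the control is scored against
#' a reference built from the remaining controls — so that the spread of S
#' is not shrunk by resubstitution.  Arm SDs below `sdFloor` are raised to
#' it; the default floor is 10% of the control mean fraction of the
#' smallest included arm.
#'
#' @param x an [ArmCounts-class] object holding at least 3 control samples,
#'   all passing QC.
#' @param sdFloor numeric SD floor; `NULL` for the default.
#' @param ... unused.
#' @return A [ControlReference-class] object.
#' @examples
#' arms <- hg38Arms()
#' ctrl <- makeControlCohort(simConfig(seed = 1), arms)
#' buildReference(ctrl)
#' @export
setMethod("buildReference", "ArmCounts", function(x, sdFloor = NULL, ...) {
    if (ncol(x) < 3)
        stop("at least 3 control profiles are required")
    qc <- SummarizedExperiment::colData(x)$qc_pass
    if (!all(qc))
        stop("control(s) failing QC: ",
             paste(colnames(x)[!qc], collapse = ", "))
    fr <- normalizeCounts(x)
    mu <- rowMeans(fr)
    if (is.null(sdFloor))
        sdFloor <- 0.1 * min(mu)
    sdv <- pmax(apply(fr, 1, sd), sdFloor)
    n <- ncol(fr)
    S <- vapply(seq_len(n), function(i) {
        fi <- fr[, -i, drop = FALSE]
        mi <- rowMeans(fi)
        si <- pmax(apply(fi, 1, sd), sdFloor)
        sum(((fr[, i] - mi) / si)^2)
    }, numeric(1))
    new("ControlReference", armMean = mu, armSd = sdv,
        nControls = as.integer(n), sMean = mean(S), sSd = sd(S),
        sdFloor = sdFloor)
})

#' Per-arm Z-scores against a control reference
#'
#' Computes `z_a = (p_a - mu_a) / sigma_a` for every included arm, where
#' `p_a` are normalized fractions and `mu_a`, `sigma_a` come from the
#' healthy-control reference.
#'
#' @param fractions matrix (arms x samples) or named vector of normalized
#'   fractions as returned by [normalizeCounts()], covering all reference
#'   arms.
#' @param ref a [ControlReference-class] object.
#' @return Numeric matrix (included arms x samples) of Z-scores.
#' @export
armZscores <- function(fractions, ref) {
    stopifnot(is(ref, "ControlReference"))
    if (is.null(dim(fractions)))
        fractions <- matrix(fractions, ncol = 1,
                            dimnames = list(names(fractions), NULL))
    armNames <- names(armMeans(ref))
    missing <- setdiff(armNames, rownames(fractions))
    if (length(missing))
        stop("fraction(s) missing for arm(s): ",
             paste(missing, collapse = ", "))
    extra <- setdiff(rownames(fractions), armNames)
    if (length(extra))
        stop("arm(s) missing from reference: ",
             paste(extra, collapse = ", "))
    fr <- fractions[armNames, , drop = FALSE]
    (fr - armMeans(ref)) / armSds(ref)
}

#' Genome-wide aneuploidy (GWA) score
#'
#' Squares and sums the per-arm Z-scores into `s_raw = sum(z_a^2)`.  In the
#' default `"standardized"` mode the score is re-standardized against the
#' control S distribution, `gwa = (s_raw - mean(S)) / sd(S)`, which makes
#' the published cutoff of 5 meaningful (a raw sum over 41 arms has null
#' expectation near 41); `"raw"` mode returns `s_raw` for inspection.
#' Samples are dichotomized `high` when `gwa >= threshold` (boundary
#' inclusive), else `low`.
#'
#' @param z Z-score matrix from [armZscores()] (arms x samples).
#' @param ref a [ControlReference-class] object.
#' @param threshold dichotomization cutoff (default 5).
#' @param mode `"standardized"` (default) or `"raw"`.
#' @param timepoint optional per-sample timepoint labels carried through.
#' @return A [S4Vectors::DataFrame] with columns `sample_id`, `timepoint`,
#'   `sRaw`, `gwa`, `status` (`"low"`/`"high"`) and `threshold`.
#' @export
gwaScore <- function(z, ref, threshold = 5,
                     mode = c("standardized", "raw"), timepoint = NA) {
    mode <- match.arg(mode)
    stopifnot(is(ref, "ControlReference"))
    if (is.null(dim(z)))
        z <- matrix(z, ncol = 1, dimnames = list(names(z), NULL))
    sRaw <- colSums(z^2)
    if (mode == "standardized") {
        s <- sStats(ref)
        if (s[["sd"]] <= 0)
            stop("degenerate control reference: sd(S) <= 0")
        gwa <- (sRaw - s[["mean"]]) / s[["sd"]]
    } else {
        gwa <- sRaw
    }
    ids <- colnames(z)
    if (is.null(ids)) ids <- paste0("sample", seq_along(sRaw))
    S4Vectors::DataFrame(
        sample_id = ids,
        timepoint = rep(timepoint, length.out = length(sRaw)),
        sRaw = unname(sRaw), gwa = unname(gwa),
        status = unname(ifelse(gwa >= threshold, "high", "low")),
        threshold = threshold)
}

#' Score samples end to end
#'
#' Convenience pipeline: normalize an [ArmCounts-class] object, compute
#' per-arm Z-scores against `ref`, and return GWA scores.
#'
#' @param x an [ArmCounts-class] object.
#' @param ref a [ControlReference-class] object.
#' @inheritParams gwaScore
#' @return See [gwaScore()].
#' @export
scoreSamples <- function(x, ref, threshold = 5,
                         mode = c("standardized", "raw")) {
    gwaScore(armZscores(normalizeCounts(x), ref), ref,
             threshold = threshold, mode = mode,
             timepoint = SummarizedExperiment::colData(x)$timepoint)
}

#' Longitudinal GWA dynamics label
#'
#' Combines the dichotomized GWA status at baseline and at the early
#' on-treatment timepoint into three groups: `GWAlow` (low at both),
#' `GWAhigh` (high at both) and `GWAswitch` (discordant, either
#' direction).  Missing statuses are an error; no imputation is performed.
#'
#' @param statusBl,statusEt character vectors of `"low"`/`"high"` statuses,
#'   recycled to a common length.
#' @return Character vector in `{GWAlow, GWAswitch, GWAhigh}`.
#' @examples
#' classifyDynamics(c("low", "high", "high"), c("low", "low", "high"))
#' @export
classifyDynamics <- function(statusBl, statusEt) {
    n <- max(length(statusBl), length(statusEt))
    statusBl <- rep(statusBl, length.out = n)
    statusEt <- rep(statusEt, length.out = n)
    if (anyNA(statusBl) || anyNA(statusEt))
        stop("missing GWA status; dynamics require both timepoints")
    ok <- c("low", "high")
    if (!all(statusBl %in% ok) || !all(statusEt %in% ok))
        stop("statuses must be 'low' or 'high'")
    ifelse(statusBl == statusEt,
           ifelse(statusBl == "high", "GWAhigh", "GWAlow"),
           "GWAswitch")
}

#' Serialize a control reference
#'
#' Writes/reads a single structured text file: a version tag, key-value
#' header (`nControls`, `sMean`, `sSd`, `sdFloor`) and a per-arm TSV table
#' of means and SDs.
#'
#' @param ref a [ControlReference-class] object.
#' @param path file path.
#' @return `writeControlReference` returns `path` invisibly;
#'   `readControlReference` returns a [ControlReference-class] object.
#' @export
writeControlReference <- function(ref, path) {
    stopifnot(is(ref, "ControlReference"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# aneuscore control reference v1",
                 sprintf("nControls\t%d", nControls(ref)),
                 sprintf("sMean\t%.15g", sStats(ref)[["mean"]]),
                 sprintf("sSd\t%.15g", sStats(ref)[["sd"]]),
                 sprintf("sdFloor\t%.15g", sdFloor(ref)),
                 "arm\tmean\tsd"), con)
    tab <- data.frame(arm = names(armMeans(ref)),
                      mean = sprintf("%.15g", armMeans(ref)),
                      sd = sprintf("%.15g", armSds(ref)))
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' @rdname writeControlReference
#' @export
readControlReference <- function(path) {
    lines <- readLines(path)
    if (!grepl("^# aneuscore control reference v1", lines[1]))
        stop("unrecognized reference file (missing version tag)")
    kv <- strsplit(lines[2:5], "\t")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, `[`, "", 2)
    names(vals) <- keys
    tabStart <- which(lines == "arm\tmean\tsd")[1]
    tab <- read.table(text = lines[(tabStart + 1):length(lines)],
                      sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("arm", "mean", "sd"))
    new("ControlReference",
        armMean = setNames(tab$mean, tab$arm),
        armSd = setNames(tab$sd, tab$arm),
        nControls = as.integer(vals[["nControls"]]),
        sMean = as.numeric(vals[["sMean"]]),
        sSd = as.numeric(vals[["sSd"]]),
        sdFloor = as.numeric(vals[["sdFloor"]]))
}
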