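## Synthetic-data generator: healthy-control cohorts, tumor-fraction cfDNA
## mixtures (Dirichlet-multinomial arm counts), matched tissue segments,
## dPCR wells, and survival outcomes under a proportional-hazards model
## with a treatment-by-GWA interaction.  Everything is reproducible from
## (config, seed); per-component child seeds are derived deterministically.

.childSeed <- function(seed, k) {
    # keep derived seeds inside 32-bit integer range
    as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629)
}

#' Diploid (normal male) arm copy-number profile
#'
#' Two copies on autosomal arms, one on chrX arms, over the included arms.
#'
#' @param arms arm `GRanges`.
#' @return Named numeric vector of copy numbers.
#' @export
diploidProfile <- function(arms) {
    expectedCnMale(arms, includedOnly = TRUE)
}

# Arm-level copy-number alterations of the high-aneuploidy prostate preset:
# a heavily aneuploid metastatic castration-resistant prostate genome with
# recurrent single-copy arm losses, broad gains, a high-level 8q gain and a
# high-level Xq gain modeling AR amplification (4 copies against the 1-copy
# male X background).  About half of the included arms are altered, in line
# with the elevated ploidy and structural-variant burden of high-aneuploidy
# mCRPC tumors.
.PROSTATE_HIGH <- c(
    "2q" = 1, "4p" = 1, "5q" = 1, "6q" = 1, "8p" = 1, "10q" = 1,
    "12p" = 1, "13q" = 1, "16q" = 1, "17p" = 1, "18q" = 1,
    "1q" = 3, "2p" = 3, "3q" = 3, "5p" = 3, "7p" = 3, "7q" = 3, "20q" = 3,
    "8q" = 4, "Xq" = 4)

#' Tumor arm copy-number profiles (presets)
#'
#' `"prostate_high"` is a heavily aneuploid metastatic prostate cancer
#' genome: single-copy losses of 2q, 4p, 5q, 6q, 8p, 10q, 12p, 13q, 16q,
#' 17p and 18q; broad gains of 1q, 2p, 3q, 5p, 7p, 7q and 20q (3 copies);
#' and high-level gains of 8q and Xq (4 copies; the Xq gain models AR
#' amplification on the single male X).  `"diploid"` is the normal male
#' background.
#'
#' @param preset `"prostate_high"` or `"diploid"`.
#' @param arms arm `GRanges`.
#' @return Named numeric vector of tumor copy numbers over included arms,
#'   with the preset name in `attr(, "name")`.
#' @export
tumorProfile <- function(preset = c("prostate_high", "diploid"),
                         arms = hg38Arms()) {
    preset <- match.arg(preset)
    prof <- diploidProfile(arms)
    if (preset == "prostate_high") {
        stopifnot(all(names(.PROSTATE_HIGH) %in% names(prof)))
        prof[names(.PROSTATE_HIGH)] <- .PROSTATE_HIGH
    }
    attr(prof, "name") <- preset
    prof
}

#' Simulation configuration
#'
#' Bundles the generator's knobs with their defaults: a 17-sample healthy
#' male control cohort, 100,000 reads per sample, Dirichlet-multinomial
#' overdispersion with concentration 1e5 (arm-fraction CV of roughly 3% at
#' the default depth), the 90,000-read QC floor, tissue noise SD of 0.1
#' copies, and survival parameters shaped like the treatment-by-GWA
#' interaction analysis (reference: taxane-treated GWA-low; hazard ratios
#' 2.36 for ARSI, 1.08 for GWA-high, 2.58 for their interaction; 20%
#' administrative censoring; baseline hazard 1/400 per day).
#'
#' The baseline tumor fraction mixture gives about half of patients
#' detectable disease (`f ~ U(0.15, 0.60)`) and half low burden
#' (`f ~ U(0, 0.05)`), deliberately separated from the f = 0.10 decision
#' boundary; at the early timepoint responders' f is multiplied by a
#' `U(0, 0.3)` draw while non-responders are unchanged, which produces the
#' predominantly high-to-low switch group.
#'
#' @param nControls control cohort size (default 17).
#' @param depth reads per sample (default 1e5).
#' @param concentration Dirichlet concentration; larger = closer to pure
#'   multinomial (default 1e5).
#' @param minReads QC floor (default 90,000).
#' @param tumorFraction default tumor fraction for single-sample draws.
#' @param tissueNoiseSd SD of segment copy-number noise (copies).
#' @param pHighBaseline probability of the detectable-f mixture component.
#' @param fLowRange,fHighRange ranges of the two mixture components.
#' @param responderProb probability that a patient responds (f shrinks at
#'   the early timepoint).
#' @param survival list: `baselineHazard` (events/day), `logHrTreatment`,
#'   `logHrGwa`, `logHrInteraction`, `censoring` (target fraction).
#' @param seed master seed.
#' @return A list of class `"aneuscore_simconfig"`.
#' @export
simConfig <- function(nControls = 17L, depth = 1e5, concentration = 1e5,
                      minReads = 90000L, tumorFraction = 0,
                      tissueNoiseSd = 0.1, pHighBaseline = 0.5,
                      fLowRange = c(0, 0.05), fHighRange = c(0.15, 0.6),
                      responderProb = 0.5,
                      survival = list(baselineHazard = 1 / 400,
                                      logHrTreatment = log(2.36),
                                      logHrGwa = log(1.08),
                                      logHrInteraction = log(2.58),
                                      censoring = 0.2),
                      seed = 1L) {
    stopifnot(nControls >= 3, depth > 0, concentration > 0,
              tumorFraction >= 0, tumorFraction <= 1, tissueNoiseSd >= 0,
              survival$baselineHazard > 0, survival$censoring >= 0,
              survival$censoring < 1)
    structure(list(nControls = as.integer(nControls), depth = depth,
                   concentration = concentration,
                   minReads = as.integer(minReads),
                   tumorFraction = tumorFraction,
                   tissueNoiseSd = tissueNoiseSd,
                   pHighBaseline = pHighBaseline, fLowRange = fLowRange,
                   fHighRange = fHighRange, responderProb = responderProb,
                   survival = survival, seed = as.integer(seed)),
              class = "aneuscore_simconfig")
}

# Expected arm mass of a cfDNA mixture: per-arm LINE-1 weight times the
# mixture copy number (1-f) * N_a + f * T_a (N: normal male, T: tumor).
.armMasses <- function(profile, arms, tumorFraction) {
    inc <- S4Vectors::mcols(arms)$included
    w <- S4Vectors::mcols(arms)$weight[inc]
    armNames <- S4Vectors::mcols(arms)$armName[inc]
    normalCn <- expectedCnMale(arms)
    tumorCn <- profile[armNames]
    if (anyNA(tumorCn))
        stop("profile missing arm(s): ",
             paste(armNames[is.na(tumorCn)], collapse = ", "))
    outer(w * normalCn[armNames], 1 - tumorFraction) +
        outer(w * tumorCn, tumorFraction)
}

#' Simulate cfDNA arm-count profiles
#'
#' Draws per-arm read counts from a Dirichlet-multinomial whose expected
#' arm mass is `w_a * ((1-f) * N_a + f * T_a)`: LINE-1 weight times the
#' copy number of a (1-f):f mixture of normal male (N) and tumor (T)
#' genomes.  `f = 0` reduces to the healthy-control model.  Overdispersion
#' is governed by the Dirichlet concentration: the multinomial fraction
#' variance is inflated by roughly `(depth + concentration) /
#' (concentration + 1)`.
#'
#' @param profile tumor copy-number profile over included arms (see
#'   [tumorProfile()]).
#' @param arms arm `GRanges`.
#' @param n number of samples.
#' @param tumorFraction tumor fraction f in [0, 1]; scalar or length-n
#'   vector.
#' @param depth reads per sample.
#' @param concentration Dirichlet concentration parameter.
#' @param seed optional seed (`NULL` = use the current RNG stream).
#' @param sampleIds,timepoint,minReads passed to [ArmCounts()].
#' @return An [ArmCounts-class] object with `n` columns; excluded arms
#'   carry zero counts (the generator does not emulate off-target reads).
#' @export
simulateCfdna <- function(profile, arms, n = 1L, tumorFraction = 0,
                          depth = 1e5, concentration = 1e5, seed = NULL,
                          sampleIds = NULL, timepoint = "baseline",
                          minReads = 90000L) {
    .checkArms(arms)
    if (!is.null(seed)) set.seed(seed)
    stopifnot(all(tumorFraction >= 0), all(tumorFraction <= 1))
    f <- rep(tumorFraction, length.out = n)
    mass <- .armMasses(profile, arms, f)     # included arms x n
    if (any(colSums(mass) <= 0)) stop("all arm masses are zero")
    alpha <- sweep(mass, 2, colSums(mass), "/") * concentration
    g <- matrix(rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
    p <- sweep(g, 2, colSums(g), "/")
    cnt <- vapply(seq_len(n),
                  function(j) rmultinom(1, size = depth, prob = p[, j])[, 1],
                  numeric(nrow(p)))
    rownames(cnt) <- rownames(mass)
    if (is.null(sampleIds)) sampleIds <- paste0("sim", seq_len(n))
    colnames(cnt) <- sampleIds
    ArmCounts(cnt, arms, sampleIds = sampleIds, timepoint = timepoint,
              minReads = minReads)
}

#' Simulate a healthy-control cohort
#'
#' `nControls` diploid male profiles at tumor fraction 0.  A depth below
#' the QC floor triggers a warning and the profiles are flagged
#' `qc_pass = FALSE`.
#'
#' @param config a [simConfig()] list.
#' @param arms arm `GRanges`.
#' @param seed optional override of `config$seed`.
#' @return An [ArmCounts-class] object.
#' @export
makeControlCohort <- function(config = simConfig(), arms = hg38Arms(),
                              seed = config$seed) {
    if (config$depth < config$minReads)
        warning("depth below QC minimum; control profiles flagged")
    simulateCfdna(diploidProfile(arms), arms, n = config$nControls,
                  tumorFraction = 0, depth = config$depth,
                  concentration = config$concentration, seed = seed,
                  sampleIds = sprintf("control%02d",
                                      seq_len(config$nControls)),
                  minReads = config$minReads)
}

#' Simulate tissue copy-number segments
#'
#' Emulates a purity-adjusted segment table for a tumor profile: each
#' included arm is split into 1-3 segments with random internal
#' boundaries, each segment's copy number being the arm's tumor copy
#' number plus Gaussian noise truncated at 0.
#'
#' @param profile tumor copy-number profile.
#' @param arms arm `GRanges`.
#' @param noiseSd Gaussian copy-number noise SD (copies).
#' @param seed optional seed.
#' @param maxSegments maximum segments per arm (default 3).
#' @return `GRanges` with metadata column `cn`, covering every included
#'   arm completely.
#' @export
simulateTissueSegments <- function(profile, arms, noiseSd = 0.1,
                                   seed = NULL, maxSegments = 3L) {
    .checkArms(arms)
    stopifnot(noiseSd >= 0)
    if (!is.null(seed)) set.seed(seed)
    incArms <- arms[S4Vectors::mcols(arms)$included]
    segs <- lapply(seq_along(incArms), function(i) {
        a <- incArms[i]
        armName <- S4Vectors::mcols(a)$armName
        k <- sample.int(maxSegments, 1)
        s0 <- GenomicRanges::start(a) - 1L   # back to 0-based
        e0 <- GenomicRanges::end(a)
        cuts <- sort(round(runif(k - 1, s0 + 1, e0 - 1)))
        bounds <- unique(c(s0, cuts, e0))
        k <- length(bounds) - 1
        cn <- pmax(0, profile[armName] + rnorm(k, 0, noiseSd))
        data.frame(chromosome = as.character(GenomicRanges::seqnames(a)),
                   start = bounds[-length(bounds)], end = bounds[-1],
                   copyNumber = cn)
    })
    segmentRanges(do.call(rbind, segs))
}

#' Simulate a patient cohort with outcomes
#'
#' Generates, per patient: a treatment assignment, a baseline tumor
#' fraction from the config's two-component mixture, an early-timepoint
#' fraction (shrunk by a `U(0, 0.3)` factor for responders), cfDNA
#' arm-count profiles at both timepoints, and an event time from an
#' exponential proportional-hazards model
#' `log h = log h0 + bTrt * I[ARSI] + bGwa * I[GWAhigh] +
#' bInt * I[ARSI] * I[GWAhigh]` (true baseline status, defined as
#' `f >= 0.10`), with administrative censoring calibrated to the target
#' censoring fraction.  The truth table (f values, true statuses, true
#' betas) is emitted alongside so downstream estimates can be scored
#' without re-reading generator internals.
#'
#' @param config a [simConfig()] list.
#' @param nPatients number of patients (>= 20).
#' @param arms arm `GRanges`.
#' @param profile tumor profile shared by patients (default
#'   `prostate_high`).
#' @param treatmentMix named probabilities for `ARSI` and `taxane`
#'   (default roughly the 154:42 cohort split).
#' @param forInteraction error if the treatment mix is degenerate (needed
#'   when the interaction model will be fit downstream).
#' @param seed optional override of `config$seed`.
#' @return List with `counts` (an [ArmCounts-class] with `2 * nPatients`
#'   columns, baseline and early per patient), `clinical` (records
#'   `data.frame` with true statuses and dynamics), and `truth`
#'   (per-patient f values, statuses, and the true betas as attributes).
#' @export
simulateCohort <- function(config = simConfig(), nPatients = 100L,
                           arms = hg38Arms(),
                           profile = tumorProfile("prostate_high", arms),
                           treatmentMix = c(ARSI = 0.785, taxane = 0.215),
                           forInteraction = FALSE, seed = config$seed) {
    stopifnot(nPatients >= 20)
    if (forInteraction && (min(treatmentMix) <= 0 ||
                           length(treatmentMix) < 2))
        stop("degenerate treatment mix: interaction recovery needs both ",
             "treatment classes")
    if (!is.null(seed)) set.seed(seed)
    trt <- sample(names(treatmentMix), nPatients, replace = TRUE,
                  prob = treatmentMix)
    highComp <- runif(nPatients) < config$pHighBaseline
    fBl <- ifelse(highComp,
                  runif(nPatients, config$fHighRange[1],
                        config$fHighRange[2]),
                  runif(nPatients, config$fLowRange[1],
                        config$fLowRange[2]))
    responder <- runif(nPatients) < config$responderProb
    fEt <- ifelse(responder, fBl * runif(nPatients, 0, 0.3), fBl)
    statusBl <- ifelse(fBl >= 0.10, "high", "low")
    statusEt <- ifelse(fEt >= 0.10, "high", "low")

    sv <- config$survival
    iArsi <- as.integer(trt == "ARSI")
    iHigh <- as.integer(statusBl == "high")
    rate <- sv$baselineHazard * exp(sv$logHrTreatment * iArsi +
                                    sv$logHrGwa * iHigh +
                                    sv$logHrInteraction * iArsi * iHigh)
    tEvent <- rexp(nPatients, rate)
    if (sv$censoring > 0) {
        cTime <- uniroot(function(C) mean(exp(-rate * C)) - sv$censoring,
                         interval = c(1e-6, 1e8))$root
    } else cTime <- Inf
    event <- as.integer(tEvent <= cTime)
    time <- pmin(tEvent, cTime)

    pid <- sprintf("pt%04d", seq_len(nPatients))
    bl <- simulateCfdna(profile, arms, n = nPatients, tumorFraction = fBl,
                        depth = config$depth,
                        concentration = config$concentration,
                        sampleIds = paste0(pid, "_BL"),
                        timepoint = "baseline", minReads = config$minReads)
    et <- simulateCfdna(profile, arms, n = nPatients, tumorFraction = fEt,
                        depth = config$depth,
                        concentration = config$concentration,
                        sampleIds = paste0(pid, "_ET"),
                        timepoint = "early", minReads = config$minReads)
    counts <- ArmCounts(
        cbind(SummarizedExperiment::assay(bl, "counts"),
              SummarizedExperiment::assay(et, "counts")),
        arms,
        timepoint = rep(c("baseline", "early"), each = nPatients),
        minReads = config$minReads)
    SummarizedExperiment::colData(counts)$patient_id <- rep(pid, 2)

    clinical <- data.frame(
        patient_id = pid, treatment = trt,
        endpoint = ifelse(trt == "ARSI", "FFS", "TTNT"),
        time = time, event = event,
        status_bl = statusBl, status_et = statusEt,
        dynamics = classifyDynamics(statusBl, statusEt),
        stringsAsFactors = FALSE)
    truth <- data.frame(
        patient_id = pid, f_bl = fBl, f_et = fEt, responder = responder,
        status_bl = statusBl, status_et = statusEt,
        stringsAsFactors = FALSE)
    attr(truth, "betas") <- c(treatment = sv$logHrTreatment,
                              gwa = sv$logHrGwa,
                              interaction = sv$logHrInteraction)
    attr(truth, "censorTime") <- cTime
    list(counts = counts, clinical = clinical, truth = truth)
}

#' Simulate dPCR AR/AGO1 well pairs
#'
#' One AR (target) and one AGO1 (reference) well per sample.  AGO1 is
#' diploid autosomal, so its mean copies per partition is `refLambda`
#' scaled by 2/2; AR occupancy scales with the sample's AR copy number
#' relative to the diploid autosomal dose, `lambda_AR = refLambda *
#' arCn / 2` — an unamplified male (1 AR copy on the single X) therefore
#' has a true AR/AGO1 ratio of 0.5.
#'
#' @param arCn numeric vector of absolute AR copy numbers per sample
#'   (1 = unamplified male).
#' @param nPartitions partitions per well (default 20,000).
#' @param refLambda AGO1 mean copies per partition (default 0.15).
#' @param partitionVolume nanoliters (default 0.85).
#' @param seed optional seed.
#' @return `data.frame` with columns `sample_id`, `target`,
#'   `n_partitions`, `n_positive`, `partition_volume_nl`.
#' @export
simulateDpcrWells <- function(arCn, nPartitions = 20000L,
                              refLambda = 0.15, partitionVolume = 0.85,
                              seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(arCn)
    lamT <- refLambda * arCn / 2
    lamR <- rep(refLambda, n)
    posT <- rbinom(n, nPartitions, 1 - exp(-lamT))
    posR <- rbinom(n, nPartitions, 1 - exp(-lamR))
    ids <- if (!is.null(names(arCn))) names(arCn)
           else sprintf("sample%03d", seq_len(n))
    data.frame(
        sample_id = rep(ids, each = 2),
        target = rep(c("AR", "AGO1"), n),
        n_partitions = as.integer(nPartitions),
        n_positive = as.integer(rbind(posT, posR)),
        partition_volume_nl = partitionVolume,
        stringsAsFactors = FALSE)
}
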