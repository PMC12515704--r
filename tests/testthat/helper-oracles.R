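# Shared fixtures and independent oracles used across test files.

# A 4-arm toy genome (two chromosomes with centromeric gaps):
#   1p = [0, 50), 1q = [60, 100); 2p = [0, 40), 2q = [50, 120)
toyCytobands <- function() {
    data.frame(
        chrom = rep(c("chr1", "chr2"), each = 4),
        start = c(0, 50, 55, 60, 0, 40, 45, 50),
        end   = c(50, 55, 60, 100, 40, 45, 50, 120),
        band  = rep(c("p1", "p11", "q11", "q1"), 2),
        stain = rep(c("gneg", "acen", "acen", "gneg"), 2))
}

toyArms <- function(excluded = character(0)) {
    loadCytobands(toyCytobands(), excluded = excluded)
}

# No-ties Cox partial log-likelihood for one covariate (independent of the
# package's survival-based fit).
coxPartialLogLik <- function(beta, time, event, x) {
    s <- 0
    for (i in which(event == 1)) {
        risk <- time >= time[i]
        s <- s + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
    s
}

# Grid-refined maximizer of the hand-coded partial likelihood.
coxOracleMax <- function(time, event, x, lower = -10, upper = 10) {
    opt <- optimize(function(b) coxPartialLogLik(b, time, event, x),
                    c(lower, upper), maximum = TRUE, tol = 1e-10)
    grid <- seq(max(lower, opt$maximum - 0.01),
                min(upper, opt$maximum + 0.01), by = 1e-4)
    ll <- vapply(grid, function(b) coxPartialLogLik(b, time, event, x),
                 numeric(1))
    grid[which.max(ll)]
}

# Observed-minus-expected two-group log-rank statistic (hypergeometric
# variance with tie correction).
logrankOracle <- function(time, event, group) {
    stopifnot(all(group %in% c(0, 1)))
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(time[event == 1]))) {
        atRisk <- time >= t
        n <- sum(atRisk)
        n1 <- sum(atRisk & group == 1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & group == 1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

# Score a cohort's profiles end to end against a reference and return
# estimated low/high statuses per patient for one timepoint.
estimatedStatuses <- function(cohort, ref, timepoint = "baseline") {
    cd <- SummarizedExperiment::colData(cohort$counts)
    sel <- cd$timepoint == timepoint
    sc <- scoreSamples(cohort$counts[, sel], ref)
    setNames(sc$status, cd$patient_id[sel])[cohort$clinical$patient_id]
}
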