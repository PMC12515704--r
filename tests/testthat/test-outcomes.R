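test_that("Kaplan-Meier estimate matches hand-computed product limits", {
    # four events, no censoring: survival drops by quarters, median at 2
    rec <- data.frame(time = 1:4, event = 1)
    km <- kmEstimate(rec)
    expect_equal(km$fit$surv, c(0.75, 0.5, 0.25, 0))
    expect_equal(unname(km$median), 2)
    # all censored: flat at 1, median undefined
    cens <- data.frame(time = 1:4, event = 0)
    kmc <- kmEstimate(cens)
    expect_true(all(kmc$fit$surv == 1))
    expect_true(is.na(kmc$median))
    # mixed censoring, hand-computed product-limit table:
    # events at 1, 3, 4, 6; censored at 2 and 5
    mix <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                      event = c(1, 0, 1, 1, 0, 1))
    kmm <- kmEstimate(mix)
    sAt <- stats::stepfun(kmm$fit$time, c(1, kmm$fit$surv))
    expect_equal(sAt(1), 5 / 6)
    expect_equal(sAt(3), 5 / 6 * 3 / 4)
    expect_equal(sAt(4), 5 / 6 * 3 / 4 * 2 / 3)
    expect_equal(sAt(6), 0)
    expect_equal(unname(kmm$median), 4)
    # with no censoring the KM curve is the empirical survival function
    set.seed(43)
    tt <- sort(rexp(30))
    fit <- kmEstimate(data.frame(time = tt, event = 1))$fit
    expect_equal(fit$surv, 1 - seq_len(30) / 30)
})

test_that("log-rank test matches the observed-minus-expected oracle", {
    # identical groups: statistic 0, p = 1
    one <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
    both <- rbind(cbind(one, g = "a"), cbind(one, g = "b"))
    lr <- logrankTest(both, "g")
    expect_equal(lr$chisq, 0, tolerance = 1e-12)
    expect_equal(lr$pValue, 1, tolerance = 1e-12)
    # small two-group data against the hand-coded statistic
    set.seed(47)
    for (i in 1:10) {
        n <- 12
        d <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.8),
                        g = rep(0:1, each = n / 2))
        if (sum(d$event) == 0) next
        lr <- logrankTest(d, "g")
        expect_equal(lr$chisq, logrankOracle(d$time, d$event, d$g),
                     tolerance = 1e-9)
    }
    # three groups are accepted with df = 2
    d3 <- data.frame(time = rexp(30), event = 1,
                     g = rep(c("GWAlow", "GWAswitch", "GWAhigh"), 10))
    expect_equal(logrankTest(d3, "g")$df, 2)
    expect_error(logrankTest(data.frame(time = 1:4, event = 0,
                                        g = rep(0:1, 2)), "g"),
                 "no events")
})

test_that("two-group log-rank equals the squared Cox score test at beta 0", {
    set.seed(53)
    for (i in 1:5) {
        n <- 20
        d <- data.frame(time = rexp(n) + runif(n) * 1e-4,
                        event = rbinom(n, 1, 0.8), x = rep(0:1, n / 2))
        fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d)
        expect_equal(logrankTest(d, "x")$chisq, unname(fit$score),
                     tolerance = 1e-6)
    }
})

test_that("Cox fit agrees with the brute-force partial likelihood", {
    set.seed(59)
    for (i in 1:20) {
        n <- 8
        d <- data.frame(time = rexp(n), event = rbinom(n, 1, 0.75),
                        x = rep(0:1, each = 4))
        if (sum(d$event[d$x == 0]) == 0 || sum(d$event[d$x == 1]) == 0)
            next
        oracle <- coxOracleMax(d$time, d$event, d$x)
        if (abs(oracle) > 5) {
            expect_error(coxFit(d, "x"), "separation")
        } else {
            fit <- coxFit(d, "x")
            expect_lt(abs(fit@coef - oracle), 1e-3)
        }
    }
})

test_that("identical event patterns give HR near 1 with CI spanning 1", {
    base <- data.frame(time = c(2, 4, 6, 8, 10, 12),
                       event = c(1, 1, 0, 1, 1, 1))
    d <- rbind(cbind(base, x = 0), cbind(base, x = 1))
    fit <- coxFit(d, "x")
    expect_equal(fit@hr, 1, tolerance = 1e-6)
    expect_lt(fit@ciLow, 1)
    expect_gt(fit@ciHigh, 1)
    expect_equal(fit@n, 12L)
    tab <- fitTable(fit)
    expect_equal(tab$term, "x")
    expect_equal(tab$hr, fit@hr)
})

test_that("hazard ratios are invariant to time-unit rescaling", {
    set.seed(61)
    n <- 80
    d <- data.frame(time = rexp(n, exp(0.7 * rep(0:1, n / 2))),
                    event = rbinom(n, 1, 0.8), x = rep(0:1, n / 2))
    fit1 <- coxFit(d, "x")
    d2 <- d; d2$time <- d$time * 30.44     # days -> months
    fit2 <- coxFit(d2, "x")
    expect_equal(fit1@hr, fit2@hr, tolerance = 1e-8)
    expect_equal(fit1@ciLow, fit2@ciLow, tolerance = 1e-8)
})

test_that("log-HR recovery is unbiased across a grid of true HRs", {
    set.seed(67)
    for (hr in c(1, 2, 4, 8)) {
        beta <- log(hr)
        est <- replicate(25, {
            n <- 500
            x <- rbinom(n, 1, 0.5)
            tt <- rexp(n, 0.01 * exp(beta * x))
            cens <- quantile(tt, 0.8)
            coxFit(data.frame(time = pmin(tt, cens),
                              event = as.integer(tt <= cens), x = x),
                   "x")@coef
        })
        tol <- max(0.1 * abs(beta), 0.06)
        expect_lt(abs(median(est) - beta), tol)
    }
})

test_that("interaction model reports treatment, GWA and product terms", {
    set.seed(71)
    n <- 240
    d <- data.frame(
        treatment = rep(c("ARSI", "taxane"), each = n / 2),
        status_bl = rep(c("low", "high"), n / 2),
        stringsAsFactors = FALSE)
    iA <- as.integer(d$treatment == "ARSI")
    iH <- as.integer(d$status_bl == "high")
    d$time <- rexp(n, 0.01 * exp(log(2) * iA * iH))
    d$event <- 1
    fit <- interactionModel(d)
    expect_equal(fit@terms, c("treatmentARSI", "gwaHigh", "interaction"))
    expect_equal(fit@n, n)
    # interaction generated at HR 2: point estimate in a sane range and
    # main effects near 1
    expect_gt(fit@hr[3], 1.2)
    expect_lt(abs(fit@coef[1]), 0.5)
    # an empty stratum is refused by name
    sub <- d[!(d$treatment == "taxane" & d$status_bl == "high"), ]
    expect_error(interactionModel(sub), "treatment=taxane, status=high")
})

test_that("dynamics model uses GWAlow as reference and recovers ordering", {
    set.seed(73)
    n <- 300
    dyn <- sample(c("GWAlow", "GWAswitch", "GWAhigh"), n, replace = TRUE)
    mult <- c(GWAlow = 1, GWAswitch = 1.3, GWAhigh = 7)
    d <- data.frame(time = rexp(n, 0.01 * mult[dyn]), event = 1,
                    dynamics = dyn, stringsAsFactors = FALSE)
    fit <- dynamicsAnalysis(d)
    expect_equal(fit@terms, c("GWAswitch", "GWAhigh"))
    expect_gt(fit@hr[2], fit@hr[1])    # high > switch, as generated
    expect_gt(fit@hr[2], 3)
    # shared event distribution: both HRs near 1
    d0 <- data.frame(time = rexp(n, 0.01), event = 1, dynamics = dyn,
                     stringsAsFactors = FALSE)
    fit0 <- dynamicsAnalysis(d0)
    expect_true(all(fit0@ciLow < 1 & fit0@ciHigh > 1))
    # statuses can substitute for explicit dynamics labels
    d2 <- data.frame(time = rexp(40, 0.01), event = 1,
                     status_bl = rep(c("low", "high", "high", "low"), 10),
                     status_et = rep(c("low", "high", "low", "high"), 10))
    expect_s4_class(dynamicsAnalysis(d2), "SurvivalFit")
    # missing group is an error; single-record group warns
    dm <- d[d$dynamics != "GWAswitch", ]
    expect_error(dynamicsAnalysis(dm), "GWAswitch")
    d1 <- rbind(d0[d0$dynamics != "GWAswitch", ],
                data.frame(time = 5, event = 1, dynamics = "GWAswitch"))
    expect_warning(dynamicsAnalysis(d1), "single record")
})

test_that("clinical CSV ingestion enforces the endpoint pairing", {
    path <- tempfile(fileext = ".csv")
    df <- data.frame(patient_id = c("p1", "p2"),
                     treatment = c("ARSI", "taxane"),
                     endpoint = c("FFS", "TTNT"),
                     time_days = c(120, 80), event = c(1, 0),
                     status_bl = c("high", "low"),
                     status_et = c("low", "low"))
    write.csv(df, path, row.names = FALSE)
    rec <- readClinical(path)
    expect_equal(rec$time, c(120, 80))
    df$endpoint[1] <- "TTNT"
    write.csv(df, path, row.names = FALSE)
    expect_error(readClinical(path), "FFS")
})
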