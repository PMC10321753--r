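test_that("KM curve equals 1 - ECDF without censoring and handles censoring", {
    km <- kmCurve(c(1, 2, 3), c(1, 1, 1))
    expect_equal(survProb(km), c(2 / 3, 1 / 3, 0))
    # censoring at t = 2: risk set at t = 3 is a single subject
    km <- kmCurve(c(1, 2, 3), c(1, 0, 1))
    expect_equal(eventTimes(km), c(1, 3))
    expect_equal(survProb(km), c(2 / 3, 0))
    # all censored: no event times, S identically one
    km <- kmCurve(c(4, 5), c(0, 0))
    expect_length(eventTimes(km), 0)
    set.seed(21)
    for (i in 1:15) {
        tm <- sample(1:20, sample(5:40, 1), replace = TRUE)
        km <- kmCurve(tm, rep(1, length(tm)))
        ec <- stats::ecdf(tm)
        expect_equal(survProb(km), 1 - ec(eventTimes(km)))
    }
    expect_error(kmCurve(c(-1, 2), c(1, 1)), "positive")
    expect_error(kmCurve(c(1, 2), c(1, 2)), "0/1")
})

test_that("KM matches survival::survfit with random censoring", {
    library(survival)
    set.seed(22)
    for (i in 1:10) {
        n <- sample(10:60, 1)
        tm <- sample(1:15, n, replace = TRUE)
        ev <- rbinom(n, 1, 0.7)
        if (sum(ev) == 0) ev[1] <- 1
        km <- kmCurve(tm, ev)
        sf <- summary(survfit(Surv(tm, ev) ~ 1),
                      times = eventTimes(km))
        expect_equal(survProb(km), sf$surv, tolerance = 1e-12)
        expect_equal(atRisk(km), sf$n.risk, tolerance = 1e-12)
    }
})

test_that("log-rank reproduces the hand-computed O/E/V table", {
    # arm A dies at 1 and 2, arm B at 3 and 4: O - E = 7/6, V = 17/36
    lr <- logRank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
    expect_equal(lr@observed - lr@expected, 7 / 6)
    expect_equal(lr@variance, 17 / 36)
    expect_equal(chisqStat(lr), 49 / 17)
    expect_equal(pValue(lr), pchisq(49 / 17, 1, lower.tail = FALSE))
    expect_equal(deficitArm(lr), "A")
})

test_that("log-rank symmetry, degeneracy and survdiff agreement", {
    tm <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 0, 1, 1, 0, 1)
    same <- logRank(c(tm, tm), c(ev, ev),
                    rep(c("X", "Y"), each = 6))
    expect_equal(chisqStat(same), 0)
    expect_equal(pValue(same), 1)
    expect_equal(deficitArm(same), "none")
    set.seed(23)
    library(survival)
    for (i in 1:15) {
        n <- sample(12:60, 1)
        tmr <- sample(1:10, n, replace = TRUE)
        evr <- rbinom(n, 1, 0.7); if (sum(evr) == 0) evr[1] <- 1
        g <- sample(c("A", "B"), n, replace = TRUE)
        if (length(unique(g)) < 2) g[1:2] <- c("A", "B")
        lr <- logRank(tmr, evr, g)
        swapped <- logRank(tmr, evr, ifelse(g == "A", "B", "A"))
        expect_equal(chisqStat(lr), chisqStat(swapped))
        expect_equal(pValue(lr), pValue(swapped))
        sd <- survdiff(Surv(tmr, evr) ~ g)
        expect_equal(chisqStat(lr), unname(sd$chisq), tolerance = 1e-10)
    }
    expect_error(logRank(1:4, c(1, 1, 1, 1), rep("A", 4)), "two distinct")
    expect_error(logRank(1:4, c(0, 0, 0, 0), rep(c("A", "B"), 2)),
                 "at least one event")
    # only event time has a single-arm risk set of itself: zero variance
    expect_warning(lr0 <- logRank(c(5, 1, 1), c(1, 0, 0), c("A", "B", "B")),
                   "degenerate")
    expect_equal(pValue(lr0), 1)
})

test_that("restricted mean and median survival summarize KM curves", {
    km <- kmCurve(c(1, 2, 3), c(1, 1, 1))
    # area: 1*1 + (2/3)*1 + (1/3)*1 over [0,3]
    expect_equal(restrictedMean(km, 3), 2)
    expect_equal(medianSurvival(km), 2)
    expect_true(is.na(medianSurvival(kmCurve(c(1, 2), c(0, 0)))))
})
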