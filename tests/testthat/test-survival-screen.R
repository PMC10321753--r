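test_that("quartile grouping matches a counting oracle, ties included", {
    v <- setNames(1:100, paste0("s", 1:100))
    g <- quartileGroups(v)
    expect_equal(sum(g == "low", na.rm = TRUE), 25)
    expect_equal(sum(g == "high", na.rm = TRUE), 25)
    v8 <- setNames(1:8, paste0("s", 1:8))
    g8 <- quartileGroups(v8)
    expect_equal(sum(g8 == "low", na.rm = TRUE), 2)
    expect_equal(sum(g8 == "high", na.rm = TRUE), 2)
    set.seed(61)
    for (i in 1:15) {
        vals <- setNames(sample(1:6, 40, replace = TRUE), paste0("s", 1:40))
        g <- quartileGroups(vals)
        qs <- quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
        # counting oracle applied to the stated boundary rule
        expect_equal(which(g == "low"), unname(which(vals <= qs[1])))
        expect_equal(which(g == "high"), unname(which(vals >= qs[2])))
    }
    expect_error(quartileGroups(setNames(rep(1, 20), 1:20)), "degenerate")
    expect_error(quartileGroups(setNames(1:5, 1:5)), "at least 8")
})

test_that("quartile groups are invariant under monotone transforms", {
    set.seed(62)
    v <- setNames(rnorm(60), paste0("s", 1:60))
    expect_identical(quartileGroups(exp(v)), quartileGroups(v))
})

test_that("z-score grouping isolates the upper tail", {
    set.seed(63)
    v <- setNames(rnorm(1000), paste0("s", 1:1000))
    g <- zscoreGroups(v)
    frac <- mean(g == "high")
    expect_lt(abs(frac - 0.023), 0.01)
    # location shifts leave the grouping unchanged
    expect_identical(zscoreGroups(v + 100), g)
    expect_identical(zscoreGroups(v * 7), g)
    expect_error(zscoreGroups(setNames(rep(2, 10), 1:10)), "variance")
    expect_error(zscoreGroups(v, cutoff = min(v) - 10), "empty arm")
})

test_that("survival contrast labels planted hazard directions", {
    se <- simulateBulkCohort(bulkCohortConfig(seed = 64))
    res <- screenSurvival(se, "NR2F6", mode = "quartile")
    expect_equal(res$label, "unfavorable")
    expect_lt(pValue(res$logrank), 0.05)
    resP <- screenSurvival(se, "NR1H3", mode = "quartile")
    expect_equal(resP$label, "favorable")
    # null NR: no label
    resN <- screenSurvival(se, "VDR", mode = "quartile")
    expect_gt(pValue(resN$logrank), 0.01)
    # identical survival in both arms: label none, p = 1
    cl <- data.frame(time = rep(c(1, 2, 3, 4, 5), 4),
                     event = rep(1, 20),
                     row.names = paste0("s", 1:20))
    # both arms carry the identical time/event multiset
    g <- setNames(factor(rep(rep(c("high", "low"), each = 5), 2),
                         levels = c("high", "low")),
                  paste0("s", 1:20))
    res0 <- survivalContrast(g, cl)
    expect_equal(res0$label, "none")
    expect_equal(pValue(res0$logrank), 1)
})

test_that("relabeling the arms flips the label but not the p-value", {
    se <- simulateBulkCohort(bulkCohortConfig(seed = 65))
    m <- SummarizedExperiment::assay(se)
    v <- setNames(m["NR2F6", ], colnames(m))
    g <- quartileGroups(v)
    res <- survivalContrast(g, se)
    gSwap <- setNames(factor(ifelse(g == "high", "low", "high"),
                             levels = c("high", "low")), names(g))
    resSwap <- survivalContrast(gSwap, se)
    expect_equal(pValue(resSwap$logrank), pValue(res$logrank))
    expect_equal(setdiff(c("favorable", "unfavorable"), res$label),
                 resSwap$label)
})
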