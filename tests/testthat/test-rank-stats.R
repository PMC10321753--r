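test_that("average ranks handle ties by midrank and preserve the rank sum", {
    expect_equal(averageRanks(c(10, 20, 30)), c(1, 2, 3))
    expect_equal(averageRanks(c(5, 5, 10)), c(1.5, 1.5, 3))
    expect_equal(averageRanks(c(7, 7, 7, 7)), rep(2.5, 4))
    set.seed(11)
    for (i in 1:20) {
        x <- sample(round(rnorm(sample(2:40, 1)), 1), replace = TRUE)
        n <- length(x)
        expect_equal(sum(averageRanks(x)), n * (n + 1) / 2)
        expect_equal(averageRanks(x), rank(x))  # base-R midrank cross-check
    }
    expect_error(averageRanks(numeric(0)), "nonempty")
    expect_error(averageRanks(c(1, NA)), "finite")
    expect_error(averageRanks(c(1, Inf)), "finite")
})

test_that("rank percentiles are rank/n and monotone-transform invariant", {
    expect_equal(rankPercentile(c(10, 20, 30, 40)), c(0.25, 0.5, 0.75, 1))
    expect_equal(rankPercentile(c(5, 5, 10)), c(0.5, 0.5, 1))
    set.seed(12)
    maps <- list(exp, function(v) v^3, function(v) atan(v) + 10,
                 function(v) 5 * v - 2, function(v) 1 / (1 + exp(-v)))
    for (i in 1:20) {
        x <- rnorm(sample(3:50, 1))
        f <- maps[[sample(length(maps), 1)]]
        expect_identical(rankPercentile(f(x)), rankPercentile(x))
        p <- rankPercentile(x)
        expect_true(all(p > 0 & p <= 1))
    }
})

test_that("Spearman rho matches the rank-Pearson and d-squared forms", {
    expect_equal(spearmanTest(1:3, 3:1)$rho, -1)
    x <- 1:5; y <- c(2, 1, 4, 3, 5)
    st <- spearmanTest(x, y)
    expect_equal(st$rho, 0.8)
    # classical no-ties formula 1 - 6*sum(d^2)/(n(n^2-1)), sum(d^2) = 4
    expect_equal(st$rho, 1 - 6 * 4 / (5 * 24))
    set.seed(13)
    for (i in 1:20) {
        n <- sample(4:30, 1)
        a <- rnorm(n); b <- rnorm(n)
        ct <- suppressWarnings(
            cor.test(a, b, method = "spearman", exact = FALSE))
        st <- spearmanTest(a, b)
        expect_equal(st$rho, unname(ct$estimate))
        expect_equal(st$p, ct$p.value, tolerance = 1e-12)
    }
    expect_error(spearmanTest(c(1, 1, 1), 1:3), "constant")
    expect_error(spearmanTest(1:4, 1:3), "equal length")
    expect_error(spearmanTest(1:10, 10:1, pMethod = "exact"), "n <=")
})

test_that("exact permutation p equals full enumeration", {
    expect_equal(spearmanTest(1:3, 3:1, pMethod = "exact")$p, 1 / 3)
    set.seed(14)
    for (i in 1:10) {
        n <- sample(3:6, 1)
        a <- rnorm(n)
        b <- sample(c(rnorm(n - 1), a[1]))  # allow an occasional tie
        expect_equal(spearmanTest(a, b, pMethod = "exact")$p,
                     spearmanExactOracle(a, b))
    }
})

test_that("Wilcoxon rank-sum: exact enumeration, symmetry, ties", {
    expect_equal(wilcoxonRankSum(1:3, 4:6)$p, 0.1)
    expect_equal(wilcoxonRankSum(c(3, 1, 2), c(3, 1, 2))$p, 1)
    set.seed(15)
    for (i in 1:10) {
        a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(2:5, 1))
        expect_equal(wilcoxonRankSum(a, b)$p, wilcoxonRankSum(b, a)$p)
        # exact route agrees with wilcox.test when there are no ties
        expect_equal(wilcoxonRankSum(a, b)$p,
                     wilcox.test(a, b, exact = TRUE)$p.value)
    }
    # large-sample route: normal approximation with tie correction
    for (i in 1:10) {
        a <- sample(round(rnorm(30), 1), replace = TRUE)
        b <- sample(round(rnorm(25), 1), replace = TRUE)
        wt <- suppressWarnings(
            wilcox.test(a, b, exact = FALSE, correct = FALSE))
        expect_equal(wilcoxonRankSum(a, b)$p, wt$p.value, tolerance = 1e-10)
    }
    expect_error(wilcoxonRankSum(numeric(0), 1:3), "nonempty")
})

test_that("BH adjustment equals the direct-formula oracle and p.adjust", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.5), 0.5)
    set.seed(16)
    for (i in 1:50) {
        p <- runif(sample(1:40, 1))
        adj <- bhAdjust(p)
        expect_identical(adj, bhOracle(p))
        expect_identical(adj, p.adjust(p, method = "BH"))
        expect_true(all(adj >= p))
        expect_true(all(adj <= 1))
    }
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(-0.1)), "\\[0, 1\\]")
})
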