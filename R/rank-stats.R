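#' Average (midrank) ranks
#'
#' Ranks a numeric vector from 1 to n, assigning tied values the mean of the
#' ranks they span. This tie convention propagates to every rank-based
#' statistic in the package: the rank-percentile signature index, Spearman
#' correlation and the Wilcoxon rank-sum test.
#'
#' @param x numeric vector, nonempty, all values finite.
#' @return numeric vector of average ranks; `sum(averageRanks(x))` always
#'   equals `n (n + 1) / 2`.
#' @examples
#' averageRanks(c(5, 5, 10))   # 1.5 1.5 3
#' @export
averageRanks <- function(x) {
    if (length(x) == 0L)
        stop("'x' must be nonempty")
    if (!is.numeric(x) || any(!is.finite(x)))
        stop("'x' must be numeric with all values finite")
    n <- length(x)
    o <- order(x)
    s <- x[o]
    r <- numeric(n)
    i <- 1L
    while (i <= n) {
        j <- i
        while (j < n && s[j + 1L] == s[i]) j <- j + 1L
        r[o[i:j]] <- (i + j) / 2
        i <- j + 1L
    }
    r
}

#' Rank percentiles
#'
#' The rank percentile of element i is its average rank divided by n, a
#' value in (0, 1]. Percentiles are invariant under any strictly increasing
#' transform of the input, which is what makes the signature index robust
#' to the expression scale (z-scores, log-TPM, ...).
#'
#' @inheritParams averageRanks
#' @return numeric vector of percentiles in (0, 1].
#' @examples
#' rankPercentile(c(10, 20, 30, 40))  # 0.25 0.50 0.75 1.00
#' @export
rankPercentile <- function(x) {
    averageRanks(x) / length(x)
}

#' Spearman rank correlation with t or exact-permutation p-value
#'
#' Computes rho as the Pearson correlation of the two average-rank vectors.
#' The two-sided p-value uses either the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom, or,
#' for small samples, exact enumeration of all n! pairings of the two
#' vectors (the permutation null of rho, counting `|rho_perm| >= |rho_obs|`).
#'
#' @param x,y numeric vectors of equal length n >= 3, each with at least
#'   two distinct values.
#' @param pMethod `"t"` (default) or `"exact"`; the exact method is
#'   refused above `exactCap` observations since it enumerates n! pairings.
#' @param exactCap largest n for which exact enumeration is allowed.
#' @return list with elements `rho`, `p`, `n`, `method`.
#' @examples
#' spearmanTest(c(1, 2, 3), c(3, 2, 1), pMethod = "exact")  # rho -1, p 1/3
#' @export
spearmanTest <- function(x, y, pMethod = c("t", "exact"), exactCap = 7L) {
    pMethod <- match.arg(pMethod)
    n <- length(x)
    if (length(y) != n)
        stop("'x' and 'y' must have equal length")
    if (n < 3L)
        stop("need at least 3 paired observations")
    if (!is.numeric(x) || !is.numeric(y) ||
        any(!is.finite(x)) || any(!is.finite(y)))
        stop("inputs must be numeric with all values finite")
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
        stop("constant input: Spearman correlation is undefined")
    rx <- averageRanks(x)
    ry <- averageRanks(y)
    rho <- stats::cor(rx, ry)
    if (pMethod == "t") {
        if (1 - rho^2 < 1e-14) {
            p <- 0
        } else {
            tstat <- rho * sqrt((n - 2) / (1 - rho^2))
            p <- 2 * stats::pt(-abs(tstat), df = n - 2)
        }
    } else {
        if (n > exactCap)
            stop("exact permutation p-value limited to n <= ", exactCap)
        perms <- .permutations(n)
        rxc <- rx - mean(rx)
        ryc <- ry - mean(ry)
        denom <- sqrt(sum(rxc^2) * sum(ryc^2))
        ryPerm <- matrix(ryc[perms], nrow = nrow(perms))
        rhos <- as.vector(ryPerm %*% rxc) / denom
        p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    }
    list(rho = rho, p = p, n = n, method = pMethod)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Unpaired rank-sum test on pooled average ranks. The statistic is the rank
#' sum of the first sample. The two-sided p-value is computed by exact
#' enumeration of all group assignments when the pooled size is at most
#' `exactMax`, otherwise by the normal approximation with the usual tie
#' correction of the rank variance.
#'
#' @param a,b numeric vectors, both nonempty, all values finite.
#' @param exactMax largest pooled size for exact enumeration.
#' @return list with `statistic` (rank sum of `a`), `p`, `nA`, `nB`,
#'   `method`.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided 0.1
#' @export
wilcoxonRankSum <- function(a, b, exactMax = 12L) {
    if (length(a) == 0L || length(b) == 0L)
        stop("both groups must be nonempty")
    if (!is.numeric(a) || !is.numeric(b) ||
        any(!is.finite(a)) || any(!is.finite(b)))
        stop("inputs must be numeric with all values finite")
    na <- length(a)
    nb <- length(b)
    n <- na + nb
    r <- averageRanks(c(a, b))
    W <- sum(r[seq_len(na)])
    E <- na * (n + 1) / 2
    if (n <= exactMax) {
        combs <- utils::combn(n, na)
        sums <- colSums(matrix(r[combs], nrow = na))
        p <- mean(abs(sums - E) >= abs(W - E) - 1e-12)
        method <- "exact"
    } else {
        V <- na * nb / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
        p <- if (V <= 0) 1 else
            min(1, 2 * stats::pnorm(-abs(W - E) / sqrt(V)))
        method <- "normal"
    }
    list(statistic = W, p = p, nA = na, nB = nb, method = method)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment of raw p-values: each adjusted value is
#' the running minimum, from the largest rank downward, of `p * m / rank`,
#' capped at 1, returned in the original input order.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order as the input; every
#'   adjusted value is at least its raw value.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("all p-values must lie in [0, 1]")
    m <- length(p)
    if (m == 0L) return(numeric(0))
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))
    adj[order(o)]
}

# all permutations of 1..n as an (n!) x n integer matrix
.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutations(n - 1L)
    m <- nrow(sub)
    out <- matrix(0L, n * m, n)
    for (i in seq_len(n)) {
        rows <- ((i - 1L) * m + 1L):(i * m)
        rest <- seq_len(n)[-i]
        out[rows, 1L] <- i
        out[rows, -1L] <- matrix(rest[sub], m)
    }
    out
}
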