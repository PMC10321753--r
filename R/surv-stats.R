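#' Kaplan-Meier product-limit estimate
#'
#' Estimates S(t) over the distinct event times. Subjects censored at an
#' event time are still counted in the risk set at that time (events are
#' processed before censorings at ties). With no censoring the curve equals
#' one minus the empirical CDF of the times.
#'
#' @param time positive follow-up times.
#' @param event event indicator, 1 = death, 0 = censored.
#' @return a [KMCurve-class] object. With no events the curve has no event
#'   times and S is identically 1.
#' @examples
#' kmCurve(c(1, 2, 3), c(1, 1, 1))  # S = 2/3, 1/3, 0
#' @export
kmCurve <- function(time, event) {
    .checkSurvInput(time, event)
    n <- length(time)
    et <- sort(unique(time[event == 1]))
    atRisk <- vapply(et, function(t) sum(time >= t), numeric(1))
    d <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
    s <- cumprod(1 - d / atRisk)
    new("KMCurve", time = as.numeric(et), surv = as.numeric(s),
        atRisk = atRisk, events = d, n = as.integer(n))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' At each distinct event time the observed number of first-group deaths is
#' compared with its hypergeometric expectation given the risk sets, and the
#' hypergeometric variance is accumulated. The statistic
#' `(O - E)^2 / V` is referred to the chi-squared distribution with one
#' degree of freedom. When no event time is informative (zero accumulated
#' variance) the test is degenerate: p is reported as 1 with a warning.
#'
#' @inheritParams kmCurve
#' @param group vector with exactly two distinct values assigning each
#'   subject to an arm; the first level (factor order) is the "first" group.
#' @return a [LogRankResult-class]. The `direction` slot names the arm with
#'   the survival deficit (excess hazard), or `"none"` when O = E.
#' @examples
#' logRank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#' @export
logRank <- function(time, event, group) {
    .checkSurvInput(time, event)
    if (length(group) != length(time))
        stop("'group' must match the length of 'time'")
    g <- factor(group)
    if (nlevels(g) != 2L)
        stop("'group' must contain exactly two distinct values")
    if (sum(event) < 1)
        stop("need at least one event overall")
    g1 <- g == levels(g)[1L]
    et <- sort(unique(time[event == 1]))
    O <- E <- V <- 0
    for (t in et) {
        at <- time >= t
        nAt <- sum(at)
        n1 <- sum(at & g1)
        dAt <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & g1)
        O <- O + d1
        E <- E + dAt * n1 / nAt
        if (nAt > 1)
            V <- V + dAt * (n1 / nAt) * (1 - n1 / nAt) * (nAt - dAt) / (nAt - 1)
    }
    if (V <= 0) {
        warning("no informative event time; log-rank test is degenerate")
        chi2 <- 0
        p <- 1
    } else {
        chi2 <- (O - E)^2 / V
        p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    }
    direction <- if (abs(O - E) < 1e-12) "none" else
        if (O > E) levels(g)[1L] else levels(g)[2L]
    new("LogRankResult", observed = O, expected = E, variance = V,
        chi2 = chi2, p = p, direction = direction, groups = levels(g))
}

#' Restricted mean survival time from a KM curve
#'
#' Area under the step survival curve from time zero up to `tau`. Used to
#' decide which arm of a survival contrast is the favorable one; unlike the
#' median it is always defined, even under heavy censoring.
#'
#' @param km a [KMCurve-class].
#' @param tau truncation time (must be positive).
#' @return restricted mean survival, in the time units of the input.
#' @export
restrictedMean <- function(km, tau) {
    stopifnot(is(km, "KMCurve"), is.numeric(tau), tau > 0)
    tms <- c(0, km@time[km@time <= tau], tau)
    s <- c(1, km@surv[km@time <= tau])
    sum(s * diff(tms))
}

#' Median survival from a KM curve
#'
#' First event time at which S(t) drops to 0.5 or below; NA when the curve
#' never reaches 0.5 (more than half the subjects survive follow-up).
#'
#' @param km a [KMCurve-class].
#' @return median survival time or NA.
#' @export
medianSurvival <- function(km) {
    i <- which(km@surv <= 0.5)
    if (length(i) == 0L) NA_real_ else km@time[min(i)]
}

.checkSurvInput <- function(time, event) {
    if (!is.numeric(time) || any(!is.finite(time)) || any(time <= 0))
        stop("'time' must be finite and strictly positive")
    if (length(event) != length(time) || !all(event %in% c(0, 1)))
        stop("'event' must be a 0/1 vector matching 'time'")
    invisible(TRUE)
}
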