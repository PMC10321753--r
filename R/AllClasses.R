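#' @import methods
NULL

#' Kaplan-Meier product-limit curve
#'
#' Container for a product-limit survival estimate over the distinct event
#' times of one group of subjects. Censored subjects contribute to the risk
#' sets; at tied times, events are processed before censorings (the standard
#' Mantel-Cox convention).
#'
#' @slot time ordered distinct event (death) times, in the units of the
#'   input follow-up times.
#' @slot surv survival probability S(t) at each event time.
#' @slot atRisk number of subjects at risk just before each event time.
#' @slot events number of deaths at each event time.
#' @slot n total number of subjects the curve was estimated from.
#'
#' @seealso [kmCurve()], [logRank()]
#' @exportClass KMCurve
setClass("KMCurve",
    representation(
        time = "numeric",
        surv = "numeric",
        atRisk = "numeric",
        events = "numeric",
        n = "integer"
    )
)

setValidity("KMCurve", function(object) {
    msg <- NULL
    k <- length(object@time)
    if (length(object@surv) != k || length(object@atRisk) != k ||
        length(object@events) != k)
        msg <- c(msg, "time, surv, atRisk and events must have equal length")
    if (k > 1 && any(diff(object@time) <= 0))
        msg <- c(msg, "event times must be strictly increasing")
    if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12))
        msg <- c(msg, "survival probabilities must lie in [0, 1]")
    if (k > 1 && any(diff(object@surv) > 1e-12))
        msg <- c(msg, "survival must be nonincreasing")
    if (is.null(msg)) TRUE else msg
})

#' Two-group log-rank (Mantel-Cox) test result
#'
#' Holds the observed and expected event counts for the first group, the
#' hypergeometric variance accumulated over event times, the chi-squared
#' statistic and its upper-tail p-value (1 df), and which arm carries the
#' survival deficit (the excess-hazard arm).
#'
#' @slot observed observed events in the first group.
#' @slot expected expected events in the first group under the null.
#' @slot variance accumulated hypergeometric variance.
#' @slot chi2 (observed - expected)^2 / variance.
#' @slot p upper-tail chi-squared probability, 1 degree of freedom.
#' @slot direction label of the arm with the survival deficit, or "none".
#' @slot groups the two group labels, first group first.
#'
#' @seealso [logRank()]
#' @exportClass LogRankResult
setClass("LogRankResult",
    representation(
        observed = "numeric",
        expected = "numeric",
        variance = "numeric",
        chi2 = "numeric",
        p = "numeric",
        direction = "character",
        groups = "character"
    )
)

setValidity("LogRankResult", function(object) {
    msg <- NULL
    if (object@chi2 < 0) msg <- c(msg, "chi2 must be nonnegative")
    if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
    if (length(object@groups) != 2) msg <- c(msg, "exactly two group labels")
    if (is.null(msg)) TRUE else msg
})

#' Full screening-cascade result
#'
#' Result of [runScreen()]: one verdict row per candidate gene with the four
#' stage flags (signature correlation, survival association, checkpoint-
#' therapy response association, tumor-intrinsic expression), the per-stage
#' statistics, and the final call; plus the funnel report describing how
#' many candidates survive each successive stage.
#'
#' @slot verdicts a [S4Vectors::DataFrame] keyed by gene with stage flags,
#'   statistics and the `final_call` column.
#' @slot funnel named integer vector of cumulative stage-survivor counts.
#' @slot thresholds list of thresholds the run used.
#' @slot seed integer seed recorded from the input cohorts (NA when inputs
#'   carry none).
#'
#' @seealso [runScreen()], [funnelReport()]
#' @exportClass NRScreenResult
setClass("NRScreenResult",
    representation(
        verdicts = "DataFrame",
        funnel = "integer",
        thresholds = "list",
        seed = "integer"
    )
)

setValidity("NRScreenResult", function(object) {
    msg <- NULL
    if (length(object@funnel) > 1 && any(diff(object@funnel) > 0))
        msg <- c(msg, "funnel counts must be nonincreasing")
    if (is.null(msg)) TRUE else msg
})
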