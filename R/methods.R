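#' @include AllClasses.R
NULL

#' Accessors for survival-statistics objects
#'
#' Small generics giving read access to the slots of [KMCurve-class],
#' [LogRankResult-class] and [NRScreenResult-class] objects.
#'
#' @param object a package result object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eventTimes", function(object) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setGeneric("survProb", function(object) standardGeneric("survProb"))
#' @rdname accessors
#' @export
setGeneric("atRisk", function(object) standardGeneric("atRisk"))
#' @rdname accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))
#' @rdname accessors
#' @export
setGeneric("chisqStat", function(object) standardGeneric("chisqStat"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("deficitArm", function(object) standardGeneric("deficitArm"))
#' @rdname accessors
#' @export
setGeneric("verdicts", function(object) standardGeneric("verdicts"))
#' @rdname accessors
#' @export
setGeneric("funnelReport", function(object) standardGeneric("funnelReport"))

#' @rdname accessors
#' @export
setMethod("eventTimes", "KMCurve", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("survProb", "KMCurve", function(object) object@surv)
#' @rdname accessors
#' @export
setMethod("atRisk", "KMCurve", function(object) object@atRisk)
#' @rdname accessors
#' @export
setMethod("nEvents", "KMCurve", function(object) object@events)

#' @rdname accessors
#' @export
setMethod("chisqStat", "LogRankResult", function(object) object@chi2)
#' @rdname accessors
#' @export
setMethod("pValue", "LogRankResult", function(object) object@p)
#' @rdname accessors
#' @export
setMethod("deficitArm", "LogRankResult", function(object) object@direction)

#' @rdname accessors
#' @export
setMethod("verdicts", "NRScreenResult", function(object) object@verdicts)

#' @rdname accessors
#' @export
setMethod("funnelReport", "NRScreenResult", function(object) {
    list(
        funnel = as.list(object@funnel),
        n_candidates = nrow(object@verdicts),
        thresholds = object@thresholds,
        seed = if (is.na(object@seed)) NULL else object@seed,
        package_version = as.character(utils::packageVersion("nrscreen"))
    )
})

setMethod("show", "KMCurve", function(object) {
    cat("KMCurve:", object@n, "subjects,",
        length(object@time), "distinct event times\n")
    if (length(object@time)) {
        cat("  S(t) range:", format(object@surv[length(object@surv)],
            digits = 3), "-", format(object@surv[1], digits = 3), "\n")
        med <- medianSurvival(object)
        cat("  median survival:",
            if (is.na(med)) "not reached" else format(med, digits = 4), "\n")
    } else {
        cat("  no events observed; S(t) = 1 throughout\n")
    }
})

setMethod("show", "LogRankResult", function(object) {
    cat("Log-rank (Mantel-Cox) test:",
        paste(object@groups, collapse = " vs "), "\n")
    cat(sprintf("  O = %.3f  E = %.3f  V = %.3f\n",
        object@observed, object@expected, object@variance))
    cat(sprintf("  chi2 = %.4f  p = %.4g  deficit arm: %s\n",
        object@chi2, object@p, object@direction))
})

setMethod("show", "NRScreenResult", function(object) {
    cat("NRScreenResult:", nrow(object@verdicts), "candidate genes\n")
    cat("  funnel:", paste(names(object@funnel), object@funnel,
        sep = "=", collapse = " -> "), "\n")
    calls <- object@verdicts$final_call
    cat("  immune-evasion candidates:",
        paste(object@verdicts$gene[calls == "immune_evasion"],
              collapse = ", "), "\n")
    prot <- object@verdicts$gene[calls == "protective"]
    if (length(prot))
        cat("  protective candidates:", paste(prot, collapse = ", "), "\n")
})
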