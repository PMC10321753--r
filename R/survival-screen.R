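#' Extreme-quartile expression grouping
#'
#' Splits samples into a low group (values at or below the `lo` quantile)
#' and a high group (values at or above the `hi` quantile); the middle is
#' excluded. Quantiles use the linear-interpolation convention (R type 7),
#' and the boundary rule is inclusive on both sides, so tied values at a
#' cut all enter the corresponding group.
#'
#' @param values named per-sample expression vector (>= 8 samples).
#' @param lo,hi quantile fractions, default 0.25 and 0.75.
#' @return factor keyed by sample with levels `high`, `low`; middle-band
#'   samples are `NA`.
#' @export
quartileGroups <- function(values, lo = 0.25, hi = 0.75) {
    if (length(values) < 8L)
        stop("need at least 8 samples for quartile grouping")
    if (length(unique(values)) < 2L)
        stop("degenerate input: all values equal")
    qs <- stats::quantile(values, probs = c(lo, hi), type = 7, names = FALSE)
    grp <- rep(NA_character_, length(values))
    grp[values <= qs[1]] <- "low"
    grp[values >= qs[2]] <- "high"
    if (qs[1] == qs[2] && any(values == qs[1]))
        stop("degenerate quantiles: low and high cuts coincide")
    stats::setNames(factor(grp, levels = c("high", "low")), names(values))
}

#' High-expressor z-score grouping
#'
#' Splits samples into high expressors (cohort z-score strictly above
#' `cutoff`) versus all other samples. The z-score is computed across the
#' cohort, so the grouping is invariant to location and scale shifts of
#' the input.
#'
#' @param values named per-sample expression vector with positive SD.
#' @param cutoff z-score cutoff, default 2.0.
#' @return factor keyed by sample with levels `high`, `rest`; errors when
#'   either group is empty.
#' @export
zscoreGroups <- function(values, cutoff = 2.0) {
    s <- stats::sd(values)
    if (!is.finite(s) || s <= 0)
        stop("zero variance: z-score grouping undefined")
    z <- (values - mean(values)) / s
    grp <- ifelse(z > cutoff, "high", "rest")
    if (all(grp == "high") || all(grp == "rest"))
        stop("empty arm: no samples on one side of the z cutoff")
    stats::setNames(factor(grp, levels = c("high", "rest")), names(values))
}

#' Survival contrast between expression groups
#'
#' Stage 2 of the cascade: Kaplan-Meier plus log-rank comparison of the
#' high-expression arm against the other arm. The gene is labeled
#' `unfavorable` when high expressors have significantly worse survival,
#' `favorable` when significantly better, `none` otherwise. "Worse" is
#' decided by restricted mean survival over the common follow-up horizon
#' rather than by medians, which can be undefined under heavy censoring;
#' arm medians are still reported.
#'
#' @param groups factor from [quartileGroups()] or [zscoreGroups()] keyed
#'   by sample (NA entries excluded).
#' @param clinical clinical table or SummarizedExperiment with `time` and
#'   `event` keyed by sample id.
#' @param alpha significance level for labeling.
#' @return list of class `SurvivalScreenResult`: `label`, `logrank`,
#'   `km` (per-arm [KMCurve-class]s), `groupSizes`, `medians`, `rmst`,
#'   `alpha`.
#' @export
survivalContrast <- function(groups, clinical, alpha = 0.05) {
    cl <- .clinicalTable(clinical)
    groups <- groups[!is.na(groups)]
    if (length(groups) == 0L || nlevels(droplevels(groups)) < 2L)
        stop("both expression arms must be nonempty")
    if (!all(names(groups) %in% rownames(cl)))
        stop("group sample ids absent from clinical table")
    tm <- cl[names(groups), "time"]
    ev <- cl[names(groups), "event"]
    lr <- logRank(tm, ev, groups)
    arms <- levels(groups)
    km <- lapply(arms, function(a)
        kmCurve(tm[groups == a], ev[groups == a]))
    names(km) <- arms
    tau <- min(vapply(arms, function(a) max(tm[groups == a]), numeric(1)))
    rmst <- vapply(km, restrictedMean, numeric(1), tau = tau)
    label <- "none"
    if (lr@p < alpha) {
        label <- if (rmst[[1L]] < rmst[[2L]]) "unfavorable" else "favorable"
    }
    structure(list(label = label, logrank = lr, km = km,
                   groupSizes = table(groups),
                   medians = vapply(km, medianSurvival, numeric(1)),
                   rmst = rmst, alpha = alpha),
              class = "SurvivalScreenResult")
}

#' Survival screen of one gene's expression
#'
#' Convenience wrapper: extracts the gene's expression, forms groups with
#' the requested rule and runs [survivalContrast()].
#'
#' @param expr gene x sample matrix or SummarizedExperiment (clinical data
#'   taken from colData unless `clinical` is supplied).
#' @param gene gene identifier.
#' @param clinical optional clinical table.
#' @param mode `"quartile"` (extreme quartiles) or `"zscore"` (z > cutoff
#'   versus the rest).
#' @param lo,hi quartile fractions for `mode = "quartile"`.
#' @param cutoff z cutoff for `mode = "zscore"`.
#' @param alpha significance level.
#' @return a `SurvivalScreenResult` (see [survivalContrast()]).
#' @export
screenSurvival <- function(expr, gene, clinical = expr,
                           mode = c("quartile", "zscore"),
                           lo = 0.25, hi = 0.75, cutoff = 2.0,
                           alpha = 0.05) {
    mode <- match.arg(mode)
    m <- .exprMatrix(expr)
    if (!gene %in% rownames(m))
        stop("gene absent from expression matrix: ", gene)
    v <- stats::setNames(m[gene, ], colnames(m))
    groups <- if (mode == "quartile") quartileGroups(v, lo = lo, hi = hi)
              else zscoreGroups(v, cutoff = cutoff)
    res <- survivalContrast(groups, clinical, alpha = alpha)
    res$mode <- mode
    res$gene <- gene
    res
}
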