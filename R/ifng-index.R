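#' Per-sample IFN-gamma signature index
#'
#' For each signature gene, every sample receives that gene's rank
#' percentile across the cohort; the index of a sample is the mean of its
#' ten percentiles. The index lives in (0, 1], is invariant under per-gene
#' strictly monotone transforms of expression, and a value of 1 means the
#' sample tops the cohort on every signature gene.
#'
#' @param expr a gene x sample matrix or
#'   [SummarizedExperiment::SummarizedExperiment].
#' @param signature signature gene identifiers; every one must be present
#'   in the matrix.
#' @return named numeric vector of per-sample indices, keyed by sample id.
#' @examples
#' m <- rbind(A = c(s1 = 1, s2 = 2), B = c(s1 = 0, s2 = 5))
#' computeIndex(m, c("A", "B"))  # s1 0.5, s2 1.0
#' @export
computeIndex <- function(expr, signature = ifngSignature()) {
    m <- .exprMatrix(expr)
    missing <- setdiff(signature, rownames(m))
    if (length(missing))
        stop("signature gene(s) absent from expression matrix: ",
             paste(missing, collapse = ", "))
    if (ncol(m) < 2L)
        stop("need at least 2 samples")
    pct <- t(apply(m[signature, , drop = FALSE], 1L, rankPercentile))
    idx <- colMeans(pct)
    stats::setNames(idx, colnames(m))
}

#' Survival contrast between extreme signature-index strata
#'
#' Compares samples with index strictly above `hiCut` against samples
#' strictly below `loCut` (the middle band is excluded; boundary samples
#' fall in the middle band) by Kaplan-Meier estimation and the log-rank
#' test.
#'
#' @param index named per-sample index as returned by [computeIndex()].
#' @param clinical clinical table (or SummarizedExperiment whose colData
#'   carries it) with `time` and `event`, keyed by sample id.
#' @param hiCut,loCut stratification fractions, default 0.75 / 0.25.
#' @return list with `logrank` ([LogRankResult-class]), `kmHigh`, `kmLow`
#'   ([KMCurve-class]), the two stratum sample-id vectors and arm median
#'   survivals.
#' @export
indexSurvivalContrast <- function(index, clinical,
                                  hiCut = 0.75, loCut = 0.25) {
    cl <- .clinicalTable(clinical)
    common <- intersect(names(index), rownames(cl))
    if (length(common) < length(index) || length(common) < nrow(cl))
        stop("index and clinical table disagree on sample ids")
    idx <- index[common]
    hi <- names(idx)[idx > hiCut]
    lo <- names(idx)[idx < loCut]
    if (length(hi) == 0L || length(lo) == 0L)
        stop("empty stratum: no samples beyond the index cuts")
    sel <- c(hi, lo)
    grp <- factor(rep(c("high", "low"), c(length(hi), length(lo))),
                  levels = c("high", "low"))
    lr <- logRank(cl[sel, "time"], cl[sel, "event"], grp)
    kmHigh <- kmCurve(cl[hi, "time"], cl[hi, "event"])
    kmLow <- kmCurve(cl[lo, "time"], cl[lo, "event"])
    list(logrank = lr, kmHigh = kmHigh, kmLow = kmLow,
         highSamples = hi, lowSamples = lo,
         medians = c(high = medianSurvival(kmHigh),
                     low = medianSurvival(kmLow)))
}
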