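#' Correlate one candidate gene with every signature gene
#'
#' Spearman correlation of the candidate's expression against each of the
#' ten signature genes, over pairwise complete samples. A candidate that
#' is itself a signature gene has that self-pair excluded and flagged
#' rather than trivially counted as a perfect correlation.
#'
#' @param expr gene x sample matrix or SummarizedExperiment.
#' @param gene candidate gene identifier.
#' @param signature signature gene identifiers.
#' @param pMethod p-value method passed to [spearmanTest()].
#' @return list with `gene`, `rho` and `p` (named by signature gene; NA
#'   for excluded or degenerate pairs), `n` samples used per pair,
#'   `excluded` (self-pairs), and `degenerate` (TRUE when the candidate
#'   row is constant).
#' @export
correlateVsSignature <- function(expr, gene, signature = ifngSignature(),
                                 pMethod = "t") {
    m <- .exprMatrix(expr)
    missing <- setdiff(c(gene, signature), rownames(m))
    if (length(missing))
        stop("gene(s) absent from expression matrix: ",
             paste(missing, collapse = ", "))
    x <- m[gene, ]
    rho <- p <- stats::setNames(rep(NA_real_, length(signature)), signature)
    nUsed <- stats::setNames(rep(NA_integer_, length(signature)), signature)
    degenerate <- length(unique(x[is.finite(x)])) < 2L
    excluded <- intersect(gene, signature)
    for (sg in setdiff(signature, gene)) {
        y <- m[sg, ]
        ok <- is.finite(x) & is.finite(y)
        nUsed[sg] <- sum(ok)
        if (degenerate || sum(ok) < 3L ||
            length(unique(y[ok])) < 2L) next
        st <- spearmanTest(x[ok], y[ok], pMethod = pMethod)
        rho[sg] <- st$rho
        p[sg] <- st$p
    }
    list(gene = gene, rho = rho, p = p, n = nUsed,
         excluded = excluded, degenerate = degenerate)
}

#' Classify a candidate's correlation direction
#'
#' Aggregates the ten per-pair tests into one direction call: `positive`
#' when at least `kMin` signature genes are significantly positively
#' correlated and none is significantly negative; `negative` by symmetry;
#' `none` otherwise (including conflicts and degenerate rows). Excluded
#' self-pairs do not count toward `kMin`.
#'
#' @param row result of [correlateVsSignature()].
#' @param alpha per-pair significance level (raw p, no multiplicity
#'   correction across the panel, matching a raw-p heatmap readout).
#' @param kMin minimum number of significant concordant pairs.
#' @return one of `"positive"`, `"negative"`, `"none"`.
#' @export
classifyDirection <- function(row, alpha = 0.05, kMin = 5L) {
    ok <- !is.na(row$rho) & !is.na(row$p)
    sigPos <- sum(ok & row$p < alpha & row$rho > 0)
    sigNeg <- sum(ok & row$p < alpha & row$rho < 0)
    if (sigPos >= kMin && sigNeg == 0L) return("positive")
    if (sigNeg >= kMin && sigPos == 0L) return("negative")
    "none"
}

#' Screen a candidate panel against the signature
#'
#' Stage 1 of the cascade: one [correlateVsSignature()] row per candidate,
#' with the aggregated direction call. Candidates keep their input order.
#'
#' @inheritParams correlateVsSignature
#' @param candidates candidate gene identifiers (all must be present).
#' @inheritParams classifyDirection
#' @return a [S4Vectors::DataFrame] with one row per candidate: `gene`,
#'   `direction`, `n_significant`, and per-signature-gene `rho_*` / `p_*`
#'   columns. Thresholds used are recorded in `metadata()`.
#' @export
screenCorrelation <- function(expr, candidates, signature = ifngSignature(),
                              alpha = 0.05, kMin = 5L, pMethod = "t") {
    if (length(candidates) == 0L)
        stop("'candidates' must be nonempty")
    m <- .exprMatrix(expr)
    missing <- setdiff(candidates, rownames(m))
    if (length(missing))
        stop("candidate gene(s) absent from expression matrix: ",
             paste(missing, collapse = ", "))
    rows <- lapply(candidates, function(g)
        correlateVsSignature(m, g, signature, pMethod = pMethod))
    direction <- vapply(rows, classifyDirection, character(1),
                        alpha = alpha, kMin = kMin)
    nSig <- vapply(rows, function(r)
        sum(!is.na(r$p) & r$p < alpha), integer(1))
    rho <- do.call(rbind, lapply(rows, `[[`, "rho"))
    p <- do.call(rbind, lapply(rows, `[[`, "p"))
    colnames(rho) <- paste0("rho_", signature)
    colnames(p) <- paste0("p_", signature)
    out <- S4Vectors::DataFrame(
        gene = candidates, direction = direction, n_significant = nSig,
        rho, p, row.names = candidates, check.names = FALSE)
    S4Vectors::metadata(out) <- list(alpha = alpha, kMin = kMin,
                                     signature = signature)
    out
}
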