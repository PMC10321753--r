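#' Run the full NR prioritization cascade
#'
#' Orchestrates the four screening stages for every candidate nuclear
#' receptor: (1) Spearman correlation with the IFN-gamma signature,
#' (2) extreme-quartile overall-survival contrast, (3) responder versus
#' nonresponder contrast in malignant cells, (4) tumor-intrinsic
#' percent-expression filter. All stages are computed for all candidates
#' (no early exit) so the funnel report mirrors the full selection
#' workflow; the final call requires all four flags with coherent
#' directions. A negatively correlated, unfavorable-survival,
#' higher-in-nonresponders, tumor-intrinsic gene is an `immune_evasion`
#' candidate; the mirrored pattern is reported separately as `protective`.
#'
#' @param bulk bulk cohort: SummarizedExperiment with a z-score assay and
#'   clinical colData, or a path to an expression TSV (then `clinical`
#'   must be supplied).
#' @param cells single-cell cohort: SingleCellExperiment with `cell_type`,
#'   `patient`, `response` annotations, or a path readable by
#'   [readCells()].
#' @param candidates candidate gene identifiers (default: the panel NRs
#'   present in the bulk matrix).
#' @param signature signature gene identifiers.
#' @param clinical clinical table when `bulk` does not carry one.
#' @param alpha significance level used by stages 1-3.
#' @param kMin minimum significant concordant pairs for stage 1.
#' @param lo,hi quartile fractions for stage 2.
#' @param tau percent-expressing cutoff for stage 4.
#' @return an [NRScreenResult-class]; see [verdicts()] and
#'   [funnelReport()].
#' @examples
#' bulk <- simulateBulkCohort(bulkCohortConfig(nSamples = 120, seed = 3))
#' sc <- simulateScCohort(scCohortConfig(cellsPerPatient = 30L, seed = 3))
#' res <- runScreen(bulk, sc)
#' @export
runScreen <- function(bulk, cells, candidates = NULL,
                      signature = ifngSignature(), clinical = NULL,
                      alpha = 0.05, kMin = 5L, lo = 0.25, hi = 0.75,
                      tau = 10.0) {
    if (is.character(bulk)) bulk <- readExpression(bulk)
    if (is.character(cells)) cells <- readCells(cells)
    m <- .exprMatrix(bulk)
    cl <- .clinicalTable(if (is.null(clinical)) bulk else clinical)
    bad <- setdiff(colnames(m), rownames(cl))
    if (length(bad))
        stop("samples missing from clinical table: ",
             paste(bad, collapse = ", "))
    if (is.null(candidates))
        candidates <- intersect(nrPanel(), rownames(m))
    if (length(candidates) == 0L) stop("'candidates' must be nonempty")
    scGenes <- rownames(.cellMatrix(cells))
    bad <- setdiff(candidates, scGenes)
    if (length(bad))
        stop("candidates missing from single-cell matrix: ",
             paste(bad, collapse = ", "))

    corr <- screenCorrelation(m, candidates, signature,
                              alpha = alpha, kMin = kMin)
    surv <- lapply(candidates, function(g) tryCatch(
        screenSurvival(m, g, cl, mode = "quartile", lo = lo, hi = hi,
                       alpha = alpha),
        error = function(e) NULL))
    survLabel <- vapply(surv, function(s)
        if (is.null(s)) "none" else s$label, character(1))
    survP <- vapply(surv, function(s)
        if (is.null(s)) NA_real_ else pValue(s$logrank), numeric(1))
    resp <- lapply(candidates, function(g) responseContrast(cells, g))
    respP <- vapply(resp, `[[`, numeric(1), "p")
    respDiff <- vapply(resp, `[[`, numeric(1), "difference")
    scSummary <- scExpressionSummary(cells, genes = candidates)
    intrinsic <- malignantFilter(scSummary, tau = tau)[candidates]
    pctMalignant <- stats::setNames(
        scSummary$percent_expressing[scSummary$cell_type == "malignant"],
        scSummary$gene[scSummary$cell_type == "malignant"])[candidates]

    sigFlag <- corr$direction != "none"
    survFlag <- survLabel != "none"
    respFlag <- !is.na(respP) & respP < alpha
    intrFlag <- as.logical(intrinsic)
    call <- rep("none", length(candidates))
    evasion <- sigFlag & survFlag & respFlag & intrFlag &
        corr$direction == "negative" & survLabel == "unfavorable" &
        respDiff > 0
    protective <- sigFlag & survFlag & respFlag & intrFlag &
        corr$direction == "positive" & survLabel == "favorable" &
        respDiff < 0
    call[evasion] <- "immune_evasion"
    call[protective] <- "protective"

    vd <- S4Vectors::DataFrame(
        gene = candidates,
        signature_correlated = sigFlag,
        survival_associated = survFlag,
        response_associated = respFlag,
        tumor_intrinsic = intrFlag,
        direction = corr$direction,
        survival_label = survLabel,
        survival_p = survP,
        response_difference = respDiff,
        response_p = respP,
        percent_malignant = pctMalignant,
        final_call = call,
        row.names = candidates)
    funnel <- c(candidates = length(candidates),
                signature_correlated = sum(sigFlag),
                plus_survival = sum(sigFlag & survFlag),
                plus_response = sum(sigFlag & survFlag & respFlag),
                plus_tumor_intrinsic =
                    sum(sigFlag & survFlag & respFlag & intrFlag))
    new("NRScreenResult", verdicts = vd, funnel = funnel,
        thresholds = list(alpha = alpha, kMin = kMin, lo = lo, hi = hi,
                          tau = tau),
        seed = .cohortSeed(bulk))
}

#' Write the funnel report as JSON
#'
#' @param result an [NRScreenResult-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFunnelReport <- function(result, path) {
    rpt <- funnelReport(result)
    rpt$immune_evasion_candidates <- as.list(
        result@verdicts$gene[result@verdicts$final_call == "immune_evasion"])
    rpt$protective_candidates <- as.list(
        result@verdicts$gene[result@verdicts$final_call == "protective"])
    jsonlite::write_json(rpt, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}
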