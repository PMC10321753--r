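#' Default detection-fraction array for the synthetic single-cell cohort
#'
#' Builds the gene x cell-type x response-group array of detection
#' fractions (probability a cell of that type in that group expresses the
#' gene above zero). The baseline is a low uniform detection; the planted
#' immune-evasion NR and the planted suppressive effectors are detected in
#' `plantedHigh` of malignant cells from nonresponders versus `plantedLow`
#' from responders, and the planted protective genes use the mirrored
#' pattern.
#'
#' @param genes gene identifiers.
#' @param cellTypes cell-type labels.
#' @param plantedNonresponderHigh genes detected at `plantedHigh` in
#'   malignant cells of nonresponders (and `plantedLow` in responders).
#' @param plantedResponderHigh genes with the mirrored pattern.
#' @param base baseline detection fraction everywhere else.
#' @param plantedHigh,plantedLow the two planted malignant-cell detection
#'   fractions.
#' @return 3-d numeric array `[gene, cellType, response]` with response
#'   levels `responder`, `nonresponder`.
#' @export
scDetectionDefaults <- function(genes,
                                cellTypes = c("malignant", "T_cell",
                                    "B_cell", "macrophage", "NK",
                                    "endothelial", "CAF"),
                                plantedNonresponderHigh =
                                    c("NR2F6", "NACC1", "FKBP10"),
                                plantedResponderHigh =
                                    c("NR1H3", "CXCL10"),
                                base = 0.05,
                                plantedHigh = 0.40,
                                plantedLow = 0.10) {
    det <- array(base,
        dim = c(length(genes), length(cellTypes), 2L),
        dimnames = list(genes, cellTypes,
                        c("responder", "nonresponder")))
    hi <- intersect(plantedNonresponderHigh, genes)
    det[hi, "malignant", "nonresponder"] <- plantedHigh
    det[hi, "malignant", "responder"] <- plantedLow
    lo <- intersect(plantedResponderHigh, genes)
    det[lo, "malignant", "responder"] <- plantedHigh
    det[lo, "malignant", "nonresponder"] <- plantedLow
    det
}

#' Configuration for the synthetic single-cell cohort
#'
#' The generator emulates an annotated melanoma single-cell expression
#' matrix: each patient contributes `cellsPerPatient` cells whose types are
#' drawn from `cellTypeProportions`; a gene is detected in a cell with the
#' configured detection fraction for that gene / cell type / response
#' group, and detected cells carry lognormal positive expression (so the
#' stored values are continuous log-scale expression, thresholded strictly
#' above zero by the screens).
#'
#' @param nPatients named counts per response group, default 12 responders
#'   and 23 nonresponders as in checkpoint-therapy melanoma cohorts.
#' @param cellsPerPatient cells sampled per patient.
#' @param cellTypeProportions named proportions over the seven cell types;
#'   must sum to 1.
#' @param genes gene identifiers carried by the matrix.
#' @param detection detection-fraction array as built by
#'   [scDetectionDefaults()]; all values in \[0, 1\].
#' @param expressionScale mean of the log of nonzero expression values.
#' @param expressionSD standard deviation of the log of nonzero values.
#' @param seed integer RNG seed.
#' @return a validated list of class `ScCohortConfig`.
#' @export
scCohortConfig <- function(nPatients = c(responder = 12L,
                                         nonresponder = 23L),
                           cellsPerPatient = 100L,
                           cellTypeProportions = c(malignant = 0.50,
                               T_cell = 0.20, B_cell = 0.08,
                               macrophage = 0.08, NK = 0.04,
                               endothelial = 0.05, CAF = 0.05),
                           genes = unique(c(ifngSignature(), nrPanel(),
                                            "NACC1", "FKBP10")),
                           detection = scDetectionDefaults(genes,
                               cellTypes = names(cellTypeProportions)),
                           expressionScale = 1,
                           expressionSD = 0.5,
                           seed = 1L) {
    cfg <- list(nPatients = nPatients,
                cellsPerPatient = as.integer(cellsPerPatient),
                cellTypeProportions = cellTypeProportions,
                genes = genes, detection = detection,
                expressionScale = expressionScale,
                expressionSD = expressionSD,
                seed = as.integer(seed))
    class(cfg) <- "ScCohortConfig"
    .validateScConfig(cfg)
    cfg
}

.validateScConfig <- function(cfg) {
    if (is.null(names(cfg$nPatients)) ||
        !all(c("responder", "nonresponder") %in% names(cfg$nPatients)))
        stop("nPatients must be named with responder and nonresponder")
    if (abs(sum(cfg$cellTypeProportions) - 1) > 1e-8)
        stop("cell type proportions must sum to 1")
    if (any(cfg$cellTypeProportions < 0))
        stop("cell type proportions must be nonnegative")
    if (any(cfg$detection < 0 | cfg$detection > 1))
        stop("detection fractions must lie in [0, 1]")
    dn <- dimnames(cfg$detection)
    if (!identical(dn[[1]], cfg$genes) ||
        !identical(dn[[2]], names(cfg$cellTypeProportions)) ||
        !identical(dn[[3]], c("responder", "nonresponder")))
        stop("detection array dimnames must match genes, cell types and ",
             "response groups")
    invisible(TRUE)
}

#' Simulate an annotated single-cell expression cohort
#'
#' @param config a `ScCohortConfig`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `"logexpr"` assay (continuous positive values for detected gene/cell
#'   pairs, zero otherwise) and colData columns `cell_type`, `patient`,
#'   `response`; the detection truth is stored in `metadata()$truth`.
#' @examples
#' sce <- simulateScCohort(scCohortConfig(cellsPerPatient = 20L))
#' @export
simulateScCohort <- function(config = scCohortConfig()) {
    stopifnot(inherits(config, "ScCohortConfig"))
    .validateScConfig(config)
    set.seed(config$seed)
    types <- names(config$cellTypeProportions)
    groups <- rep(names(config$nPatients), config$nPatients)
    patients <- sprintf("%s%02d", ifelse(groups == "responder", "R", "N"),
                        unlist(lapply(config$nPatients, seq_len)))
    nCells <- length(patients) * config$cellsPerPatient
    cellPatient <- rep(patients, each = config$cellsPerPatient)
    cellResponse <- rep(groups, each = config$cellsPerPatient)
    cellType <- sample(types, nCells, replace = TRUE,
                       prob = config$cellTypeProportions)
    typeIdx <- match(cellType, types)
    respIdx <- match(cellResponse, c("responder", "nonresponder"))

    iList <- vector("list", length(config$genes))
    xList <- vector("list", length(config$genes))
    jList <- vector("list", length(config$genes))
    for (g in seq_along(config$genes)) {
        p <- config$detection[cbind(g, typeIdx, respIdx)]
        on <- which(stats::runif(nCells) < p)
        iList[[g]] <- rep.int(g, length(on))
        jList[[g]] <- on
        xList[[g]] <- exp(stats::rnorm(length(on),
            mean = config$expressionScale, sd = config$expressionSD))
    }
    mat <- Matrix::sparseMatrix(
        i = unlist(iList), j = unlist(jList), x = unlist(xList),
        dims = c(length(config$genes), nCells),
        dimnames = list(config$genes,
                        sprintf("cell%05d", seq_len(nCells))))

    truth <- list(detection = config$detection, seed = config$seed,
                  config = config)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(logexpr = mat),
        colData = S4Vectors::DataFrame(
            cell_type = cellType, patient = cellPatient,
            response = cellResponse, row.names = colnames(mat)))
    S4Vectors::metadata(sce)$truth <- truth
    sce
}
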