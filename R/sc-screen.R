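#' Percent of cells of a type expressing a gene
#'
#' 100 times the fraction of cells of the annotated type whose expression
#' of the gene exceeds the detection threshold (strictly greater than 0 by
#' default, matching log-scale single-cell matrices where zero means not
#' detected).
#'
#' @param cells a [SingleCellExperiment::SingleCellExperiment] with a
#'   `cell_type` colData column, or a gene x cell matrix plus `cellTypes`.
#' @param gene gene identifier.
#' @param cellType cell-type label; at least one cell of that type must
#'   exist.
#' @param threshold detection threshold (exceeded strictly).
#' @param cellTypes per-cell type labels when `cells` is a plain matrix.
#' @return percent in \[0, 100\].
#' @export
percentExpressing <- function(cells, gene, cellType = "malignant",
                              threshold = 0, cellTypes = NULL) {
    m <- .cellMatrix(cells)
    ct <- .cellAnnotation(cells, cellTypes, "cell_type")
    if (!gene %in% rownames(m))
        stop("gene absent from cell matrix: ", gene)
    sel <- ct == cellType
    if (!any(sel))
        stop("no cells annotated as ", cellType)
    100 * sum(m[gene, sel] > threshold) / sum(sel)
}

#' Per-gene, per-cell-type expression summary
#'
#' For every requested gene and every annotated cell type: the percent of
#' expressing cells, the mean expression among expressing cells, and the
#' cell count. The backbone of the tumor-intrinsic (malignant-cell)
#' expression filter.
#'
#' @param cells a SingleCellExperiment with `cell_type` annotations.
#' @param genes gene identifiers (default: all).
#' @param threshold detection threshold.
#' @return a [S4Vectors::DataFrame] with columns `gene`, `cell_type`,
#'   `percent_expressing`, `mean_expressing`, `n_cells`.
#' @export
scExpressionSummary <- function(cells, genes = NULL, threshold = 0) {
    m <- .cellMatrix(cells)
    ct <- .cellAnnotation(cells, NULL, "cell_type")
    if (is.null(genes)) genes <- rownames(m)
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
        stop("gene(s) absent from cell matrix: ",
             paste(missing, collapse = ", "))
    types <- sort(unique(ct))
    grid <- expand.grid(gene = genes, cell_type = types,
                        stringsAsFactors = FALSE)
    res <- mapply(function(g, ty) {
        v <- m[g, ct == ty]
        on <- v > threshold
        c(pct = 100 * sum(on) / length(v),
          mean = if (any(on)) mean(v[on]) else NA_real_,
          n = length(v))
    }, grid$gene, grid$cell_type)
    S4Vectors::DataFrame(gene = grid$gene, cell_type = grid$cell_type,
                         percent_expressing = res["pct", ],
                         mean_expressing = res["mean", ],
                         n_cells = as.integer(res["n", ]))
}

#' Tumor-intrinsic expression filter
#'
#' Stage 4 of the cascade: a gene passes when its percent of expressing
#' malignant cells strictly exceeds `tau` (default 10 percent; a gene at
#' exactly 10.0 percent fails).
#'
#' @param summary result of [scExpressionSummary()] (or any DataFrame with
#'   `gene`, `cell_type`, `percent_expressing`).
#' @param tau percent-expressing threshold.
#' @param cellType the tumor cell-type label.
#' @return named logical vector, one entry per gene in the summary.
#' @export
malignantFilter <- function(summary, tau = 10.0, cellType = "malignant") {
    sel <- summary$cell_type == cellType
    if (!any(sel))
        stop("summary has no rows for cell type ", cellType)
    stats::setNames(summary$percent_expressing[sel] > tau,
                    summary$gene[sel])
}

#' Responder versus nonresponder expression contrast in malignant cells
#'
#' Stage 3 of the cascade: pools the gene's expression over malignant
#' cells per response group and compares the groups with the unpaired
#' Wilcoxon rank-sum test at the cell level (each observation is one
#' malignant cell). A positive difference means higher expression in
#' nonresponders. Cell-level pooling ignores patient correlation; set
#' `byPatient = TRUE` to compare patient means instead.
#'
#' @param cells a SingleCellExperiment with `cell_type`, `patient` and
#'   `response` annotations (`responder` / `nonresponder`).
#' @param gene gene identifier.
#' @param cellType tumor cell-type label.
#' @param threshold detection threshold (used only for reporting percent
#'   expressing per group).
#' @param byPatient compare per-patient mean expression instead of cells.
#' @return list with `difference` (mean nonresponder minus mean
#'   responder), `p` (two-sided Wilcoxon), group sizes and per-group
#'   percent expressing.
#' @export
responseContrast <- function(cells, gene, cellType = "malignant",
                             threshold = 0, byPatient = FALSE) {
    m <- .cellMatrix(cells)
    ct <- .cellAnnotation(cells, NULL, "cell_type")
    resp <- .cellAnnotation(cells, NULL, "response")
    pat <- .cellAnnotation(cells, NULL, "patient")
    if (!gene %in% rownames(m))
        stop("gene absent from cell matrix: ", gene)
    if (any(is.na(resp)))
        stop("missing response labels")
    selR <- ct == cellType & resp == "responder"
    selN <- ct == cellType & resp == "nonresponder"
    if (!any(selR) || !any(selN))
        stop("both response groups need at least one ", cellType, " cell")
    vR <- m[gene, selR]
    vN <- m[gene, selN]
    if (byPatient) {
        vR <- tapply(vR, pat[selR], mean)
        vN <- tapply(vN, pat[selN], mean)
    }
    w <- wilcoxonRankSum(as.numeric(vN), as.numeric(vR))
    list(gene = gene, difference = mean(vN) - mean(vR), p = w$p,
         nResponder = sum(selR), nNonresponder = sum(selN),
         percentExpressing = c(
             responder = 100 * mean(m[gene, selR] > threshold),
             nonresponder = 100 * mean(m[gene, selN] > threshold)),
         byPatient = byPatient)
}

.cellMatrix <- function(cells) {
    if (is(cells, "SummarizedExperiment"))
        cells <- SummarizedExperiment::assay(cells)
    if (is.null(rownames(cells)))
        stop("cell matrix must carry gene identifiers as rownames")
    cells
}

.cellAnnotation <- function(cells, override, column) {
    if (!is.null(override)) return(override)
    if (!is(cells, "SummarizedExperiment"))
        stop("per-cell '", column, "' annotations are required")
    cd <- SummarizedExperiment::colData(cells)
    if (!column %in% names(cd))
        stop("colData lacks the '", column, "' annotation")
    as.character(cd[[column]])
}
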