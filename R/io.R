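#' Read / write the bulk expression matrix
#'
#' TSV with gene identifiers in the first column and one column per
#' sample. Duplicate gene or sample identifiers and non-numeric cells are
#' rejected.
#'
#' @param path file path.
#' @return numeric gene x sample matrix.
#' @export
readExpression <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expression TSV needs gene + sample columns")
    genes <- df[[1L]]
    if (anyDuplicated(genes))
        stop("duplicated gene identifier(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (anyDuplicated(colnames(m)))
        stop("duplicated sample identifier(s)")
    if (!is.numeric(m))
        stop("non-numeric expression value(s) in ", path)
    rownames(m) <- genes
    m
}

#' @rdname readExpression
#' @param expr gene x sample matrix or SummarizedExperiment.
#' @export
writeExpression <- function(expr, path) {
    m <- .exprMatrix(expr)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write the clinical table
#'
#' TSV with columns `sample_id`, `time`, `event` and optionally
#' `response`.
#'
#' @param path file path.
#' @return data.frame keyed by sample id.
#' @export
readClinical <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "time", "event")
    if (!all(need %in% names(df)))
        stop("clinical TSV needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample identifier(s) in clinical table")
    if (!is.numeric(df$time) || any(!is.finite(df$time)) ||
        any(df$time <= 0))
        stop("clinical 'time' must be positive and finite")
    if (!all(df$event %in% c(0L, 1L)))
        stop("clinical 'event' must be 0 or 1")
    rownames(df) <- df$sample_id
    df
}

#' @rdname readClinical
#' @param clinical data.frame or SummarizedExperiment colData with `time`,
#'   `event` (and optional `response`).
#' @export
writeClinical <- function(clinical, path) {
    cl <- .clinicalTable(clinical)
    df <- data.frame(sample_id = rownames(cl), time = cl$time,
                     event = cl$event,
                     response = if ("response" %in% names(cl))
                         cl$response else NA_character_)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read / write the annotated single-cell matrix
#'
#' The on-disk layout is a MatrixMarket triplet file (`matrix.mtx`), a
#' one-column `genes.tsv`, and a `barcodes.tsv` whose columns are
#' `barcode`, `cell_type`, `patient`, `response`. `readCells` also accepts
#' a dense TSV (genes x cells) plus the same barcode annotation file.
#'
#' @param dir directory holding `matrix.mtx` (or `matrix.tsv`),
#'   `genes.tsv` and `barcodes.tsv`.
#' @return a [SingleCellExperiment::SingleCellExperiment].
#' @export
readCells <- function(dir) {
    bcPath <- file.path(dir, "barcodes.tsv")
    gPath <- file.path(dir, "genes.tsv")
    mtxPath <- file.path(dir, "matrix.mtx")
    tsvPath <- file.path(dir, "matrix.tsv")
    if (!file.exists(bcPath) || !file.exists(gPath))
        stop("missing barcodes.tsv or genes.tsv under ", dir)
    bc <- utils::read.delim(bcPath, stringsAsFactors = FALSE)
    need <- c("barcode", "cell_type", "patient", "response")
    if (!all(need %in% names(bc)))
        stop("barcodes.tsv needs columns: ", paste(need, collapse = ", "))
    genes <- utils::read.delim(gPath, header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    if (anyDuplicated(genes))
        stop("duplicated gene identifier(s) in genes.tsv")
    if (file.exists(mtxPath)) {
        m <- tryCatch(Matrix::readMM(mtxPath), error = function(e)
            stop("malformed MatrixMarket file ", mtxPath, ": ",
                 conditionMessage(e)))
        m <- methods::as(m, "CsparseMatrix")
    } else if (file.exists(tsvPath)) {
        m <- methods::as(as.matrix(utils::read.delim(tsvPath,
            header = FALSE)), "CsparseMatrix")
    } else {
        stop("missing matrix.mtx or matrix.tsv under ", dir)
    }
    if (nrow(m) != length(genes) || ncol(m) != nrow(bc))
        stop("matrix dimensions disagree with genes.tsv / barcodes.tsv")
    dimnames(m) <- list(genes, bc$barcode)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(logexpr = m),
        colData = S4Vectors::DataFrame(
            cell_type = bc$cell_type, patient = bc$patient,
            response = bc$response, row.names = bc$barcode))
}

#' @rdname readCells
#' @param cells a SingleCellExperiment as produced by
#'   [simulateScCohort()].
#' @export
writeCells <- function(cells, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    m <- .cellMatrix(cells)
    Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    utils::write.table(data.frame(gene = rownames(m)),
        file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    cd <- SummarizedExperiment::colData(cells)
    utils::write.table(data.frame(barcode = rownames(cd),
        cell_type = cd$cell_type, patient = cd$patient,
        response = cd$response),
        file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(dir)
}

#' Read / write a differential-expression table
#'
#' TSV with columns `gene`, `log2fc`, `pval` (optional `padj`).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readDETable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "log2fc", "pval")
    if (!all(need %in% names(df)))
        stop("DE TSV needs columns: ", paste(need, collapse = ", "))
    dup <- df$gene[duplicated(df$gene)]
    if (length(dup))
        stop("duplicated gene identifier(s): ",
             paste(unique(dup), collapse = ", "))
    if (!is.numeric(df$log2fc) || !is.numeric(df$pval))
        stop("log2fc and pval must be numeric")
    df
}

#' @rdname readDETable
#' @param table DE data.frame.
#' @export
writeDETable <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a cohort manifest
#'
#' JSON record of the generator configuration, seed and planted truth of
#' a synthetic cohort, for provenance alongside the data files.
#'
#' @param cohort a simulated bulk or single-cell cohort.
#' @param path output path.
#' @export
writeManifest <- function(cohort, path) {
    tr <- S4Vectors::metadata(cohort)$truth
    if (is.null(tr)) stop("cohort carries no truth metadata")
    drop <- c("immuneFactor", "detection")
    out <- tr[setdiff(names(tr), drop)]
    out$config <- unclass(out$config)
    out$config$detection <- NULL
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)
    invisible(path)
}
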