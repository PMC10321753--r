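# coerce a SummarizedExperiment or plain matrix to the gene x sample matrix
.exprMatrix <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x)
    if (is.null(rownames(x)))
        stop("expression matrix must carry gene identifiers as rownames")
    if (anyDuplicated(rownames(x)))
        stop("duplicated gene identifiers in expression matrix")
    as.matrix(x)
}

# coerce a SummarizedExperiment colData or data.frame to the clinical table
.clinicalTable <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- as.data.frame(SummarizedExperiment::colData(x))
    x <- as.data.frame(x)
    if (is.null(rownames(x)) && "sample_id" %in% names(x))
        rownames(x) <- x$sample_id
    if (!all(c("time", "event") %in% names(x)))
        stop("clinical table needs 'time' and 'event' columns")
    x
}

.cohortSeed <- function(x) {
    tr <- tryCatch(S4Vectors::metadata(x)$truth, error = function(e) NULL)
    if (is.null(tr$seed)) NA_integer_ else as.integer(tr$seed)
}
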