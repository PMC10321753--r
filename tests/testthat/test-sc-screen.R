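test_that("percent expressing is an exact count", {
    m <- rbind(NR2F6 = c(1.2, 0, 0.4), GZMA = c(0, 0, 0))
    colnames(m) <- paste0("c", 1:3)
    types <- rep("malignant", 3)
    expect_equal(percentExpressing(m, "NR2F6", cellTypes = types),
                 100 * 2 / 3)
    expect_equal(percentExpressing(m, "GZMA", cellTypes = types), 0)
    expect_error(percentExpressing(m, "NR2F6", cellType = "T_cell",
                                   cellTypes = types), "no cells")
    set.seed(71)
    for (i in 1:20) {
        nc <- sample(5:50, 1)
        mat <- matrix(rbinom(4 * nc, 1, 0.4) * runif(4 * nc), 4,
                      dimnames = list(paste0("g", 1:4), paste0("c", 1:nc)))
        tys <- sample(c("malignant", "T_cell"), nc, replace = TRUE)
        if (!any(tys == "malignant")) tys[1] <- "malignant"
        g <- sample(rownames(mat), 1)
        expect_identical(
            percentExpressing(mat, g, "malignant", cellTypes = tys),
            percentOracle(mat, tys, g, "malignant"))
    }
})

test_that("summary percent/cell counts are internally consistent", {
    sce <- simulateScCohort(scCohortConfig(cellsPerPatient = 40L,
                                           seed = 72))
    sm <- scExpressionSummary(sce, genes = c("NR2F6", "VDR", "IFNG"))
    expect_true(all(sm$percent_expressing >= 0 &
                    sm$percent_expressing <= 100))
    m <- SummarizedExperiment::assay(sce)
    for (g in c("NR2F6", "VDR")) {
        sub <- sm[sm$gene == g, ]
        # per-type expressing counts add up to the matrix-wide count
        expect_equal(sum(sub$percent_expressing * sub$n_cells / 100),
                     sum(m[g, ] > 0))
        expect_equal(sum(sub$n_cells), ncol(m))
    }
    # invariant to cell-column ordering
    perm <- sample(ncol(sce))
    smP <- scExpressionSummary(sce[, perm], genes = "NR2F6")
    expect_equal(as.data.frame(smP), as.data.frame(sm[sm$gene == "NR2F6", ]))
})

test_that("the malignant filter is strict at the threshold", {
    sm <- S4Vectors::DataFrame(
        gene = c("A", "B", "C"), cell_type = "malignant",
        percent_expressing = c(10.0, 13.0, 0))
    keep <- malignantFilter(sm)
    expect_identical(keep, c(A = FALSE, B = TRUE, C = FALSE))
    expect_error(malignantFilter(sm, cellType = "NK"), "no rows")
})

test_that("response contrast recovers planted detection differences", {
    sce <- simulateScCohort(scCohortConfig(seed = 73))
    rc <- responseContrast(sce, "NR2F6")
    expect_gt(rc$difference, 0)      # higher in nonresponders
    expect_lt(rc$p, 0.05)
    expect_gt(rc$nResponder, 500)
    expect_gt(rc$nNonresponder, 500)
    # mirrored planted gene
    rcP <- responseContrast(sce, "NR1H3")
    expect_lt(rcP$difference, 0)
    # swapping the group labels negates the difference, same p
    cd <- SummarizedExperiment::colData(sce)
    swapped <- sce
    SummarizedExperiment::colData(swapped)$response <-
        ifelse(cd$response == "responder", "nonresponder", "responder")
    rcS <- responseContrast(swapped, "NR2F6")
    expect_equal(rcS$difference, -rc$difference)
    expect_equal(rcS$p, rc$p)
    # patient-level variant agrees on direction
    rcPat <- responseContrast(sce, "NR2F6", byPatient = TRUE)
    expect_gt(rcPat$difference, 0)
})

test_that("null genes show uniform response p-values over seeds", {
    ps <- vapply(1:10, function(s) {
        sce <- simulateScCohort(scCohortConfig(cellsPerPatient = 30L,
                                               seed = 200 + s))
        responseContrast(sce, "VDR")$p
    }, numeric(1))
    expect_gt(min(ps), 1e-4)
    expect_lte(sum(ps < 0.05), 2)
})
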