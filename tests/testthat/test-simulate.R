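test_that("bulk cohort generation is deterministic and z-scored", {
    cfg <- smallBulkConfig(seed = 5)
    a <- simulateBulkCohort(cfg)
    b <- simulateBulkCohort(cfg)
    expect_identical(SummarizedExperiment::assay(a),
                     SummarizedExperiment::assay(b))
    expect_identical(a$time, b$time)
    z <- SummarizedExperiment::assay(a)
    expect_true(all(abs(rowMeans(z)) < 1e-6))
    expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-6))
    tr <- S4Vectors::metadata(a)$truth
    expect_true(all(c(tr$plantedNegativeNR, tr$plantedPositiveNR,
                      tr$effectors$gene) %in% rownames(z)))
})

test_that("bulk cohort censoring lands near its target", {
    cfg <- bulkCohortConfig(nSamples = 300L, censorFraction = 0.2,
                            seed = 31)
    se <- simulateBulkCohort(cfg)
    expect_lt(abs(mean(se$event == 0) - 0.2), 0.05)
    cfg0 <- bulkCohortConfig(nSamples = 100L, censorFraction = 0, seed = 31)
    expect_true(all(simulateBulkCohort(cfg0)$event == 1))
})

test_that("bulk config invariants are enforced", {
    expect_error(bulkCohortConfig(nSamples = 10L), "at least 20")
    expect_error(bulkCohortConfig(immuneLoading = -1.5), "immuneLoading")
    expect_error(bulkCohortConfig(censorFraction = 1), "censorFraction")
    expect_error(bulkCohortConfig(plantedNegativeNR = "NOTANR"), "panel")
})

test_that("null generator leaves the planted NR indistinguishable", {
    # zero loading and zero hazard: the planted NR should not separate
    # from nulls at the correlation screen beyond chance
    hits <- vapply(1:10, function(s) {
        se <- simulateBulkCohort(nullBulkConfig(seed = s, nSamples = 200L))
        row <- correlateVsSignature(SummarizedExperiment::assay(se),
                                    "NR2F6")
        classifyDirection(row) != "none"
    }, logical(1))
    expect_lte(sum(hits), 2)
})

test_that("single-cell cohort respects annotations and detection", {
    cfg <- scCohortConfig(seed = 8)
    a <- simulateScCohort(cfg)
    b <- simulateScCohort(cfg)
    expect_identical(SummarizedExperiment::assay(a),
                     SummarizedExperiment::assay(b))
    cd <- SummarizedExperiment::colData(a)
    expect_equal(sum(cd$response == "responder"), 12 * 100)
    expect_equal(sum(cd$response == "nonresponder"), 23 * 100)
    # planted malignant detection 40% in nonresponders, within 5 points
    selN <- cd$cell_type == "malignant" & cd$response == "nonresponder"
    expect_gt(sum(selN), 500)
    pct <- 100 * mean(SummarizedExperiment::assay(a)["NR2F6", selN] > 0)
    expect_lt(abs(pct - 40), 5)

    # degenerate settings
    genes <- c("A", "B")
    det <- scDetectionDefaults(genes, cellTypes = "malignant",
        plantedNonresponderHigh = character(0),
        plantedResponderHigh = character(0), base = 0)
    cfg0 <- scCohortConfig(nPatients = c(responder = 2L,
                                         nonresponder = 2L),
        cellsPerPatient = 30L, cellTypeProportions = c(malignant = 1),
        genes = genes, detection = det, seed = 9)
    sce0 <- simulateScCohort(cfg0)
    expect_true(all(SummarizedExperiment::colData(sce0)$cell_type ==
                    "malignant"))
    expect_equal(percentExpressing(sce0, "A"), 0)
    expect_error(scCohortConfig(cellTypeProportions = c(malignant = 0.5)),
                 "sum to 1")
})

test_that("DE fixture plants direction-consistent and inconsistent genes", {
    cfg <- deFixtureConfig(nGenes = 80L, seed = 4)
    a <- simulateDETables(cfg)
    b <- simulateDETables(cfg)
    expect_identical(a$tables, b$tables)
    for (tab in a$tables) {
        down <- tab[tab$gene %in% cfg$plantedCommonDown, ]
        expect_true(all(down$log2fc <= -log2(1.5)))
        expect_true(all(down$pval < 1e-5))
        up <- tab[tab$gene %in% cfg$plantedCommonUp, ]
        expect_true(all(up$log2fc >= log2(1.5)))
        nulls <- tab[grepl("^G\\d+$", tab$gene), ]
        expect_true(all(abs(nulls$log2fc) < log2(1.5)))
    }
    incSigns <- sapply(a$tables, function(tab)
        sign(tab$log2fc[tab$gene == cfg$plantedInconsistent]))
    expect_gt(length(unique(incSigns)), 1)
    expect_error(deFixtureConfig(plantedCommonDown = "X",
                                 plantedCommonUp = "X"), "disjoint")
})
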