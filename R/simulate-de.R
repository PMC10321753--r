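#' Configuration for the planted differential-expression fixture
#'
#' Describes three knockout-versus-control DE tables (bulk tumor, sorted
#' tumor cells, cultured cells) over one gene universe. Planted
#' common-direction genes receive fold changes beyond the 1.5x cutoff with
#' tiny p-values in all three compartments; planted inconsistent genes are
#' strong but flip sign across compartments; null genes sit inside the
#' fold-change cutoff with uniform p-values.
#'
#' @param nGenes total genes per table (planted genes included).
#' @param plantedCommonDown genes down-regulated in all three compartments.
#' @param plantedCommonUp genes up-regulated in all three compartments.
#' @param plantedInconsistent genes strong in every compartment but with
#'   mixed directions (must never reach a common set).
#' @param seed integer RNG seed.
#' @return a validated list of class `DEFixtureConfig`.
#' @export
deFixtureConfig <- function(nGenes = 500L,
                            plantedCommonDown = c("NACC1", "FKBP10"),
                            plantedCommonUp = "CXCL10",
                            plantedInconsistent = "LDHA",
                            seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes),
                plantedCommonDown = plantedCommonDown,
                plantedCommonUp = plantedCommonUp,
                plantedInconsistent = plantedInconsistent,
                seed = as.integer(seed))
    class(cfg) <- "DEFixtureConfig"
    planted <- c(cfg$plantedCommonDown, cfg$plantedCommonUp,
                 cfg$plantedInconsistent)
    if (anyDuplicated(planted))
        stop("planted gene sets must be disjoint")
    if (cfg$nGenes < length(planted) + 1L)
        stop("nGenes too small for the planted genes")
    cfg
}

#' Simulate the three-compartment DE tables
#'
#' @param config a `DEFixtureConfig`.
#' @return list with `tables` (named list of data.frames `bulk_tumor`,
#'   `sorted_tumor`, `cultured`, each with columns `gene`, `log2fc`,
#'   `pval`) and `truth` (the planted sets and seed).
#' @examples
#' fx <- simulateDETables(deFixtureConfig(nGenes = 50L))
#' @export
simulateDETables <- function(config = deFixtureConfig()) {
    stopifnot(inherits(config, "DEFixtureConfig"))
    set.seed(config$seed)
    planted <- c(config$plantedCommonDown, config$plantedCommonUp,
                 config$plantedInconsistent)
    nNull <- config$nGenes - length(planted)
    genes <- c(planted, sprintf("G%04d", seq_len(nNull)))
    fcCutLog2 <- log2(1.5)
    compartments <- c("bulk_tumor", "sorted_tumor", "cultured")
    # inconsistent genes flip sign in the middle compartment only
    incSign <- c(bulk_tumor = 1, sorted_tumor = -1, cultured = 1)
    tables <- lapply(compartments, function(comp) {
        lfc <- stats::runif(length(genes), -0.95 * fcCutLog2,
                            0.95 * fcCutLog2)
        p <- stats::runif(length(genes))
        names(lfc) <- names(p) <- genes
        strong <- function(k) stats::runif(k, fcCutLog2 + 0.3, 2.5)
        tiny <- function(k) 10^stats::runif(k, -10, -6)
        dn <- config$plantedCommonDown
        up <- config$plantedCommonUp
        inc <- config$plantedInconsistent
        lfc[dn] <- -strong(length(dn)); p[dn] <- tiny(length(dn))
        lfc[up] <- strong(length(up)); p[up] <- tiny(length(up))
        lfc[inc] <- incSign[comp] * strong(length(inc))
        p[inc] <- tiny(length(inc))
        data.frame(gene = genes, log2fc = unname(lfc), pval = unname(p),
                   stringsAsFactors = FALSE)
    })
    names(tables) <- compartments
    list(tables = tables,
         truth = list(commonDown = config$plantedCommonDown,
                      commonUp = config$plantedCommonUp,
                      inconsistent = config$plantedInconsistent,
                      seed = config$seed))
}
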