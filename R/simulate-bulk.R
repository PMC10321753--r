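#' Configuration for the synthetic bulk cohort
#'
#' Describes the generative model of the synthetic bulk expression cohort:
#' a latent per-sample immune-activity factor drives the ten signature
#' genes (loading 1) and the two planted nuclear receptors (signed loading
#' `immuneLoading` for the planted immune-evasion NR, its negation for the
#' planted protective NR); all other panel NRs are pure noise. Survival is
#' exponential with log-hazard
#' `hazardLogHR * z(planted evasion NR) - immuneProtectLogHR * factor`
#' plus any per-effector terms, and independent uniform censoring tuned to
#' the target censored fraction.
#'
#' @param nSamples number of samples (>= 20).
#' @param nNRs size of the NR candidate panel (the first `nNRs` genes of
#'   [nrPanel()] are used; must cover the two planted NRs).
#' @param signatureGenes the signature gene identifiers.
#' @param plantedNegativeNR NR planted with negative loading on the immune
#'   factor (the immune-evasion candidate the screen should recover).
#' @param plantedPositiveNR NR planted with the mirrored positive loading.
#' @param immuneLoading signed loading of the planted evasion NR on the
#'   latent factor; must satisfy `abs(immuneLoading) <= 1`.
#' @param hazardLogHR log hazard ratio per standard deviation of the
#'   planted evasion NR's expression.
#' @param immuneProtectLogHR protective log hazard ratio per unit of the
#'   latent immune factor (entering the hazard with a minus sign), so that
#'   high signature activity and good survival co-occur.
#' @param effectors data.frame with columns `gene`, `loading`,
#'   `hazardLogHR` describing planted downstream effector genes; may be
#'   empty. A gene listed here that is also a signature gene keeps the
#'   effector loading.
#' @param baselineHazard exponential baseline hazard (per time unit; the
#'   default 0.1 puts median survival near 7 time units, months-like).
#' @param censorFraction target fraction of censored samples, in \[0, 1).
#' @param noiseSD residual standard deviation of every gene.
#' @param seed integer RNG seed.
#' @return a validated list of class `BulkCohortConfig`.
#' @export
bulkCohortConfig <- function(nSamples = 400L,
                             nNRs = 48L,
                             signatureGenes = ifngSignature(),
                             plantedNegativeNR = "NR2F6",
                             plantedPositiveNR = "NR1H3",
                             immuneLoading = -0.6,
                             hazardLogHR = log(2),
                             immuneProtectLogHR = log(2),
                             effectors = data.frame(
                                 gene = c("NACC1", "FKBP10", "CXCL10"),
                                 loading = c(-0.5, -0.5, 0.5),
                                 hazardLogHR = c(log(2), log(2), -log(2)),
                                 stringsAsFactors = FALSE),
                             baselineHazard = 0.1,
                             censorFraction = 0.2,
                             noiseSD = 1,
                             seed = 1L) {
    cfg <- list(nSamples = as.integer(nSamples), nNRs = as.integer(nNRs),
                signatureGenes = signatureGenes,
                plantedNegativeNR = plantedNegativeNR,
                plantedPositiveNR = plantedPositiveNR,
                immuneLoading = immuneLoading,
                hazardLogHR = hazardLogHR,
                immuneProtectLogHR = immuneProtectLogHR,
                effectors = effectors,
                baselineHazard = baselineHazard,
                censorFraction = censorFraction,
                noiseSD = noiseSD, seed = as.integer(seed))
    class(cfg) <- "BulkCohortConfig"
    .validateBulkConfig(cfg)
    cfg
}

.validateBulkConfig <- function(cfg) {
    if (cfg$nSamples < 20L)
        stop("nSamples must be at least 20")
    if (abs(cfg$immuneLoading) > 1)
        stop("abs(immuneLoading) must not exceed 1")
    if (cfg$censorFraction < 0 || cfg$censorFraction >= 1)
        stop("censorFraction must lie in [0, 1)")
    if (cfg$noiseSD <= 0)
        stop("noiseSD must be positive")
    if (anyDuplicated(cfg$signatureGenes))
        stop("signature genes must be unique")
    nrs <- nrPanel()[seq_len(cfg$nNRs)]
    if (!all(c(cfg$plantedNegativeNR, cfg$plantedPositiveNR) %in% nrs))
        stop("planted NRs must belong to the NR panel slice")
    if (nrow(cfg$effectors) &&
        !all(c("gene", "loading", "hazardLogHR") %in% names(cfg$effectors)))
        stop("effectors needs columns gene, loading, hazardLogHR")
    invisible(TRUE)
}

#' Simulate a bulk expression cohort with clinical follow-up
#'
#' Generates the gene-by-sample z-score matrix and the clinical table of
#' the synthetic cohort described by a [bulkCohortConfig()]. Each gene is
#' `loading * factor + noise`, standardized to mean 0 / SD 1 across
#' samples. Follow-up is exponential with the configured log-hazard model;
#' censoring times are uniform on (0, u) with u solved (by root finding on
#' the expected censored fraction given the realized hazard rates) so the
#' censored fraction matches the target in expectation.
#'
#' @param config a `BulkCohortConfig`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"zscore"`, colData columns `time`, `event`, `response` (NA for the
#'   bulk cohort), rowData columns `role`, `loading`, `hazardLogHR`, and
#'   the planted ground truth in `metadata()$truth`.
#' @examples
#' se <- simulateBulkCohort(bulkCohortConfig(nSamples = 60, seed = 7))
#' @export
simulateBulkCohort <- function(config = bulkCohortConfig()) {
    stopifnot(inherits(config, "BulkCohortConfig"))
    .validateBulkConfig(config)
    set.seed(config$seed)
    n <- config$nSamples
    nrs <- nrPanel()[seq_len(config$nNRs)]
    sig <- config$signatureGenes
    eff <- config$effectors
    genes <- unique(c(sig, nrs, eff$gene))

    loading <- stats::setNames(rep(0, length(genes)), genes)
    loading[sig] <- 1
    loading[nrs] <- 0
    loading[config$plantedNegativeNR] <- config$immuneLoading
    loading[config$plantedPositiveNR] <- -config$immuneLoading
    if (nrow(eff)) loading[eff$gene] <- eff$loading

    hazardCoef <- stats::setNames(rep(0, length(genes)), genes)
    hazardCoef[config$plantedNegativeNR] <- config$hazardLogHR
    if (nrow(eff)) hazardCoef[eff$gene] <- eff$hazardLogHR

    f <- stats::rnorm(n)
    expr <- matrix(stats::rnorm(length(genes) * n, sd = config$noiseSD),
                   nrow = length(genes), dimnames = list(genes, NULL))
    expr <- expr + outer(loading, f)
    z <- t(scale(t(expr)))            # per-gene mean 0, sd 1
    attr(z, "scaled:center") <- NULL
    attr(z, "scaled:scale") <- NULL
    colnames(z) <- sprintf("S%03d", seq_len(n))

    logHaz <- drop(crossprod(z, hazardCoef)) - config$immuneProtectLogHR * f
    rate <- config$baselineHazard * exp(logHaz)
    tDeath <- stats::rexp(n, rate = rate)
    if (config$censorFraction > 0) {
        u <- .censorHorizon(rate, config$censorFraction)
        cens <- stats::runif(n, 0, u)
    } else {
        cens <- rep(Inf, n)
    }
    time <- pmin(tDeath, cens)
    event <- as.integer(tDeath <= cens)

    role <- ifelse(genes %in% sig, "signature",
            ifelse(genes %in% nrs, "nr", "effector"))
    role[genes %in% eff$gene & genes %in% sig] <- "signature"
    truth <- list(plantedNegativeNR = config$plantedNegativeNR,
                  plantedPositiveNR = config$plantedPositiveNR,
                  effectors = eff,
                  immuneFactor = f,
                  seed = config$seed,
                  config = config)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(zscore = z),
        colData = S4Vectors::DataFrame(
            time = time, event = event,
            response = rep(NA_character_, n),
            row.names = colnames(z)),
        rowData = S4Vectors::DataFrame(
            role = role, loading = unname(loading),
            hazardLogHR = unname(hazardCoef), row.names = genes))
    S4Vectors::metadata(se)$truth <- truth
    se
}

# uniform-censoring horizon u with expected censored fraction = target,
# given per-sample exponential rates: P(C < T) = (1 - exp(-r u)) / (r u)
.censorHorizon <- function(rate, target) {
    fn <- function(u) mean((1 - exp(-rate * u)) / (rate * u)) - target
    stats::uniroot(fn, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}
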