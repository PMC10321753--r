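# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# direct-formula BH oracle: adj_i = min over ranks j >= rank_i of p_(j)*m/j
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    sorted <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m)) {
        cand <- m / (i:m) * sorted[i:m]
        adj[o[i]] <- min(1, cand)
    }
    adj
}

# brute-force permutation generator via backtracking (distinct from the
# recursive block construction inside the package)
permsOracle <- function(n) {
    out <- list()
    recurse <- function(prefix, remaining) {
        if (length(remaining) == 0L) {
            out[[length(out) + 1L]] <<- prefix
            return(invisible())
        }
        for (v in remaining)
            recurse(c(prefix, v), setdiff(remaining, v))
    }
    recurse(integer(0), seq_len(n))
    do.call(rbind, out)
}

# exact permutation p for Spearman via base cor() over all pairings
spearmanExactOracle <- function(x, y) {
    n <- length(x)
    perms <- permsOracle(n)
    obs <- abs(stats::cor(x, y, method = "spearman"))
    rhos <- apply(perms, 1L, function(pm)
        stats::cor(x, y[pm], method = "spearman"))
    mean(abs(rhos) >= obs - 1e-12)
}

# counting oracle for percent expressing
percentOracle <- function(mat, types, gene, type, threshold = 0) {
    cols <- which(types == type)
    k <- 0L
    for (j in cols) if (mat[gene, j] > threshold) k <- k + 1L
    100 * k / length(cols)
}

# small null survival dataset: one exponential population, uniform
# censoring hitting the target fraction in expectation
nullSurvData <- function(n, censorFraction = 0.2) {
    t0 <- stats::rexp(n)
    if (censorFraction > 0) {
        u <- stats::uniroot(function(u) (1 - exp(-u)) / u - censorFraction,
                            c(1e-6, 1e3))$root
        cens <- stats::runif(n, 0, u)
    } else cens <- rep(Inf, n)
    list(time = pmin(t0, cens), event = as.integer(t0 <= cens))
}

smallBulkConfig <- function(seed, nSamples = 60L, ...) {
    bulkCohortConfig(nSamples = nSamples, seed = seed, ...)
}

nullBulkConfig <- function(seed, nSamples = 60L) {
    bulkCohortConfig(nSamples = nSamples, nNRs = 2L,
        plantedNegativeNR = "NR2F6", plantedPositiveNR = "ESRRA",
        immuneLoading = 0, hazardLogHR = 0, immuneProtectLogHR = 0,
        effectors = data.frame(gene = character(0), loading = numeric(0),
                               hazardLogHR = numeric(0)),
        seed = seed)
}
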