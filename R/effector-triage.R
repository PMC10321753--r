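#' Filter a differential-expression table
#'
#' Keeps genes with BH-adjusted p below `qCut` and linear-scale fold
#' change at least `fcCut` (up) or at most `-fcCut` (down), i.e.
#' `|log2FC| >= log2(fcCut)`. When the table carries no `padj` column the
#' adjustment is recomputed from the raw p-values with [bhAdjust()].
#'
#' @param table data.frame with columns `gene`, `log2fc`, `pval` (and
#'   optionally `padj`).
#' @param fcCut linear fold-change cutoff, default 1.5.
#' @param qCut adjusted-p cutoff, default 0.05.
#' @return list with character vectors `up` and `down`.
#' @export
filterDE <- function(table, fcCut = 1.5, qCut = 0.05) {
    need <- c("gene", "log2fc", "pval")
    if (!all(need %in% names(table)))
        stop("DE table needs columns: ", paste(need, collapse = ", "))
    padj <- if ("padj" %in% names(table)) table$padj else
        bhAdjust(table$pval)
    lcut <- log2(fcCut)
    list(up = table$gene[padj < qCut & table$log2fc >= lcut],
         down = table$gene[padj < qCut & table$log2fc <= -lcut])
}

#' Direction-consistent intersection across compartments
#'
#' Given per-compartment up/down gene sets, returns the genes up-regulated
#' in every compartment and those down-regulated in every compartment. A
#' gene that changes direction between compartments reaches neither set,
#' so the two outputs are always disjoint.
#'
#' @param sets list of [filterDE()] results, one per compartment (three
#'   compartments in the knockout experiment: bulk tumor, sorted tumor
#'   cells, cultured cells).
#' @return list with character vectors `commonUp` and `commonDown`.
#' @export
intersectConsistent <- function(sets) {
    if (length(sets) < 2L)
        stop("need at least two compartments to intersect")
    commonUp <- Reduce(intersect, lapply(sets, `[[`, "up"))
    commonDown <- Reduce(intersect, lapply(sets, `[[`, "down"))
    anyUp <- Reduce(union, lapply(sets, `[[`, "up"))
    anyDown <- Reduce(union, lapply(sets, `[[`, "down"))
    list(commonUp = setdiff(commonUp, anyDown),
         commonDown = setdiff(commonDown, anyUp))
}

#' Triage common DE genes into effector roles
#'
#' For every direction-consistent gene: Spearman correlation against the
#' signature (with the usual direction call), correlation with the
#' candidate nuclear receptor, and a z-score (z > `zCutoff` versus the
#' rest) survival contrast. Roles follow the coherence rule: a
#' `suppressive_effector` is commonly down-regulated by the knockout,
#' negatively correlated with the signature and unfavorable for survival;
#' an `immune_activating` gene is commonly up-regulated, positively
#' correlated and favorable. Everything else is `none`. Genes absent from
#' the bulk matrix, or with degenerate z splits, are flagged rather than
#' fatal.
#'
#' @param common result of [intersectConsistent()].
#' @param expr bulk gene x sample matrix or SummarizedExperiment.
#' @param clinical clinical table (defaults to the colData of `expr`).
#' @param signature signature gene identifiers.
#' @param candidateNR the upstream nuclear receptor being triaged.
#' @param alpha significance level for correlation and survival calls.
#' @param kMin minimum significant concordant signature pairs.
#' @param zCutoff z-score split for the survival contrast.
#' @return a [S4Vectors::DataFrame], one row per common gene: regulation,
#'   signature direction, rho/p versus the candidate NR, survival label
#'   and final `role`.
#' @export
triageEffectors <- function(common, expr, clinical = expr,
                            signature = ifngSignature(),
                            candidateNR = "NR2F6",
                            alpha = 0.05, kMin = 5L, zCutoff = 2.0) {
    genes <- c(common$commonUp, common$commonDown)
    regulation <- rep(c("common_up", "common_down"),
                      c(length(common$commonUp), length(common$commonDown)))
    if (length(genes) == 0L)
        return(S4Vectors::DataFrame(
            gene = character(0), regulation = character(0),
            signature_direction = character(0), rho_nr = numeric(0),
            p_nr = numeric(0), survival_label = character(0),
            role = character(0), flag = character(0)))
    m <- .exprMatrix(expr)
    cl <- .clinicalTable(clinical)
    out <- lapply(seq_along(genes), function(i) {
        g <- genes[i]
        if (!g %in% rownames(m))
            return(list(direction = "none", rho = NA_real_, p = NA_real_,
                        label = "none", flag = "absent_from_bulk"))
        row <- correlateVsSignature(m, g, signature)
        direction <- classifyDirection(row, alpha = alpha, kMin = kMin)
        nr <- if (candidateNR %in% rownames(m) && g != candidateNR) {
            st <- spearmanTest(m[g, ], m[candidateNR, ])
            list(rho = st$rho, p = st$p)
        } else list(rho = NA_real_, p = NA_real_)
        surv <- tryCatch(
            screenSurvival(m, g, cl, mode = "zscore", cutoff = zCutoff,
                           alpha = alpha),
            error = function(e) NULL)
        list(direction = direction, rho = nr$rho, p = nr$p,
             label = if (is.null(surv)) "none" else surv$label,
             flag = if (is.null(surv)) "degenerate_z_split" else "")
    })
    direction <- vapply(out, `[[`, character(1), "direction")
    label <- vapply(out, `[[`, character(1), "label")
    role <- rep("none", length(genes))
    role[regulation == "common_down" & direction == "negative" &
         label == "unfavorable"] <- "suppressive_effector"
    role[regulation == "common_up" & direction == "positive" &
         label == "favorable"] <- "immune_activating"
    S4Vectors::DataFrame(
        gene = genes, regulation = regulation,
        signature_direction = direction,
        rho_nr = vapply(out, `[[`, numeric(1), "rho"),
        p_nr = vapply(out, `[[`, numeric(1), "p"),
        survival_label = label, role = role,
        flag = vapply(out, `[[`, character(1), "flag"),
        row.names = genes)
}
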