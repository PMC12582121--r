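#' Median-of-ratios size factors
#'
#' Computes one positive scaling factor per sample: for each gene that is
#' nonzero in every sample (the reference set), the ratio of its count to
#' its geometric mean across samples is formed, and the per-sample median of
#' these ratios is the size factor. Dividing counts by the factors makes
#' samples comparable; a sample sequenced twice as deep gets a factor twice
#' as large.
#'
#' @param counts numeric matrix (genes x samples) or a
#'   `SummarizedExperiment` with a `counts` assay.
#' @return named numeric vector of per-sample size factors.
#' @examples
#' m <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
#' estimateSizeFactorsMedianRatio(m)   # c(1/sqrt(2), sqrt(2))
#' @export
estimateSizeFactorsMedianRatio <- function(counts) {
    m <- .countMatrix(counts)
    ref <- rowSums(m > 0) == ncol(m)
    if (!any(ref))
        stop("no gene is nonzero in every sample; consider total-count ",
             "normalization instead")
    logGeo <- rowMeans(log(m[ref, , drop = FALSE]))
    apply(m[ref, , drop = FALSE], 2L,
          function(col) exp(median(log(col) - logGeo)))
}

.countMatrix <- function(counts) {
    if (is(counts, "SummarizedExperiment"))
        counts <- SummarizedExperiment::assay(counts, "counts")
    if (!is.matrix(counts)) counts <- as.matrix(counts)
    if (any(counts < 0)) stop("negative counts")
    counts
}

.normalizedCounts <- function(counts) {
    m <- .countMatrix(counts)
    sf <- estimateSizeFactorsMedianRatio(m)
    sweep(m, 2L, sf, "/")
}

#' Minimal differential expression: normalized LFC, Welch test, BH
#'
#' A deliberately small differential-expression layer feeding the
#' stabilization eCDF statistic: counts are normalized by median-of-ratios
#' size factors, the per-gene log2 fold change is computed from group means
#' with a pseudocount, the p-value comes from a two-sample unequal-variance
#' (Welch) t-test on log2 normalized counts, and adjusted p-values use
#' Benjamini-Hochberg. This is not a shrinkage-based GLM framework; it is a
#' transparent stand-in adequate for the downstream rank-based statistics,
#' and documented as such.
#'
#' @param counts matrix or `SummarizedExperiment` (assay `counts`).
#' @param group factor/character per sample with two levels; the second
#'   level of `levels` is the numerator of the fold change.
#' @param levels the two group labels, `c(reference, treatment)`.
#' @param pseudocount added to normalized counts before logs (default 0.5).
#' @return `data.frame` with `gene_id`, `log2fc` (treatment over reference),
#'   `p`, `padj`.
#' @export
differentialExpression <- function(counts, group,
                                   levels = c("control", "knockdown"),
                                   pseudocount = 0.5) {
    m <- .countMatrix(counts)
    if (is(counts, "SummarizedExperiment") && missing(group))
        group <- SummarizedExperiment::colData(counts)$group
    if (length(group) != ncol(m))
        stop("'group' must have one entry per sample")
    if (!all(levels %in% group))
        stop("both group levels must be present: ",
             paste(levels, collapse = ", "))
    norm <- .normalizedCounts(m)
    refIdx <- which(group == levels[1L]); trtIdx <- which(group == levels[2L])
    lfc <- log2((rowMeans(norm[, trtIdx, drop = FALSE]) + pseudocount) /
                (rowMeans(norm[, refIdx, drop = FALSE]) + pseudocount))
    logNorm <- log2(norm + pseudocount)
    p <- rep(NA_real_, nrow(m))
    if (length(refIdx) >= 2L && length(trtIdx) >= 2L) {
        p <- vapply(seq_len(nrow(m)), function(i) {
            x <- logNorm[i, trtIdx]; y <- logNorm[i, refIdx]
            if (var(x) == 0 && var(y) == 0)
                return(if (mean(x) == mean(y)) 1 else NA_real_)
            t.test(x, y)$p.value
        }, numeric(1))
    }
    data.frame(gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
               log2fc = unname(lfc), p = p,
               padj = p.adjust(p, method = "BH"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Relative expression by the 2^-ddCt method
#'
#' Classic relative qPCR quantification: per sample, the target Ct minus the
#' reference-gene (e.g. 18S rRNA) Ct gives dCt; the sample dCt minus the
#' calibrator dCt gives ddCt; relative expression is `2^-ddCt`.
#'
#' @param ctTargetSample,ctRefSample Ct values in the sample of interest.
#' @param ctTargetCalibrator,ctRefCalibrator Ct values in the calibrator.
#' @return relative expression (vectorized over its arguments).
#' @examples
#' ddct(20, 10, 22, 10)   # ddCt = -2 -> 4
#' @export
ddct <- function(ctTargetSample, ctRefSample, ctTargetCalibrator,
                 ctRefCalibrator) {
    args <- list(ctTargetSample, ctRefSample, ctTargetCalibrator,
                 ctRefCalibrator)
    if (any(vapply(args, function(x) any(is.na(x)) || length(x) == 0L,
                   logical(1))))
        stop("all four Ct values must be present")
    dctSample <- ctTargetSample - ctRefSample
    dctCal <- ctTargetCalibrator - ctRefCalibrator
    2^-(dctSample - dctCal)
}

#' Translation efficiency from RNC versus total fractions
#'
#' For each gene, translation efficiency (TE) is the ratio of normalized
#' ribosome-nascent-chain (RNC) counts to normalized total counts (both with
#' a pseudocount). The per-group TE uses group-mean normalized counts, and
#' `delta_log2_te` is `log2 TE(knockdown) - log2 TE(control)`. The p-value
#' applies the same Welch test to per-replicate log2 TE values (replicates
#' matched by their `replicate` annotation within group and condition).
#'
#' @param se `SummarizedExperiment` with assay `counts` and colData columns
#'   `group`, `fraction` (`total`/`RNC`), `replicate`.
#' @param levels the two group labels, `c(reference, treatment)`.
#' @param pseudocount pseudocount on normalized counts (default 0.5).
#' @return `data.frame` with `gene_id`, `te_control`, `te_kd`,
#'   `delta_log2_te`, `p`.
#' @export
translationEfficiency <- function(se, levels = c("control", "knockdown"),
                                  pseudocount = 0.5) {
    stopifnot(is(se, "SummarizedExperiment"))
    cd <- SummarizedExperiment::colData(se)
    need <- c("group", "fraction", "replicate")
    if (!all(need %in% names(cd)))
        stop("colData must contain: ", paste(need, collapse = ", "))
    for (g in levels) for (f in c("total", "RNC"))
        if (!any(cd$group == g & cd$fraction == f))
            stop(sprintf("missing fraction '%s' for group '%s'", f, g))
    norm <- .normalizedCounts(se)
    groupMean <- function(g, f)
        rowMeans(norm[, cd$group == g & cd$fraction == f, drop = FALSE]) +
            pseudocount
    teRef <- groupMean(levels[1L], "RNC") / groupMean(levels[1L], "total")
    teTrt <- groupMean(levels[2L], "RNC") / groupMean(levels[2L], "total")

    # per-replicate log2 TE for the test, pairing RNC with total within
    # (group, condition, replicate)
    repKey <- paste(cd$group,
                    if ("condition" %in% names(cd)) cd$condition else "",
                    cd$replicate)
    logTe <- list()
    for (key in unique(repKey)) {
        rnc <- which(repKey == key & cd$fraction == "RNC")
        tot <- which(repKey == key & cd$fraction == "total")
        if (length(rnc) == 1L && length(tot) == 1L)
            logTe[[key]] <- list(
                group = as.character(cd$group[rnc]),
                val = log2((norm[, rnc] + pseudocount) /
                           (norm[, tot] + pseudocount)))
    }
    grp <- vapply(logTe, `[[`, character(1), "group")
    vals <- do.call(cbind, lapply(logTe, `[[`, "val"))
    p <- rep(NA_real_, nrow(norm))
    if (sum(grp == levels[1L]) >= 2L && sum(grp == levels[2L]) >= 2L) {
        refC <- vals[, grp == levels[1L], drop = FALSE]
        trtC <- vals[, grp == levels[2L], drop = FALSE]
        p <- vapply(seq_len(nrow(norm)), function(i) {
            x <- trtC[i, ]; y <- refC[i, ]
            if (var(x) == 0 && var(y) == 0)
                return(if (mean(x) == mean(y)) 1 else NA_real_)
            t.test(x, y)$p.value
        }, numeric(1))
    }
    data.frame(gene_id = rownames(norm) %||%
                   as.character(seq_len(nrow(norm))),
               te_control = unname(teRef), te_kd = unname(teTrt),
               delta_log2_te = unname(log2(teTrt) - log2(teRef)),
               p = p)
}
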