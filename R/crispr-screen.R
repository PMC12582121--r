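#' Normalize guide counts to reads per 100,000
#'
#' Per-sample normalization of a pooled-screen guide count table: each
#' guide's count is divided by its sample's total and multiplied by 100,000,
#' so normalized abundances within a sample always sum to 100,000. A sample
#' is one (cell line, timepoint, replicate) combination.
#'
#' @param counts `data.frame` with columns `guide_id`, `gene_id`,
#'   `cell_line`, `timepoint`, `replicate`, `count`.
#' @return the input with an added `norm_count` column.
#' @examples
#' tab <- data.frame(guide_id = c("g1", "g2"), gene_id = "G",
#'                   cell_line = "MOLM13", timepoint = "day4",
#'                   replicate = 1, count = c(50, 150))
#' normalizeGuideCounts(tab)$norm_count   # 25000 75000
#' @export
normalizeGuideCounts <- function(counts) {
    .checkGuideTable(counts)
    key <- interaction(counts$cell_line, counts$timepoint,
                       counts$replicate, drop = TRUE)
    totals <- tapply(counts$count, key, sum)
    if (any(totals <= 0))
        stop("sample(s) with non-positive total read count: ",
             paste(names(totals)[totals <= 0], collapse = ", "))
    counts$norm_count <- counts$count / as.numeric(totals[key]) * 1e5
    counts
}

.checkGuideTable <- function(counts) {
    need <- c("guide_id", "gene_id", "cell_line", "timepoint", "replicate",
              "count")
    miss <- setdiff(need, names(counts))
    if (length(miss))
        stop("guide count table lacks column(s): ",
             paste(miss, collapse = ", "))
    if (nrow(counts) == 0L)
        stop("empty guide count table")
    if (any(counts$count < 0)) stop("negative guide counts")
    g2g <- unique(counts[, c("guide_id", "gene_id")])
    if (anyDuplicated(g2g$guide_id))
        stop("guide(s) mapping to more than one gene")
    invisible(TRUE)
}

#' Gene-level depletion scores (day 4 over day 20)
#'
#' For each guide, replicate-averaged normalized abundances at day 4 and
#' day 20 enter `log2((d4 + pc) / (d20 + pc))`; a gene's score is the
#' unweighted mean of its guides' log2 fold changes, per cell line.
#' Positive scores indicate depletion over the screen.
#'
#' @param normalized output of [normalizeGuideCounts()].
#' @param pseudocount added to both normalized abundances before the ratio
#'   (default 0.5; keeps scores finite when a guide drops out).
#' @return `data.frame` with `gene_id`, `cell_line`, `log2fc`, `n_guides`.
#' @examples
#' tab <- simScreenCounts(simConfig(seed = 1, nGenes = 20,
#'                        screenDepth = 1e5))
#' scores <- geneLog2FC(normalizeGuideCounts(tab))
#' head(scores)
#' @export
geneLog2FC <- function(normalized, pseudocount = 0.5) {
    if (is.null(normalized$norm_count))
        stop("run normalizeGuideCounts() first ('norm_count' missing)")
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    # replicate-average per guide x cell line x timepoint
    agg <- aggregate(norm_count ~ guide_id + gene_id + cell_line + timepoint,
                     data = normalized, FUN = mean)
    wide <- merge(
        agg[agg$timepoint == "day4",
            c("guide_id", "gene_id", "cell_line", "norm_count")],
        agg[agg$timepoint == "day20",
            c("guide_id", "cell_line", "norm_count")],
        by = c("guide_id", "cell_line"), suffixes = c("_d4", "_d20"))
    if (nrow(wide) == 0L)
        stop("both timepoints (day4, day20) must be present per cell line")
    wide$guide_lfc <- log2((wide$norm_count_d4 + pseudocount) /
                           (wide$norm_count_d20 + pseudocount))
    out <- aggregate(guide_lfc ~ gene_id + cell_line, data = wide,
                     FUN = mean)
    names(out)[names(out) == "guide_lfc"] <- "log2fc"
    nG <- aggregate(guide_id ~ gene_id + cell_line, data = wide,
                    FUN = function(x) length(unique(x)))
    names(nG)[names(nG) == "guide_id"] <- "n_guides"
    out <- merge(out, nG, by = c("gene_id", "cell_line"))
    out[order(out$cell_line, out$gene_id), , drop = FALSE]
}

#' Select screen hits by depletion and counter-screen thresholds
#'
#' Applies the study's selection filters to gene-level scores:
#' * `depleted`: score at least `log2(fold_threshold)` (default five-fold)
#'   in every AML line;
#' * `lineage_specific`: score above `primary_delta` in each AML line and
#'   below it in the T-ALL counter-screen line;
#' * `aml_line_specific`: analogous rule with `secondary_delta` between the
#'   two AML lines (above in the focal line, `amlLines[1]`);
#' * `core_fitness`: membership in a supplied fitness gene list.
#'
#' @param scores output of [geneLog2FC()].
#' @param foldThreshold depletion fold cut-off (default 5).
#' @param primaryDelta AML vs T-ALL log2fc threshold (default 1).
#' @param secondaryDelta threshold for the two-AML-line contrast
#'   (default 2.5).
#' @param fitnessList character vector of known core-fitness genes.
#' @param amlLines,tallLine cell-line names used in the contrasts.
#' @return `data.frame` with one row per gene and logical flag columns.
#' @export
selectScreenHits <- function(scores, foldThreshold = 5, primaryDelta = 1,
                             secondaryDelta = 2.5,
                             fitnessList = character(0),
                             amlLines = c("MOLM13", "THP1"),
                             tallLine = "CUTLL1") {
    if (nrow(scores) == 0L)
        return(data.frame(gene_id = character(0), depleted = logical(0),
                          lineage_specific = logical(0),
                          aml_line_specific = logical(0),
                          core_fitness = logical(0)))
    lines <- unique(scores$cell_line)
    need <- c(amlLines, tallLine)
    if (!all(need %in% lines))
        stop("missing contrast cell line(s): ",
             paste(setdiff(need, lines), collapse = ", "))
    byLine <- lapply(setNames(need, need), function(l) {
        s <- scores[scores$cell_line == l, ]
        setNames(s$log2fc, s$gene_id)
    })
    genes <- sort(unique(scores$gene_id))
    get <- function(l) byLine[[l]][genes]
    amlMat <- matrix(unlist(lapply(amlLines, get)), nrow = length(genes),
                     dimnames = list(genes, amlLines))
    tall <- get(tallLine)
    depleted <- apply(amlMat >= log2(foldThreshold), 1L, all)
    lineageSpecific <- apply(amlMat > primaryDelta, 1L, all) &
        (tall < primaryDelta)
    amlLineSpecific <- (amlMat[, 1L] > secondaryDelta) &
        (amlMat[, 2L] < secondaryDelta)
    res <- data.frame(
        gene_id = genes,
        depleted = unname(depleted & !is.na(depleted)),
        lineage_specific = unname(lineageSpecific %in% TRUE),
        aml_line_specific = unname(amlLineSpecific %in% TRUE),
        core_fitness = genes %in% fitnessList)
    # lineage specificity presupposes depletion signal in the focal lines
    res$lineage_specific <- res$lineage_specific & res$depleted
    res
}
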