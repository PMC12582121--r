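#' Draw a seeded random non-target control gene set
#'
#' Samples `n` genes uniformly without replacement from the universe minus
#' the target set, reproducibly under `seed`. This mirrors the negative
#' control of the stabilization analysis: genes without a detected CLIP peak.
#'
#' @param universe character vector of all quantified gene identifiers.
#' @param targets character vector of CLIP target genes.
#' @param n control-set size.
#' @param seed integer seed.
#' @return character vector of control gene identifiers (never intersecting
#'   `targets`).
#' @export
drawControlSet <- function(universe, targets, n, seed) {
    pool <- setdiff(unique(universe), targets)
    if (n > length(pool))
        stop("non-target pool (", length(pool),
             ") smaller than requested control size (", n, ")")
    withStream(as.integer(seed), "control", sort(sample(pool, n)))
}

#' eCDF shift of target-gene log fold changes with a rank-sum test
#'
#' Compares the knockdown log2 fold-change distribution of a CLIP target
#' gene set against a background set (all quantified genes, or a random
#' non-target control): reports both set medians, the difference of mean
#' LFCs, and a Wilcoxon rank-sum test. The test is exact when the smaller
#' set has at most `exactLimit` observations and there are no ties;
#' otherwise the normal approximation with tie correction is used. A
#' negative shift of the target eCDF indicates that targets drop more than
#' background upon knockdown, i.e. that the protein stabilizes its targets.
#'
#' @param lfc named numeric vector: gene -> log2 fold change.
#' @param targets,background character vectors of gene identifiers; every
#'   gene must have an LFC.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exactLimit largest min(n) for which the exact null is used
#'   (default 25).
#' @return a [CdfComparison-class].
#' @examples
#' lfc <- c(a = 1, b = 2, c = 3, d = 4)
#' cdfShiftTest(lfc, targets = c("a", "b"), background = c("c", "d"))
#' @export
cdfShiftTest <- function(lfc, targets, background,
                         alternative = c("two.sided", "less", "greater"),
                         exactLimit = 25L) {
    alternative <- match.arg(alternative)
    if (length(targets) == 0L || length(background) == 0L)
        stop("empty gene set")
    if (is.null(names(lfc))) stop("'lfc' must be a named vector")
    missT <- setdiff(targets, names(lfc))
    missB <- setdiff(background, names(lfc))
    if (length(missT) || length(missB))
        stop("gene(s) without an LFC: ",
             paste(head(c(missT, missB), 5), collapse = ", "))
    x <- unname(lfc[targets]); y <- unname(lfc[background])
    useExact <- min(length(x), length(y)) <= exactLimit &&
        !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
        wilcox.test(x, y, alternative = alternative, exact = useExact,
                    correct = !useExact))
    new("CdfComparison",
        medianTarget = median(x), medianBackground = median(y),
        meanLfcDifference = mean(x) - mean(y),
        rankSumStatistic = unname(wt$statistic),
        pValue = wt$p.value,
        nTarget = length(x), nBackground = length(y),
        targetLfc = sort(x), backgroundLfc = sort(y),
        exact = useExact)
}

#' Genes whose transcripts overlap at least one CLIP peak
#'
#' Intersects peaks with the transcript annotation (same strand, >= 1 bp
#' overlap) and returns the unique set of overlapped gene identifiers.
#'
#' @param peaks peak `GRanges`.
#' @param annotation feature `GRanges` with a `gene_id` column.
#' @return sorted character vector of gene identifiers (possibly empty).
#' @export
crosslinkTargets <- function(peaks, annotation) {
    stopifnot(is(peaks, "GRanges"), is(annotation, "GRanges"))
    if (length(peaks) == 0L) return(character(0))
    ov <- GenomicRanges::findOverlaps(peaks, annotation,
                                      ignore.strand = FALSE)
    sort(unique(annotation$gene_id[S4Vectors::subjectHits(ov)]))
}
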