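#' Merge crosslink sites into peaks
#'
#' Single-nucleotide crosslink sites on the same chromosome and strand whose
#' positions lie within `mergeGap` of each other (chained, single linkage)
#' form one peak spanning the cluster. Clusters consisting of a single site
#' are extended symmetrically to a width of `soloWidth` bp. Output peaks are
#' sorted and pairwise disjoint per strand.
#'
#' @param sites width-1 `GRanges` of crosslink sites (metadata columns are
#'   ignored except for counting).
#' @param mergeGap maximum distance (bp) between site positions merged into
#'   one cluster (default 50).
#' @param soloWidth width (bp) given to single-site peaks (default 50).
#' @return `GRanges` of peaks with metadata column `n_sites`.
#' @examples
#' s <- GenomicRanges::GRanges("chr1",
#'        IRanges::IRanges(c(101, 121, 500), width = 1), strand = "+")
#' mergeCrosslinkSites(s)
#' @export
mergeCrosslinkSites <- function(sites, mergeGap = 50L, soloWidth = 50L) {
    stopifnot(is(sites, "GRanges"))
    if (mergeGap <= 0 || soloWidth <= 0)
        stop("mergeGap and soloWidth must be positive")
    if (length(sites) == 0L) {
        out <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(sites))
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(n_sites = integer(0))
        return(out)
    }
    if (any(GenomicRanges::start(sites) < 1L))
        stop("negative or zero coordinates in crosslink sites")
    # two width-1 sites at distance d have gap d - 1, so merging sites with
    # distance <= mergeGap means merging ranges with gap < mergeGap
    peaks <- GenomicRanges::reduce(sites, min.gapwidth = mergeGap,
                                   ignore.strand = FALSE)
    hits <- GenomicRanges::countOverlaps(peaks, sites)
    solo <- hits == 1L
    if (any(solo)) {
        # symmetric extension of the single site to soloWidth
        ctr <- GenomicRanges::start(peaks)[solo]
        half <- soloWidth %/% 2L
        newStart <- pmax(1L, ctr - half)
        GenomicRanges::ranges(peaks)[solo] <-
            IRanges::IRanges(newStart, width = soloWidth)
    }
    # extension may have created touching/overlapping solo peaks; keep the
    # per-strand disjointness contract by a final overlap-only merge
    merged <- GenomicRanges::reduce(peaks, min.gapwidth = 0L,
                                    with.revmap = TRUE)
    nS <- vapply(merged$revmap, function(i) sum(hits[i]), integer(1))
    merged$revmap <- NULL
    merged$n_sites <- nS
    sort(merged, ignore.strand = TRUE)
}

#' Merge sites per condition
#'
#' Convenience wrapper: splits a site track by its `condition` metadata
#' column (pooling replicates) and merges each condition separately.
#'
#' @param sites `GRanges` with a `condition` metadata column.
#' @inheritParams mergeCrosslinkSites
#' @return named list of peak `GRanges`, one per condition.
#' @export
mergeSitesByCondition <- function(sites, mergeGap = 50L, soloWidth = 50L) {
    if (is.null(sites$condition))
        stop("sites lack a 'condition' metadata column")
    lapply(S4Vectors::split(sites, sites$condition), mergeCrosslinkSites,
           mergeGap = mergeGap, soloWidth = soloWidth)
}

#' Cross-condition peak overlap (Venn) counts
#'
#' Clusters peaks from all conditions by single-linkage on same-strand
#' overlap of at least 1 bp, then counts clusters by the number of distinct
#' conditions represented: present in all three, in exactly two, or in only
#' one. Categories are mutually exclusive and exhaustive.
#'
#' @param peaksets named list of peak `GRanges`, one per condition.
#' @param maxConditions sanity limit on the number of condition sets
#'   (default 3, matching the three metabolic conditions).
#' @return list with `three`, `exactly_two`, `exactly_one`, `total_clusters`
#'   and `total_peaks` (the summed per-condition peak count).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50), strand = "+")
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(41, 90), strand = "+")
#' c <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 250),
#'                             strand = "+")
#' conditionOverlap(list(norm = a, low = b, gal = c))
#' @export
conditionOverlap <- function(peaksets, maxConditions = 3L) {
    if (!is.list(peaksets) || is.null(names(peaksets)))
        stop("'peaksets' must be a named list of GRanges")
    if (length(peaksets) < 1L || length(peaksets) > maxConditions)
        stop("number of condition peak sets must be in 1..", maxConditions)
    conds <- names(peaksets)
    all <- suppressWarnings(do.call(c, unname(lapply(conds, function(cn) {
        gr <- peaksets[[cn]]
        S4Vectors::mcols(gr) <- NULL
        gr$condition <- rep(cn, length(gr))
        gr
    }))))
    if (length(all) == 0L)
        return(list(three = 0L, exactly_two = 0L, exactly_one = 0L,
                    total_clusters = 0L, total_peaks = 0L))
    # single-linkage overlap clustering == strand-aware overlap-only reduce
    clusters <- GenomicRanges::reduce(all, min.gapwidth = 0L,
                                      with.revmap = TRUE)
    nCond <- vapply(clusters$revmap,
                    function(i) length(unique(all$condition[i])),
                    integer(1))
    list(three = sum(nCond >= 3L),
         exactly_two = sum(nCond == 2L),
         exactly_one = sum(nCond == 1L),
         total_clusters = length(clusters),
         total_peaks = length(all))
}

.FEATURE_PRECEDENCE <- c("5UTR", "CDS", "3UTR", "intron", "lncRNA",
                         "other_ncRNA", "intergenic")

#' Annotate peaks to genomic feature categories
#'
#' Assigns each peak exactly one category by overlap (same strand, >= 1 bp)
#' with the transcript annotation, using the precedence
#' 5UTR > CDS > 3UTR > intron > lncRNA > other_ncRNA > intergenic.
#' Introns are inferred as the gaps between a protein-coding transcript's
#' annotated features.
#'
#' @param peaks peak `GRanges`.
#' @param annotation feature `GRanges` as produced by
#'   [simAnnotationAndSites()] or [readAnnotationGtf()].
#' @param precedence category order, highest priority first.
#' @return list with `labels` (character per peak) and `distribution`
#'   (`data.frame` of category counts and fractions over all categories).
#' @export
annotatePeaks <- function(peaks, annotation,
                          precedence = .FEATURE_PRECEDENCE) {
    stopifnot(is(peaks, "GRanges"), is(annotation, "GRanges"))
    validateAnnotation(annotation)
    catRanges <- .categoryRanges(annotation)
    labels <- rep("intergenic", length(peaks))
    assigned <- rep(FALSE, length(peaks))
    for (cat in setdiff(precedence, "intergenic")) {
        gr <- catRanges[[cat]]
        if (is.null(gr) || length(gr) == 0L) next
        ov <- IRanges::overlapsAny(peaks, gr, ignore.strand = FALSE)
        hit <- ov & !assigned
        labels[hit] <- cat
        assigned <- assigned | ov
    }
    counts <- vapply(precedence, function(cat) sum(labels == cat),
                     integer(1))
    dist <- data.frame(category = precedence, count = unname(counts),
                       fraction = if (length(peaks))
                           unname(counts) / length(peaks) else
                           rep(NA_real_, length(precedence)))
    list(labels = labels, distribution = dist)
}

.categoryRanges <- function(annotation) {
    pc <- annotation[annotation$biotype == "protein_coding"]
    introns <- GenomicRanges::GRanges()
    if (length(pc)) {
        byTx <- S4Vectors::split(pc, pc$transcript_id)
        txSpan <- BiocGenerics::unlist(
            GenomicRanges::reduce(byTx, min.gapwidth = 1000000000L))
        gaps <- BiocGenerics::unlist(GenomicRanges::psetdiff(txSpan, byTx))
        introns <- gaps[GenomicRanges::width(gaps) > 0L]
    }
    list(
        "5UTR" = annotation[annotation$type == "five_prime_utr"],
        "CDS" = annotation[annotation$type == "CDS"],
        "3UTR" = annotation[annotation$type == "three_prime_utr"],
        "intron" = introns,
        "lncRNA" = annotation[annotation$biotype == "lncRNA"],
        "other_ncRNA" = annotation[!annotation$biotype %in%
                                   c("protein_coding", "lncRNA")])
}

#' Metagene coverage profile over scaled 5'UTRs
#'
#' Scales every annotated 5'UTR to `nBins` bins in transcript orientation
#' (5' to 3', strand-aware) and records, per bin, the fraction of 5'UTRs
#' whose bin is covered by at least one peak. Peak height is not used;
#' coverage is presence/absence per UTR.
#'
#' @param peaks peak `GRanges`.
#' @param annotation feature `GRanges` with `five_prime_utr` entries.
#' @param nBins number of bins (default 50).
#' @return numeric vector of length `nBins` with values in `[0, 1]`.
#' @export
metageneProfile <- function(peaks, annotation, nBins = 50L) {
    stopifnot(is(peaks, "GRanges"), nBins >= 1L)
    utrs <- annotation[annotation$type == "five_prime_utr"]
    if (length(utrs) == 0L)
        stop("annotation contains no 5'UTR features")
    zero <- GenomicRanges::width(utrs) == 0L
    if (any(zero)) {
        warning(sum(zero), " zero-length 5'UTR(s) skipped")
        utrs <- utrs[!zero]
    }
    profile <- matrix(0, nrow = length(utrs), ncol = nBins)
    ov <- GenomicRanges::findOverlaps(utrs, peaks, ignore.strand = FALSE)
    if (length(ov)) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        for (k in seq_along(qh)) {
            u <- utrs[qh[k]]; p <- peaks[sh[k]]
            w <- GenomicRanges::width(u)
            # covered genomic offsets within the UTR, 0-based
            lo <- max(GenomicRanges::start(p), GenomicRanges::start(u)) -
                GenomicRanges::start(u)
            hi <- min(GenomicRanges::end(p), GenomicRanges::end(u)) -
                GenomicRanges::start(u)
            offs <- lo:hi
            if (as.character(GenomicRanges::strand(u)) == "-")
                offs <- w - 1L - offs      # transcript orientation
            bins <- unique(floor(offs / w * nBins) + 1L)
            profile[qh[k], bins] <- 1
        }
    }
    colMeans(profile)
}
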