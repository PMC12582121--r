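# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and GenomicRanges machinery where the package
# relies on it) so that agreement is evidence, not tautology.

# Brute-force single-linkage clustering of 1-D intervals / positions:
# all-pairs adjacency + connected components via repeated expansion.
bruteForceClusters <- function(start, end, linkDist = 0L) {
    n <- length(start)
    if (n == 0L) return(integer(0))
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        # overlap or within linkDist: gap = max(start) - min(end) - 1
        gap <- max(start[i], start[j]) - min(end[i], end[j]) - 1L
        adj[i, j] <- gap < linkDist || (start[i] <= end[j] &&
                                        start[j] <= end[i])
    }
    comp <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (adj[i, j] && comp[j] != comp[i]) {
                comp[comp == comp[j]] <- comp[i]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    match(comp, unique(comp))
}

# Exhaustive-enumeration two-sided rank-sum p-value (no ties assumed):
# enumerate every assignment of ranks to the smaller group.
exactRankSumP <- function(x, y) {
    n <- length(x); m <- length(y)
    ranks <- rank(c(x, y))
    wObs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
    combs <- combn(n + m, n)
    allRanks <- rank(c(x, y))   # ranks of the pooled sample
    ws <- apply(combs, 2L, function(idx)
        sum(sort(allRanks)[idx]) - n * (n + 1) / 2)
    pLe <- mean(ws <= wObs); pGe <- mean(ws >= wObs)
    min(1, 2 * min(pLe, pGe))
}

# Closed-form eCDF evaluation
stepEcdf <- function(values, at) vapply(at, function(a) mean(values <= a),
                                        numeric(1))

makeSiteGR <- function(pos, strand = "+", chrom = "chr1",
                       condition = "norm", replicate = 1L) {
    n <- length(pos)
    GenomicRanges::GRanges(rep(chrom, n), IRanges::IRanges(pos, width = 1L),
                           strand = rep(strand, n),
                           condition = rep(condition, n),
                           replicate = rep(replicate, n),
                           score = rep(1, n))
}

makePeakGR <- function(start, end, strand = "+", chrom = "chr1") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                           strand = strand)
}

# Two-transcript toy annotation: one plus-strand and one minus-strand
# protein-coding transcript plus one lncRNA.
toyAnnotation <- function() {
    GenomicRanges::GRanges(
        "chr1",
        IRanges::IRanges(
            start = c(101, 301, 901,    2101, 2501, 3101,  5001),
            end   = c(300, 900, 1300,   2500, 3100, 3300,  6000)),
        strand = c("+", "+", "+", "-", "-", "-", "+"),
        type = c("five_prime_utr", "CDS", "three_prime_utr",
                 "three_prime_utr", "CDS", "five_prime_utr", "exon"),
        gene_id = c(rep("gplus", 3), rep("gminus", 3), "glnc"),
        transcript_id = c(rep("gplus.t1", 3), rep("gminus.t1", 3),
                          "glnc.t1"),
        biotype = c(rep("protein_coding", 6), "lncRNA"))
}
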