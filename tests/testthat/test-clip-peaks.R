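test_that("solo sites are extended symmetrically to the solo width", {
    # single site at 1-based 101 (0-based 100) -> 0-based [75, 125), width 50
    pk <- mergeCrosslinkSites(makeSiteGR(101))
    expect_equal(GenomicRanges::start(pk), 76)
    expect_equal(GenomicRanges::end(pk), 125)
    expect_equal(GenomicRanges::width(pk), 50)
    expect_equal(pk$n_sites, 1L)
})

test_that("nearby sites merge into one cluster spanning the sites", {
    # sites 20 bp apart (<= 50) form one two-site peak over [min, max]
    pk <- mergeCrosslinkSites(makeSiteGR(c(101, 121)))
    expect_length(pk, 1L)
    expect_equal(GenomicRanges::start(pk), 101)
    expect_equal(GenomicRanges::end(pk), 121)
    expect_equal(pk$n_sites, 2L)
    # distance exactly mergeGap merges; one more base does not
    expect_length(mergeCrosslinkSites(makeSiteGR(c(101, 151))), 1L)
    expect_length(mergeCrosslinkSites(makeSiteGR(c(101, 152))), 2L)
})

test_that("opposite strands never merge", {
    s <- c(makeSiteGR(101, "+"), makeSiteGR(101, "-"))
    pk <- mergeCrosslinkSites(s)
    expect_length(pk, 2L)
    expect_setequal(as.character(GenomicRanges::strand(pk)), c("+", "-"))
})

test_that("merging agrees with a brute-force single-linkage oracle", {
    set.seed(99)
    for (trial in 1:5) {
        pos <- sort(sample(1:4000, 120))
        pk <- mergeCrosslinkSites(makeSiteGR(pos), mergeGap = 50,
                                  soloWidth = 50)
        # oracle clusters: chained linkage of positions within 50 bp
        comp <- bruteForceClusters(pos, pos, linkDist = 50L)
        expect_equal(length(pk), length(unique(comp)))
        # every input site lies inside exactly one output peak
        hits <- GenomicRanges::countOverlaps(makeSiteGR(pos), pk)
        expect_true(all(hits == 1L))
        # peaks are pairwise disjoint per strand
        expect_true(all(GenomicRanges::countOverlaps(pk, pk) == 1L))
        # multi-site cluster spans match the oracle
        spans <- t(vapply(split(pos, comp), range, numeric(2)))
        sizes <- tabulate(comp)
        ord <- order(spans[, 1L])
        spans <- spans[ord, , drop = FALSE]; sizes <- sizes[ord]
        expect_equal(GenomicRanges::start(pk)[pk$n_sites > 1],
                     unname(spans[sizes > 1, 1L]))
        expect_equal(GenomicRanges::end(pk)[pk$n_sites > 1],
                     unname(spans[sizes > 1, 2L]))
    }
})

test_that("merging is idempotent on its own output", {
    set.seed(7)
    pos <- sort(sample(1:2000, 60))
    pk <- mergeCrosslinkSites(makeSiteGR(pos))
    mids <- round((GenomicRanges::start(pk) + GenomicRanges::end(pk)) / 2)
    pk2 <- mergeCrosslinkSites(makeSiteGR(mids))
    expect_lte(length(pk2), length(pk))
    expect_true(all(GenomicRanges::countOverlaps(pk2, pk2) == 1L))
})

test_that("empty input gives an empty peak set; bad coordinates error", {
    empty <- makeSiteGR(integer(0))
    expect_length(mergeCrosslinkSites(empty), 0L)
    expect_error(mergeCrosslinkSites(makeSiteGR(101), mergeGap = 0),
                 "positive")
})

test_that("condition overlap reproduces enumerated Venn categories", {
    # A=[1,50], B=[41,90], C=[201,250]: one 2-condition and one 1-condition
    ps <- list(norm = makePeakGR(1, 50), low = makePeakGR(41, 90),
               gal = makePeakGR(201, 250))
    v <- conditionOverlap(ps)
    expect_equal(v[c("three", "exactly_two", "exactly_one")],
                 list(three = 0L, exactly_two = 1L, exactly_one = 1L))
    # identical sets in all three conditions: everything in "three"
    same <- makePeakGR(c(1, 100), c(50, 150))
    v2 <- conditionOverlap(list(norm = same, low = same, gal = same))
    expect_equal(v2$three, 2L)
    expect_equal(v2$exactly_two + v2$exactly_one, 0L)
    # empty inputs
    e <- GenomicRanges::GRanges()
    v3 <- conditionOverlap(list(norm = e, low = e, gal = e))
    expect_equal(v3$total_clusters, 0L)
})

test_that("condition overlap is invariant to relabeling and partitions all clusters", {
    set.seed(21)
    mk <- function() {
        st <- sort(sample(1:5000, 40)) * 10
        makePeakGR(st, st + sample(20:80, 40, replace = TRUE))
    }
    ps <- list(norm = mk(), low = mk(), gal = mk())
    v <- conditionOverlap(ps)
    vPerm <- conditionOverlap(ps[c("gal", "norm", "low")])
    expect_equal(v[c("three", "exactly_two", "exactly_one")],
                 vPerm[c("three", "exactly_two", "exactly_one")])
    expect_equal(v$three + v$exactly_two + v$exactly_one,
                 v$total_clusters)
    # oracle equivalence on the pooled intervals
    all <- suppressWarnings(do.call(c, unname(ps)))
    comp <- bruteForceClusters(GenomicRanges::start(all),
                               GenomicRanges::end(all))
    expect_equal(v$total_clusters, length(unique(comp)))
})

test_that("strandedness separates otherwise identical condition peaks", {
    ps <- list(norm = makePeakGR(1, 50, "+"), low = makePeakGR(1, 50, "-"))
    v <- conditionOverlap(ps)
    expect_equal(v$exactly_one, 2L)
    expect_equal(v$exactly_two, 0L)
})

test_that("peak annotation follows the 5'UTR-first precedence", {
    ann <- toyAnnotation()
    # wholly inside the plus-strand 5'UTR
    r1 <- annotatePeaks(makePeakGR(120, 180), ann)
    expect_equal(r1$labels, "5UTR")
    # spanning the 5'UTR/CDS boundary resolves to 5'UTR by precedence
    r2 <- annotatePeaks(makePeakGR(250, 350), ann)
    expect_equal(r2$labels, "5UTR")
    # inside the minus-strand 5'UTR (right end of the locus), matching strand
    r3 <- annotatePeaks(makePeakGR(3150, 3200, "-"), ann)
    expect_equal(r3$labels, "5UTR")
    # same interval on the wrong strand falls through to intergenic
    r4 <- annotatePeaks(makePeakGR(3150, 3200, "+"), ann)
    expect_equal(r4$labels, "intergenic")
    # lncRNA exon
    r5 <- annotatePeaks(makePeakGR(5100, 5200), ann)
    expect_equal(r5$labels, "lncRNA")
    # overlapping nothing
    r6 <- annotatePeaks(makePeakGR(9000, 9050), ann)
    expect_equal(r6$labels, "intergenic")
    # fractions sum to one over categories
    rAll <- annotatePeaks(makePeakGR(c(120, 250, 5100, 9000),
                                     c(180, 350, 5200, 9050)), ann)
    expect_equal(sum(rAll$distribution$fraction), 1)
})

test_that("annotation with unknown strand is rejected", {
    bad <- toyAnnotation()
    GenomicRanges::strand(bad)[1] <- "*"
    expect_error(annotatePeaks(makePeakGR(120, 180), bad), "strand")
})

test_that("metagene profile bins 5'UTR coverage in transcript orientation", {
    ann <- toyAnnotation()
    # plus-strand UTR is 101-300 (200 nt); cover its first half
    prof <- metageneProfile(makePeakGR(101, 200), ann, nBins = 10)
    # two UTRs in the annotation; only one covered in bins 1-5
    expect_equal(prof, c(rep(0.5, 5), rep(0, 5)))
    # minus-strand UTR is 3101-3300; its 5' end is the RIGHT end
    profM <- metageneProfile(makePeakGR(3201, 3300, "-"), ann, nBins = 10)
    expect_equal(profM, c(rep(0.5, 5), rep(0, 5)))
    # full coverage of both UTRs -> all bins 1
    both <- c(makePeakGR(101, 300), makePeakGR(3101, 3300, "-"))
    expect_equal(metageneProfile(both, ann, nBins = 10), rep(1, 10))
    # no peaks -> all bins 0
    expect_equal(metageneProfile(GenomicRanges::GRanges(), ann, 10),
                 rep(0, 10))
})

test_that("minus-strand metagene mirrors the plus-strand profile", {
    ann <- toyAnnotation()
    # cover the transcript-5' 25% of each UTR
    plus <- metageneProfile(makePeakGR(101, 150), ann, nBins = 8)
    minus <- metageneProfile(makePeakGR(3251, 3300, "-"), ann, nBins = 8)
    expect_equal(plus, minus)
})
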