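test_that("generators are deterministic under a fixed seed", {
    cfg <- simConfig(seed = 42, nGenes = 40, screenDepth = 1e5,
                     nSitesPerSample = 100, nMassEvents = 500L)
    expect_identical(simScreenCounts(cfg), simScreenCounts(cfg))
    s1 <- simAnnotationAndSites(cfg); s2 <- simAnnotationAndSites(cfg)
    expect_identical(as.data.frame(s1$sites), as.data.frame(s2$sites))
    e1 <- simExpressionCounts(cfg); e2 <- simExpressionCounts(cfg)
    expect_identical(SummarizedExperiment::assay(e1),
                     SummarizedExperiment::assay(e2))
    expect_identical(simAssayCurves(cfg), simAssayCurves(cfg))
})

test_that("generator substreams leave the caller's RNG state untouched", {
    cfg <- simConfig(seed = 7, nGenes = 20, screenDepth = 1e4,
                     nMassEvents = 200L)
    set.seed(123); before <- .Random.seed
    invisible(simScreenCounts(cfg))
    invisible(simAssayCurves(cfg))
    expect_identical(.Random.seed, before)
})

test_that("screen counts: no injected effect means near-zero gene LFCs", {
    cfg <- simConfig(seed = 3, nGenes = 100, depletedGeneFraction = 0,
                     screenDepth = 2e6)
    tab <- simScreenCounts(cfg)
    expect_length(attr(tab, "depleted_genes"), 0L)
    scores <- geneLog2FC(normalizeGuideCounts(tab))
    expect_lt(max(abs(scores$log2fc)), 0.5)
    expect_lt(abs(mean(scores$log2fc)), 0.05)
})

test_that("screen counts: noiseless forced five-fold drop gives log2(5) exactly", {
    cfg <- simConfig(seed = 5, nGenes = 30, depletedGeneFraction = 0.2,
                     screenFold = 5, noise = list(screen = FALSE))
    tab <- simScreenCounts(cfg)
    depl <- attr(tab, "depleted_genes")
    expect_gt(length(depl), 0)
    scores <- geneLog2FC(normalizeGuideCounts(tab), pseudocount = 0)
    aml <- scores[scores$cell_line == "MOLM13", ]
    expect_equal(aml$log2fc[aml$gene_id %in% depl],
                 rep(log2(5), length(depl)), tolerance = 1e-9)
    # survivors repopulate the culture: non-depleted genes share a small
    # negative score of exactly -log2(f), f the repopulation factor
    nDepl <- length(depl); nAll <- 30
    f <- (nAll - nDepl / 5) / (nAll - nDepl)
    expect_equal(aml$log2fc[!aml$gene_id %in% depl],
                 rep(-log2(f), sum(!aml$gene_id %in% depl)),
                 tolerance = 1e-9)
    # counter-screen line carries no depletion
    tall <- scores[scores$cell_line == "CUTLL1", ]
    expect_equal(tall$log2fc, rep(0, nrow(tall)), tolerance = 1e-12)
})

test_that("screen sample totals match the configured depth under multinomial noise", {
    cfg <- simConfig(seed = 11, nGenes = 50, screenDepth = 123457)
    tab <- simScreenCounts(cfg)
    totals <- tapply(tab$count, paste(tab$cell_line, tab$timepoint), sum)
    expect_true(all(totals == 123457))
})

test_that("screen generator rejects non-positive depth", {
    expect_error(simScreenCounts(simConfig(seed = 1, nGenes = 5,
                                           screenDepth = 0)),
                 "depth")
})

test_that("site placement respects the 5'UTR enrichment weight", {
    # degenerate weight: everything in 5'UTRs
    cfg1 <- simConfig(seed = 2, nGenes = 50, utr5Enrichment = 1,
                      nSitesPerSample = 200)
    sim1 <- simAnnotationAndSites(cfg1)
    utr5 <- sim1$annotation[sim1$annotation$type == "five_prime_utr"]
    inUtr <- IRanges::overlapsAny(sim1$sites, utr5, ignore.strand = FALSE)
    expect_true(all(inUtr))

    # weight 0.5 at large n: within 3 binomial SEs
    n <- 10000L
    cfg2 <- simConfig(seed = 2, nGenes = 200, utr5Enrichment = 0.5,
                      nSitesPerSample = n)
    sim2 <- simAnnotationAndSites(cfg2, nReplicates = 1L)
    utr5 <- sim2$annotation[sim2$annotation$type == "five_prime_utr"]
    frac <- mean(IRanges::overlapsAny(sim2$sites, utr5,
                                      ignore.strand = FALSE))
    se <- sqrt(0.5 * 0.5 / (3 * n))     # 3 conditions x n sites
    expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("zero requested sites give an empty track with a valid annotation", {
    cfg <- simConfig(seed = 9, nGenes = 20, nSitesPerSample = 0)
    sim <- simAnnotationAndSites(cfg)
    expect_length(sim$sites, 0L)
    expect_true(validateAnnotation(sim$annotation))
})

test_that("annotation features are stranded, non-overlapping and typed", {
    cfg <- simConfig(seed = 4, nGenes = 120)
    ann <- simAnnotationAndSites(cfg)$annotation
    expect_true(validateAnnotation(ann))
    expect_true(all(as.character(GenomicRanges::strand(ann)) %in%
                    c("+", "-")))
    pc <- ann[ann$biotype == "protein_coding"]
    expect_setequal(unique(pc$type),
                    c("five_prime_utr", "CDS", "three_prime_utr"))
    # malformed (overlapping) input is rejected
    bad <- toyAnnotation()
    GenomicRanges::end(bad)[1] <- 400   # 5'UTR now overlaps the CDS
    expect_error(validateAnnotation(bad), "malformed")
})

test_that("expression counts recover the injected stabilization LFC", {
    # near-noiseless limit: exact expected counts
    cfg <- simConfig(seed = 6, nGenes = 200, stabilizationLfc = -1,
                     noise = list(expression = FALSE))
    se <- simExpressionCounts(cfg)
    de <- differentialExpression(se, group = se$group)
    isTarget <- de$gene_id %in% cfg@targetGeneIds
    # pseudocount 0.5 biases the LFC slightly towards 0 at finite depth
    expect_equal(median(de$log2fc[isTarget]), -1, tolerance = 0.02)
    expect_equal(median(abs(de$log2fc[!isTarget])), 0, tolerance = 1e-9)

    # law-of-large-numbers check with small dispersion
    cfg2 <- simConfig(seed = 6, nGenes = 2000, stabilizationLfc = -1,
                      nbDispersion = 1e-4)
    se2 <- simExpressionCounts(cfg2)
    de2 <- differentialExpression(se2, group = se2$group)
    isT2 <- de2$gene_id %in% cfg2@targetGeneIds
    expect_equal(median(de2$log2fc[isT2]), -1, tolerance = 0.05)
})

test_that("expression generator: null effect gives indistinguishable sets", {
    cfg <- simConfig(seed = 8, nGenes = 400, stabilizationLfc = 0)
    se <- simExpressionCounts(cfg)
    de <- differentialExpression(se, group = se$group)
    lfc <- setNames(de$log2fc, de$gene_id)
    cmp <- cdfShiftTest(lfc, cfg@targetGeneIds, de$gene_id)
    expect_gt(cmp@pValue, 0.01)
    expect_lt(abs(cmp@meanLfcDifference), 0.1)
})

test_that("expression generator rejects non-positive dispersion", {
    expect_error(
        simExpressionCounts(simConfig(seed = 1, nGenes = 10,
                                      nbDispersion = -1)),
        "dispersion")
})

test_that("assay curves honour their closed-form ground truth when noiseless", {
    cfg <- simConfig(seed = 10,
                     bindingTruth = list(kd_nM = 100, r_free = 20,
                                         r_bound = 220, probe_nM = 2),
                     massComponents = list(list(mean_kDa = 150, sd_kDa = 0,
                                                weight = 1)),
                     nMassEvents = 200L,
                     decayHalflivesH = c(control = 2),
                     noise = list(titration_sd = 0, decay_sdlog = 0))
    curves <- simAssayCurves(cfg)
    # isotherm midpoint at [P] = Kd
    atKd <- curves$titration[curves$titration$protein_conc_nM == 100, ]
    expect_equal(atKd$response_mP, rep((20 + 220) / 2, nrow(atKd)),
                 tolerance = 1e-12)
    # degenerate mixture: every event exactly at the component mean
    expect_true(all(curves$massEvents$mass_kDa == 150))
    # decay half-life 2 h: abundance at 8 h is 2^-4
    d <- curves$decay[curves$decay$replicate == 1, ]
    expect_equal(d$rel_abundance[d$time_h == 8], 2^-4, tolerance = 1e-12)
})

test_that("assay generator rejects non-positive Kd", {
    cfg <- simConfig(seed = 1)
    cfg@bindingTruth$kd_nM <- -5
    expect_error(simAssayCurves(cfg), "kd_nM")
})
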