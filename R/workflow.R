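#' Default pipeline configuration
#'
#' Returns the configuration list accepted by [runPipeline()], with every
#' stage enabled on synthetic inputs and the analysis thresholds at their
#' documented defaults. Any sub-list can be overridden via `...` (merged
#' recursively), or by editing the YAML form written by
#' [writePipelineConfig()].
#'
#' @param seed master seed.
#' @param ... named overrides merged into the default config, e.g.
#'   `synthetic = list(n_genes = 200)`.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L, ...) {
    cfg <- list(
        seed = as.integer(seed),
        synthetic = list(n_genes = 300L, n_guides_per_gene = 4L,
                         depleted_gene_fraction = 0.1, screen_depth = 5e5,
                         screen_fold = 8, nb_dispersion = 0.05,
                         stabilization_lfc = -0.5, te_lfc = 0,
                         utr5_enrichment = 0.5, n_sites_per_sample = 500L),
        stages = list(screen = TRUE, clip = TRUE, de = TRUE, te = TRUE,
                      cdf = TRUE, assays = TRUE),
        thresholds = list(fold_threshold = 5, primary_delta = 1,
                          secondary_delta = 2.5, merge_gap = 50L,
                          solo_width = 50L, n_bins = 50L,
                          pseudocount = 0.5, control_set_size = 100L))
    modifyList(cfg, list(...))
}

#' Write / read a pipeline configuration as YAML
#' @param config configuration list.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    modifyList(defaultPipelineConfig(seed = cfg$seed %||% 1L), cfg)
}

.validatePipelineConfig <- function(config) {
    bad <- character(0)
    th <- config$thresholds
    for (k in c("fold_threshold", "primary_delta", "secondary_delta",
                "merge_gap", "solo_width", "n_bins", "pseudocount"))
        if (is.null(th[[k]]) || !is.numeric(th[[k]]) || th[[k]] < 0)
            bad <- c(bad, paste0("thresholds$", k))
    if (is.null(config$seed)) bad <- c(bad, "seed")
    if (length(bad))
        stop("invalid pipeline config, offending key(s): ",
             paste(bad, collapse = ", "))
    st <- config$stages
    if (isTRUE(st$cdf) && (!isTRUE(st$clip) || !isTRUE(st$de)))
        stop("stage 'cdf' requires stages 'clip' and 'de' to be enabled")
    if (isTRUE(st$te) && !isTRUE(st$de))
        stop("stage 'te' requires stage 'de' (shared normalization layer)")
    invisible(TRUE)
}

.configHash <- function(config) {
    f <- tempfile(fileext = ".yaml")
    on.exit(unlink(f))
    yaml::write_yaml(config, f)
    unname(tools::md5sum(f))
}

.provenance <- function(config, stage) {
    sprintf("# ncRBPtools %s | stage=%s | seed=%d | config_md5=%s",
            as.character(utils::packageVersion("ncRBPtools")), stage,
            as.integer(config$seed), .configHash(config))
}

.writeStageTable <- function(df, path, config, stage) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.provenance(config, stage), con)
    suppressWarnings(
        write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
    invisible(path)
}

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates all stages on synthetic inputs generated from the config's
#' seed: screen scoring and hit selection; CLIP site merging,
#' cross-condition Venn counts, peak annotation and 5'UTR metagene profile;
#' differential expression and translation efficiency; the target
#' stabilization eCDF comparison (against all genes and against a seeded
#' random non-target control); and the assay curve fits. Each enabled stage
#' writes TSV/JSON outputs carrying a provenance header (package version,
#' seed, config hash) into `outDir`, plus a small self-contained HTML
#' summary. Identical config and seed give identical outputs.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or the
#'   path to a YAML file.
#' @param outDir output directory, created if needed.
#' @return (invisibly) a named list with each stage's in-memory results.
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outDir = tempfile("ncrbp_run_")) {
    if (is.character(config)) config <- readPipelineConfig(config)
    .validatePipelineConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    syn <- config$synthetic
    cfg <- simConfig(
        seed = config$seed, nGenes = syn$n_genes,
        nGuidesPerGene = syn$n_guides_per_gene,
        depletedGeneFraction = syn$depleted_gene_fraction,
        screenDepth = syn$screen_depth, screenFold = syn$screen_fold,
        nbDispersion = syn$nb_dispersion,
        stabilizationLfc = syn$stabilization_lfc, teLfc = syn$te_lfc,
        utr5Enrichment = syn$utr5_enrichment,
        nSitesPerSample = syn$n_sites_per_sample)
    th <- config$thresholds
    st <- config$stages
    bundle <- list(config = config)

    if (isTRUE(st$screen)) {
        tab <- simScreenCounts(cfg)
        scores <- geneLog2FC(normalizeGuideCounts(tab),
                             pseudocount = th$pseudocount)
        hits <- selectScreenHits(scores,
                                 foldThreshold = th$fold_threshold,
                                 primaryDelta = th$primary_delta,
                                 secondaryDelta = th$secondary_delta)
        .writeStageTable(scores, file.path(outDir, "screen_scores.tsv"),
                         config, "screen")
        .writeStageTable(hits, file.path(outDir, "screen_hits.tsv"),
                         config, "screen")
        bundle$screen <- list(scores = scores, hits = hits,
                              truth = attr(tab, "depleted_genes"))
    }

    annotation <- NULL
    peaksByCondition <- NULL
    if (isTRUE(st$clip)) {
        sim <- simAnnotationAndSites(cfg)
        annotation <- sim$annotation
        peaksByCondition <- mergeSitesByCondition(
            sim$sites, mergeGap = th$merge_gap, soloWidth = th$solo_width)
        venn <- conditionOverlap(peaksByCondition)
        allPeaks <- suppressWarnings(
            do.call(c, unname(peaksByCondition)))
        ann <- annotatePeaks(allPeaks, annotation)
        meta <- metageneProfile(allPeaks, annotation, nBins = th$n_bins)
        writeAnnotationGtf(annotation,
                           file.path(outDir, "annotation.gtf"))
        for (cond in names(peaksByCondition))
            writePeaksBed(peaksByCondition[[cond]],
                          file.path(outDir,
                                    sprintf("peaks_%s.bed", cond)))
        jsonlite::write_json(venn, file.path(outDir, "clip_venn.json"),
                             auto_unbox = TRUE)
        .writeStageTable(ann$distribution,
                         file.path(outDir, "clip_feature_distribution.tsv"),
                         config, "clip")
        .writeStageTable(
            data.frame(bin = seq_along(meta), mean_coverage = meta),
            file.path(outDir, "clip_metagene.tsv"), config, "clip")
        bundle$clip <- list(peaks = peaksByCondition, venn = venn,
                            featureDistribution = ann$distribution,
                            metagene = meta)
    }

    de <- NULL
    if (isTRUE(st$de)) {
        fr <- if (isTRUE(st$te)) c("total", "RNC") else "total"
        se <- simExpressionCounts(cfg, fractions = fr)
        seTotal <- se[, se$fraction == "total"]
        de <- differentialExpression(seTotal, group = seTotal$group)
        .writeStageTable(de, file.path(outDir, "de_results.tsv"),
                         config, "de")
        bundle$de <- de
        if (isTRUE(st$te)) {
            te <- translationEfficiency(se)
            .writeStageTable(te, file.path(outDir, "te_results.tsv"),
                             config, "te")
            bundle$te <- te
        }
    }

    if (isTRUE(st$cdf)) {
        allPeaks <- suppressWarnings(do.call(c, unname(peaksByCondition)))
        targets <- crosslinkTargets(allPeaks, annotation)
        lfc <- setNames(de$log2fc, de$gene_id)
        targets <- intersect(targets, names(lfc))
        cmpAll <- cdfShiftTest(lfc, targets, names(lfc))
        nCtl <- min(th$control_set_size %||% 100L,
                    length(setdiff(names(lfc), targets)))
        control <- drawControlSet(names(lfc), targets, nCtl, config$seed)
        cmpCtl <- cdfShiftTest(lfc, targets, control)
        jsonlite::write_json(
            list(vs_all_genes = comparisonStats(cmpAll),
                 vs_random_control = comparisonStats(cmpCtl)),
            file.path(outDir, "cdf_comparison.json"), auto_unbox = TRUE,
            digits = NA)
        .writeStageTable(ecdfCurves(cmpAll),
                         file.path(outDir, "cdf_curves.tsv"),
                         config, "cdf")
        bundle$cdf <- list(vsAll = cmpAll, vsControl = cmpCtl,
                           targets = targets, control = control)
    }

    if (isTRUE(st$assays)) {
        curves <- simAssayCurves(cfg)
        bind <- fitBinding(curves$titration$protein_conc_nM,
                           curves$titration$response_mP)
        mix <- fitMassMixture(curves$massEvents$mass_kDa, k = "auto",
                              seed = config$seed)
        byCond <- split(curves$decay, curves$decay$condition)
        decayFits <- lapply(byCond, function(d)
            fitDecay(d$time_h, d$rel_abundance))
        fits <- list(
            binding = list(kd_nM = bind@kd, se_kd = bind@seKd,
                           r_free = bind@responseFree,
                           r_bound = bind@responseBound,
                           r_squared = bind@rSquared),
            mass_mixture = mixtureComponents(mix),
            decay = lapply(decayFits, function(f)
                list(lambda_per_h = f@lambda, half_life_h = f@halfLife,
                     se_half_life_h = f@seHalfLife,
                     r_squared = f@rSquared)))
        if (all(c("control", "knockdown") %in% names(decayFits)))
            fits$halflife_ratio <- halflifeRatio(decayFits$control,
                                                 decayFits$knockdown)
        jsonlite::write_json(fits, file.path(outDir, "assay_fits.json"),
                             auto_unbox = TRUE, digits = NA)
        bundle$assays <- list(binding = bind, mixture = mix,
                              decay = decayFits)
    }

    .writeHtmlSummary(bundle, file.path(outDir, "summary.html"))
    invisible(bundle)
}

# Minimal self-contained HTML report; numeric content only, no plots.
.writeHtmlSummary <- function(bundle, path) {
    esc <- function(x) gsub("<", "&lt;", as.character(x))
    lines <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
               "<title>ncRBPtools pipeline summary</title></head><body>",
               "<h1>ncRBPtools pipeline summary</h1>",
               sprintf("<p>seed %d | config md5 %s</p>",
                       bundle$config$seed, .configHash(bundle$config)))
    if (!is.null(bundle$screen)) {
        h <- bundle$screen$hits
        lines <- c(lines, "<h2>CRISPR screen</h2>",
                   sprintf("<p>%d genes scored; %d depleted (&ge; fold threshold); %d lineage-specific (AML vs T-ALL); %d AML-line-specific.</p>",
                           nrow(h), sum(h$depleted),
                           sum(h$lineage_specific),
                           sum(h$aml_line_specific)))
    }
    if (!is.null(bundle$clip)) {
        v <- bundle$clip$venn
        fd <- bundle$clip$featureDistribution
        lines <- c(lines, "<h2>CLIP peaks</h2>",
                   sprintf("<p>Venn: %d in all three conditions, %d in exactly two, %d in one (of %d clusters, %d peaks).</p>",
                           v$three, v$exactly_two, v$exactly_one,
                           v$total_clusters, v$total_peaks),
                   "<p>Feature distribution: ",
                   paste(sprintf("%s %.1f%%", esc(fd$category),
                                 100 * fd$fraction), collapse = ", "),
                   "</p>")
    }
    if (!is.null(bundle$cdf)) {
        s <- comparisonStats(bundle$cdf$vsAll)
        lines <- c(lines, "<h2>Target stabilization (eCDF)</h2>",
                   sprintf("<p>median target LFC %+.3f vs background %+.3f; mean LFC difference %+.3f; rank-sum p = %.3g (n = %d vs %d).</p>",
                           s$median_target_lfc, s$median_background_lfc,
                           s$mean_lfc_difference, s$p, s$n_target,
                           s$n_background))
    }
    if (!is.null(bundle$assays)) {
        b <- bundle$assays$binding
        lines <- c(lines, "<h2>Assay fits</h2>",
                   sprintf("<p>Binding Kd = %.1f nM (R<sup>2</sup> = %.3f); mixture components at %s kDa.</p>",
                           b@kd, b@rSquared,
                           paste(sprintf("%.1f", bundle$assays$mixture@means),
                                 collapse = " / ")))
        if (length(bundle$assays$decay))
            lines <- c(lines, "<p>Half-lives: ",
                       paste(sprintf("%s %.2f h",
                                     esc(names(bundle$assays$decay)),
                                     vapply(bundle$assays$decay, halfLife,
                                            numeric(1))),
                             collapse = ", "), "</p>")
    }
    writeLines(c(lines, "</body></html>"), path)
    invisible(path)
}
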