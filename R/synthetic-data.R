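#' Build a simulation configuration
#'
#' Constructs a validated [SimConfig-class] holding the ground truth for all
#' synthetic-data generators. Defaults mirror the study conditions the
#' pipeline was designed around: a four-guide-per-gene knockout library over
#' ~1000 candidate genes, pooled-screen depths of 300-500x coverage, CLIP
#' crosslink sites biased towards 5'UTRs across three metabolic conditions
#' (normal glucose, low glucose, galactose) with two replicates each,
#' negative-binomial expression counts with a mild destabilization of CLIP
#' targets upon knockdown, a one-site fluorescence-polarization isotherm with
#' a nanomolar-range dissociation constant, a monomer/tetramer mass-photometry
#' mixture, and an actinomycin-D decay time course sampled hourly over 8 h
#' with a threefold half-life difference between control and knockdown.
#'
#' @param seed integer master seed; all generators derive named substreams
#'   from it, so a fixed seed gives byte-identical outputs.
#' @param nGenes,nGuidesPerGene library design.
#' @param depletedGeneFraction fraction of genes made AML-depleted in the
#'   screen.
#' @param screenDepth reads per screen sample.
#' @param screenFold fold reduction of day-20 relative abundance for
#'   depleted genes (default 8, comfortably past the five-fold hit
#'   threshold).
#' @param nbDispersion shared NB dispersion for expression counts (> 0).
#' @param targetGeneIds stabilization target genes; default: the first
#'   `min(300, nGenes %/% 3)` gene identifiers.
#' @param stabilizationLfc log2 expression shift of targets in knockdown.
#' @param teLfc log2 translation-efficiency shift of targets in knockdown.
#' @param utr5Enrichment probability a crosslink site is placed in a 5'UTR.
#' @param nSitesPerSample crosslink sites per condition x replicate.
#' @param bindingTruth list(kd_nM, r_free, r_bound, probe_nM).
#' @param massComponents list of list(mean_kDa, sd_kDa, weight); weights sum
#'   to 1.
#' @param nMassEvents events per mass-photometry acquisition.
#' @param decayHalflivesH named numeric of half-lives (hours) per condition.
#' @param noise list(screen =, expression =, titration_sd =, decay_sdlog =);
#'   logical entries toggle count resampling, numeric entries set noise
#'   magnitudes (0 = noiseless).
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 50)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nGenes = 1045L,
                      nGuidesPerGene = 4L,
                      depletedGeneFraction = 0.1,
                      screenDepth = 2e6,
                      screenFold = 8,
                      nbDispersion = 0.05,
                      targetGeneIds = NULL,
                      stabilizationLfc = -0.5,
                      teLfc = 0,
                      utr5Enrichment = 0.5,
                      nSitesPerSample = 1000L,
                      bindingTruth = list(kd_nM = 167, r_free = 50,
                                          r_bound = 250, probe_nM = 2),
                      massComponents = list(
                          list(mean_kDa = 38.5, sd_kDa = 6, weight = 0.35),
                          list(mean_kDa = 148.3, sd_kDa = 6, weight = 0.65)),
                      nMassEvents = 20000L,
                      decayHalflivesH = c(control = 6, knockdown = 2),
                      noise = list()) {
    noiseDefaults <- list(screen = TRUE, expression = TRUE,
                          titration_sd = 5, decay_sdlog = 0.1)
    noise <- modifyList(noiseDefaults, noise)
    if (is.null(targetGeneIds)) {
        nTargets <- min(300L, max(1L, nGenes %/% 3L))
        targetGeneIds <- geneIds(nGenes)[seq_len(nTargets)]
    }
    new("SimConfig",
        seed = as.integer(seed), nGenes = as.integer(nGenes),
        nGuidesPerGene = as.integer(nGuidesPerGene),
        depletedGeneFraction = depletedGeneFraction,
        screenDepth = screenDepth, screenFold = screenFold,
        nbDispersion = nbDispersion,
        targetGeneIds = as.character(targetGeneIds),
        stabilizationLfc = stabilizationLfc, teLfc = teLfc,
        utr5Enrichment = utr5Enrichment,
        nSitesPerSample = as.integer(nSitesPerSample),
        bindingTruth = bindingTruth, massComponents = massComponents,
        nMassEvents = as.integer(nMassEvents),
        decayHalflivesH = decayHalflivesH, noise = noise)
}

geneIds <- function(n) sprintf("gene%05d", seq_len(n))

.AML_LINES <- c("MOLM13", "THP1")
.TALL_LINE <- "CUTLL1"
.CONDITIONS <- c("norm", "low", "gal")

#' Simulate a pooled CRISPR screen guide count table
#'
#' Draws day-4 and day-20 guide counts for two AML lines (MOLM13, THP1) and
#' one T-ALL counter-screen line (CUTLL1). Latent guide abundances are
#' log-normal; genes designated as depleted have their day-20 abundance
#' divided by `screenFold` in the AML lines only, and per-sample counts are
#' drawn multinomially at `screenDepth`. With `noise$screen = FALSE` the
#' latent abundances are equal integers and returned without resampling, so
#' the injected fold change is exact.
#'
#' @param cfg a [SimConfig-class].
#' @param nReplicates screen replicates per (cell line, timepoint).
#' @return `data.frame` with columns `guide_id`, `gene_id`, `cell_line`,
#'   `timepoint` (`day4`/`day20`), `replicate`, `count`, plus attributes
#'   `depleted_genes` (character) naming the ground-truth depleted set.
#' @examples
#' tab <- simScreenCounts(simConfig(seed = 1, nGenes = 20, screenDepth = 1e5))
#' head(tab)
#' @export
simScreenCounts <- function(cfg, nReplicates = 1L) {
    stopifnot(is(cfg, "SimConfig"))
    if (cfg@screenDepth <= 0)
        stop("screen depth must be positive")
    genes <- geneIds(cfg@nGenes)
    nGuides <- cfg@nGenes * cfg@nGuidesPerGene
    guideGene <- rep(genes, each = cfg@nGuidesPerGene)
    guideIds <- paste0(guideGene, "_sg", seq_len(cfg@nGuidesPerGene))
    nDepleted <- round(cfg@depletedGeneFraction * cfg@nGenes)

    withStream(cfg@seed, "screen", {
        depleted <- if (nDepleted > 0) sort(sample(genes, nDepleted))
                    else character(0)
        isDepleted <- guideGene %in% depleted
        noisy <- isTRUE(cfg@noise$screen)
        base <- if (noisy) rlnorm(nGuides, meanlog = log(500), sdlog = 0.5)
                else rep(500, nGuides)
        rows <- list()
        for (line in c(.AML_LINES, .TALL_LINE)) {
            d20 <- base
            if (line %in% .AML_LINES && any(isDepleted)) {
                d20[isDepleted] <- base[isDepleted] / cfg@screenFold
                # surviving cells repopulate the culture, so the total
                # stays put and the relative abundance of a depleted guide
                # drops by exactly the configured fold
                f <- (sum(base) - sum(d20[isDepleted])) /
                    sum(base[!isDepleted])
                d20[!isDepleted] <- base[!isDepleted] * f
            }
            for (tp in c("day4", "day20")) {
                abund <- if (tp == "day4") base else d20
                for (rep_i in seq_len(nReplicates)) {
                    cnt <- if (noisy)
                        as.vector(rmultinom(1, size = round(cfg@screenDepth),
                                            prob = abund))
                    else abund
                    rows[[length(rows) + 1L]] <- data.frame(
                        guide_id = guideIds, gene_id = guideGene,
                        cell_line = line, timepoint = tp,
                        replicate = rep_i, count = cnt,
                        stringsAsFactors = FALSE)
                }
            }
        }
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        attr(out, "depleted_genes") <- depleted
        out
    })
}

# Toy genome layout: transcripts tiled along chromosomes (~50 per chromosome,
# alternating strands), protein-coding transcripts carrying 200 nt 5'UTR,
# 600 nt CDS and 400 nt 3'UTR laid out in transcript orientation.
.TX_PER_CHROM <- 50L
.UTR5_LEN <- 200L
.CDS_LEN <- 600L
.UTR3_LEN <- 400L
.TX_GAP <- 500L

#' Simulate a toy transcript annotation and CLIP crosslink sites
#'
#' Builds a toy genome in which each gene has one transcript: 80% are
#' protein-coding (5'UTR/CDS/3'UTR features), 12% lncRNA and 8% other
#' non-coding (single exon feature). Crosslink sites for the three metabolic
#' conditions (`norm`, `low`, `gal`) x `nReplicates` are placed in 5'UTRs
#' with probability `utr5Enrichment`, the remainder spread over CDS, 3'UTR
#' and lncRNA exons. Sites are placed on the configured target genes, so the
#' CLIP target set recovered downstream coincides with the genes carrying
#' the injected stabilization effect.
#'
#' @param cfg a [SimConfig-class].
#' @param nReplicates CLIP replicates per condition (default 2).
#' @return list with `annotation` (a `GRanges` with `type`, `gene_id`,
#'   `transcript_id`, `biotype`) and `sites` (a width-1 `GRanges` with
#'   `condition`, `replicate`, `score`).
#' @examples
#' sim <- simAnnotationAndSites(simConfig(seed = 1, nGenes = 40,
#'                                        nSitesPerSample = 50))
#' table(sim$sites$condition)
#' @export
simAnnotationAndSites <- function(cfg, nReplicates = 2L) {
    stopifnot(is(cfg, "SimConfig"))
    genes <- geneIds(cfg@nGenes)
    n <- cfg@nGenes

    withStream(cfg@seed, "annotation", {
        biotype <- rep("protein_coding", n)
        if (n >= 10) {
            nLnc <- round(0.12 * n); nOther <- round(0.08 * n)
            extra <- sample(n, nLnc + nOther)
            biotype[extra[seq_len(nLnc)]] <- "lncRNA"
            biotype[extra[nLnc + seq_len(nOther)]] <- "other_ncRNA"
        }
        txLen <- .UTR5_LEN + .CDS_LEN + .UTR3_LEN
        chromIdx <- (seq_len(n) - 1L) %/% .TX_PER_CHROM + 1L
        slot <- (seq_len(n) - 1L) %% .TX_PER_CHROM
        txStart <- slot * (txLen + .TX_GAP) + 1L     # 1-based
        strand <- ifelse(seq_len(n) %% 2L == 1L, "+", "-")
        feats <- list()
        for (i in seq_len(n)) {
            ch <- paste0("chr", chromIdx[i]); s <- txStart[i]
            tx <- paste0(genes[i], ".t1")
            if (biotype[i] == "protein_coding") {
                # genomic order depends on strand: 5'UTR is leftmost on "+"
                lens <- c(five_prime_utr = .UTR5_LEN, CDS = .CDS_LEN,
                          three_prime_utr = .UTR3_LEN)
                if (strand[i] == "-") lens <- rev(lens)
                starts <- s + cumsum(c(0L, unname(lens)[-3L]))
                feats[[i]] <- GenomicRanges::GRanges(
                    ch, IRanges::IRanges(starts, width = unname(lens)),
                    strand = strand[i], type = names(lens),
                    gene_id = genes[i], transcript_id = tx,
                    biotype = biotype[i])
            } else {
                feats[[i]] <- GenomicRanges::GRanges(
                    ch, IRanges::IRanges(s, width = txLen),
                    strand = strand[i], type = "exon",
                    gene_id = genes[i], transcript_id = tx,
                    biotype = biotype[i])
            }
        }
        annotation <- suppressWarnings(do.call(c, feats))
        GenomeInfoDb::seqlevels(annotation) <-
            paste0("chr", sort(unique(chromIdx)))
        validateAnnotation(annotation)

        sites <- withStream(cfg@seed, "sites",
                            .placeSites(cfg, annotation, nReplicates))
        list(annotation = annotation, sites = sites)
    })
}

.placeSites <- function(cfg, annotation, nReplicates) {
    nPer <- cfg@nSitesPerSample
    if (nPer == 0L) {
        emptySites <- GenomicRanges::GRanges(
            seqinfo = GenomeInfoDb::seqinfo(annotation))
        S4Vectors::mcols(emptySites) <- S4Vectors::DataFrame(
            condition = character(0), replicate = integer(0),
            score = numeric(0))
        return(emptySites)
    }
    w5 <- cfg@utr5Enrichment
    # sites live on the designated target genes (that is what makes them
    # CLIP targets downstream); fall back to the whole annotation if the
    # target set lacks 5'UTR features
    onTargets <- annotation[annotation$gene_id %in% cfg@targetGeneIds]
    pool0 <- if (any(onTargets$type == "five_prime_utr")) onTargets
             else annotation
    pools <- list(
        five_prime_utr = pool0[pool0$type == "five_prime_utr"],
        CDS = pool0[pool0$type == "CDS"],
        three_prime_utr = pool0[pool0$type == "three_prime_utr"],
        lncRNA = pool0[pool0$type == "exon" &
                       pool0$biotype == "lncRNA"])
    if (length(pools$five_prime_utr) == 0L)
        stop("annotation has no 5'UTR features to place sites in")
    restWeights <- c(CDS = 0.45, three_prime_utr = 0.25, lncRNA = 0.30)
    restWeights <- restWeights[vapply(pools[names(restWeights)], length,
                                      integer(1)) > 0L]
    restWeights <- restWeights / sum(restWeights)
    out <- list()
    for (cond in .CONDITIONS) {
        for (rep_i in seq_len(nReplicates)) {
            inUtr5 <- runif(nPer) < w5
            compartment <- character(nPer)
            compartment[inUtr5] <- "five_prime_utr"
            if (any(!inUtr5))
                compartment[!inUtr5] <- sample(names(restWeights),
                                               sum(!inUtr5), replace = TRUE,
                                               prob = restWeights)
            pos <- integer(nPer); chrom <- character(nPer)
            str <- character(nPer)
            for (cp in unique(compartment)) {
                idx <- which(compartment == cp)
                pool <- pools[[cp]]
                pick <- sample(length(pool), length(idx), replace = TRUE)
                offs <- floor(runif(length(idx)) *
                              GenomicRanges::width(pool)[pick])
                pos[idx] <- GenomicRanges::start(pool)[pick] + offs
                chrom[idx] <- as.character(
                    GenomicRanges::seqnames(pool))[pick]
                str[idx] <- as.character(GenomicRanges::strand(pool))[pick]
            }
            gr <- GenomicRanges::GRanges(
                chrom, IRanges::IRanges(pos, width = 1L), strand = str,
                condition = cond, replicate = rep_i,
                score = 1 + rpois(nPer, 2),
                seqinfo = GenomeInfoDb::seqinfo(annotation))
            out[[paste(cond, rep_i)]] <- gr
        }
    }
    sort(suppressWarnings(do.call(c, unname(out))), ignore.strand = TRUE)
}

#' Validate a transcript feature annotation
#'
#' Checks that features of one transcript share chromosome and strand and
#' that 5'UTR/CDS/3'UTR intervals within a transcript do not overlap.
#'
#' @param annotation `GRanges` with `type`, `gene_id`, `transcript_id`.
#' @return invisibly `TRUE`; stops on malformed input.
#' @export
validateAnnotation <- function(annotation) {
    if (any(GenomicRanges::strand(annotation) == "*"))
        stop("annotation contains features with unknown strand")
    byTx <- S4Vectors::split(annotation, annotation$transcript_id)
    bad <- vapply(byTx, function(gr) {
        length(unique(as.character(GenomicRanges::seqnames(gr)))) > 1L ||
        length(unique(as.character(GenomicRanges::strand(gr)))) > 1L ||
        sum(GenomicRanges::width(GenomicRanges::reduce(gr))) <
            sum(GenomicRanges::width(gr))
    }, logical(1))
    if (any(bad))
        stop("malformed annotation: overlapping or inconsistent features in ",
             paste(head(names(byTx)[bad], 5), collapse = ", "))
    invisible(TRUE)
}

#' Simulate a gene x sample expression count matrix
#'
#' Negative-binomial counts (shared dispersion) for a two-group design
#' (`control` vs `knockdown`) across the three metabolic conditions, with an
#' optional ribosome-nascent-chain (RNC) fraction alongside the total
#' fraction. Genes in `targetGeneIds` carry a mean log2 shift of
#' `stabilizationLfc` in knockdown samples (both fractions); `teLfc`
#' additionally shifts their RNC counts in knockdown, i.e. a
#' translation-efficiency change. With `noise$expression = FALSE` the exact
#' expected counts are returned.
#'
#' @param cfg a [SimConfig-class].
#' @param fractions `"total"` or `c("total", "RNC")`.
#' @param nReplicates replicates per (group, condition, fraction).
#' @param conditions metabolic conditions to simulate.
#' @return `SummarizedExperiment` with assay `counts` and colData columns
#'   `group`, `condition`, `fraction`, `replicate`.
#' @examples
#' se <- simExpressionCounts(simConfig(seed = 1, nGenes = 100))
#' dim(se)
#' @export
simExpressionCounts <- function(cfg, fractions = "total", nReplicates = 2L,
                                conditions = .CONDITIONS) {
    stopifnot(is(cfg, "SimConfig"))
    if (cfg@nbDispersion <= 0)
        stop("NB dispersion must be positive")
    fractions <- match.arg(fractions, c("total", "RNC"), several.ok = TRUE)
    genes <- geneIds(cfg@nGenes)
    isTarget <- genes %in% cfg@targetGeneIds

    withStream(cfg@seed, "expression", {
        baseMu <- rlnorm(cfg@nGenes, meanlog = log(200), sdlog = 1)
        design <- expand.grid(replicate = seq_len(nReplicates),
                              condition = conditions,
                              group = c("control", "knockdown"),
                              fraction = fractions,
                              stringsAsFactors = FALSE)
        design$sample_id <- sprintf("%s_%s_%s_r%d", design$group,
                                    design$condition, design$fraction,
                                    design$replicate)
        noisy <- isTRUE(cfg@noise$expression)
        size <- 1 / cfg@nbDispersion
        counts <- matrix(0, nrow = cfg@nGenes, ncol = nrow(design),
                         dimnames = list(genes, design$sample_id))
        for (j in seq_len(nrow(design))) {
            mu <- baseMu
            if (design$group[j] == "knockdown") {
                mu[isTarget] <- mu[isTarget] * 2^cfg@stabilizationLfc
                if (design$fraction[j] == "RNC")
                    mu[isTarget] <- mu[isTarget] * 2^cfg@teLfc
            }
            counts[, j] <- if (noisy) rnbinom(cfg@nGenes, mu = mu,
                                              size = size)
                           else mu
        }
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(design,
                                           row.names = design$sample_id),
            rowData = S4Vectors::DataFrame(gene_id = genes,
                                           is_target = isTarget,
                                           row.names = genes))
    })
}

#' Simulate biophysical and kinetic assay inputs
#'
#' Generates the three curve-fitting inputs with known ground truth:
#' a fluorescence-polarization titration from the one-site isotherm
#' (two-fold protein dilution series around the true Kd, Gaussian mP noise),
#' mass-photometry events drawn from the configured Gaussian mixture, and an
#' actinomycin-D decay time course sampled hourly over 0-8 h with
#' multiplicative log-normal noise, normalized to t = 0 per replicate.
#'
#' @param cfg a [SimConfig-class].
#' @param nTitrationReplicates titration replicates (default 3).
#' @param nDecayReplicates decay replicates per condition (default 4).
#' @return list with `titration`, `massEvents`, `decay` data frames.
#' @examples
#' curves <- simAssayCurves(simConfig(seed = 1))
#' head(curves$titration)
#' @export
simAssayCurves <- function(cfg, nTitrationReplicates = 3L,
                           nDecayReplicates = 4L) {
    stopifnot(is(cfg, "SimConfig"))
    bt <- cfg@bindingTruth
    if (is.null(bt$kd_nM) || bt$kd_nM <= 0)
        stop("binding truth kd_nM must be positive")

    titration <- withStream(cfg@seed, "titration", {
        conc <- bt$kd_nM * 2^seq(-5, 5)      # 2-fold dilution series
        sdN <- cfg@noise$titration_sd
        do.call(rbind, lapply(seq_len(nTitrationReplicates), function(r) {
            resp <- bt$r_free + (bt$r_bound - bt$r_free) * conc /
                (bt$kd_nM + conc)
            if (sdN > 0) resp <- resp + rnorm(length(conc), sd = sdN)
            data.frame(protein_conc_nM = conc, response_mP = resp,
                       probe_conc_nM = bt$probe_nM, replicate = r)
        }))
    })

    massEvents <- withStream(cfg@seed, "mass", {
        comp <- cfg@massComponents
        w <- vapply(comp, function(x) x$weight, numeric(1))
        pick <- sample(length(comp), cfg@nMassEvents, replace = TRUE,
                       prob = w)
        mass <- vapply(seq_len(cfg@nMassEvents), function(i) {
            c_i <- comp[[pick[i]]]
            if (c_i$sd_kDa > 0) rnorm(1, c_i$mean_kDa, c_i$sd_kDa)
            else c_i$mean_kDa
        }, numeric(1))
        data.frame(condition = "sim", mass_kDa = mass,
                   component = pick)
    })

    decay <- withStream(cfg@seed, "decay", {
        times <- 0:8
        sdlog <- cfg@noise$decay_sdlog
        rows <- list()
        for (cond in names(cfg@decayHalflivesH)) {
            lambda <- log(2) / cfg@decayHalflivesH[[cond]]
            for (r in seq_len(nDecayReplicates)) {
                ab <- exp(-lambda * times)
                if (sdlog > 0)
                    ab <- ab * rlnorm(length(times), 0, sdlog)
                ab <- ab / ab[1]              # normalize to t = 0
                rows[[paste(cond, r)]] <- data.frame(
                    time_h = times, rel_abundance = ab, condition = cond,
                    replicate = r)
            }
        }
        out <- do.call(rbind, unname(rows))
        rownames(out) <- NULL
        out
    })

    list(titration = titration, massEvents = massEvents, decay = decay)
}
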