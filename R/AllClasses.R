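#' @import methods
#' @importFrom stats aggregate approx coef ecdf lm median na.omit p.adjust
#'   pnorm predict quantile rbinom rlnorm rmultinom rnbinom rnorm rpois
#'   runif sd setNames t.test wilcox.test dnorm kmeans nls resid var
#' @importFrom utils head modifyList packageVersion read.csv read.delim
#'   write.csv write.table
NULL

#' Simulation configuration for the synthetic-data generators
#'
#' A `SimConfig` bundles every ground-truth parameter consumed by the
#' synthetic-data generators: screen library layout and depletion effects,
#' toy-genome/crosslink-site placement, negative-binomial expression with a
#' stabilization effect on a designated target set, and the biophysical assay
#' curves (binding isotherm, mass-photometry mixture, decay time course).
#' All randomness flows from `seed` through named per-generator substreams,
#' so identical configurations give identical outputs stage by stage.
#'
#' @slot seed integer master seed.
#' @slot nGenes number of genes in the screen library / expression matrix.
#' @slot nGuidesPerGene guides per gene (screen library design; default 4).
#' @slot depletedGeneFraction fraction of genes depleted in the AML lineage.
#' @slot screenDepth reads per screen sample.
#' @slot screenFold fold-depletion applied to day-20 abundances of depleted
#'   genes in the depleted lineage.
#' @slot nbDispersion shared negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 selects Poisson noise.
#' @slot targetGeneIds gene identifiers carrying the stabilization effect.
#' @slot stabilizationLfc expected log2 shift of target genes in knockdown
#'   versus control (negative = destabilized on knockdown).
#' @slot teLfc log2 translation-efficiency shift of target genes in knockdown.
#' @slot utr5Enrichment probability that a crosslink site lands in a 5'UTR.
#' @slot nSitesPerSample crosslink sites per condition x replicate track.
#' @slot bindingTruth named list `kd_nM`, `r_free`, `r_bound`, `probe_nM`.
#' @slot massComponents list of `list(mean_kDa, sd_kDa, weight)` components.
#' @slot nMassEvents events per simulated mass-photometry acquisition.
#' @slot decayHalflivesH named numeric, condition -> half-life in hours.
#' @slot noise named list of per-assay noise levels: `screen` (logical,
#'   multinomial resampling on/off), `expression` (logical, NB sampling
#'   on/off), `titration_sd` (mP), `decay_sdlog` (lognormal sigma).
#' @export
setClass("SimConfig", representation(
    seed = "integer",
    nGenes = "integer",
    nGuidesPerGene = "integer",
    depletedGeneFraction = "numeric",
    screenDepth = "numeric",
    screenFold = "numeric",
    nbDispersion = "numeric",
    targetGeneIds = "character",
    stabilizationLfc = "numeric",
    teLfc = "numeric",
    utr5Enrichment = "numeric",
    nSitesPerSample = "integer",
    bindingTruth = "list",
    massComponents = "list",
    nMassEvents = "integer",
    decayHalflivesH = "numeric",
    noise = "list"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "'seed' must be a single non-missing integer")
    if (object@nGenes < 1L) msg <- c(msg, "'nGenes' must be >= 1")
    if (object@nGuidesPerGene < 1L) msg <- c(msg, "'nGuidesPerGene' must be >= 1")
    for (p in c("depletedGeneFraction", "utr5Enrichment")) {
        v <- slot(object, p)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, sprintf("'%s' must lie in [0, 1]", p))
    }
    if (length(object@massComponents)) {
        w <- vapply(object@massComponents, function(x) x$weight, numeric(1))
        if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
            msg <- c(msg, "mass component weights must be >= 0 and sum to 1")
    }
    if (any(object@decayHalflivesH <= 0))
        msg <- c(msg, "decay half-lives must be positive")
    if (length(msg)) msg else TRUE
})

#' Target-set versus background log-fold-change comparison
#'
#' Result of [cdfShiftTest()]: the empirical cumulative distributions of
#' knockdown log2 fold changes for a CLIP target set and a background set,
#' summarized by set medians, the difference of mean LFCs, and a two-sided
#' Wilcoxon rank-sum test.
#'
#' @slot medianTarget,medianBackground per-set median log2 fold change.
#' @slot meanLfcDifference mean(target LFC) - mean(background LFC).
#' @slot rankSumStatistic Mann-Whitney U of the target set.
#' @slot pValue two-sided rank-sum p-value.
#' @slot nTarget,nBackground set sizes.
#' @slot targetLfc,backgroundLfc the LFC values entering each eCDF.
#' @slot exact whether the exact rank-sum null was used.
#' @export
setClass("CdfComparison", representation(
    medianTarget = "numeric", medianBackground = "numeric",
    meanLfcDifference = "numeric", rankSumStatistic = "numeric",
    pValue = "numeric", nTarget = "integer", nBackground = "integer",
    targetLfc = "numeric", backgroundLfc = "numeric", exact = "logical"
))

#' One-site binding isotherm fit
#'
#' @slot kd dissociation constant, nM.
#' @slot responseFree,responseBound free- and bound-probe plateaus (mP or
#'   fraction bound).
#' @slot seKd standard error of the dissociation constant.
#' @slot rSquared coefficient of determination of the fit.
#' @slot model `"hyperbolic"` or `"quadratic"` (ligand depletion).
#' @slot data the fitted concentration/response table with fitted values.
#' @export
setClass("BindingFit", representation(
    kd = "numeric", responseFree = "numeric", responseBound = "numeric",
    seKd = "numeric", rSquared = "numeric", model = "character",
    data = "data.frame"
))

#' Four-parameter logistic competition fit
#'
#' @slot ic50 half-maximal inhibitory concentration (same units as input).
#' @slot maxInhibition 1 - lower plateau / upper plateau.
#' @slot hill Hill slope of the logistic.
#' @slot upper,lower fitted plateaus.
#' @slot rSquared coefficient of determination.
#' @slot noInhibition flag set when the data show no concentration-dependent
#'   decrease (ic50 is then `NA`).
#' @export
setClass("CompetitionFit", representation(
    ic50 = "numeric", maxInhibition = "numeric", hill = "numeric",
    upper = "numeric", lower = "numeric", rSquared = "numeric",
    noInhibition = "logical"
))

#' One-dimensional Gaussian mixture fit of particle masses
#'
#' @slot means,sds,weights component parameters, means ascending.
#' @slot k number of components.
#' @slot logLik maximized log-likelihood.
#' @slot bic Bayesian information criterion of the chosen model.
#' @slot assignment hard component assignment (MAP) per event.
#' @slot nEvents number of events fitted.
#' @export
setClass("MixtureFit", representation(
    means = "numeric", sds = "numeric", weights = "numeric",
    k = "integer", logLik = "numeric", bic = "numeric",
    assignment = "integer", nEvents = "integer"
))

#' Enzyme activity from a kinetic trace and an NADH standard curve
#'
#' @slot activity nmole NADH / min / mL.
#' @slot standardSlope,standardIntercept A450-per-nmole standard curve.
#' @slot kineticSlope A450 per minute in the linear range.
#' @slot sampleVolumeML reaction sample volume.
#' @export
setClass("ActivityResult", representation(
    activity = "numeric", standardSlope = "numeric",
    standardIntercept = "numeric", kineticSlope = "numeric",
    sampleVolumeML = "numeric"
))

#' First-order decay fit of an mRNA stability time course
#'
#' @slot lambda per-hour decay constant (positive for decaying series).
#' @slot halfLife ln(2) / lambda, hours; `Inf` for non-decaying series.
#' @slot seHalfLife delta-method standard error of the half-life.
#' @slot rSquared coefficient of determination on the fitted scale.
#' @slot method `"loglinear"` or `"nonlinear"`.
#' @slot nPoints number of (time, abundance) points fitted.
#' @export
setClass("DecayFit", representation(
    lambda = "numeric", halfLife = "numeric", seHalfLife = "numeric",
    rSquared = "numeric", method = "character", nPoints = "integer"
))

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig | seed", object@seed,
        "|", object@nGenes, "genes x", object@nGuidesPerGene, "guides",
        "|", length(object@targetGeneIds), "stabilization targets",
        sprintf("(lfc %+.2f)\n", object@stabilizationLfc))
})

setMethod("show", "CdfComparison", function(object) {
    cat("CdfComparison:", object@nTarget, "targets vs",
        object@nBackground, "background genes\n")
    cat(sprintf("  median LFC  target %+.4f | background %+.4f\n",
                object@medianTarget, object@medianBackground))
    cat(sprintf("  mean LFC difference %+.4f\n", object@meanLfcDifference))
    cat(sprintf("  rank-sum W = %.1f, p = %.3g (%s)\n",
                object@rankSumStatistic, object@pValue,
                if (object@exact) "exact" else "normal approximation"))
})

setMethod("show", "BindingFit", function(object) {
    cat(sprintf("BindingFit (%s): Kd = %.4g (se %.3g), plateaus %.4g -> %.4g, R2 = %.4f\n",
                object@model, object@kd, object@seKd,
                object@responseFree, object@responseBound, object@rSquared))
})

setMethod("show", "CompetitionFit", function(object) {
    if (object@noInhibition) {
        cat("CompetitionFit: no inhibition detected (ic50 = NA)\n")
    } else {
        cat(sprintf("CompetitionFit: IC50 = %.4g, max inhibition %.1f%%, R2 = %.4f\n",
                    object@ic50, 100 * object@maxInhibition, object@rSquared))
    }
})

setMethod("show", "MixtureFit", function(object) {
    cat(sprintf("MixtureFit: %d component(s), %d events, BIC %.1f\n",
                object@k, object@nEvents, object@bic))
    for (i in seq_len(object@k))
        cat(sprintf("  %2d: mean %8.2f kDa, sd %6.2f, weight %.3f\n",
                    i, object@means[i], object@sds[i], object@weights[i]))
})

setMethod("show", "ActivityResult", function(object) {
    cat(sprintf("ActivityResult: %.4g nmole NADH/min/mL (kinetic %.4g A450/min, standard %.4g A450/nmole)\n",
                object@activity, object@kineticSlope, object@standardSlope))
})

setMethod("show", "DecayFit", function(object) {
    if (is.finite(object@halfLife)) {
        cat(sprintf("DecayFit (%s): lambda = %.4f /h, half-life = %.3f h (se %.3f), R2 = %.4f\n",
                    object@method, object@lambda, object@halfLife,
                    object@seHalfLife, object@rSquared))
    } else {
        cat(sprintf("DecayFit (%s): non-decaying series, half-life = Inf\n",
                    object@method))
    }
})
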