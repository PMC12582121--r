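hyperbolic <- function(conc, kd, rf, rb) rf + (rb - rf) * conc / (kd + conc)

test_that("binding fit recovers noiseless isotherms exactly", {
    conc <- 100 * 2^seq(-5, 5)
    for (kdTrue in c(100, 167, 1309)) {
        resp <- hyperbolic(conc, kdTrue, 50, 250)
        fit <- fitBinding(conc, resp)
        expect_equal(kdEstimate(fit), kdTrue, tolerance = 1e-6)
        expect_equal(fit@responseFree, 50, tolerance = 1e-6)
        expect_equal(fit@responseBound, 250, tolerance = 1e-6)
        expect_gt(fit@rSquared, 1 - 1e-10)
    }
    # isotherm midpoint at [P] = Kd
    fit <- fitBinding(conc, hyperbolic(conc, 100, 50, 250))
    mid <- fit@responseFree +
        (fit@responseBound - fit@responseFree) * 100 / (100 + 100)
    expect_equal(mid, (50 + 250) / 2, tolerance = 1e-9)
})

test_that("binding Kd is invariant to affine response rescaling", {
    conc <- 200 * 2^seq(-4, 4)
    resp <- hyperbolic(conc, 200, 30, 180)
    f1 <- fitBinding(conc, resp)
    f2 <- fitBinding(conc, 3 * resp + 40)
    expect_equal(kdEstimate(f1), kdEstimate(f2), tolerance = 1e-6)
    expect_equal(f2@responseFree, 3 * f1@responseFree + 40,
                 tolerance = 1e-4)
})

test_that("quadratic and hyperbolic models agree in the probe << Kd regime", {
    # 2 nM probe vs ~200 nM Kd: ligand depletion is negligible
    conc <- 200 * 2^seq(-4, 4)
    L <- 2; kdTrue <- 200
    fb <- ((conc + L + kdTrue) -
           sqrt((conc + L + kdTrue)^2 - 4 * conc * L)) / (2 * L)
    resp <- 50 + 200 * fb
    fH <- fitBinding(conc, resp, model = "hyperbolic")
    fQ <- fitBinding(conc, resp, model = "quadratic", probeConc = L)
    expect_equal(kdEstimate(fQ), kdTrue, tolerance = 1e-6)
    expect_lt(abs(kdEstimate(fH) - kdEstimate(fQ)) / kdEstimate(fQ), 0.01)
})

test_that("flat titrations and bad inputs are rejected", {
    conc <- 10 * 2^(0:8)
    expect_error(fitBinding(conc, rep(100, 9), noiseFloor = 1),
                 "no binding signal")
    expect_error(fitBinding(conc[1:4], rnorm(4)), ">= 5")
    expect_error(fitBinding(-conc, rnorm(9)), "positive")
})

test_that("competition fit recovers a noiseless 4PL and flags flat data", {
    conc <- 10 * 2^seq(-6, 6)
    r <- 60 + (260 - 60) / (1 + (conc / 10)^1)
    fit <- fitCompetition(conc, r)
    expect_false(fit@noInhibition)
    expect_equal(fit@ic50, 10, tolerance = 1e-6)
    expect_equal(fit@maxInhibition, 1 - 60 / 260, tolerance = 1e-6)
    # lower plateau at 70% of baseline: max inhibition 0.30
    r2 <- 70 + (100 - 70) / (1 + (conc / 10)^1.5)
    fit2 <- fitCompetition(conc, r2)
    expect_equal(fit2@maxInhibition, 0.30, tolerance = 1e-6)
    # flat -> no inhibition
    flat <- fitCompetition(conc, rep(150, length(conc)), noiseFloor = 1)
    expect_true(flat@noInhibition)
    expect_true(is.na(flat@ic50))
    expect_equal(flat@maxInhibition, 0)
    # monotonically increasing -> no inhibition
    up <- fitCompetition(conc, seq(100, 200, length.out = length(conc)))
    expect_true(up@noInhibition)
})

test_that("mass calibration is an exact line through the standards", {
    # BSA and thyroglobulin standards on an exact line
    std <- data.frame(contrast = c(0.005, 0.05), mass = c(66.5, 660))
    cal <- calibrateMasses(std$contrast, std$mass,
                           contrasts = c(0.005, 0.0275, 0.05))
    expect_equal(cal$r_squared, 1)
    expect_equal(cal$masses_kDa[1], 66.5, tolerance = 1e-9)
    expect_equal(cal$masses_kDa[3], 660, tolerance = 1e-9)
    # midway contrast maps to midway mass
    expect_equal(cal$masses_kDa[2], (66.5 + 660) / 2, tolerance = 1e-9)
    # empty contrasts give empty masses
    expect_length(calibrateMasses(std$contrast, std$mass,
                                  numeric(0))$masses_kDa, 0L)
    expect_error(calibrateMasses(0.005, 66.5, 0.01), ">= 2")
    expect_error(calibrateMasses(c(0.005, 0.005), c(66.5, 660), 0.01),
                 "distinct")
    # three collinear standards: residuals equal OLS residuals (zero)
    cal3 <- calibrateMasses(c(1, 2, 3), c(10, 20, 30), c(1.5))
    expect_equal(cal3$masses_kDa, 15)
})

test_that("mixture EM recovers single and well-separated components", {
    cfg <- simConfig(seed = 41,
                     massComponents = list(list(mean_kDa = 150, sd_kDa = 8,
                                                weight = 1)),
                     nMassEvents = 5000L)
    ev <- simAssayCurves(cfg)$massEvents$mass_kDa
    fit1 <- fitMassMixture(ev, k = 1, seed = 1)
    expect_lt(abs(fit1@means - 150), 3 * 8 / sqrt(5000) + 0.2)
    # two components at the monomer / tetramer masses
    cfg2 <- simConfig(seed = 43,
                      massComponents = list(
                          list(mean_kDa = 37.5, sd_kDa = 4, weight = 0.4),
                          list(mean_kDa = 150, sd_kDa = 8, weight = 0.6)),
                      nMassEvents = 4000L)
    ev2 <- simAssayCurves(cfg2)$massEvents$mass_kDa
    fit2 <- fitMassMixture(ev2, k = 2, seed = 1)
    expect_equal(fit2@means, c(37.5, 150), tolerance = 0.02)
    expect_equal(fit2@weights, c(0.4, 0.6), tolerance = 0.05)
    expect_true(all(diff(fit2@means) > 0))
    expect_equal(sum(fit2@weights), 1, tolerance = 1e-9)
})

test_that("mixture fitting is reproducible and BIC picks a sane k", {
    cfg <- simConfig(seed = 47,
                     massComponents = list(
                         list(mean_kDa = 38.5, sd_kDa = 5, weight = 0.5),
                         list(mean_kDa = 148.3, sd_kDa = 6, weight = 0.5)),
                     nMassEvents = 2000L)
    ev <- simAssayCurves(cfg)$massEvents$mass_kDa
    f1 <- fitMassMixture(ev, k = 2, seed = 9)
    f2 <- fitMassMixture(ev, k = 2, seed = 9)
    expect_identical(f1@means, f2@means)
    auto <- fitMassMixture(ev, k = "auto", seed = 9)
    expect_equal(auto@k, 2L)
    expect_error(fitMassMixture(ev[1:50], k = 1), ">= 100")
    expect_error(fitMassMixture(rep(c(1, 2), 100), k = 3), "distinct")
})

test_that("mixture EM agrees with an independent mixture implementation", {
    skip_if_not_installed("mclust")
    suppressPackageStartupMessages(library(mclust))
    cfg <- simConfig(seed = 53,
                     massComponents = list(
                         list(mean_kDa = 40, sd_kDa = 5, weight = 0.3),
                         list(mean_kDa = 150, sd_kDa = 7, weight = 0.7)),
                     nMassEvents = 3000L)
    ev <- simAssayCurves(cfg)$massEvents$mass_kDa
    ours <- fitMassMixture(ev, k = 2, seed = 1)
    ref <- mclust::Mclust(ev, G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(sort(ours@means), sort(as.numeric(ref$parameters$mean)),
                 tolerance = 0.01)
    expect_equal(ours@logLik, ref$loglik, tolerance = 1e-4)
})

test_that("mass shift matches components by nearest mean", {
    cfgA <- simConfig(seed = 59,
                      massComponents = list(
                          list(mean_kDa = 38.5, sd_kDa = 5, weight = 0.4),
                          list(mean_kDa = 148.3, sd_kDa = 6, weight = 0.6)),
                      nMassEvents = 4000L)
    cfgB <- simConfig(seed = 61,
                      massComponents = list(
                          list(mean_kDa = 38.5, sd_kDa = 5, weight = 0.4),
                          list(mean_kDa = 165.3, sd_kDa = 6, weight = 0.6)),
                      nMassEvents = 4000L)
    fitA <- fitMassMixture(simAssayCurves(cfgA)$massEvents$mass_kDa,
                           k = 2, seed = 1)
    fitB <- fitMassMixture(simAssayCurves(cfgB)$massEvents$mass_kDa,
                           k = 2, seed = 1)
    # tetramer component selected by reference mass
    shift <- massShift(fitA, fitB, component = 148.3)
    expect_equal(shift, 17, tolerance = 0.5)
    # identical event lists shift by zero
    expect_equal(massShift(fitA, fitA, component = 2L), 0)
})

test_that("enzyme activity follows the standard-curve arithmetic", {
    # slope 0.02 A450/min over 0.1 A450/nmole in 0.1 mL -> 2 nmole/min/mL
    act <- enzymeActivity(0:10, 0.02 * (0:10), c(0, 5, 10),
                          c(0, 0.5, 1.0), 0.1)
    expect_equal(act@activity, 2)
    # zero kinetic slope -> zero activity
    act0 <- enzymeActivity(0:5, rep(0.3, 6), c(0, 5, 10), c(0, 0.5, 1.0),
                           0.1)
    expect_equal(act0@activity, 0)
    # doubling the kinetic increments doubles activity
    act2 <- enzymeActivity(0:10, 0.04 * (0:10), c(0, 5, 10),
                           c(0, 0.5, 1.0), 0.1)
    expect_equal(act2@activity, 2 * act@activity)
    expect_error(enzymeActivity(0:5, 0.02 * (0:5), c(0, 5, 10),
                                c(0.2, 0.2, 0.2), 0.1), "zero slope")
    expect_error(enzymeActivity(0:1, c(0, 1), c(0, 5, 10),
                                c(0, 0.5, 1), 0.1), "kinetic")
})
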