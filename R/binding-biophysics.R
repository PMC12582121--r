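#' Fit a one-site binding isotherm
#'
#' Least-squares fit of a titration (response vs protein concentration) to a
#' one-site binding model. The default `hyperbolic` model,
#' `r(P) = r_free + (r_bound - r_free) * P / (Kd + P)`, assumes the labelled
#' probe is present at a concentration far below Kd. The `quadratic` model
#' accounts for probe depletion using the probe concentration `L`:
#' fraction bound `= ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / (2 L)`.
#' Kd is constrained positive; its standard error comes from the fit
#' covariance.
#'
#' @param concentration protein concentrations, strictly increasing (nM).
#' @param response measured responses (mP or fraction bound), one per
#'   concentration (replicate tables can be stacked; rows need not be
#'   unique).
#' @param model `"hyperbolic"` (default) or `"quadratic"`.
#' @param probeConc probe concentration (nM), required for the quadratic
#'   model.
#' @param noiseFloor smallest response range treated as signal; a flatter
#'   curve raises a "no binding signal" error (default 1e-8, i.e. off).
#' @return a [BindingFit-class].
#' @examples
#' conc <- 100 * 2^seq(-4, 4)
#' resp <- 50 + 200 * conc / (100 + conc)
#' kdEstimate(fitBinding(conc, resp))   # 100
#' @export
fitBinding <- function(concentration, response,
                       model = c("hyperbolic", "quadratic"),
                       probeConc = NULL, noiseFloor = 1e-8) {
    model <- match.arg(model)
    stopifnot(length(concentration) == length(response))
    if (any(concentration <= 0)) stop("concentrations must be positive")
    if (length(unique(concentration)) < 5L)
        stop("need >= 5 distinct concentrations spanning the transition")
    rng <- diff(range(response))
    if (rng < noiseFloor)
        stop("no binding signal: response range ", signif(rng, 3),
             " below noise floor")
    d <- data.frame(conc = concentration, resp = response)
    rfStart <- min(response); rbStart <- max(response)
    kdStart <- approx(response, concentration,
                      xout = (rfStart + rbStart) / 2, ties = mean)$y
    if (is.na(kdStart) || kdStart <= 0) kdStart <- median(concentration)
    fit <- if (model == "hyperbolic") {
        minpack.lm::nlsLM(
            resp ~ rf + (rb - rf) * conc / (kd + conc), data = d,
            start = list(rf = rfStart, rb = rbStart, kd = kdStart),
            lower = c(rf = -Inf, rb = -Inf, kd = 1e-12),
            control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
        if (is.null(probeConc) || probeConc <= 0)
            stop("quadratic model requires a positive 'probeConc'")
        L <- probeConc
        minpack.lm::nlsLM(
            resp ~ rf + (rb - rf) *
                ((conc + L + kd) - sqrt((conc + L + kd)^2 -
                                        4 * conc * L)) / (2 * L),
            data = d,
            start = list(rf = rfStart, rb = rbStart, kd = kdStart),
            lower = c(rf = -Inf, rb = -Inf, kd = 1e-12),
            control = minpack.lm::nls.lm.control(maxiter = 500))
    }
    est <- coef(fit)
    se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                   error = function(e) NA_real_)
    d$fitted <- predict(fit)
    ssRes <- sum((d$resp - d$fitted)^2)
    ssTot <- sum((d$resp - mean(d$resp))^2)
    new("BindingFit", kd = unname(est["kd"]),
        responseFree = unname(est["rf"]), responseBound = unname(est["rb"]),
        seKd = unname(se),
        rSquared = if (ssTot > 0) 1 - ssRes / ssTot else 1,
        model = model, data = d)
}

#' Fit a competition (inhibition) curve
#'
#' Four-parameter logistic fit of response versus inhibitor concentration on
#' a log scale:
#' `r(c) = lower + (upper - lower) / (1 + (c / ic50)^h)`.
#' Maximum inhibition is `1 - lower / upper`. Data with no
#' concentration-dependent decrease (flat, or monotonically increasing)
#' return `ic50 = NA` with the `noInhibition` flag set.
#'
#' @param inhibitorConc inhibitor concentrations (any consistent unit).
#' @param response responses (mP), one per concentration.
#' @param noiseFloor response range below which the curve is called flat.
#' @return a [CompetitionFit-class].
#' @export
fitCompetition <- function(inhibitorConc, response, noiseFloor = 1e-8) {
    stopifnot(length(inhibitorConc) == length(response))
    if (length(unique(inhibitorConc)) < 5L)
        stop("need >= 5 distinct inhibitor concentrations")
    if (any(inhibitorConc <= 0))
        stop("inhibitor concentrations must be positive for the log-scale fit")
    rng <- diff(range(response))
    slope <- coef(lm(response ~ log(inhibitorConc)))[2L]
    if (rng < noiseFloor || slope >= 0) {
        return(new("CompetitionFit", ic50 = NA_real_, maxInhibition = 0,
                   hill = NA_real_, upper = max(response),
                   lower = min(response), rSquared = NA_real_,
                   noInhibition = TRUE))
    }
    d <- data.frame(conc = inhibitorConc, resp = response)
    fit <- minpack.lm::nlsLM(
        resp ~ lower + (upper - lower) / (1 + (conc / ic50)^h), data = d,
        start = list(lower = min(response), upper = max(response),
                     ic50 = exp(mean(log(range(inhibitorConc)))), h = 1),
        lower = c(lower = -Inf, upper = -Inf, ic50 = 1e-12, h = 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- coef(fit)
    ssRes <- sum(resid(fit)^2)
    ssTot <- sum((d$resp - mean(d$resp))^2)
    new("CompetitionFit", ic50 = unname(est["ic50"]),
        maxInhibition = unname(1 - est["lower"] / est["upper"]),
        hill = unname(est["h"]), upper = unname(est["upper"]),
        lower = unname(est["lower"]),
        rSquared = if (ssTot > 0) 1 - ssRes / ssTot else 1,
        noInhibition = FALSE)
}

#' Calibrate mass-photometry contrasts to molecular mass
#'
#' Ordinary least-squares line through the calibration standards (measured
#' interferometric contrast versus known mass, e.g. bovine serum albumin
#' 66.5 kDa and thyroglobulin 660 kDa) applied to event contrasts.
#'
#' @param standardContrast,standardMassKDa calibration standards (>= 2, with
#'   distinct contrasts and masses).
#' @param contrasts event contrasts to convert (may be empty).
#' @return list with `masses_kDa`, `slope`, `intercept`, `r_squared`.
#' @export
calibrateMasses <- function(standardContrast, standardMassKDa, contrasts) {
    stopifnot(length(standardContrast) == length(standardMassKDa))
    if (length(standardContrast) < 2L)
        stop("need >= 2 calibration standards")
    if (length(unique(standardContrast)) < 2L ||
        length(unique(standardMassKDa)) < 2L)
        stop("calibration standards must have distinct contrasts and masses")
    fit <- lm(standardMassKDa ~ standardContrast)
    # collinear standards are a legitimate (noise-free) calibration
    r2 <- if (length(standardContrast) == 2L) 1
          else suppressWarnings(summary(fit))$r.squared
    co <- coef(fit)
    list(masses_kDa = unname(co[1L] + co[2L] * contrasts),
         slope = unname(co[2L]), intercept = unname(co[1L]),
         r_squared = r2)
}

#' Fit a one-dimensional Gaussian mixture to particle masses
#'
#' Expectation-maximization fit of a k-component Gaussian mixture to a mass
#' event list, the standard reduction of a mass-photometry histogram into
#' oligomeric species. Initialization is k-means++ from the caller's seed,
#' so the fit is reproducible bit for bit; components are returned with
#' means ascending. With `k = "auto"` the component count is chosen by BIC
#' over k in 1..4. Convergence: relative log-likelihood change below `tol`
#' or `maxIter` iterations.
#'
#' @param masses numeric vector of event masses (kDa); >= 100 events.
#' @param k integer number of components, or `"auto"`.
#' @param seed integer seed for the k-means++ initialization.
#' @param tol,maxIter EM convergence controls.
#' @return a [MixtureFit-class].
#' @examples
#' m <- c(rnorm(500, 38.5, 4), rnorm(500, 148.3, 6))
#' fitMassMixture(m, k = 2, seed = 1)
#' @export
fitMassMixture <- function(masses, k = "auto", seed = 1L, tol = 1e-8,
                           maxIter = 500L) {
    masses <- as.numeric(masses)
    if (length(masses) < 100L)
        stop("need >= 100 events for mixture fitting")
    if (identical(k, "auto")) {
        fits <- lapply(1:4, function(kk)
            tryCatch(fitMassMixture(masses, k = kk, seed = seed, tol = tol,
                                    maxIter = maxIter),
                     error = function(e) NULL))
        fits <- Filter(Negate(is.null), fits)
        if (!length(fits)) stop("no mixture model could be fitted")
        return(fits[[which.min(vapply(fits, function(f) f@bic,
                                      numeric(1)))]])
    }
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (k > length(unique(masses)))
        stop("k exceeds the number of distinct mass values")
    n <- length(masses)

    mu <- withStream(as.integer(seed), "mass", .kmeansPlusPlus(masses, k))
    sdAll <- sd(masses); if (sdAll == 0) sdAll <- 1e-6
    sig <- rep(max(sdAll / k, 1e-6), k)
    w <- rep(1 / k, k)
    llOld <- -Inf
    for (iter in seq_len(maxIter)) {
        dens <- vapply(seq_len(k),
                       function(j) w[j] * dnorm(masses, mu[j], sig[j]),
                       numeric(n))
        rowTot <- rowSums(dens)
        rowTot[rowTot == 0] <- .Machine$double.xmin
        resp <- dens / rowTot
        ll <- sum(log(rowTot))
        nk <- colSums(resp)
        w <- nk / n
        mu <- colSums(resp * masses) / nk
        sig <- sqrt(colSums(resp * (outer(masses, mu, "-")^2)) / nk)
        sig <- pmax(sig, 1e-6)
        if (is.finite(llOld) && abs(ll - llOld) <=
            tol * max(1, abs(llOld))) break
        llOld <- ll
    }
    ord <- order(mu)
    mu <- mu[ord]; sig <- sig[ord]; w <- w[ord]
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(masses, mu[j], sig[j]),
                   numeric(n))
    assignment <- max.col(dens, ties.method = "first")
    nPar <- 3L * k - 1L
    new("MixtureFit", means = mu, sds = sig, weights = w, k = k,
        logLik = ll, bic = -2 * ll + nPar * log(n),
        assignment = as.integer(assignment), nEvents = as.integer(n))
}

# k-means++ seeding followed by Lloyd iterations on 1-D data; called inside
# a managed RNG stream.
.kmeansPlusPlus <- function(x, k) {
    centers <- numeric(k)
    centers[1L] <- x[sample.int(length(x), 1L)]
    if (k > 1L) for (j in 2:k) {
        d2 <- vapply(x, function(v)
            min((v - centers[seq_len(j - 1L)])^2), numeric(1))
        if (sum(d2) == 0) {
            centers[j] <- x[sample.int(length(x), 1L)]
        } else {
            centers[j] <- x[sample.int(length(x), 1L, prob = d2)]
        }
    }
    if (length(unique(centers)) < k)
        centers <- centers + seq_len(k) * 1e-9
    km <- suppressWarnings(kmeans(x, centers = matrix(centers, ncol = 1L),
                                  iter.max = 100L))
    sort(as.numeric(km$centers))
}

#' Mass shift between matched mixture components
#'
#' Difference of component means between two mixture fits, matching by
#' nearest mean. `component` selects the component of `fitA` either by
#' index or by the mass (kDa) nearest to a reference value, e.g. the
#' tetramer mass.
#'
#' @param fitA,fitB [MixtureFit-class] objects (A = reference condition).
#' @param component integer index into `fitA`'s components, or a numeric
#'   reference mass used to pick the nearest component.
#' @return mass shift in kDa (`fitB` minus `fitA` for the matched
#'   component).
#' @export
massShift <- function(fitA, fitB, component = 1L) {
    stopifnot(is(fitA, "MixtureFit"), is(fitB, "MixtureFit"))
    idxA <- if (is.numeric(component) && component > fitA@k)
        which.min(abs(fitA@means - component))
    else as.integer(component)
    if (idxA < 1L || idxA > fitA@k) stop("component out of range")
    mA <- fitA@means[idxA]
    idxB <- which.min(abs(fitB@means - mA))
    fitB@means[idxB] - mA
}

#' Enzyme activity from a kinetic trace and NADH standard curve
#'
#' Fits the kinetic absorbance trace (A450 vs time) and the NADH standard
#' curve (A450 vs nmole) by least squares, then reports
#' `activity = kinetic slope / standard slope / sample volume` in
#' nmole NADH per minute per mL.
#'
#' @param kineticTimeMin,kineticA450 kinetic readout (>= 3 points in the
#'   linear range).
#' @param standardNmole,standardA450 NADH standards (>= 3 points).
#' @param sampleVolumeML reaction sample volume in mL.
#' @return an [ActivityResult-class].
#' @examples
#' enzymeActivity(0:5, 0.02 * (0:5), c(0, 5, 10), c(0, 0.5, 1.0), 0.1)
#' @export
enzymeActivity <- function(kineticTimeMin, kineticA450, standardNmole,
                           standardA450, sampleVolumeML) {
    if (length(kineticTimeMin) < 3L)
        stop("need >= 3 kinetic points")
    if (length(standardNmole) < 3L)
        stop("need >= 3 NADH standards")
    .assertScalarNumeric(sampleVolumeML, "sampleVolumeML", positive = TRUE)
    kin <- coef(lm(kineticA450 ~ kineticTimeMin))[2L]
    std <- coef(lm(standardA450 ~ standardNmole))[2L]
    if (abs(std) < .Machine$double.eps)
        stop("NADH standard curve has zero slope")
    new("ActivityResult",
        activity = unname(kin / std / sampleVolumeML),
        standardSlope = unname(std),
        standardIntercept = unname(coef(lm(standardA450 ~
                                           standardNmole))[1L]),
        kineticSlope = unname(kin), sampleVolumeML = sampleVolumeML)
}
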