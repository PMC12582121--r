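#' Dissociation constant of a binding fit
#' @param object a [BindingFit-class].
#' @return the fitted Kd in the concentration units of the input.
#' @export
setGeneric("kdEstimate", function(object) standardGeneric("kdEstimate"))

#' @rdname kdEstimate
#' @export
setMethod("kdEstimate", "BindingFit", function(object) object@kd)

#' Half-life of a decay fit
#' @param object a [DecayFit-class].
#' @return half-life in the time units of the input (`Inf` if non-decaying).
#' @export
setGeneric("halfLife", function(object) standardGeneric("halfLife"))

#' @rdname halfLife
#' @export
setMethod("halfLife", "DecayFit", function(object) object@halfLife)

#' Component table of a mass-mixture fit
#' @param object a [MixtureFit-class].
#' @return `data.frame` with `mean_kDa`, `sd_kDa`, `weight`, means ascending.
#' @export
setGeneric("mixtureComponents",
           function(object) standardGeneric("mixtureComponents"))

#' @rdname mixtureComponents
#' @export
setMethod("mixtureComponents", "MixtureFit", function(object) {
    data.frame(mean_kDa = object@means, sd_kDa = object@sds,
               weight = object@weights)
})

#' Empirical CDF curves of a target/background comparison
#' @param object a [CdfComparison-class].
#' @return `data.frame` with columns `set`, `lfc`, `ecdf` (right-continuous
#'   step evaluated at each observed value).
#' @export
setGeneric("ecdfCurves", function(object) standardGeneric("ecdfCurves"))

#' @rdname ecdfCurves
#' @export
setMethod("ecdfCurves", "CdfComparison", function(object) {
    curve1 <- function(x, label) {
        x <- sort(x)
        data.frame(set = label, lfc = x, ecdf = seq_along(x) / length(x))
    }
    rbind(curve1(object@targetLfc, "target"),
          curve1(object@backgroundLfc, "background"))
})

#' Summary statistics of a CdfComparison
#' @param object a [CdfComparison-class].
#' @return named list: medians, mean LFC difference, rank-sum statistic,
#'   p-value and set sizes.
#' @export
setGeneric("comparisonStats",
           function(object) standardGeneric("comparisonStats"))

#' @rdname comparisonStats
#' @export
setMethod("comparisonStats", "CdfComparison", function(object) {
    list(median_target_lfc = object@medianTarget,
         median_background_lfc = object@medianBackground,
         mean_lfc_difference = object@meanLfcDifference,
         rank_sum_statistic = object@rankSumStatistic,
         p = object@pValue,
         n_target = object@nTarget,
         n_background = object@nBackground)
})
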