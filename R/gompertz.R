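#' Gompertz production parameters
#'
#' Parameters of the modified (Zwietering) Gompertz curve used to model
#' pulcherrimin accumulation (absorbance at 410 nm) over time:
#' \deqn{y(t) = y_0 + (K - y_0)\exp\{-\exp[\mu_{max} e (\lambda - t)/(K - y_0) + 1]\}}
#' so that `mumax` is the maximum slope (absorbance/h), `lambda` the lag time
#' (h), `K` the plateau (carrying capacity) and `y0` the baseline.
#'
#' @param y0 baseline absorbance.
#' @param K plateau absorbance; must exceed `y0`.
#' @param mumax maximum production rate (absorbance/hour); > 0.
#' @param lambda lag time (hours); may be negative for production that is
#'   already under way at the first sample.
#' @return an object of class `gompertz_params`.
#' @export
gompertz_params <- function(y0, K, mumax, lambda) {
  pk_assert(is.finite(y0) && is.finite(K) && is.finite(mumax) &&
              is.finite(lambda), "parameters must be finite")
  pk_assert(K > y0, "K must exceed y0")
  pk_assert(mumax > 0, "mumax must be positive")
  structure(list(y0 = y0, K = K, mumax = mumax, lambda = lambda),
            class = "gompertz_params")
}

#' Evaluate the modified Gompertz curve
#'
#' @param params a [gompertz_params()].
#' @param t time(s) in hours.
#' @return absorbance value(s); tends to `y0` as t -> -Inf and to `K` as
#'   t -> +Inf, with maximum slope `mumax` at the inflection.
#' @export
gompertz_value <- function(params, t) {
  A <- params$K - params$y0
  params$y0 + A * exp(-exp(params$mumax * exp(1) * (params$lambda - t) / A + 1))
}

#' Production duration from the inflection-tangent construction
#'
#' The duration of production is the time the tangent at the inflection point
#' (slope `mumax`) takes to climb from the baseline `y0` to the plateau `K`;
#' for the modified Gompertz form this is exactly `(K - y0)/mumax`.
#'
#' @param params a [gompertz_params()].
#' @return duration in hours (> 0).
#' @export
production_duration <- function(params) {
  (params$K - params$y0) / params$mumax
}
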