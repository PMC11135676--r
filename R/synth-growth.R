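## Seeded generators for growth and production time courses.

#' Derive a child RNG seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed from one master
#' seed through a fixed per-call offset, keeping runs reproducible while
#' decorrelating the stages.  The result stays inside the 32-bit integer
#' range.
#'
#' @param master master seed (integer).
#' @param offset fixed stage/call offset (integer).
#' @return derived integer seed.
#' @export
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1009 + as.numeric(offset)) %% 2147483629)
}

logistic_od <- function(od_params, t) {
  with(od_params,
       odmax / (1 + ((odmax - od0) / od0) * exp(-growth_rate * t)))
}

#' Generate a synthetic OD600 growth curve
#'
#' Logistic growth trajectory with additive Gaussian noise, truncated below
#' at a small positive floor.  Deterministic for a fixed seed.
#'
#' @param preset a [genotype_preset()].
#' @param times sampling times (hours), strictly increasing.
#' @param noise_sd additive noise SD (OD units, >= 0).
#' @param seed integer RNG seed.
#' @param replicate replicate label (default "r1").
#' @param floor lower truncation for noisy OD values (default 1e-4).
#' @return a [growth_curve()].
#' @export
generate_growth_curve <- function(preset, times, noise_sd, seed,
                                  replicate = "r1", floor = 1e-4) {
  pk_assert(length(times) > 0, "empty time vector")
  pk_assert(all(diff(times) > 0), "times must be strictly increasing")
  pk_assert(noise_sd >= 0, "noise_sd must be non-negative")
  od <- logistic_od(preset$od_params, times)
  if (noise_sd > 0) {
    set.seed(seed)
    od <- od + stats::rnorm(length(times), 0, noise_sd)
  }
  growth_curve(preset$name, replicate, times, pmax(od, floor))
}

#' Generate a synthetic A410 production curve
#'
#' Baseline-anchored modified Gompertz accumulation plus additive Gaussian
#' noise (values truncated at 0).  Deterministic for a fixed seed.
#'
#' @inheritParams generate_growth_curve
#' @param noise_sd additive noise SD (absorbance units, >= 0).
#' @return a [production_curve()].
#' @export
generate_production_curve <- function(preset, times, noise_sd, seed,
                                      replicate = "r1") {
  pk_assert(length(times) > 0, "empty time vector")
  pk_assert(all(diff(times) > 0), "times must be strictly increasing")
  pk_assert(noise_sd >= 0, "noise_sd must be non-negative")
  y <- gompertz_value(preset$prod_params, times)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(times), 0, noise_sd)
  }
  production_curve(preset$name, replicate, times, pmax(y, 0))
}
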