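times <- seq(0, 30, by = 0.5)

test_that("noiseless Gompertz curves are recovered to 1e-3 relative", {
  pre <- genotype_preset("x", 0.01, 2, 0.4,
                         gompertz_params(0.01, 0.10, 0.02, 2))
  pc <- generate_production_curve(pre, times, 0, seed = 1)
  f <- fit_gompertz(pc)
  expect_true(f$converged)
  truth <- c(0.01, 0.10, 0.02, 2)
  est <- c(f$y0, f$K, f$mumax, f$lambda)
  expect_lt(max(abs(est - truth) / abs(truth)), 1e-3)
})

test_that("parameter recovery holds over random parameter sets", {
  set.seed(11)
  for (i in 1:50) {
    y0 <- runif(1, 0, 0.05)
    K <- y0 + runif(1, 0.08, 0.9)
    mumax <- runif(1, 0.01, 0.12)
    lambda <- runif(1, 0, 12)
    pre <- genotype_preset("r", 0.01, 2, 0.4,
                           gompertz_params(y0, K, mumax, lambda))
    f <- fit_gompertz(generate_production_curve(pre, times, 0, seed = i))
    expect_true(f$converged)
    rel <- abs(c(f$y0, f$K, f$mumax, f$lambda) -
                 c(y0, K, mumax, lambda)) /
      pmax(abs(c(y0, K, mumax, lambda)), 1e-3)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("degenerate inputs are refused, short inputs rejected", {
  flat <- production_curve("f", "r1", times, rep(0.01, length(times)))
  expect_error(fit_gompertz(flat), class = "degenerate_fit")
  short <- production_curve("s", "r1", 1:5, c(0, 0.01, 0.05, 0.09, 0.1))
  expect_error(fit_gompertz(short), class = "invalid_input")
})

test_that("production start time follows the exhaustive-scan rule", {
  ref <- gompertz_params(0.01, 0.011, 1e-4, 100)     # essentially flat
  mut <- gompertz_params(0.01, 0.2, 0.05, 4)
  t0 <- 6
  got <- production_start_time(mut, ref, t0 = t0, delta = 0.005,
                               grid_step = 0.1)
  want <- oracle_start_time(mut, ref, t0 = t0, delta = 0.005,
                            grid_step = 0.02)
  expect_lte(abs(got - want), 0.1)
  # identical curves never deviate
  expect_true(is.na(production_start_time(mut, mut, t0 = t0, delta = 0.005)))
  # monotone: larger delta never yields an earlier start
  deltas <- c(0.002, 0.005, 0.01, 0.05, 0.1)
  starts <- vapply(deltas, function(d)
    production_start_time(mut, ref, t0 = t0, delta = d), numeric(1))
  expect_true(all(diff(starts[!is.na(starts)]) >= 0))
})

test_that("strain summaries aggregate replicates correctly", {
  pre <- genotype_presets()$scoC
  fits <- lapply(1:3, function(r)
    fit_gompertz(generate_production_curve(pre, times, 0.003, seed = r,
                                           replicate = paste0("r", r))))
  t0s <- lapply(1:3, function(r)
    structure(list(strain = "scoC", replicate = paste0("r", r), t0 = 6.5),
              class = "transition_estimate"))
  s <- summarize_strain(fits, t0s)
  expect_equal(s$replicate_n, 3)
  k <- vapply(fits, `[[`, numeric(1), "K")
  expect_equal(s$stats$mean[s$stats$parameter == "max_a410"], mean(k))
  expect_equal(s$stats$sd[s$stats$parameter == "max_a410"], sd(k))
  expect_equal(s$stats$mean[s$stats$parameter == "duration"],
               mean(vapply(fits, production_duration, numeric(1))))
  # single replicate: SD reported as 0 with n = 1
  s1 <- summarize_strain(fits[1], t0s[1])
  expect_equal(s1$stats$sd, rep(0, 4))
  expect_equal(s1$stats$n, rep(1, 4))
  # mixed strains rejected
  bad <- fits
  bad[[2]]$strain <- "other"
  expect_error(summarize_strain(bad, t0s), class = "invalid_input")
})

test_that("pairwise comparisons are Welch t-tests with Bonferroni correction", {
  mk <- function(strain, vals) {
    structure(list(strain = strain, replicate_n = length(vals),
                   replicates = data.frame(replicate = seq_along(vals),
                                           start_time = vals,
                                           duration = vals,
                                           max_rate = vals,
                                           max_a410 = vals)),
              class = "kinetic_summary")
  }
  a <- c(0.10, 0.12, 0.11); b <- c(0.30, 0.28, 0.33); c3 <- c(0.11, 0.13, 0.10)
  tab <- compare_parameters(list(mk("a", a), mk("b", b), mk("c", c3)),
                            "max_a410")
  expect_equal(nrow(tab), 3)
  # adjusted p = min(1, raw * number of pairs), always >= raw and <= 1
  expect_equal(tab$adj_p, pmin(1, tab$raw_p * 3))
  expect_true(all(tab$adj_p >= tab$raw_p & tab$adj_p <= 1))
  # hand-computed Welch t-test for the a-b pair
  ref <- stats::t.test(a, b)$p.value
  expect_equal(tab$raw_p[tab$strain_a == "a" & tab$strain_b == "b"], ref)
  # identical replicate values: handled as non-significant
  tab0 <- compare_parameters(list(mk("x", c(1, 1, 1)), mk("y", c(1, 1, 1))),
                             "duration")
  expect_false(tab0$significant)
  expect_equal(tab0$raw_p, 1)
  # under-replicated strains are rejected
  expect_error(compare_parameters(list(mk("x", 1), mk("y", c(1, 2))),
                                  "duration"),
               class = "invalid_input")
})
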