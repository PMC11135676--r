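gp <- genotype_presets()

test_that("growth generator hits the logistic asymptote and is seeded", {
  pre <- genotype_preset("x", od0 = 0.05, odmax = 2.0, growth_rate = 0.8,
                         prod_params = gompertz_params(0.01, 0.1, 0.01, 5))
  g <- generate_growth_curve(pre, c(1, 1000), noise_sd = 0, seed = 1)
  expect_lt(abs(g$od600[2] - 2.0), 1e-6)
  a <- generate_growth_curve(pre, 0:20, 0.01, seed = 3)
  b <- generate_growth_curve(pre, 0:20, 0.01, seed = 3)
  expect_identical(a$od600, b$od600)
  expect_error(generate_growth_curve(pre, numeric(0), 0, 1),
               class = "invalid_input")
})

test_that("growth noise has the configured spread", {
  pre <- gp$WT
  times <- seq(1, 20, length.out = 200)
  g <- generate_growth_curve(pre, times, noise_sd = 0.01, seed = 9)
  truth <- generate_growth_curve(pre, times, noise_sd = 0, seed = 9)
  resid_sd <- sd(g$od600 - truth$od600)
  expect_lt(abs(resid_sd - 0.01) / 0.01, 0.2)
})

test_that("production generator matches the closed-form curve without noise", {
  pre <- gp$WT
  times <- seq(0, 30, by = 0.5)
  pc <- generate_production_curve(pre, times, 0, seed = 1)
  truth <- gompertz_value(pre$prod_params, times)
  expect_lt(max(abs(pc$a410 - truth) / pmax(truth, 1e-12)), 1e-9)
  # WT plateau and pre-lag baseline
  far <- generate_production_curve(pre, c(1, 500), 0, seed = 1)
  expect_lt(abs(far$a410[2] - 0.10), 1e-6)
  early <- generate_production_curve(pre, c(-30, 0), 0, seed = 1)
  expect_lt(abs(early$a410[1] - pre$baseline_a410), 1e-6)
})

test_that("noisy production draws average to the noiseless value", {
  pre <- gp$scoC
  t_fix <- 12
  truth <- gompertz_value(pre$prod_params, t_fix)
  noise_sd <- 0.005
  draws <- vapply(1:1000, function(s)
    generate_production_curve(pre, c(t_fix, t_fix + 1), noise_sd,
                              seed = s)$a410[1], numeric(1))
  expect_lt(abs(mean(draws) - truth), 3 * noise_sd / sqrt(1000))
})

test_that("flow generator reproduces its mixture components", {
  ctrl <- flow_preset("c", 0, is_control = TRUE)
  s <- generate_flow_sample(ctrl, 5000, seed = 2)
  # all events from the negative component: far below the positive mean
  expect_lt(mean(log10(s$events)), ctrl$neg_log_mean + 0.1)
  expect_lt(max(log10(s$events)), ctrl$pos_log_mean)
  allpos <- flow_preset("p", 1)
  n <- 1e5
  s <- generate_flow_sample(allpos, n, seed = 4)
  expect_lt(abs(mean(log10(s$events)) - allpos$pos_log_mean),
            3 * allpos$pos_log_sd / sqrt(n))
  expect_error(generate_flow_sample(allpos, 0, seed = 1),
               class = "invalid_input")
  a <- generate_flow_sample(allpos, 100, seed = 5)
  b <- generate_flow_sample(allpos, 100, seed = 5)
  expect_identical(a$events, b$events)
})

test_that("trace pairs encode protection multiplicatively and share jitter", {
  probe <- pk_test_probe()
  # degenerate attenuation 1: traces identical
  none <- footprint_spec("none", 5, 10, attenuation = 1)
  pair <- generate_trace_pair(none, probe, seed = 1)
  expect_identical(pair$with$sample_signal, pair$without$sample_signal)
  expect_identical(pair$with$ladder_signal, pair$without$ladder_signal)

  # PchR window: raw with-protein peak heights are 0.3x inside +6..+28
  spec <- footprint_spec("PchR", 6, 28, attenuation = 0.3)
  pair <- generate_trace_pair(spec, probe, seed = 2, jitter_sd = 0.05)
  pw <- detect_peaks(pair$with$sample_signal)
  po <- detect_peaks(pair$without$sample_signal)
  expect_equal(nrow(pw), probe$probe_len)
  expect_equal(pw$scan_pos, po$scan_pos)
  pos <- to_promoter_coords(seq_len(probe$probe_len), probe)
  inside <- zf_to_lin(pos) >= zf_to_lin(6) & zf_to_lin(pos) <= zf_to_lin(28)
  ratio <- pw$height / po$height
  expect_lt(max(abs(ratio[inside] - 0.3)), 1e-9)
  expect_lt(max(abs(ratio[!inside] - 1)), 1e-9)

  # hypersensitive site doubles only in the with-protein trace
  hs <- footprint_spec("h", 6, 28, 0.3,
                       hypersensitive_sites = data.frame(position = -40,
                                                         amplification = 2))
  pair <- generate_trace_pair(hs, probe, seed = 3)
  pw <- detect_peaks(pair$with$sample_signal)
  po <- detect_peaks(pair$without$sample_signal)
  at <- which(pos == -40)
  expect_lt(abs(pw$height[at] / po$height[at] - 2), 1e-9)

  # window outside the probe is rejected
  expect_error(generate_trace_pair(footprint_spec("x", 150, 200, 0.3), probe,
                                   seed = 1),
               class = "invalid_input")
})
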