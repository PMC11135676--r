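test_that("the gate threshold is the control maximum", {
  ctrl <- flow_sample("c", "control", c(1, 5, 3), is_control = TRUE)
  expect_equal(gate_threshold(ctrl), 5)
  expect_equal(gate_threshold(flow_sample("c", "control", 7,
                                          is_control = TRUE)), 7)
  # a non-control sample is refused
  expect_error(gate_threshold(flow_sample("s", "WT", 1:3)),
               class = "invalid_input")
  # brute-force max on a generated control
  s <- generate_flow_sample(flow_presets()$control, 2000, seed = 8)
  expect_equal(gate_threshold(s), max(s$events))
})

test_that("percent positive counts events strictly above the threshold", {
  s <- flow_sample("s", "WT", c(1, 2, 6, 8))
  expect_equal(percent_positive(s, 5)$percent_positive, 50)
  expect_equal(percent_positive(s, 100)$percent_positive, 0)
  # boundary events do not count
  expect_equal(percent_positive(flow_sample("s", "WT", c(5, 5)), 5)
               $percent_positive, 0)
  expect_equal(percent_positive(s, 5)$median_fluorescence, median(s$events))
})

test_that("percent positive is monotone nonincreasing in the threshold", {
  s <- generate_flow_sample(flow_presets()$WT, 5000, seed = 3)
  thr <- quantile(s$events, seq(0, 1, by = 0.1))
  pct <- vapply(thr, function(x) percent_positive(s, x)$percent_positive,
                numeric(1))
  expect_true(all(diff(pct) <= 0))
})

test_that("a control gated at its own threshold is exactly 0% positive", {
  ctrl <- generate_flow_sample(flow_presets()$control, 10000, seed = 6)
  expect_equal(percent_positive(ctrl, gate_threshold(ctrl))$percent_positive,
               0)
})

test_that("gating a synthetic mixture recovers the generating fraction", {
  for (frac in c(0.3, 0.698, 0.9)) {
    pre <- flow_preset("m", frac)
    n <- 20000
    s <- generate_flow_sample(pre, n, seed = round(1000 * frac))
    ctrl <- generate_flow_sample(flow_presets()$control, n, seed = 17)
    got <- percent_positive(s, gate_threshold(ctrl))$percent_positive
    expect_lt(abs(got - 100 * frac),
              3 * sqrt(frac * (1 - frac) / n) * 100 + 0.2)
  }
})

test_that("trial summaries report mean and sample SD per strain", {
  mk <- function(id, strain, pct, med)
    structure(list(sample_id = id, strain = strain, threshold = 1,
                   percent_positive = pct, median_fluorescence = med,
                   n_events = 10), class = "gate_result")
  res <- list(mk("a1", "A", 60, 10), mk("a2", "A", 70, 12),
              mk("a3", "A", 80, 14), mk("b1", "B", 50, 9))
  s <- summarize_trials(res)
  a <- s[s$strain == "A", ]
  expect_equal(a$mean_percent_positive, 70)
  expect_equal(a$sd_percent_positive, 10)
  expect_equal(a$mean_median_fluor, 12)
  b <- s[s$strain == "B", ]
  expect_equal(b$n_trials, 1)
  expect_equal(b$sd_percent_positive, 0)
})
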