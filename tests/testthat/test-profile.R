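test_that("differential profiles are normalize-then-subtract and sum to zero", {
  pairs <- data.frame(size_bp = 1:4,
                      with_height = c(10, 5, 10, 10),
                      without_height = c(10, 10, 10, 10))
  prof <- differential_profile(pairs)
  expect_equal(prof$values, c(1 / 28, -3 / 28, 1 / 28, 1 / 28))
  expect_lt(abs(sum(prof$values)), 1e-9)
  # identical traces: all zeros
  same <- data.frame(size_bp = 1:6, with_height = 2:7, without_height = 2:7)
  expect_equal(differential_profile(same)$values, rep(0, 6))
  # random inputs still sum to zero
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    rnd <- data.frame(size_bp = seq_len(n),
                      with_height = runif(n, 0.1, 5),
                      without_height = runif(n, 0.1, 5))
    expect_lt(abs(sum(differential_profile(rnd)$values)), 1e-9)
  }
})

test_that("region calling finds protected runs and respects min_run", {
  pairs <- data.frame(size_bp = 1:4,
                      with_height = c(10, 5, 10, 10),
                      without_height = c(10, 10, 10, 10))
  prof <- differential_profile(pairs)
  reg <- call_regions(prof, tau = 0.05, min_run = 1)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$kind, "protected")
  expect_equal(c(reg$start_tss, reg$end_tss), c(2, 2))
  expect_lt(reg$mean_differential, 0)
  # min_run larger than the dip: nothing called
  expect_equal(nrow(call_regions(prof, tau = 0.05, min_run = 2)), 0)
  # an all-zero profile yields no regions
  flat <- differential_profile(data.frame(size_bp = 1:5,
                                          with_height = rep(1, 5),
                                          without_height = rep(1, 5)))
  expect_equal(nrow(call_regions(flat, tau = 0.02, min_run = 1)), 0)
})

test_that("the noise-free pipeline recovers every preset window exactly", {
  probe <- pk_test_probe()
  want <- list(PchR = c(6, 28), AbrB = c(-30, 60), ScoC = c(-10, 60))
  specs <- footprint_presets()
  for (p in names(specs)) {
    pair <- generate_trace_pair(specs[[p]], probe, seed = 1)
    ana <- analyze_footprint(pair$with, pair$without, probe,
                             tau = 0.02, min_run = 3)
    prot <- ana$regions[ana$regions$kind == "protected", ]
    expect_equal(nrow(prot), 1, info = p)
    expect_equal(c(prot$start_tss, prot$end_tss), want[[p]], info = p)
    expect_equal(ana$profile$matched_n, probe$probe_len)
    expect_lt(abs(sum(ana$profile$values)), 1e-9)
    # identical inputs produce no regions at all
    null <- analyze_footprint(pair$without, pair$without, probe,
                              tau = 0.02, min_run = 3)
    expect_equal(nrow(null$regions), 0, info = p)
  }
})

test_that("hypersensitive sites are called with positive differentials", {
  probe <- pk_test_probe()
  spec <- footprint_spec("h", 6, 28, 0.3,
                         hypersensitive_sites = data.frame(
                           position = c(-45, -44, -43),
                           amplification = 2))
  pair <- generate_trace_pair(spec, probe, seed = 5)
  ana <- analyze_footprint(pair$with, pair$without, probe,
                           tau = 0.02, min_run = 3)
  hyp <- ana$regions[ana$regions$kind == "hypersensitive", ]
  expect_equal(nrow(hyp), 1)
  expect_equal(c(hyp$start_tss, hyp$end_tss), c(-45, -43))
  expect_gt(hyp$mean_differential, 0)
})

test_that("widening the generator window never shrinks the called region", {
  probe <- pk_test_probe()
  base <- footprint_spec("a", 6, 28, 0.3)
  wider <- footprint_spec("b", 5, 28, 0.3)  # one extra attenuated position
  r1 <- with(generate_trace_pair(base, probe, seed = 2),
             analyze_footprint(with, without, probe, tau = 0.02,
                               min_run = 3))$regions
  r2 <- with(generate_trace_pair(wider, probe, seed = 2),
             analyze_footprint(with, without, probe, tau = 0.02,
                               min_run = 3))$regions
  p1 <- r1[r1$kind == "protected", ]; p2 <- r2[r2$kind == "protected", ]
  expect_lte(p2$start_tss, p1$start_tss)
  expect_gte(p2$end_tss, p1$end_tss)
})

test_that("jittered peak heights leave region bounds within 1 bp", {
  probe <- pk_test_probe()
  spec <- footprint_presets()$PchR
  hits <- 0L
  n_runs <- 25
  for (s in seq_len(n_runs)) {
    pair <- generate_trace_pair(spec, probe, seed = 1000 + s,
                                jitter_sd = 0.05)
    ana <- analyze_footprint(pair$with, pair$without, probe,
                             tau = 0.02, min_run = 3)
    prot <- ana$regions[ana$regions$kind == "protected", ]
    if (nrow(prot) == 1 && abs(prot$start_tss - 6) <= 1 &&
        abs(prot$end_tss - 28) <= 1)
      hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.95)
})
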