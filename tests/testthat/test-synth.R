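test_that("generators are pure functions of parameters and seed", {
  expect_identical(gen_gaussian_rr(500, seed = 42)$intervals,
                   gen_gaussian_rr(500, seed = 42)$intervals)
  expect_identical(gen_fgn_rr(500, target_h = 0.7, seed = 42)$intervals,
                   gen_fgn_rr(500, target_h = 0.7, seed = 42)$intervals)
  expect_false(identical(gen_gaussian_rr(500, seed = 1)$intervals,
                         gen_gaussian_rr(500, seed = 2)$intervals))
  # global RNG state is untouched
  set.seed(7); before <- .Random.seed
  invisible(gen_bimodal_rr(100, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("the healthy generator hits its target mean at large n", {
  rr <- gen_gaussian_rr(50000, seed = 8)
  expect_equal(mean(rr$intervals), 750, tolerance = 1 / 750)
  expect_equal(sd(rr$intervals), 60, tolerance = 0.02)
})

test_that("bimodal component assignment follows the mixture weight", {
  rr <- gen_bimodal_rr(50000, seed = 8)
  expect_equal(rr$meta$n_mode1 / 50000, 0.6, tolerance = 0.02)
  uni <- gen_bimodal_rr(5000, weight = 1, seed = 8)
  expect_equal(mean(uni$intervals), 600, tolerance = 0.01)
  expect_equal(uni$meta$n_mode1, 5000)
})

test_that("fgn at H = 0.5 is white and at H = 0.8 is persistent", {
  x <- gen_fgn_rr(10000, target_h = 0.5, seed = 4)$intervals
  rho1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(rho1), 0.03)
  a <- dfa(gen_fgn_rr(10000, target_h = 0.8, seed = 4))$alpha
  expect_gt(a, 0.7)
  expect_lt(a, 0.9)
})

test_that("modulated generator degenerates to constant at zero depth", {
  rr <- gen_modulated_rr(200, depth_ms = 0)
  expect_true(all(rr$intervals == 800))
  expect_error(gen_modulated_rr(100, depth_ms = 900), "below base_ms")
})

test_that("low-variability profile depresses SDNN relative to healthy", {
  worse <- 0
  for (s in 1:25) {
    sd_h <- time_domain_summary(gen_gaussian_rr(2000, seed = s))$sdnn
    sd_i <- time_domain_summary(gen_ischemia_rr(2000, seed = s + 1000))$sdnn
    worse <- worse + (sd_i < sd_h)
  }
  expect_equal(worse, 25)
})

test_that("clipping to positive intervals is counted, never silent", {
  rr <- gen_gaussian_rr(2000, mean_ms = 100, sd_ms = 200, seed = 5)
  expect_true(all(rr$intervals > 0))
  expect_gt(rr$meta$n_clipped, 0)
})

test_that("cohort generation is deterministic with distinct subject seeds", {
  spec <- list(
    ischemia = list(profile = "ischemia_lowvar", n_subjects = 16, n_beats = 50),
    arrhythmia = list(profile = "arrhythmia_bimodal", n_subjects = 64, n_beats = 50),
    healthy = list(profile = "healthy_gaussian", n_subjects = 42, n_beats = 50))
  cohort <- gen_cohort(spec, seed = 123)
  expect_length(cohort, 122)
  seeds <- vapply(cohort, function(s) s$meta$seed, 0L)
  expect_equal(anyDuplicated(seeds), 0L)
  expect_equal(table(vapply(cohort, `[[`, "", "label"))[["arrhythmia"]], 64)
  again <- gen_cohort(spec, seed = 123)
  expect_identical(lapply(cohort, `[[`, "intervals"),
                   lapply(again, `[[`, "intervals"))
  expect_error(gen_cohort(list(a = spec[[1]], a = spec[[2]]), seed = 1),
               "duplicate")
})

test_that("profile dispatcher reaches every generator", {
  for (p in c("healthy_gaussian", "arrhythmia_bimodal", "ischemia_lowvar",
              "white_noise", "fgn", "modulated", "alternating", "ramp",
              "periodic")) {
    rr <- gen_rr(p, n = 64, seed = 9)
    expect_s3_class(rr, "rr_series")
    expect_length(rr$intervals, 64)
  }
})
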