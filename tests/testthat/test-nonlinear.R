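# --- DFA ------------------------------------------------------------------

test_that("DFA alpha is invariant to affine transforms of the intervals", {
  rr <- gen_gaussian_rr(4000, seed = 17)
  d0 <- dfa(rr)
  d_shift <- dfa(rr$intervals + 250)
  d_scale <- dfa(3 * rr$intervals)
  expect_equal(d_shift$alpha, d0$alpha, tolerance = 1e-10)
  expect_equal(d_scale$alpha, d0$alpha, tolerance = 1e-10)
  expect_equal(d_scale$fluctuations, 3 * d0$fluctuations, tolerance = 1e-10)
})

test_that("DFA separates persistent, uncorrelated and anti-correlated series", {
  a_white <- dfa(gen_gaussian_rr(8000, seed = 1))$alpha
  a_fgn <- dfa(gen_fgn_rr(8000, target_h = 0.8, seed = 1))$alpha
  a_anti <- dfa(gen_alternating_rr(8000, seed = 1))$alpha
  expect_gt(a_fgn, a_white)
  expect_lt(a_anti, 0.5)
  expect_lt(abs(a_white - 0.5), 0.1)
})

test_that("fluctuations are increasing in box size on self-similar input", {
  d <- dfa(gen_fgn_rr(6000, target_h = 0.7, seed = 4))
  expect_true(all(diff(d$fluctuations) > 0))
  expect_equal(length(d$box_sizes), length(d$fluctuations))
})

test_that("short series drop oversized boxes with a warning, then error", {
  rr <- gen_gaussian_rr(100, seed = 2)
  expect_warning(d <- dfa(rr), "dropping")
  expect_true(all(d$box_sizes <= 50))
  expect_error(suppressWarnings(dfa(gen_gaussian_rr(8, seed = 2))),
               "usable box")
})

test_that("alpha1/alpha2 fit their designated box ranges", {
  d <- dfa(gen_gaussian_rr(5000, seed = 3))
  sel1 <- d$box_sizes >= 4 & d$box_sizes <= 16
  fit1 <- coef(lm(d$log2_f[sel1] ~ d$log2_n[sel1]))[[2]]
  expect_equal(d$alpha1, fit1, tolerance = 1e-12)
})

# --- Poincare -------------------------------------------------------------

test_that("constant series gives sd1 = sd2 = 0 and an absent ratio", {
  p <- poincare_descriptors(rr_series(rep(800, 50)))
  expect_equal(p$sd1, 0)
  expect_equal(p$sd2, 0)
  expect_true(is.na(p$ratio))
})

test_that("sd1^2 equals half the variance of successive differences", {
  set.seed(12)
  for (rep in 1:10) {
    x <- rnorm(40, 800, 50)
    p <- poincare_descriptors(x)
    d <- x[-1] - x[-40]
    expect_equal(p$sd1^2, mean((d - mean(d))^2) / 2, tolerance = 1e-12)
    expect_equal(p$sd1^2, oracle_poincare_sd1sq(x), tolerance = 1e-12)
  }
})

test_that("the Poincare moment identity holds at physiologic lengths", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    x <- runif(n, 300, 1500)
    p <- poincare_descriptors(x)
    pvar <- mean((x - mean(x))^2)
    if (!p$degenerate)
      expect_equal(p$sd1^2 + p$sd2^2, 2 * pvar, tolerance = 1e-9)
  }
})

test_that("extreme anti-correlation at tiny n is flagged degenerate", {
  p <- poincare_descriptors(c(300, 1500, 300))   # sd1^2 > 2 var
  expect_true(p$degenerate)
  expect_equal(p$sd2, 0)
  expect_true(is.na(p$ratio))
})

# --- entropies ------------------------------------------------------------

test_that("regular series give (near) zero entropy", {
  expect_equal(approximate_entropy(rep(800, 30), r = 1), 0)
  periodic <- rep(c(800, 600), 25)
  expect_lt(approximate_entropy(periodic, r = 50), 0.05)
  expect_equal(sample_entropy(periodic, r = 50), 0)
})

test_that("a constant series demands an explicit tolerance", {
  expect_error(approximate_entropy(rep(800, 30)), "explicit r")
  expect_error(sample_entropy(rep(800, 30)), "explicit r")
})

test_that("entropies match exhaustive template counting on random toys", {
  set.seed(99)
  for (rep in 1:12) {
    n <- sample(15:40, 1)
    x <- rnorm(n, 800, 60)
    r <- 0.2 * sd(x)
    m <- sample(1:3, 1)
    expect_equal(approximate_entropy(x, m = m, r = r),
                 oracle_apen(x, m, r), tolerance = 1e-10)
    got <- sample_entropy(x, m = m, r = r)
    want <- oracle_sampen(x, m, r)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("sample entropy does not increase when r doubles", {
  set.seed(55)
  x <- rnorm(60, 800, 50)
  r <- 0.2 * sd(x)
  s1 <- sample_entropy(x, r = r)
  s2 <- sample_entropy(x, r = 2 * r)
  expect_lte(s2, s1)
})

test_that("no-match situations return NA with a flag", {
  x <- c(1, 1000, 2, 2000, 3, 3000, 4, 4000)  # nothing within r = 0.1
  got <- sample_entropy(x, m = 2, r = 0.1)
  expect_true(is.na(got))
  expect_equal(attr(got, "flag"), "undefined (no matches)")
})

# --- Hurst ----------------------------------------------------------------

test_that("a monotone ramp is maximally persistent", {
  h <- hurst_rs(gen_ramp_rr(4000))$h
  expect_gte(h, 0.9)
})

test_that("window sizes with zero dispersion in all blocks are dropped", {
  x <- rep(800, 2000)
  expect_error(suppressWarnings(hurst_rs(x)), "usable window")
})

test_that("R/S recovers the generator exponent at moderate length", {
  hs <- vapply(1:5, function(s)
    hurst_rs(gen_fgn_rr(8000, target_h = 0.8, seed = s))$h, 0)
  expect_equal(mean(hs), 0.8, tolerance = 0.1)
  h_white <- vapply(1:5, function(s)
    hurst_rs(gen_gaussian_rr(8000, seed = s + 20))$h, 0)
  expect_equal(mean(h_white), 0.5, tolerance = 0.07)
})

test_that("the raw log-log slope is reported alongside the corrected h", {
  res <- hurst_rs(gen_gaussian_rr(4000, seed = 31))
  fit <- coef(lm(log(res$rs_values) ~ log(res$window_sizes)))[[2]]
  expect_equal(res$slope_rs, fit, tolerance = 1e-10)
  raw <- hurst_rs(gen_gaussian_rr(4000, seed = 31), correction = "none")
  expect_equal(raw$h, raw$slope_rs)
})
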