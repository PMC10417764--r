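test_that("a point mass lands in a single bin with the full count", {
  h <- rr_histogram(rr_series(rep(800, 100)))
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$mode_count, 100)
  expect_true(h$bin_edges[h$mode_bin] <= 800 &&
              800 < h$bin_edges[h$mode_bin + 1])
  expect_equal(sum(h$counts), 100)
  expect_length(h$bin_edges, length(h$counts) + 1)
})

test_that("healthy synthetic mode bin contains 750 ms", {
  h <- rr_histogram(gen_gaussian_rr(50000, seed = 2))
  expect_true(h$bin_edges[h$mode_bin] <= 750 &&
              750 < h$bin_edges[h$mode_bin + 1])
})

test_that("arrhythmia-like synthetic shows local maxima at both modes", {
  h <- rr_histogram(gen_bimodal_rr(50000, seed = 2))
  centers <- h$bin_edges[-length(h$bin_edges)] + h$bin_width / 2
  is_local_max <- function(target) {
    lo <- h$bin_edges[-length(h$bin_edges)]
    i <- which(lo <= target & target < h$bin_edges[-1])
    window <- h$counts[max(1, i - 2):min(length(h$counts), i + 2)]
    any(h$counts[max(1, i - 1):min(length(h$counts), i + 1)] ==
        max(window))
  }
  expect_true(is_local_max(600))
  expect_true(is_local_max(420))
})

test_that("mode ties break toward the shorter-RR bin", {
  # two exactly equal point masses
  h <- rr_histogram(rr_series(c(rep(500, 10), rep(900, 10))))
  expect_lt(h$mode_value, 600)
})

test_that("triangular index equals total over max and hits its extremes", {
  expect_equal(hrv_triangular_index(rr_histogram(rr_series(rep(810, 10)))), 1)
  # equal counts over k bins -> k
  k <- 5
  x <- rep(seq(500, by = 7.8125, length.out = k) + 1, each = 7)
  expect_equal(hrv_triangular_index(rr_histogram(rr_series(x))), k)
  # random toys against direct recount
  set.seed(5)
  for (rep in 1:10) {
    h <- rr_histogram(gen_bimodal_rr(500, seed = rep))
    expect_equal(hrv_triangular_index(h), oracle_hrv_ti(h$counts))
  }
})

test_that("hrv_ti is at least 1 and invariant under count scaling via tinn", {
  set.seed(8)
  for (rep in 1:10) {
    h <- rr_histogram(gen_gaussian_rr(300, seed = rep + 50))
    expect_gte(hrv_triangular_index(h), 1)
  }
})

test_that("a symmetric triangular histogram yields a near-symmetric base", {
  # build counts forming a perfect triangle over bins
  bw <- 7.8125
  k0 <- 64                       # apex bin index (absolute)
  heights <- c(1:6, 5:1)         # symmetric triangle, apex 6
  x <- unlist(lapply(seq_along(heights), function(i)
    rep((k0 + i) * bw + bw / 2, heights[i])))
  h <- rr_histogram(rr_series(x), bw)
  fit <- tinn(h)
  expect_false(fit$degenerate)
  # apex at center implies near-symmetric base
  expect_equal(fit$m2 - h$mode_value, h$mode_value - fit$m1,
               tolerance = bw + 1e-9)
  expect_equal(fit$tinn, fit$m2 - fit$m1)
})

test_that("tinn equals the exhaustive all-pairs grid search", {
  set.seed(31)
  for (rep in 1:8) {
    h <- rr_histogram(gen_gaussian_rr(400, sd_ms = 40, seed = rep + 7))
    fit <- tinn(h)
    o <- oracle_tinn(h)
    expect_equal(fit$tinn, o$tinn)
    expect_equal(fit$m1, o$m1)
    expect_equal(fit$m2, o$m2)
    expect_true(fit$m1 <= h$mode_value && h$mode_value <= fit$m2)
  }
})

test_that("tinn is invariant to scaling all counts", {
  h <- rr_histogram(gen_gaussian_rr(500, seed = 77))
  h3 <- h
  h3$counts <- h$counts * 3L
  h3$mode_count <- h$mode_count * 3L
  expect_equal(tinn(h3)$tinn, tinn(h)$tinn)
})

test_that("fewer than 3 nonzero bins gives the flagged support width", {
  h <- rr_histogram(rr_series(c(rep(500, 5), rep(900, 5))))
  fit <- tinn(h)
  expect_true(fit$degenerate)
  expect_equal(fit$tinn, fit$m2 - fit$m1)
})

test_that("halving the bin width never decreases the triangular index", {
  for (s in 1:5) {
    rr <- gen_gaussian_rr(2000, seed = s + 100)
    expect_gte(hrv_triangular_index(rr_histogram(rr, 7.8125 / 2)),
               hrv_triangular_index(rr_histogram(rr, 7.8125)))
  }
})
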