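# Independent brute-force oracles. Each recomputes a statistic from its
# definition by direct enumeration, sharing no code with the package paths
# it checks.

oracle_time_domain <- function(x, window_s = 300, min_beats = 2) {
  n <- length(x)
  d <- x[-1] - x[-n]
  mu <- sum(x) / n
  sdnn <- sqrt(sum((x - mu)^2) / (n - 1))
  rmssd <- sqrt(sum(d^2) / (n - 1))
  nn50 <- sum(abs(d) > 50)
  # windows by cumulative occurrence time (beat i at sum of previous RR)
  t <- cumsum(c(0, x[-n])) / 1000
  win <- floor(t / window_s)
  means <- c(); sds <- c()
  for (w in unique(win)) {
    xs <- x[win == w]
    if (length(xs) >= min_beats) {
      means <- c(means, mean(xs))
      sds <- c(sds, sd(xs))
    }
  }
  list(mean_rr = mu, sdnn = sdnn, rmssd = rmssd, nn50 = nn50,
       pnn50 = 100 * nn50 / (n - 1),
       sdann = if (length(means) >= 2) sd(means) else NA_real_,
       sdnn_index = if (length(sds) >= 1) mean(sds) else NA_real_)
}

oracle_hrv_ti <- function(counts) sum(counts) / max(counts)

# Exhaustive search over every (m1, m2) bin-edge pair; full residual per pair.
oracle_tinn <- function(hist) {
  centers <- hist$bin_edges[-length(hist$bin_edges)] + hist$bin_width / 2
  xm <- hist$mode_value; y <- hist$mode_count
  tri_resid <- function(m1, m2) {
    tri <- numeric(length(centers))
    left <- centers > m1 & centers < xm
    right <- centers > xm & centers < m2
    tri[left] <- y * (centers[left] - m1) / (xm - m1)
    tri[right] <- y * (m2 - centers[right]) / (m2 - xm)
    tri[centers == xm] <- y
    sum((hist$counts - tri)^2)
  }
  best <- Inf; bm1 <- NA; bm2 <- NA
  for (m1 in hist$bin_edges[hist$bin_edges < xm])
    for (m2 in hist$bin_edges[hist$bin_edges > xm]) {
      r <- tri_resid(m1, m2)
      if (r < best) { best <- r; bm1 <- m1; bm2 <- m2 }
    }
  list(tinn = bm2 - bm1, m1 = bm1, m2 = bm2)
}

cheb_dist <- function(x, i, j, m) max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))

oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logs <- numeric(nt)
    for (i in seq_len(nt)) {
      c_i <- 0
      for (j in seq_len(nt))
        if (cheb_dist(x, i, j, mm) <= r) c_i <- c_i + 1
      logs[i] <- log(c_i / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1))
    for (j in (i + 1):nt) {
      if (cheb_dist(x, i, j, m) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

oracle_poincare_sd1sq <- function(x) {
  d <- x[-1] - x[-length(x)]
  mean((d - mean(d))^2) / 2
}
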