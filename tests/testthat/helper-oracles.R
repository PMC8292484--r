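# Independent brute-force oracles for the thresholding criteria.
# Deliberately written as plain loops over slices of the histogram (no
# cumulative sums, no shared code with the package) so they provide an
# independent route to the same optima.

oracle_random_histogram <- function(seed) {
  # mix of dense, sparse and spiky histograms
  withr::with_seed(seed, {
    kind <- sample(3L, 1L)
    h <- switch(kind,
      rpois(256, lambda = runif(1, 1, 40)),
      { h <- integer(256); idx <- sample(256, sample(5:40, 1))
        h[idx] <- rpois(length(idx), 50) + 1L; h },
      { base <- rpois(256, 3)
        pk <- sample(200, 2) + 20
        base[pk[1]] <- base[pk[1]] + 500L
        base[pk[2]] <- base[pk[2]] + 300L
        base })
    if (sum(h) == 0) h[100] <- 5L
    if (sum(h > 0) < 2) h[c(30, 200)] <- h[c(30, 200)] + 3L
    h
  })
}

# generic scan: crit_fun(h, t) -> numeric or NA; lowest optimal t wins
oracle_scan <- function(h, crit_fun, maximize) {
  best_t <- NA_integer_; best <- Inf
  for (t in 0:255) {
    v <- crit_fun(h, t)
    if (is.na(v) || !is.finite(v)) next
    if (maximize) v <- -v
    if (v < best - 0) { best <- v; best_t <- t }
  }
  best_t
}

o_mass  <- function(h, lv) sum(h[lv + 1L])
o_mean  <- function(h, lv) sum(h[lv + 1L] * lv) / sum(h[lv + 1L])

oracle_otsu_crit <- function(h, t) {
  lo <- 0:t; hi <- if (t < 255) (t + 1L):255L else integer(0)
  w0 <- o_mass(h, lo); w1 <- o_mass(h, hi)
  if (w0 == 0 || w1 == 0) return(NA_real_)
  m0 <- o_mean(h, lo); m1 <- o_mean(h, hi)
  v0 <- sum(h[lo + 1L] * (lo - m0)^2) / w0
  v1 <- sum(h[hi + 1L] * (hi - m1)^2) / w1
  (w0 * v0 + w1 * v1) / (w0 + w1)
}

oracle_kapur_crit <- function(h, t) {
  p <- h / sum(h)
  lo <- 0:t; hi <- if (t < 255) (t + 1L):255L else integer(0)
  P0 <- sum(p[lo + 1L]); P1 <- sum(p[hi + 1L])
  if (P0 <= 0 || P1 <= 0) return(NA_real_)
  q0 <- p[lo + 1L] / P0; q0 <- q0[q0 > 0]
  q1 <- p[hi + 1L] / P1; q1 <- q1[q1 > 0]
  -sum(q0 * log(q0)) - sum(q1 * log(q1))
}

oracle_huang_crit <- function(h, t) {
  nz <- which(h > 0) - 1L
  C <- max(nz) - min(nz)
  lo <- 0:t; hi <- if (t < 255) (t + 1L):255L else integer(0)
  if (o_mass(h, lo) == 0 || o_mass(h, hi) == 0) return(NA_real_)
  mu0 <- o_mean(h, lo); mu1 <- o_mean(h, hi)
  S <- function(u) ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
  u_lo <- 1 / (1 + abs(lo - mu0) / C)
  u_hi <- 1 / (1 + abs(hi - mu1) / C)
  sum(h[lo + 1L] * S(u_lo)) + sum(h[hi + 1L] * S(u_hi))
}

oracle_percentile_crit <- function(h, t) {
  lo <- 0:t; hi <- if (t < 255) (t + 1L):255L else integer(0)
  w0 <- o_mass(h, lo); w1 <- o_mass(h, hi)
  if (w0 == 0 || w1 == 0) return(NA_real_)
  abs(w0 - w1)  # exact-count form of |foreground fraction - 0.5|
}

oracle_yen_crit <- function(h, t) {
  p <- h / sum(h)
  lo <- 0:t; hi <- if (t < 255) (t + 1L):255L else integer(0)
  P0 <- sum(p[lo + 1L]); P1f <- sum(p[hi + 1L])
  if (P0 <= 0 || P1f <= 0) return(NA_real_)
  s0 <- sum(p[lo + 1L]^2); s1 <- sum(p[hi + 1L]^2)
  a <- s0 * s1; bq <- P0 * (1 - P0)
  (if (a > 0) -log(a) else 0) + (if (bq > 0) 2 * log(bq) else 0)
}

oracle_shanbhag_crit <- function(h, t) {
  p <- h / sum(h)
  P1 <- numeric(256); acc <- 0
  for (i in 1:256) { acc <- acc + p[i]; P1[i] <- acc }
  P2 <- 1 - P1
  i <- t + 1L
  if (P1[i] <= 0 || P2[i] <= 0) return(NA_real_)
  term_b <- 0.5 / P1[i]
  ib <- if (i >= 2) 2:i else integer(0)
  ent_back <- -sum(p[ib] * log(1 - term_b * P1[ib - 1L])) * term_b
  term_f <- 0.5 / P2[i]
  io <- if (i + 1L <= 255L) (i + 1L):255L else integer(0)
  ent_obj <- -sum(p[io] * log(1 - term_f * P2[io + 1L])) * term_f
  if (length(ib) == 0L) ent_back <- 0
  if (length(io) == 0L) ent_obj <- 0
  abs(ent_back - ent_obj)
}

oracle_renyi_alpha_crit <- function(h, t, alpha) {
  if (alpha == 1) return(oracle_kapur_crit(h, t))
  p <- h / sum(h)
  lo <- 0:t; hi <- if (t < 255) (t + 1L):255L else integer(0)
  P0 <- sum(p[lo + 1L]); P1f <- sum(p[hi + 1L])
  if (P0 <= 0 || P1f <= 0) return(NA_real_)
  (log(sum((p[lo + 1L] / P0)^alpha)) + log(sum((p[hi + 1L] / P1f)^alpha))) /
    (1 - alpha)
}

oracle_renyi <- function(h) {
  ts <- sort(c(oracle_scan(h, function(hh, t) oracle_renyi_alpha_crit(hh, t, 1),   TRUE),
               oracle_scan(h, function(hh, t) oracle_renyi_alpha_crit(hh, t, 0.5), TRUE),
               oracle_scan(h, function(hh, t) oracle_renyi_alpha_crit(hh, t, 2),   TRUE)))
  if (abs(ts[1] - ts[2]) <= 5) {
    b <- if (abs(ts[2] - ts[3]) <= 5) c(1, 2, 1) else c(0, 1, 3)
  } else {
    b <- if (abs(ts[2] - ts[3]) <= 5) c(3, 1, 0) else c(1, 2, 1)
  }
  P1 <- function(t) sum(h[1:(t + 1L)]) / sum(h)
  omega <- P1(ts[3]) - P1(ts[1])
  as.integer(ts[1] * (P1(ts[1]) + 0.25 * omega * b[1]) +
               0.25 * ts[2] * omega * b[2] +
               ts[3] * ((1 - P1(ts[3])) + 0.25 * omega * b[3]))
}

oracle_moments <- function(h) {
  p <- h / sum(h)
  m1 <- 0; m2 <- 0; m3 <- 0
  for (x in 0:255) {
    m1 <- m1 + p[x + 1L] * x
    m2 <- m2 + p[x + 1L] * x^2
    m3 <- m3 + p[x + 1L] * x^3
  }
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- sqrt(max(c1^2 - 4 * c0, 0))
  z0 <- 0.5 * (-c1 - disc); z1 <- 0.5 * (-c1 + disc)
  p0 <- (z1 - m1) / (z1 - z0)
  oracle_scan(h, function(hh, t) {
    lo <- 0:t; hi <- if (t < 255) (t + 1L):255L else integer(0)
    if (o_mass(hh, lo) == 0 || o_mass(hh, hi) == 0) return(NA_real_)
    abs(sum(hh[lo + 1L]) / sum(hh) - p0)
  }, maximize = FALSE)
}

oracle_li_crit <- function(h, t) {
  # Li minimum cross entropy eta(t)
  lo <- 0:t; hi <- if (t < 255) (t + 1L):255L else integer(0)
  w0 <- o_mass(h, lo); w1 <- o_mass(h, hi)
  if (w0 == 0 || w1 == 0) return(NA_real_)
  m0 <- o_mean(h, lo); m1 <- o_mean(h, hi)
  if (m0 <= 0 || m1 <= 0) return(NA_real_)
  s0 <- sum(h[lo + 1L] * lo); s1 <- sum(h[hi + 1L] * hi)
  -(s0 * log(m0) + s1 * log(m1))
}

oracle_isodata_fixed_point <- function(h) {
  # independent fixed-point iteration, loop form
  nz <- which(h > 0) - 1L
  lo_s <- min(nz); hi_s <- max(nz)
  t <- max(min(floor((lo_s + hi_s) / 2), hi_s - 1L), lo_s)
  for (it in 1:500) {
    m_lo <- o_mean(h, 0:t)
    m_hi <- o_mean(h, (t + 1L):255L)
    tn <- round((m_lo + m_hi) / 2)
    tn <- max(min(tn, hi_s - 1L), lo_s)
    if (tn == t) break
    t <- tn
  }
  as.integer(t)
}
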