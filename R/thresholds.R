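# Histogram-based automatic binarization thresholds for 8-bit OCTA images.
#
# Every auto-threshold maps a 256-bin gray-level histogram to an integer
# level t in [0, 255]; a pixel is classified as vessel (foreground) iff its
# intensity is strictly greater than t.  Class splits inside the criteria
# use the same convention: background = levels <= t, foreground = levels > t.
# Criterion ties are broken by the lowest optimal level, and a histogram
# with all its mass at a single level is returned as that level with the
# `degenerate` flag set.

#' Names of the implemented thresholding methods
#'
#' @param include_fixed if `TRUE`, include `"Fixed"` (the plexus-specific
#'   fixed level) alongside the twelve automatic methods.
#' @return character vector of method names accepted by [auto_threshold()].
#' @export
octa_methods <- function(include_fixed = TRUE) {
  m <- c("Default", "Huang", "Intermodes", "Li", "MaxEntropy", "Mean",
         "Moments", "Otsu", "Percentile", "RenyiEntropy", "Shanbhag", "Yen")
  if (include_fixed) c(m, "Fixed") else m
}

#' Gray-level histogram of an 8-bit image
#'
#' @param img integer matrix with values in 0..255.
#' @return integer vector of 256 bin counts (levels 0..255).
#' @export
image_histogram <- function(img) {
  v <- as.vector(img)
  if (anyNA(v)) stop("image contains NA values")
  if (any(v < 0 | v > 255)) stop("image values must lie in [0, 255]")
  tabulate(as.integer(round(v)) + 1L, nbins = 256L)
}

check_histogram <- function(h) {
  h <- as.numeric(h)
  if (length(h) != 256L) stop("histogram must have exactly 256 bins")
  if (anyNA(h) || any(h < 0)) stop("histogram counts must be non-negative")
  if (sum(h) <= 0) stop("histogram is empty (zero total count)")
  h
}

new_level <- function(t, method, degenerate = FALSE) {
  structure(list(t = as.integer(t), method = method, degenerate = degenerate),
            class = "threshold_level")
}

#' @export
print.threshold_level <- function(x, ...) {
  cat(sprintf("<threshold_level> %s: t = %d%s\n", x$method, x$t,
              if (isTRUE(x$degenerate)) " (degenerate histogram)" else ""))
  invisible(x)
}

# single populated bin -> that level, flagged; NULL otherwise
degenerate_level <- function(h, method) {
  nz <- which(h > 0)
  if (length(nz) == 1L) new_level(nz - 1L, method, degenerate = TRUE) else NULL
}

support_range <- function(h) range(which(h > 0)) - 1L

# lowest optimal candidate; crit has one entry per t = 0..255, NA = invalid
scan_optimum <- function(crit, maximize) {
  if (maximize) crit <- -crit
  ok <- which(is.finite(crit))
  if (length(ok) == 0L) stop("no valid candidate threshold")
  ok[which.min(crit[ok])] - 1L
}

# candidate thresholds t for which both classes carry mass
valid_split <- function(h) {
  P <- cumsum(h)
  tot <- P[256L]
  P > 0 & P < tot   # index i corresponds to t = i - 1
}

#' IsoData ("Default") iterative intermeans threshold
#'
#' Iterates t <- round((mean background + mean foreground) / 2), with
#' background = levels <= t, starting at the midpoint of the histogram
#' support, until the level no longer changes.
#'
#' @param h 256-bin histogram (see [image_histogram()]).
#' @return a `threshold_level`.
#' @export
threshold_default_isodata <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Default"); if (!is.null(d)) return(d)
  lv <- 0:255
  rng <- support_range(h)
  t <- as.integer(floor(mean(rng)))
  t <- max(min(t, rng[2L] - 1L), rng[1L])
  seen <- logical(256L)
  repeat {
    lo <- lv <= t
    m_lo <- sum(h[lo] * lv[lo]) / sum(h[lo])
    m_hi <- sum(h[!lo] * lv[!lo]) / sum(h[!lo])
    t_new <- as.integer(round((m_lo + m_hi) / 2))
    t_new <- max(min(t_new, rng[2L] - 1L), rng[1L])
    if (t_new == t) break
    if (seen[t_new + 1L]) { t <- min(t, t_new); break }  # guard 2-cycles
    seen[t + 1L] <- TRUE
    t <- t_new
  }
  new_level(t, "Default")
}

huang_criterion <- function(h) {
  lv <- 0:255
  rng <- support_range(h)
  C <- rng[2L] - rng[1L]
  W <- cumsum(h); WL <- cumsum(h * lv)
  tot <- W[256L]; totL <- WL[256L]
  crit <- rep(NA_real_, 256L)
  shannon <- function(u) {
    s <- numeric(length(u))
    p <- u > 0 & u < 1
    s[p] <- -u[p] * log(u[p]) - (1 - u[p]) * log(1 - u[p])
    s
  }
  for (t in rng[1L]:(rng[2L] - 1L)) {
    i <- t + 1L
    mu0 <- WL[i] / W[i]
    mu1 <- (totL - WL[i]) / (tot - W[i])
    u <- numeric(256L)
    lo <- lv <= t
    u[lo]  <- 1 / (1 + abs(lv[lo]  - mu0) / C)
    u[!lo] <- 1 / (1 + abs(lv[!lo] - mu1) / C)
    crit[i] <- sum(h * shannon(u))
  }
  crit
}

#' Huang fuzzy-entropy threshold
#'
#' Minimizes the Huang--Wang measure of fuzziness: each gray level gets a
#' membership to its class mean (background or foreground) and the Shannon
#' entropy of the memberships, weighted by the histogram, is minimized over
#' all candidate levels.
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_huang <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Huang"); if (!is.null(d)) return(d)
  new_level(scan_optimum(huang_criterion(h), maximize = FALSE), "Huang")
}

# one pass of the window-3 running mean used by Intermodes
smooth3 <- function(y) {
  n <- length(y)
  (y[c(1L, 1L:(n - 1L))] + y + y[c(2L:n, n)]) / 3
}

local_maxima <- function(y) {
  n <- length(y)
  k <- 2L:(n - 1L)
  which(y[k] > y[k - 1L] & y[k] > y[k + 1L]) + 1L  # 1-based bin index
}

#' Intermodes threshold
#'
#' Iteratively smooths the histogram with a window-3 running average until
#' exactly two local maxima `j < k` remain, then returns `round((j + k)/2)`.
#' Histograms that never become bimodal within `max_iter` smoothing passes
#' raise an error.
#'
#' @inheritParams threshold_default_isodata
#' @param max_iter smoothing iteration cap.
#' @return a `threshold_level` with attribute `modes = c(j, k)`.
#' @export
threshold_intermodes <- function(h, max_iter = 10000L) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Intermodes"); if (!is.null(d)) return(d)
  y <- h
  for (it in seq_len(max_iter)) {
    pk <- local_maxima(y)
    if (length(pk) == 2L) {
      jk <- pk - 1L
      out <- new_level(as.integer(round(mean(jk))), "Intermodes")
      attr(out, "modes") <- jk
      return(out)
    }
    y <- smooth3(y)
  }
  stop("histogram is not bimodal: two local maxima not reached within ",
       max_iter, " smoothing iterations")
}

li_criterion <- function(h) {
  # Li cross entropy eta(t) = -sum_lo(x h) log mu0 - sum_hi(x h) log mu1
  lv <- 0:255
  W <- cumsum(h)
  S <- cumsum(h * lv)
  tot <- W[256L]; Stot <- S[256L]
  crit <- rep(NA_real_, 256L)
  i <- which(valid_split(h))
  mu0 <- S[i] / W[i]
  mu1 <- (Stot - S[i]) / (tot - W[i])
  v <- -(S[i] * ifelse(mu0 > 0, log(mu0), 0) +
           (Stot - S[i]) * ifelse(mu1 > 0, log(mu1), 0))
  v[mu0 <= 0 | mu1 <= 0] <- NA_real_
  crit[i] <- v
  crit
}

#' Li minimum cross-entropy threshold
#'
#' Minimizes Li's cross entropy between the gray-scale image and its
#' two-level segmented version, eta(t) = -sum(x h(x) log mu(x; t)), where
#' mu assigns each level the mean of its class (background = levels <= t).
#' The global minimizer over all candidate levels is returned; it is the
#' optimum that Li & Tam's fast fixed-point update approximates.
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_li <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Li"); if (!is.null(d)) return(d)
  new_level(scan_optimum(li_criterion(h), maximize = FALSE), "Li")
}

kapur_criterion <- function(h) {
  p <- h / sum(h)
  P <- cumsum(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  S <- cumsum(plogp)           # sum of p log p over levels <= t
  Stot <- S[256L]
  ok <- valid_split(h)
  crit <- rep(NA_real_, 256L)
  i <- which(ok)
  Hb <- log(P[i]) - S[i] / P[i]
  Hf <- log(1 - P[i]) - (Stot - S[i]) / (1 - P[i])
  crit[i] <- Hb + Hf
  crit
}

#' Kapur maximum-entropy threshold
#'
#' Maximizes the sum of the Shannon entropies of the background and
#' foreground gray-level distributions.
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_max_entropy <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "MaxEntropy"); if (!is.null(d)) return(d)
  new_level(scan_optimum(kapur_criterion(h), maximize = TRUE), "MaxEntropy")
}

#' Mean threshold
#'
#' The floor of the intensity-weighted mean gray level.
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_mean <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Mean"); if (!is.null(d)) return(d)
  lv <- 0:255
  new_level(as.integer(floor(sum(h * lv) / sum(h))), "Mean")
}

#' Tsai moment-preserving threshold
#'
#' Solves for the two-level image whose first three moments match those of
#' the input histogram; the implied background fraction p0 is then realized
#' as the level whose cumulative histogram mass is closest to p0.
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_moments <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Moments"); if (!is.null(d)) return(d)
  p <- h / sum(h)
  lv <- 0:255
  m1 <- sum(p * lv); m2 <- sum(p * lv^2); m3 <- sum(p * lv^3)
  cd <- m2 - m1^2
  if (cd <= 0) stop("zero-variance histogram not caught as degenerate")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- sqrt(max(c1^2 - 4 * c0, 0))
  z0 <- 0.5 * (-c1 - disc)
  z1 <- 0.5 * (-c1 + disc)
  p0 <- (z1 - m1) / (z1 - z0)
  P <- cumsum(p)
  crit <- rep(NA_real_, 256L)
  ok <- valid_split(h)
  crit[ok] <- abs(P[ok] - p0)
  new_level(scan_optimum(crit, maximize = FALSE), "Moments")
}

otsu_criterion <- function(h) {
  # within-class variance (to be minimized)
  p <- h / sum(h)
  lv <- 0:255
  P <- cumsum(p)
  M <- cumsum(p * lv)
  M2 <- cumsum(p * lv^2)
  ok <- valid_split(h)
  crit <- rep(NA_real_, 256L)
  i <- which(ok)
  w0 <- P[i]; w1 <- 1 - w0
  mu0 <- M[i] / w0; mu1 <- (M[256L] - M[i]) / w1
  v0 <- M2[i] / w0 - mu0^2
  v1 <- (M2[256L] - M2[i]) / w1 - mu1^2
  crit[i] <- w0 * v0 + w1 * v1
  crit
}

#' Otsu threshold
#'
#' Minimizes the weighted within-class intensity variance (equivalently,
#' maximizes the between-class variance).
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_otsu <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Otsu"); if (!is.null(d)) return(d)
  new_level(scan_optimum(otsu_criterion(h), maximize = FALSE), "Otsu")
}

#' Percentile (Doyle) threshold
#'
#' Selects the lowest level t whose foreground fraction (histogram mass at
#' levels > t) is closest to 0.5.
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_percentile <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Percentile"); if (!is.null(d)) return(d)
  P <- cumsum(h) / sum(h)
  crit <- rep(NA_real_, 256L)
  ok <- valid_split(h)
  crit[ok] <- abs((1 - P[ok]) - 0.5)
  new_level(scan_optimum(crit, maximize = FALSE), "Percentile")
}

renyi_alpha_criterion <- function(h, alpha) {
  if (alpha == 1) return(kapur_criterion(h))
  p <- h / sum(h)
  P <- cumsum(p)
  A <- cumsum(p^alpha)
  Atot <- A[256L]
  ok <- valid_split(h)
  crit <- rep(NA_real_, 256L)
  i <- which(ok)
  crit[i] <- (log(A[i] / P[i]^alpha) + log((Atot - A[i]) / (1 - P[i])^alpha)) /
    (1 - alpha)
  crit
}

#' Renyi-entropy threshold (Sahoo three-order rule)
#'
#' Computes the entropy-maximizing level under Renyi orders 1/2, 1 and 2,
#' then combines the three sorted candidates with the published weighting
#' rule (weights depend on how close the candidates are, window of 5
#' levels) into the final threshold.
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_renyi_entropy <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "RenyiEntropy"); if (!is.null(d)) return(d)
  ts <- sort(c(scan_optimum(renyi_alpha_criterion(h, 1),   maximize = TRUE),
               scan_optimum(renyi_alpha_criterion(h, 0.5), maximize = TRUE),
               scan_optimum(renyi_alpha_criterion(h, 2),   maximize = TRUE)))
  t1 <- ts[1L]; t2 <- ts[2L]; t3 <- ts[3L]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) b <- c(1, 2, 1) else b <- c(0, 1, 3)
  } else {
    if (abs(t2 - t3) <= 5) b <- c(3, 1, 0) else b <- c(1, 2, 1)
  }
  P <- cumsum(h) / sum(h)
  P1 <- function(t) P[t + 1L]
  omega <- P1(t3) - P1(t1)
  t_opt <- t1 * (P1(t1) + 0.25 * omega * b[1L]) +
    0.25 * t2 * omega * b[2L] +
    t3 * ((1 - P1(t3)) + 0.25 * omega * b[3L])
  new_level(as.integer(t_opt), "RenyiEntropy")
}

shanbhag_criterion <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  P2 <- 1 - P1
  ok <- valid_split(h)
  crit <- rep(NA_real_, 256L)
  for (t in which(ok) - 1L) {
    i <- t + 1L
    term_b <- 0.5 / P1[i]
    ib <- seq_len(i)[-1L]               # bins 2..i  (levels 1..t)
    ent_back <- if (length(ib))
      -sum(p[ib] * log(1 - term_b * P1[ib - 1L])) * term_b else 0
    term_f <- 0.5 / P2[i]
    io <- if (i + 1L <= 255L) (i + 1L):255L else integer(0)  # levels t+1..254
    ent_obj <- if (length(io))
      -sum(p[io] * log(1 - term_f * P2[io + 1L])) * term_f else 0
    crit[i] <- abs(ent_back - ent_obj)
  }
  crit
}

#' Shanbhag threshold
#'
#' Minimizes the absolute difference between the fuzzy information measures
#' of the background and foreground classes.
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_shanbhag <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Shanbhag"); if (!is.null(d)) return(d)
  new_level(scan_optimum(shanbhag_criterion(h), maximize = FALSE), "Shanbhag")
}

yen_criterion <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  S1 <- cumsum(p^2)
  Stot <- S1[256L]
  ok <- valid_split(h)
  crit <- rep(NA_real_, 256L)
  i <- which(ok)
  a <- S1[i] * (Stot - S1[i])
  bq <- P1[i] * (1 - P1[i])
  crit[i] <- ifelse(a > 0, -log(a), 0) + ifelse(bq > 0, 2 * log(bq), 0)
  crit
}

#' Yen maximum-correlation threshold
#'
#' Maximizes Yen's correlation criterion built from the squared class
#' probability masses.
#'
#' @inheritParams threshold_default_isodata
#' @return a `threshold_level`.
#' @export
threshold_yen <- function(h) {
  h <- check_histogram(h)
  d <- degenerate_level(h, "Yen"); if (!is.null(d)) return(d)
  new_level(scan_optimum(yen_criterion(h), maximize = TRUE), "Yen")
}

#' Fixed threshold per plexus
#'
#' Plexus-specific fixed levels for healthy 3 x 3 mm fields:
#' 65 for SCP and DCP, 85 for CC.  An explicit `value` overrides the
#' default (used for fixed-threshold sweeps).
#'
#' @param plexus one of `"SCP"`, `"DCP"`, `"CC"`.
#' @param value optional override level in 0..255.
#' @return a `threshold_level`.
#' @export
threshold_fixed <- function(plexus = c("SCP", "DCP", "CC"), value = NULL) {
  if (!is.null(value)) {
    if (value < 0 || value > 255) stop("fixed threshold must lie in [0, 255]")
    return(new_level(value, "Fixed"))
  }
  plexus <- match.arg(plexus)
  new_level(switch(plexus, SCP = 65L, DCP = 65L, CC = 85L), "Fixed")
}

#' Compute a threshold by method name
#'
#' @param h 256-bin histogram.
#' @param method one of [octa_methods()].
#' @param plexus plexus name, required when `method = "Fixed"`.
#' @param fixed_value optional override for the fixed level.
#' @return a `threshold_level`.
#' @export
auto_threshold <- function(h, method, plexus = NULL, fixed_value = NULL) {
  if (!method %in% octa_methods())
    stop("unknown method '", method, "'; valid methods: ",
         paste(octa_methods(), collapse = ", "))
  switch(method,
    Default      = threshold_default_isodata(h),
    Huang        = threshold_huang(h),
    Intermodes   = threshold_intermodes(h),
    Li           = threshold_li(h),
    MaxEntropy   = threshold_max_entropy(h),
    Mean         = threshold_mean(h),
    Moments      = threshold_moments(h),
    Otsu         = threshold_otsu(h),
    Percentile   = threshold_percentile(h),
    RenyiEntropy = threshold_renyi_entropy(h),
    Shanbhag     = threshold_shanbhag(h),
    Yen          = threshold_yen(h),
    Fixed        = threshold_fixed(plexus, fixed_value))
}

#' Apply a threshold to an 8-bit image
#'
#' @param img integer matrix with values in 0..255.
#' @param t a `threshold_level` or a bare numeric level.
#' @return logical matrix; `TRUE` where intensity is strictly greater
#'   than `t` (vessel foreground).
#' @export
apply_threshold <- function(img, t) {
  if (inherits(t, "threshold_level")) t <- t$t
  if (length(t) != 1L || t < 0 || t > 255) stop("threshold must be a single level in [0, 255]")
  m <- img > t
  storage.mode(m) <- "logical"
  m
}
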