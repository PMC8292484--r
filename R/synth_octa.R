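# Seeded synthetic OCTA angiograms with ground-truth vessel and FAZ masks.
#
# SCP/DCP eyes are grown as biased random walkers: capillaries enter from
# the image border, wander with wrapped-Gaussian direction noise and a mild
# pull toward the fovea, branch stochastically, and terminate on an
# irregular FAZ contour lined by a perifoveal arcade.  The CC is a granular
# band-pass noise texture with no FAZ.  Multiplicative speckle and additive
# sensor noise are applied after ground truth is recorded.

#' Parameters of a synthetic capillary plexus
#'
#' @param plexus one of `"SCP"`, `"DCP"`, `"CC"`.
#' @param image_size square image side in pixels (>= 64).
#' @param n_seed_vessels number of capillaries entering from the border
#'   (SCP/DCP; ignored for CC).
#' @param branch_prob per-step branching probability of a walker.
#' @param vessel_radius_px mean capillary radius in pixels.
#' @param vessel_radius_jitter SD of the per-walker radius perturbation.
#' @param faz_radius_px mean FAZ radius in pixels (SCP/DCP; must stay below
#'   `image_size / 4`).
#' @param faz_irregularity relative amplitude of the sinusoidal + random
#'   perturbation of the FAZ contour radius.
#' @param vessel_intensity mean gray of the capillary centerline (0..255).
#' @param background_intensity mean gray of avascular tissue (0..255).
#' @param speckle_sigma scale of the multiplicative (log-normal) speckle.
#' @param sensor_sd SD of the additive sensor noise, gray levels.
#' @param cc_density foreground area fraction targeted by the CC texture.
#' @param tortuosity_sd SD (radians) of the per-step direction perturbation.
#' @param vessel_brightness_sdlog log-SD of the per-capillary brightness
#'   (flow-dependent decorrelation varies between capillaries).
#' @param faz_attenuation multiplicative intensity factor inside the FAZ:
#'   the truly avascular fovea carries no flow decorrelation at any depth
#'   and images darker than generic background (SCP/DCP only).
#' @param n_large_vessels number of large radial vessels (arterioles and
#'   venules in SCP; their projections in DCP).
#' @param large_vessel_radius_px radius of the large vessels in pixels.
#' @param large_vessel_intensity mean centerline gray of the large vessels.
#' @param seed integer RNG seed; same params + seed give bit-identical eyes.
#' @return a validated `plexus_params` object.
#' @export
plexus_params <- function(plexus = c("SCP", "DCP", "CC"),
                          image_size = 320L,
                          n_seed_vessels = NULL,
                          branch_prob = 0.045,
                          vessel_radius_px = NULL,
                          vessel_radius_jitter = 0.3,
                          faz_radius_px = NULL,
                          faz_irregularity = 0.15,
                          vessel_intensity = NULL,
                          background_intensity = NULL,
                          speckle_sigma = NULL,
                          sensor_sd = 5,
                          cc_density = 0.55,
                          tortuosity_sd = 0.22,
                          vessel_brightness_sdlog = 0.15,
                          faz_attenuation = 0.7,
                          n_large_vessels = NULL,
                          large_vessel_radius_px = NULL,
                          large_vessel_intensity = NULL,
                          seed = 1L) {
  plexus <- match.arg(plexus)
  def <- switch(plexus,
    SCP = list(n_seed_vessels = 26L, vessel_radius_px = 1.7,
               faz_radius_px = 32, vessel_intensity = 115,
               background_intensity = 38, speckle_sigma = 0.33,
               n_large_vessels = 4L, large_vessel_radius_px = 3.5,
               large_vessel_intensity = 175),
    DCP = list(n_seed_vessels = 34L, vessel_radius_px = 1.4,
               faz_radius_px = 36, vessel_intensity = 112,
               background_intensity = 40, speckle_sigma = 0.33,
               n_large_vessels = 3L, large_vessel_radius_px = 2.5,
               large_vessel_intensity = 165),
    CC  = list(n_seed_vessels = 0L, vessel_radius_px = 1.3,
               faz_radius_px = 0, vessel_intensity = 165,
               background_intensity = 55, speckle_sigma = 0.25,
               n_large_vessels = 0L, large_vessel_radius_px = 0,
               large_vessel_intensity = 0))
  fill <- function(x, nm) if (is.null(x)) def[[nm]] else x
  p <- structure(list(
    plexus = plexus, image_size = as.integer(image_size),
    n_seed_vessels = as.integer(fill(n_seed_vessels, "n_seed_vessels")),
    branch_prob = branch_prob,
    vessel_radius_px = fill(vessel_radius_px, "vessel_radius_px"),
    vessel_radius_jitter = vessel_radius_jitter,
    faz_radius_px = fill(faz_radius_px, "faz_radius_px"),
    faz_irregularity = faz_irregularity,
    vessel_intensity = fill(vessel_intensity, "vessel_intensity"),
    background_intensity = fill(background_intensity, "background_intensity"),
    speckle_sigma = fill(speckle_sigma, "speckle_sigma"),
    sensor_sd = sensor_sd,
    cc_density = cc_density, tortuosity_sd = tortuosity_sd,
    vessel_brightness_sdlog = vessel_brightness_sdlog,
    faz_attenuation = faz_attenuation,
    n_large_vessels = as.integer(fill(n_large_vessels, "n_large_vessels")),
    large_vessel_radius_px = fill(large_vessel_radius_px, "large_vessel_radius_px"),
    large_vessel_intensity = fill(large_vessel_intensity, "large_vessel_intensity"),
    seed = as.integer(seed)), class = "plexus_params")
  validate_plexus_params(p)
  p
}

validate_plexus_params <- function(p) {
  if (p$image_size < 64L) stop("image_size must be at least 64 pixels")
  ints <- c(p$vessel_intensity, p$background_intensity)
  if (any(ints < 0 | ints > 255)) stop("intensities must lie in [0, 255]")
  if (p$vessel_intensity <= p$background_intensity)
    stop("vessel_intensity must exceed background_intensity")
  if (p$plexus != "CC" && p$faz_radius_px >= p$image_size / 4)
    stop("faz_radius_px must be below image_size / 4")
  if (p$n_seed_vessels < 0) stop("n_seed_vessels must be non-negative")
  if (p$plexus == "CC" && (p$cc_density <= 0 || p$cc_density >= 1))
    stop("cc_density must lie in (0, 1)")
  if (p$branch_prob < 0 || p$branch_prob > 1) stop("branch_prob must be a probability")
  if (p$faz_attenuation <= 0 || p$faz_attenuation > 1)
    stop("faz_attenuation must lie in (0, 1]")
  invisible(p)
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# FAZ contour radius as a function of polar angle
faz_contour_fun <- function(radius, irregularity) {
  amp <- runif(3, 0.3, 1)
  ph <- runif(3, 0, 2 * pi)
  ks <- c(2L, 3L, 5L)
  function(theta) {
    pert <- amp[1] * sin(ks[1] * theta + ph[1]) +
      amp[2] * sin(ks[2] * theta + ph[2]) +
      amp[3] * sin(ks[3] * theta + ph[3])
    radius * (1 + irregularity * pert / sum(amp))
  }
}

# grow all walkers simultaneously; returns list(px = n x 3 matrix of
# (row, col, walker), radius = per-walker radius)
grow_walkers <- function(p, center, contour) {
  size <- p$image_size
  n0 <- p$n_seed_vessels
  if (n0 == 0L) return(list(px = matrix(numeric(0), 0, 3), radius = numeric(0)))
  max_walkers <- 8L * n0
  side <- sample(4L, n0, replace = TRUE)
  u <- runif(n0, 2, size - 1)
  r0 <- ifelse(side == 1L, 2, ifelse(side == 2L, size - 1, u))
  c0 <- ifelse(side == 3L, 2, ifelse(side == 4L, size - 1, u))
  dir <- atan2(center[1] - r0, c0 * 0 + center[2] - c0) + rnorm(n0, 0, 0.35)
  rad <- pmax(p$vessel_radius_px + rnorm(n0, 0, p$vessel_radius_jitter), 0.9)
  pos_r <- r0; pos_c <- c0
  alive <- rep(TRUE, n0)
  rec <- vector("list", 0L)
  max_steps <- as.integer(2.5 * size)
  for (step in seq_len(max_steps)) {
    idx <- which(alive)
    if (length(idx) == 0L) break
    # pull toward the fovea keeps trajectories converging without rails
    to_cen <- atan2(center[1] - pos_r[idx], center[2] - pos_c[idx])
    dir[idx] <- dir[idx] + 0.05 * wrap_angle(to_cen - dir[idx]) +
      rnorm(length(idx), 0, p$tortuosity_sd)
    pos_r[idx] <- pos_r[idx] - sin(dir[idx])
    pos_c[idx] <- pos_c[idx] + cos(dir[idx])
    rec[[length(rec) + 1L]] <- cbind(pos_r[idx], pos_c[idx], idx)
    # terminate: off image or at the FAZ contour
    th <- atan2(center[1] - pos_r[idx], pos_c[idx] - center[2])
    d_cen <- sqrt((pos_r[idx] - center[1])^2 + (pos_c[idx] - center[2])^2)
    stop_now <- pos_r[idx] < 2 | pos_r[idx] > size - 1 |
      pos_c[idx] < 2 | pos_c[idx] > size - 1 |
      d_cen <= contour(th) + 0.5
    alive[idx[stop_now]] <- FALSE
    # branching
    idx <- which(alive)
    nw <- length(pos_r)
    if (length(idx) > 0L && nw < max_walkers) {
      born <- idx[runif(length(idx)) < p$branch_prob]
      born <- born[seq_len(min(length(born), max_walkers - nw))]
      if (length(born) > 0L) {
        k <- length(born)
        pos_r <- c(pos_r, pos_r[born]); pos_c <- c(pos_c, pos_c[born])
        dir <- c(dir, dir[born] + sample(c(-1, 1), k, TRUE) * runif(k, 0.35, 1.0))
        rad <- c(rad, pmax(rad[born] * 0.85, 0.9))
        alive <- c(alive, rep(TRUE, k))
      }
    }
  }
  px <- do.call(rbind, rec)
  list(px = px, radius = rad)
}

stamp_discs <- function(size, px, radius) {
  # px: (row, col, walker); radius: per-walker; returns logical mask
  mask <- matrix(FALSE, size, size)
  if (nrow(px) == 0L) return(mask)
  for (r_target in unique(round(radius, 1))) {
    wids <- which(round(radius, 1) == r_target)
    pts <- px[px[, 3] %in% wids, , drop = FALSE]
    if (nrow(pts) == 0L) next
    rr <- max(r_target, 0.5)
    span <- seq(-ceiling(rr), ceiling(rr))
    offs <- expand.grid(dr = span, dc = span)
    offs <- offs[offs$dr^2 + offs$dc^2 <= rr^2 + 0.25, ]
    i <- rep(round(pts[, 1]), each = nrow(offs)) + offs$dr
    j <- rep(round(pts[, 2]), each = nrow(offs)) + offs$dc
    ok <- i >= 1 & i <= size & j >= 1 & j <= size
    mask[cbind(i[ok], j[ok])] <- TRUE
  }
  mask
}

centerline_mask <- function(size, px) {
  m <- matrix(FALSE, size, size)
  if (nrow(px) == 0L) return(m)
  i <- round(px[, 1]); j <- round(px[, 2])
  ok <- i >= 1 & i <= size & j >= 1 & j <= size
  m[cbind(i[ok], j[ok])] <- TRUE
  m
}

#' Generate one synthetic plexus image with ground truth
#'
#' @param params a [plexus_params()] object.
#' @return a `synthetic_eye`: list with `image` (integer matrix 0..255),
#'   `vessel_truth`, `faz_truth` (logical matrices recorded before noise),
#'   `center` (row, col of the fovea) and `params`.
#' @export
generate_plexus <- function(params) {
  validate_plexus_params(params)
  withr::with_seed(params$seed, {
    if (params$plexus == "CC") generate_cc(params) else generate_scp_dcp(params)
  })
}

generate_scp_dcp <- function(p) {
  size <- p$image_size
  center <- round(size / 2 + runif(2, -size / 50, size / 50))
  contour <- faz_contour_fun(p$faz_radius_px, p$faz_irregularity)
  gw <- grow_walkers(p, center, contour)
  n_cap <- length(gw$radius)

  # large radial vessels: near-straight, thick, bright
  if (p$n_large_vessels > 0L) {
    pL <- p
    pL$n_seed_vessels <- p$n_large_vessels
    pL$tortuosity_sd <- 0.06
    pL$branch_prob <- 0.01
    pL$vessel_radius_px <- p$large_vessel_radius_px
    pL$vessel_radius_jitter <- 0.5
    gl <- grow_walkers(pL, center, contour)
    if (nrow(gl$px) > 0) gl$px[, 3] <- gl$px[, 3] + n_cap
  } else {
    gl <- list(px = matrix(numeric(0), 0, 3), radius = numeric(0))
  }

  # perifoveal arcade: a capillary ring tracing the FAZ contour (absent
  # when the plexus carries no vessels at all)
  if (n_cap + length(gl$radius) > 0L) {
    th <- seq(0, 2 * pi, length.out = max(64L, ceiling(2 * pi * p$faz_radius_px * 1.5)))
    ring_r <- contour(th) + p$vessel_radius_px
    ring <- cbind(center[1] - ring_r * sin(th), center[2] + ring_r * cos(th),
                  n_cap + length(gl$radius) + 1L)
    px <- rbind(gw$px, gl$px, ring)
    radius <- c(gw$radius, gl$radius, max(p$vessel_radius_px * 0.9, 0.9))
  } else {
    px <- matrix(numeric(0), 0, 3)
    radius <- numeric(0)
  }
  nw <- length(radius)

  # per-walker brightness: capillary decorrelation varies between vessels;
  # large vessels sit near the top of the (unsaturated) dynamic range
  bright <- pmin(rlnorm(nw, log(p$vessel_intensity), p$vessel_brightness_sdlog), 250)
  if (length(gl$radius) > 0)
    bright[n_cap + seq_along(gl$radius)] <-
      pmin(rnorm(length(gl$radius), p$large_vessel_intensity, 8), 250)
  bright[nw] <- p$vessel_intensity  # arcade at typical capillary brightness

  vessel <- stamp_discs(size, px, radius)
  cl <- centerline_mask(size, px)

  # FAZ truth: pixels strictly inside the irregular contour
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dth <- atan2(center[1] - rows, cols - center[2])
  dcen <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  faz <- dcen < contour(dth)
  vessel <- vessel & !faz

  # brightness and caliber of the nearest centerline, interpolated by
  # normalized convolution; Gaussian cross-section profile on top
  S <- matrix(0, size, size); Rsrc <- matrix(0, size, size)
  i <- round(px[, 1]); j <- round(px[, 2])
  ok <- i >= 1 & i <= size & j >= 1 & j <= size
  for (k in which(ok)) {
    if (bright[px[k, 3]] > S[i[k], j[k]]) {
      S[i[k], j[k]] <- bright[px[k, 3]]
      Rsrc[i[k], j[k]] <- radius[px[k, 3]]
    }
  }
  clean_base <- if (any(cl)) {
    d <- as.matrix(EBImage::distmap(EBImage::Image(1 - cl)))
    num <- as.matrix(EBImage::gblur(EBImage::Image(S), 2))
    den <- pmax(as.matrix(EBImage::gblur(EBImage::Image(cl * 1), 2)), 1e-8)
    v_eff <- num / den
    r_eff <- pmax(as.matrix(EBImage::gblur(EBImage::Image(Rsrc), 2)) / den, 0.8)
    prof <- exp(-d^2 / (2 * r_eff^2))
    p$background_intensity + pmax(v_eff - p$background_intensity, 0) * prof
  } else matrix(p$background_intensity, size, size)
  clean_base[faz] <- clean_base[faz] * p$faz_attenuation
  img <- apply_noise(clean_base, p)
  new_synthetic_eye(img, vessel, faz, center, p)
}

generate_cc <- function(p) {
  size <- p$image_size
  z <- matrix(rnorm(size * size), size, size)
  band <- as.matrix(EBImage::gblur(EBImage::Image(z), sigma = 1.3)) -
    as.matrix(EBImage::gblur(EBImage::Image(z), sigma = 5))
  band <- (band - mean(band)) / sd(band)
  truth <- band > stats::quantile(band, 1 - p$cc_density)
  clean <- p$background_intensity +
    (p$vessel_intensity - p$background_intensity) * stats::pnorm(1.4 * band)
  img <- apply_noise(clean, p)
  center <- round(c(size / 2, size / 2))
  new_synthetic_eye(img, truth, matrix(FALSE, size, size), center, p)
}

apply_noise <- function(clean, p) {
  n <- length(clean)
  speck <- exp(rnorm(n, 0, p$speckle_sigma) - p$speckle_sigma^2 / 2)
  img <- clean * matrix(speck, nrow(clean)) +
    matrix(rnorm(n, 0, p$sensor_sd), nrow(clean))
  # soft shoulder: linear response up to 180, exponential roll-off to 255,
  # emulating device log-compression (no saturation spike)
  hi <- img > 180
  img[hi] <- 180 + 75 * (1 - exp(-(img[hi] - 180) / 75))
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  img
}

new_synthetic_eye <- function(img, vessel, faz, center, params, eye_id = NULL) {
  structure(list(image = img, vessel_truth = vessel, faz_truth = faz,
                 center = as.integer(center), params = params,
                 eye_id = eye_id),
            class = "synthetic_eye")
}

#' @export
print.synthetic_eye <- function(x, ...) {
  cat(sprintf("<synthetic_eye> %s %dx%d, vessel fraction %.3f, FAZ %d px\n",
              x$params$plexus, nrow(x$image), ncol(x$image),
              mean(x$vessel_truth), sum(x$faz_truth)))
  invisible(x)
}

#' Generate a cohort of synthetic eyes
#'
#' Each eye is a triple of SCP, DCP and CC images sharing an eye id.  Eye
#' level biological variability is emulated by jittering the base
#' parameters (capillary count, FAZ radius, intensities, speckle) with a
#' seeded RNG, so a cohort is fully reproducible from its seed.
#'
#' @param n_eyes number of eyes (>= 1).
#' @param seed cohort seed.
#' @param base_params optional named list with entries `SCP`, `DCP`, `CC`
#'   of [plexus_params()] to use as jitter centers.
#' @return list of eyes; each eye is a list with `eye_id` and
#'   `synthetic_eye` elements `SCP`, `DCP`, `CC`.
#' @export
generate_cohort <- function(n_eyes, seed = 1L, base_params = NULL) {
  if (n_eyes < 1) stop("n_eyes must be at least 1")
  if (is.null(base_params))
    base_params <- list(SCP = plexus_params("SCP"), DCP = plexus_params("DCP"),
                        CC = plexus_params("CC"))
  jit <- withr::with_seed(seed, {
    list(seeds = matrix(sample.int(.Machine$integer.max - 1L, 3L * n_eyes),
                        nrow = n_eyes),
         n_scale = runif(n_eyes, 0.85, 1.15),
         faz_scale = runif(n_eyes, 0.9, 1.1),
         int_shift = rnorm(n_eyes, 0, 6),
         bg_shift = rnorm(n_eyes, 0, 3),
         speckle_scale = runif(n_eyes, 0.9, 1.1),
         dens_shift = runif(n_eyes, -0.04, 0.04))
  })
  lapply(seq_len(n_eyes), function(i) {
    eye_id <- sprintf("eye%03d", i)
    triple <- lapply(c("SCP", "DCP", "CC"), function(plx) {
      b <- base_params[[plx]]
      b$n_seed_vessels <- as.integer(round(b$n_seed_vessels * jit$n_scale[i]))
      b$faz_radius_px <- b$faz_radius_px * jit$faz_scale[i]
      b$vessel_intensity <- min(max(b$vessel_intensity + jit$int_shift[i],
                                    b$background_intensity + 20), 255)
      b$background_intensity <- max(b$background_intensity + jit$bg_shift[i], 0)
      b$speckle_sigma <- b$speckle_sigma * jit$speckle_scale[i]
      if (plx == "CC") b$cc_density <- min(max(b$cc_density + jit$dens_shift[i],
                                               0.05), 0.95)
      b$seed <- jit$seeds[i, match(plx, c("SCP", "DCP", "CC"))]
      eye <- generate_plexus(b)
      eye$eye_id <- eye_id
      eye
    })
    names(triple) <- c("SCP", "DCP", "CC")
    c(list(eye_id = eye_id), triple)
  })
}
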