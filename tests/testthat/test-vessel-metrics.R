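blank <- function(n = 64) matrix(FALSE, n, n)

draw_bar <- function(m, rows, cols) { m[rows, cols] <- TRUE; m }

quarter_circle_mask <- function(r = 40, thick = 1.2, size = 64) {
  m <- blank(size)
  cen <- c(size - 6, 6)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    d <- sqrt((i - cen[1])^2 + (j - cen[2])^2)
    ang <- atan2(cen[1] - i, j - cen[2])
    if (abs(d - r) <= thick && ang >= 0 && ang <= pi / 2) m[i, j] <- TRUE
  }
  m
}

test_that("vessel density counts foreground over evaluable pixels", {
  expect_equal(vessel_density(matrix(TRUE, 8, 8)), 1.0)
  expect_equal(vessel_density(blank(8)), 0.0)
  withr::with_seed(5, {
    m <- blank(10); m[sample(100, 37)] <- TRUE
    expect_equal(vessel_density(m), 0.37)
  })
  # exclusion removes pixels from numerator and denominator
  m <- blank(10); m[1:5, ] <- TRUE
  ex <- blank(10); ex[1:10, 1:5] <- TRUE
  expect_equal(vessel_density(m, ex), 25 / 50)
  expect_error(vessel_density(m, matrix(TRUE, 10, 10)), "no evaluable")
})

test_that("skeleton of a thick bar is a single near-straight branch inside the mask", {
  m <- draw_bar(blank(), 30:32, 8:57)   # 3 px thick, 50 px long
  g <- skeletonize(m)
  expect_equal(length(g$branches), 1L)
  b <- g$branches[[1]]
  expect_lte(abs(b$arc_length - b$chord_length), 2)
  expect_gte(b$chord_length, 50 - 4)    # end effects only
  expect_true(all(m[g$skeleton]))       # skeleton subset of mask
  expect_equal(skeletonize(blank())$branches, list())
})

test_that("crossing bars decompose into four branches at one junction", {
  m <- draw_bar(blank(), 31:33, 10:55)
  m <- draw_bar(m, 10:55, 31:33)
  g <- skeletonize(m)
  expect_equal(g$n_junctions, 1L)
  expect_equal(length(g$branches), 4L)
})

test_that("tortuosity is 1 for straight segments and ~1.1107 for a quarter circle", {
  m <- draw_bar(blank(), 20:22, 5:60)
  expect_equal(vessel_tortuosity(skeletonize(m)), 1.0, tolerance = 1e-6)
  # diagonal straight segment at vessel caliber (3 px wide)
  d <- blank()
  for (k in 5:58) { d[k, k] <- TRUE; d[k + 1, k] <- TRUE; d[k, k + 1] <- TRUE }
  expect_lte(abs(vessel_tortuosity(skeletonize(d)) - 1), 0.02)
  vt <- vessel_tortuosity(skeletonize(quarter_circle_mask()))
  expect_lte(abs(vt - pi / (2 * sqrt(2))), 0.05)
})

test_that("tortuosity is the arc-weighted mean of branch ratios", {
  fake <- structure(list(skeleton = NULL, n_junctions = 0L, branches = list(
    list(path = NULL, arc_length = 10, arc_calibrated = 10,
         chord_length = 10, is_loop = FALSE),
    list(path = NULL, arc_length = 10, arc_calibrated = 10,
         chord_length = 10 / 1.5, is_loop = FALSE))),
    class = "skeleton_graph")
  expect_equal(vessel_tortuosity(fake), 1.25)
  empty <- structure(list(skeleton = NULL, branches = list(), n_junctions = 0L),
                     class = "skeleton_graph")
  expect_true(is.na(vessel_tortuosity(empty)))
})

test_that("dispersion is 0 for parallel skeletons and maximal for a 0/90 mix", {
  horiz <- draw_bar(draw_bar(blank(), 10, 5:60), 40, 5:60)
  expect_equal(vessel_dispersion(skeletonize(horiz)), 0, tolerance = 1e-8)
  expect_equal(axial_dispersion(c(rep(0, 500), rep(90, 500))),
               axial_dispersion_max())
})

test_that("uniform orientations reach the analytic axial dispersion", {
  withr::with_seed(42, ang <- runif(10000, 0, 180))
  # closed form at R = 0: (180/pi) * sqrt(2) / 2
  expect_lte(abs(axial_dispersion(ang) - axial_dispersion_max()), 2)
})

test_that("VT and Vdisp are invariant under a 90-degree mask rotation", {
  # disjoint arc + bar at full vessel caliber: no junctions, so the only
  # asymmetry left is the thinning discretization itself
  m <- quarter_circle_mask(34, 1.6, size = 80)
  m <- draw_bar(m, 16:18, 30:64)
  rot <- t(m)[ncol(m):1, ]
  g1 <- skeletonize(m); g2 <- skeletonize(rot)
  expect_lte(abs(vessel_tortuosity(g1) - vessel_tortuosity(g2)), 0.03)
  expect_lte(abs(vessel_dispersion(g1) - vessel_dispersion(g2)), 2)
})

test_that("VD is non-increasing in the threshold (mask nesting)", {
  withr::with_seed(21, img <- matrix(sample(0:255, 2500, TRUE), 50, 50))
  vd <- vapply(seq(15, 85, 10),
               function(t) vessel_density(apply_threshold(img, t)), numeric(1))
  expect_true(all(diff(vd) <= 0))
})
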