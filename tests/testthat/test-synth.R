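test_that("generation is deterministic for identical params and seed", {
  p <- plexus_params("SCP", seed = 42)
  e1 <- generate_plexus(p)
  e2 <- generate_plexus(p)
  expect_identical(e1$image, e2$image)
  expect_identical(e1$vessel_truth, e2$vessel_truth)
  expect_identical(e1$faz_truth, e2$faz_truth)
  # a different seed changes the image
  e3 <- generate_plexus(plexus_params("SCP", seed = 43))
  expect_false(identical(e1$image, e3$image))
})

test_that("generated SCP eyes satisfy the structural invariants", {
  eye <- generate_plexus(plexus_params("SCP", seed = 1))
  expect_equal(sum(eye$vessel_truth & eye$faz_truth), 0)  # FAZ avascularity
  expect_true(all(eye$image >= 0 & eye$image <= 255))
  expect_true(is.integer(eye$image))
  frac <- mean(eye$vessel_truth)
  expect_gte(frac, 0.25); expect_lte(frac, 0.55)
  # intensity ordering at default noise
  expect_gt(mean(eye$image[eye$vessel_truth]), mean(eye$image[!eye$vessel_truth]))
  # FAZ is one connected region containing the center
  lab <- EBImage::bwlabel(EBImage::Image(eye$faz_truth * 1))
  lab <- matrix(as.integer(lab), nrow(eye$faz_truth))
  expect_equal(max(lab), 1L)
  expect_true(eye$faz_truth[eye$center[1], eye$center[2]])
})

test_that("zero seed vessels give an empty vessel truth over noisy background", {
  eye <- generate_plexus(plexus_params("SCP", n_seed_vessels = 0,
                                       n_large_vessels = 0, seed = 5))
  expect_equal(sum(eye$vessel_truth), 0)
  expect_gt(stats::sd(as.numeric(eye$image)), 0)  # background is noisy
})

test_that("degenerate parameters are rejected", {
  expect_error(plexus_params("SCP", image_size = 32), "image_size")
  expect_error(plexus_params("SCP", faz_radius_px = 100), "faz_radius_px")
  expect_error(plexus_params("SCP", vessel_intensity = 30,
                             background_intensity = 40), "exceed")
  expect_error(plexus_params("SCP", n_seed_vessels = -2), "non-negative")
  expect_error(plexus_params("CC", cc_density = 1.2), "cc_density")
})

test_that("CC eyes are granular textures with no FAZ", {
  eye <- generate_plexus(plexus_params("CC", seed = 3))
  expect_equal(sum(eye$faz_truth), 0)
  expect_gt(mean(eye$vessel_truth), 0.4)
  expect_lt(mean(eye$vessel_truth), 0.7)
  expect_gt(mean(eye$image[eye$vessel_truth]), mean(eye$image[!eye$vessel_truth]))
})

test_that("cohorts are reproducible and vary across eyes and seeds", {
  c1 <- generate_cohort(2, seed = 7)
  c2 <- generate_cohort(2, seed = 7)
  expect_identical(c1[[1]]$SCP$image, c2[[1]]$SCP$image)
  expect_identical(c1[[2]]$DCP$image, c2[[2]]$DCP$image)
  expect_false(identical(c1[[1]]$SCP$image, c1[[2]]$SCP$image))  # across eyes
  c3 <- generate_cohort(2, seed = 8)
  expect_false(identical(c1[[1]]$SCP$image, c3[[1]]$SCP$image))  # across seeds
  expect_equal(sum(c1[[1]]$CC$faz_truth), 0)
  expect_equal(length(c1), 2L)
})

test_that("eyes round-trip through the on-disk PNG + JSON layout", {
  dir <- withr::local_tempdir()
  eye <- generate_plexus(plexus_params("DCP", image_size = 96,
                                       faz_radius_px = 14, seed = 11))
  eye$eye_id <- "eye001"
  write_eye(eye, dir)
  back <- read_eye(dir, "eye001", "DCP")
  expect_identical(back$image, eye$image)
  expect_identical(back$vessel_truth, eye$vessel_truth)
  expect_identical(back$faz_truth, eye$faz_truth)
  expect_equal(back$params$seed, eye$params$seed)
  expect_equal(back$center, eye$center)
})

test_that("reading rejects malformed masks and handles 16-bit images by policy", {
  dir <- withr::local_tempdir()
  # mask with a mid-gray value
  bad <- matrix(c(0, 0.5, 1, 1), 2, 2)
  png::writePNG(bad, file.path(dir, "bad.png"))
  expect_error(octathresh:::read_mask_png(file.path(dir, "bad.png")),
               "other than")
  # 16-bit image: rescale with warning, or error when configured strict
  img16 <- matrix(seq(0, 1, length.out = 64), 8, 8)
  tiff::writeTIFF(img16, file.path(dir, "deep.tif"), bits.per.sample = 16L)
  expect_warning(octathresh:::read_gray_image(file.path(dir, "deep.tif")),
                 "rescaling")
  expect_error(octathresh:::read_gray_image(file.path(dir, "deep.tif"),
                                            on_16bit = "error"),
               "not allowed")
  expect_error(octathresh:::read_gray_image(file.path(dir, "missing.png")),
               "not found")
})
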