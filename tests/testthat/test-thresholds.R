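two_delta <- function(a, b, wa = 100L, wb = 100L) {
  h <- integer(256); h[a + 1L] <- wa; h[b + 1L] <- h[b + 1L] + wb; h
}

test_that("IsoData bisection finds the symmetric fixed point and matches its oracle", {
  expect_equal(threshold_default_isodata(two_delta(0, 200))$t, 100L)
  d <- threshold_default_isodata(two_delta(37, 37, 10, 0))
  expect_equal(d$t, 37L)
  expect_true(d$degenerate)
  for (s in 1:25) {
    h <- oracle_random_histogram(s)
    expect_equal(threshold_default_isodata(h)$t, oracle_isodata_fixed_point(h),
                 info = paste("seed", s))
  }
})

test_that("Huang fuzziness threshold separates delta peaks and matches exhaustive scan", {
  # equal deltas make the fuzziness flat between the peaks (all memberships 1),
  # so under the lowest-tie rule the scan settles on the lower peak; unequal
  # weights break the tie and give an interior level
  expect_equal(threshold_huang(two_delta(30, 220))$t,
               oracle_scan(two_delta(30, 220), oracle_huang_crit, FALSE))
  t <- threshold_huang(two_delta(30, 220, 120L, 80L))$t
  expect_gte(t, 30); expect_lt(t, 220)
  expect_true(threshold_huang(two_delta(80, 80, 5, 0))$degenerate)
  for (s in 1:25) {
    h <- oracle_random_histogram(s)
    expect_equal(threshold_huang(h)$t,
                 oracle_scan(h, oracle_huang_crit, maximize = FALSE),
                 info = paste("seed", s))
  }
})

test_that("Intermodes returns the mid-mode level and rejects unimodal histograms", {
  expect_equal(threshold_intermodes(two_delta(50, 180))$t, 115L)
  expect_equal(threshold_intermodes(two_delta(60, 196))$t, 128L)
  mono <- as.integer(1:256)  # strictly increasing; smoothing keeps it monotone
  expect_error(threshold_intermodes(mono, max_iter = 500L), "not bimodal")
})

test_that("Li iterative threshold lands within one level of the cross-entropy optimum", {
  expect_true(threshold_li(two_delta(42, 42, 7, 0))$degenerate)
  for (s in 1:25) {
    h <- oracle_random_histogram(s)
    opt <- oracle_scan(h, oracle_li_crit, maximize = FALSE)
    expect_lte(abs(threshold_li(h)$t - opt), 1, label = paste("seed", s, "|t-opt|"))
  }
})

test_that("criterion-scan methods equal their exhaustive oracles on random histograms", {
  cases <- list(
    list(fun = threshold_max_entropy, or = function(h) oracle_scan(h, oracle_kapur_crit, TRUE)),
    list(fun = threshold_otsu,        or = function(h) oracle_scan(h, oracle_otsu_crit, FALSE)),
    list(fun = threshold_percentile,  or = function(h) oracle_scan(h, oracle_percentile_crit, FALSE)),
    list(fun = threshold_yen,         or = function(h) oracle_scan(h, oracle_yen_crit, TRUE)),
    list(fun = threshold_shanbhag,    or = function(h) oracle_scan(h, oracle_shanbhag_crit, FALSE)),
    list(fun = threshold_renyi_entropy, or = oracle_renyi),
    list(fun = threshold_moments,     or = oracle_moments))
  for (s in 1:15) {
    h <- oracle_random_histogram(s)
    for (cs in cases) {
      expect_equal(cs$fun(h)$t, cs$or(h), info = paste("seed", s))
    }
  }
})

test_that("Otsu tie-break picks the lowest level of the optimal plateau", {
  expect_equal(threshold_otsu(two_delta(40, 200))$t, 40L)
})

test_that("Mean threshold is the floor of the weighted mean", {
  expect_equal(threshold_mean(two_delta(0, 100))$t, 50L)
  d <- threshold_mean(two_delta(255, 255, 9, 0))
  expect_equal(d$t, 255L); expect_true(d$degenerate)
  for (s in 1:10) {
    h <- oracle_random_histogram(s)
    expect_equal(threshold_mean(h)$t,
                 as.integer(floor(sum((0:255) * h) / sum(h))))
  }
})

test_that("Percentile threshold halves a uniform histogram exactly", {
  h <- rep(4L, 256)
  t <- threshold_percentile(h)
  expect_equal(t$t, 127L)
  expect_equal(sum(h[(t$t + 2L):256L]) / sum(h), 0.5)
})

test_that("Fixed thresholds follow the per-plexus convention with override", {
  expect_equal(threshold_fixed("SCP")$t, 65L)
  expect_equal(threshold_fixed("DCP")$t, 65L)
  expect_equal(threshold_fixed("CC")$t, 85L)
  expect_equal(threshold_fixed("SCP", value = 45)$t, 45L)
})

test_that("mean/percentile/otsu/default thresholds are shift-equivariant", {
  for (s in 1:8) {
    h2 <- oracle_random_histogram(s)
    h2[207:256] <- 0L                      # keep support in [0,205] so +50 fits
    if (sum(h2 > 0) < 2) h2[c(31, 181)] <- h2[c(31, 181)] + 5L
    hs <- c(integer(50), h2[1:206])        # every level shifted up by 50
    for (f in list(threshold_mean, threshold_percentile,
                   threshold_otsu, threshold_default_isodata)) {
      expect_equal(f(hs)$t, f(h2)$t + 50L)
    }
  }
})

test_that("apply_threshold uses the strict > convention and masks nest", {
  img <- matrix(c(10L, 66L, 65L, 200L), 2, 2, byrow = TRUE)
  expect_equal(apply_threshold(img, threshold_fixed("SCP")),
               matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2, byrow = TRUE))
  expect_false(any(apply_threshold(img, 255)))
  expect_true(all(apply_threshold(matrix(80L, 3, 3), 79)))
  withr::with_seed(11, {
    im <- matrix(sample(0:255, 400, TRUE), 20, 20)
    m1 <- apply_threshold(im, 60); m2 <- apply_threshold(im, 140)
    expect_true(all(m1[m2]))  # higher threshold nested in lower
  })
})

test_that("degenerate-histogram policy is uniform across all automatic methods", {
  h <- integer(256); h[101] <- 42L
  for (m in octa_methods(include_fixed = FALSE)) {
    r <- auto_threshold(h, m)
    expect_equal(r$t, 100L, info = m)
    expect_true(r$degenerate, info = m)
  }
})

test_that("auto_threshold rejects unknown method names with the valid list", {
  expect_error(auto_threshold(rep(1L, 256), "Bogus"), "valid methods")
})

test_that("implemented Otsu agrees with EBImage's Otsu on random images", {
  # independent library cross-check (EBImage::otsu returns a [0,1] level)
  for (s in 1:5) {
    withr::with_seed(s, {
      im <- matrix(sample(0:255, 64 * 64, TRUE, prob = runif(256)^2), 64, 64)
    })
    ours <- threshold_otsu(image_histogram(im))$t
    ref <- EBImage::otsu(EBImage::Image(im / 255), range = c(0, 1), levels = 256)
    expect_lte(abs(ours - round(ref * 255)), 1)
  }
})
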