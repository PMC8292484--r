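small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(3, seed = 77)
    cache
  }
})

test_that("fixed-threshold sweep yields non-increasing VD and Mean reference rows", {
  res <- run_experiment1(small_cohort(), sweep_levels = c(15L, 45L, 85L))
  expect_equal(nrow(res$summary), 3 * 4)  # 3 plexuses x (3 levels + Mean)
  for (plx in c("SCP", "DCP", "CC")) {
    s <- res$summary[res$summary$plexus == plx, ]
    vd <- s$vd_mean[match(sprintf("Fixed %d", c(15, 45, 85)), s$threshold)]
    expect_true(all(diff(vd) <= 0), info = plx)
  }
  one <- run_experiment1(small_cohort()[1], sweep_levels = 40L,
                         include_mean = FALSE)
  expect_equal(nrow(one$summary), 3)
  expect_true(all(one$summary$vd_sd == 0))
  expect_error(run_experiment1(small_cohort(), sweep_levels = integer(0)),
               "non-empty")
})

test_that("experiment 2 produces one record per eye/plexus/method", {
  res <- run_experiment2(small_cohort(), metrics = FALSE)
  expect_equal(nrow(res$records), 3 * 3 * 13)
  expect_equal(nrow(res$quality_summary), 3 * 13)
  expect_true(all(res$records$quality %in% 0:2))
  expect_false(is.null(res$fixed_vs_mean))
  expect_equal(nrow(res$fixed_vs_mean), 3)
  expect_error(run_experiment2(small_cohort(), methods = c("Otsu", "Sobel")),
               "valid names")
})

test_that("experiment 3 covers SCP/DCP only and categories partition the cohort", {
  res <- run_experiment3(small_cohort(), methods = c("Fixed", "MaxEntropy"))
  expect_setequal(unique(res$records$plexus), c("SCP", "DCP"))
  expect_equal(nrow(res$records), 3 * 2 * 2)
  for (m in c("Fixed", "MaxEntropy")) for (plx in c("SCP", "DCP")) {
    s <- res$summary[res$summary$method == m & res$summary$plexus == plx, ]
    expect_equal(sum(s$n_eyes), 3L)
  }
  expect_error(run_experiment3(small_cohort(), methods = "Sobel"), "valid names")
})

test_that("paired t-test matches the closed form on a 4-eye example", {
  a <- c(0.42, 0.44, 0.40, 0.43)
  b <- c(0.46, 0.49, 0.44, 0.47)
  # differences (-0.04, -0.05, -0.04, -0.04): mean -0.0425, sd 0.005
  # t = -0.0425 / (0.005 / 2) = -17, df = 3
  r <- paired_t_test(a, b)
  expect_equal(r$t_statistic, -17, tolerance = 1e-10)
  expect_equal(r$p_value, 2 * stats::pt(-17, df = 3), tolerance = 1e-10)
  expect_true(r$significant)
})

test_that("paired t-test handles identical and constant-shift vectors by policy", {
  r0 <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_true(r0$degenerate)
  r1 <- paired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r1$p_value, 0)
  expect_true(r1$degenerate)
  expect_true(r1$significant)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

# independent ICC(A,1) oracle via the two-way ANOVA table
oracle_icc_a1 <- function(g1, g2) {
  n <- length(g1)
  df <- data.frame(y = c(g1, g2),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- anova(stats::lm(y ~ subj + rater, df))[["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + MSE + (2 / n) * (MSC - MSE))
}

test_that("two-grader ICC matches the ANOVA mean-squares oracle", {
  expect_equal(icc_two_graders(c(0, 1, 2, 1), c(0, 1, 2, 1))$icc, 1)
  g1 <- c(0, 1, 2, 3); g2 <- c(3, 2, 1, 0)   # reversed ranking
  r <- icc_two_graders(g1, g2)
  expect_lt(r$icc, 0)
  expect_equal(r$icc, oracle_icc_a1(g1, g2), tolerance = 1e-10)
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- rnorm(8); y <- x + rnorm(8, 0, 0.5)
      expect_equal(icc_two_graders(x, y)$icc, oracle_icc_a1(x, y),
                   tolerance = 1e-10)
    }
  })
  expect_true(icc_two_graders(rep(1, 5), rep(1, 5))$degenerate)
})

test_that("simulated graders agree perfectly without noise and are seeded", {
  ov <- c(85, 50, 10, 95, 70, 30, 88, 15)
  g <- simulate_graders(ov, noise_sd = 0, seed = 3)
  expect_identical(g$g1, g$g2)
  expect_equal(icc_two_graders(g$g1, g$g2)$icc, 1)
  g2 <- simulate_graders(ov, noise_sd = 10, seed = 3)
  expect_identical(g2, simulate_graders(ov, noise_sd = 10, seed = 3))
})

test_that("grader noise degrades the ICC in expectation", {
  withr::with_seed(12, ov <- runif(40, 0, 100))
  mean_icc <- function(sd) {
    mean(vapply(1:25, function(r) {
      g <- simulate_graders(ov, noise_sd = sd, seed = r)
      v <- icc_two_graders(g$g1, g$g2)$icc
      if (is.na(v)) 1 else v
    }, numeric(1)))
  }
  lo <- mean_icc(2); mid <- mean_icc(15); hi <- mean_icc(60)
  expect_gt(lo, mid)
  expect_gt(mid, hi)
})
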