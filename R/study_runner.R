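# Orchestration of the three experiments over a cohort of eyes, plus the
# cohort statistics (paired t-tests, two-rater ICC).
#
# Experiment 1: vessel density under a sweep of fixed thresholds, with the
#   Mean threshold as reference.
# Experiment 2: the thirteen thresholding methods; overlap-based quality
#   scores and the quantitative metrics (VD always; VT/Vdisp for the
#   tubular plexuses).
# Experiment 3: FAZ detection on the binarized SCP/DCP images, stratified
#   into overlap categories.

plexus_names <- function() c("SCP", "DCP", "CC")

# threshold an eye with a method; returns list(t, mask) or NULL when the
# method fails on that histogram (e.g. Intermodes on a unimodal one)
eye_threshold <- function(eye, method, fixed_value = NULL) {
  h <- image_histogram(eye$image)
  lev <- tryCatch(
    auto_threshold(h, method, plexus = eye$params$plexus, fixed_value = fixed_value),
    error = function(e) NULL)
  if (is.null(lev)) return(NULL)
  list(t = lev$t, mask = apply_threshold(eye$image, lev))
}

#' Experiment 1: fixed-threshold sweep of vessel density
#'
#' Binarizes every eye at each level of `sweep_levels` plus the Mean
#' threshold, and summarizes vessel density (FAZ excluded for SCP/DCP) as
#' mean and SD per plexus and level.
#'
#' @param cohort list of eyes from [generate_cohort()].
#' @param sweep_levels integer vector of fixed levels (default 15..85 by 10).
#' @param include_mean append the Mean-threshold reference row.
#' @return list with `records` (per eye) and `summary` (per level) data
#'   frames.
#' @export
run_experiment1 <- function(cohort, sweep_levels = seq(15L, 85L, 10L),
                            include_mean = TRUE) {
  if (length(sweep_levels) == 0) stop("sweep_levels must be non-empty")
  rec <- list()
  for (eye_entry in cohort) {
    for (plx in plexus_names()) {
      eye <- eye_entry[[plx]]
      excl <- if (plx == "CC") NULL else eye$faz_truth
      labels <- c(sprintf("Fixed %d", sweep_levels),
                  if (include_mean) "Mean")
      levels <- c(sweep_levels,
                  if (include_mean) threshold_mean(image_histogram(eye$image))$t)
      for (k in seq_along(levels)) {
        vd <- vessel_density(apply_threshold(eye$image, levels[k]), excl)
        rec[[length(rec) + 1L]] <- data.frame(
          eye_id = eye_entry$eye_id, plexus = plx, threshold = labels[k],
          t = levels[k], vd = vd, stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rec)
  summary <- stats::aggregate(vd ~ threshold + plexus, records,
                              function(x) c(mean = mean(x), sd = stats::sd(x)))
  summary <- data.frame(threshold = summary$threshold, plexus = summary$plexus,
                        vd_mean = summary$vd[, "mean"],
                        vd_sd = ifelse(is.na(summary$vd[, "sd"]), 0,
                                       summary$vd[, "sd"]),
                        stringsAsFactors = FALSE)
  ord <- order(summary$plexus, match(summary$threshold,
                                     c(sprintf("Fixed %d", sort(sweep_levels)), "Mean")))
  list(records = records, summary = summary[ord, ])
}

#' Experiment 2: the thirteen thresholding methods
#'
#' For every eye, plexus and method: the threshold level, the binarized
#' mask's overlap with the ground truth (`truth_sensitivity`) and with the
#' original image signal (`signal_residual`), the quality score (banded
#' truth overlap), vessel density, and — for the tubular plexuses —
#' skeleton tortuosity and dispersion.  A method that fails on an eye
#' (Intermodes on a unimodal histogram) is recorded with `t = NA` and
#' quality score 0: its binarization is unusable.
#'
#' @param cohort list of eyes from [generate_cohort()].
#' @param methods character vector of method names (default all thirteen).
#' @param metrics compute VT/Vdisp (skeletonization; the slow part).
#' @param metrics_plexus plexuses for which skeleton metrics are computed.
#' @return list with `records`, `quality_summary` (score mean ± SD per
#'   method and plexus) and `metrics_summary` (VD/VT/Vdisp mean and SD),
#'   plus `fixed_vs_mean` paired t-tests on VD.
#' @export
run_experiment2 <- function(cohort, methods = octa_methods(),
                            metrics = TRUE,
                            metrics_plexus = c("SCP", "DCP")) {
  bad <- setdiff(methods, octa_methods())
  if (length(bad))
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; valid names: ", paste(octa_methods(), collapse = ", "))
  rec <- list()
  for (eye_entry in cohort) {
    for (plx in plexus_names()) {
      eye <- eye_entry[[plx]]
      excl <- if (plx == "CC") NULL else eye$faz_truth
      for (m in methods) {
        thr <- eye_threshold(eye, m)
        if (is.null(thr)) {
          rec[[length(rec) + 1L]] <- data.frame(
            eye_id = eye_entry$eye_id, plexus = plx, method = m,
            t = NA_integer_, vd = NA_real_, overlap_truth = 0,
            overlap_signal = 0, quality = 0L,
            vt = NA_real_, vdisp = NA_real_, n_branches = NA_integer_,
            stringsAsFactors = FALSE)
          next
        }
        ovt <- truth_overlap(eye$vessel_truth, thr$mask)$overlap_pct
        ovs <- subtract_overlap(eye$image, thr$mask)$overlap_pct
        vt <- vdisp <- NA_real_; nbr <- NA_integer_
        if (metrics && plx %in% metrics_plexus) {
          g <- skeletonize(thr$mask)
          vt <- vessel_tortuosity(g)
          vdisp <- vessel_dispersion(g)
          nbr <- length(g$branches)
        }
        rec[[length(rec) + 1L]] <- data.frame(
          eye_id = eye_entry$eye_id, plexus = plx, method = m,
          t = thr$t, vd = vessel_density(thr$mask, excl),
          overlap_truth = ovt, overlap_signal = ovs,
          quality = quality_score(ovt),
          vt = vt, vdisp = vdisp, n_branches = nbr,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rec)
  agg2 <- function(v) {
    a <- stats::aggregate(records[[v]],
                          by = list(method = records$method, plexus = records$plexus),
                          FUN = function(x) c(mean(x, na.rm = TRUE),
                                              stats::sd(x, na.rm = TRUE)))
    data.frame(method = a$method, plexus = a$plexus,
               mean = a$x[, 1], sd = a$x[, 2], stringsAsFactors = FALSE)
  }
  quality_summary <- agg2("quality")
  names(quality_summary)[3:4] <- c("score_mean", "score_sd")
  metrics_summary <- Reduce(function(a, b) merge(a, b, by = c("method", "plexus")),
    lapply(c("vd", "vt", "vdisp"), function(v) {
      s <- agg2(v); names(s)[3:4] <- paste0(v, c("_mean", "_sd")); s
    }))
  fixed_vs_mean <- NULL
  if (all(c("Fixed", "Mean") %in% methods)) {
    fixed_vs_mean <- do.call(rbind, lapply(plexus_names(), function(plx) {
      a <- records[records$plexus == plx & records$method == "Fixed", ]
      b <- records[records$plexus == plx & records$method == "Mean", ]
      a <- a[order(a$eye_id), ]; b <- b[order(b$eye_id), ]
      tt <- paired_t_test(a$vd, b$vd)
      data.frame(plexus = plx, comparison = "VD Fixed vs Mean",
                 mean_a = mean(a$vd, na.rm = TRUE), mean_b = mean(b$vd, na.rm = TRUE),
                 t = tt$t_statistic, p = tt$p_value,
                 significant = tt$significant, stringsAsFactors = FALSE)
    }))
  }
  list(records = records, quality_summary = quality_summary,
       metrics_summary = metrics_summary, fixed_vs_mean = fixed_vs_mean)
}

#' Experiment 3: FAZ detection per thresholding method
#'
#' Detects the FAZ on each binarized SCP/DCP image, measures its Jaccard
#' overlap with the ground-truth FAZ, bands it into the three categories,
#' and summarizes category counts and cohort colors per method and plexus.
#' A method failure or an unbounded flood scores 0%.
#'
#' @param cohort list of eyes from [generate_cohort()].
#' @param methods character vector of method names.
#' @param r_close closing radius passed to [detect_faz()].
#' @return list with `records` and `summary` (per method/plexus category
#'   counts with colors).
#' @export
run_experiment3 <- function(cohort, methods = octa_methods(), r_close = 2) {
  bad <- setdiff(methods, octa_methods())
  if (length(bad))
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; valid names: ", paste(octa_methods(), collapse = ", "))
  rec <- list()
  for (eye_entry in cohort) {
    for (plx in c("SCP", "DCP")) {
      eye <- eye_entry[[plx]]
      for (m in methods) {
        thr <- eye_threshold(eye, m)
        ov <- if (is.null(thr)) {
          list(overlap_pct = 0, category = "<20%")
        } else {
          faz <- tryCatch(detect_faz(thr$mask, eye$center, r_close = r_close),
                          error = function(e) NULL)
          if (is.null(faz)) list(overlap_pct = 0, category = "<20%")
          else faz_overlap(faz, eye$faz_truth)
        }
        rec[[length(rec) + 1L]] <- data.frame(
          eye_id = eye_entry$eye_id, plexus = plx, method = m,
          faz_overlap_pct = ov$overlap_pct, category = ov$category,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rec)
  summary <- do.call(rbind, lapply(c("SCP", "DCP"), function(plx) {
    do.call(rbind, lapply(methods, function(m) {
      r <- records[records$plexus == plx & records$method == m, ]
      s <- summarize_faz_cohort(r$category)
      cbind(data.frame(method = m, plexus = plx, stringsAsFactors = FALSE), s)
    }))
  }))
  list(records = records, summary = summary)
}

#' Paired two-tailed t-test
#'
#' Thin wrapper around [stats::t.test()] with explicit handling of the
#' degenerate cases: identical vectors give t = 0, p = 1; a constant
#' non-zero difference has zero variance and is reported as p = 0 with the
#' `degenerate` flag.
#'
#' @param a,b paired numeric vectors (same eyes under two conditions).
#' @return a `stat_result` list: means, `t_statistic`, `p_value`,
#'   `significant` (p < 0.05), `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (all(d == 0)) {
    res <- list(mean_a = mean(a), mean_b = mean(b), t_statistic = 0,
                p_value = 1, significant = FALSE, degenerate = TRUE)
  } else if (stats::sd(d) == 0) {
    res <- list(mean_a = mean(a), mean_b = mean(b),
                t_statistic = sign(mean(d)) * Inf,
                p_value = 0, significant = TRUE, degenerate = TRUE)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(mean_a = mean(a), mean_b = mean(b),
                t_statistic = unname(tt$statistic),
                p_value = tt$p.value,
                significant = tt$p.value < 0.05, degenerate = FALSE)
  }
  structure(res, class = "stat_result")
}

#' Two-rater intraclass correlation (absolute agreement, single rater)
#'
#' ICC(A,1) of McGraw & Wong: two-way mixed effects, absolute agreement,
#' single rater — the form matching two fixed graders scoring the same
#' eyes.  Computed from the ANOVA mean squares.
#'
#' @param g1,g2 numeric score vectors from the two graders (length >= 3).
#' @return an `icc_result` list: `icc`, `model`, `degenerate`.
#' @export
icc_two_graders <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("grader vectors must have equal length")
  n <- length(g1)
  if (n < 3) stop("need at least 3 rated eyes")
  x <- cbind(g1, g2)
  k <- 2
  if (stats::sd(as.numeric(x)) == 0)
    return(structure(list(icc = NA_real_, model = "ICC(A,1)",
                          degenerate = TRUE), class = "icc_result"))
  ri <- rowMeans(x); cj <- colMeans(x); gm <- mean(x)
  MSR <- k * sum((ri - gm)^2) / (n - 1)
  MSC <- n * sum((cj - gm)^2) / (k - 1)
  MSE <- sum((x - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + gm)^2) /
    ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  structure(list(icc = icc, model = "ICC(A,1)", degenerate = FALSE),
            class = "icc_result")
}

#' Simulate two graders banding noisy overlap readings
#'
#' Each grader perceives the per-eye overlap percentage with seeded
#' Gaussian error and bands it into the 0/1/2 quality score; this provides
#' a synthetic surrogate for two independent expert graders so the ICC
#' machinery can be exercised end to end.
#'
#' @param overlap_pcts numeric vector of true overlap percentages.
#' @param noise_sd SD of the per-grader perception error, in percentage
#'   points (0 gives identical graders).
#' @param seed RNG seed.
#' @return list with integer score vectors `g1`, `g2`.
#' @export
simulate_graders <- function(overlap_pcts, noise_sd = 5, seed = 1L) {
  withr::with_seed(seed, {
    g1 <- quality_score(overlap_pcts + stats::rnorm(length(overlap_pcts), 0, noise_sd))
    g2 <- quality_score(overlap_pcts + stats::rnorm(length(overlap_pcts), 0, noise_sd))
  })
  list(g1 = g1, g2 = g2)
}

#' Run the full study on a synthetic cohort
#'
#' Generates a seeded cohort, runs experiments 1--3, simulates the two
#' graders for the ICC, and (optionally) writes the result tables as CSV
#' plus a JSON manifest.  Identical `n_eyes` + `seed` + parameters give
#' byte-identical outputs.
#'
#' @param n_eyes cohort size (default study condition: 30 eyes).
#' @param seed cohort seed.
#' @param methods thresholding methods for experiments 2 and 3.
#' @param metrics compute skeleton metrics in experiment 2.
#' @param out_dir optional output directory for CSVs + manifest.
#' @param grader_noise_sd perception noise of the simulated graders.
#' @return list with `cohort`, `exp1`, `exp2`, `exp3`, `icc`.
#' @export
run_study <- function(n_eyes = 30L, seed = 1L, methods = octa_methods(),
                      metrics = TRUE, out_dir = NULL, grader_noise_sd = 5) {
  cohort <- generate_cohort(n_eyes, seed = seed)
  exp1 <- run_experiment1(cohort)
  exp2 <- run_experiment2(cohort, methods, metrics = metrics)
  exp3 <- run_experiment3(cohort, methods)
  gr <- simulate_graders(exp2$records$overlap_truth, noise_sd = grader_noise_sd,
                         seed = seed + 1L)
  icc <- icc_two_graders(gr$g1, gr$g2)
  out <- list(cohort = cohort, exp1 = exp1, exp2 = exp2, exp3 = exp3,
              icc = icc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(exp1$summary, file.path(out_dir, "table1_fixed_sweep.csv"),
              row.names = FALSE)
    write.csv(exp2$quality_summary, file.path(out_dir, "table2_quality.csv"),
              row.names = FALSE)
    write.csv(exp2$metrics_summary, file.path(out_dir, "table3_metrics.csv"),
              row.names = FALSE)
    write.csv(exp3$summary, file.path(out_dir, "table4_faz.csv"),
              row.names = FALSE)
    write.csv(exp2$records, file.path(out_dir, "records_experiment2.csv"),
              row.names = FALSE)
    write.csv(exp3$records, file.path(out_dir, "records_experiment3.csv"),
              row.names = FALSE)
    manifest <- list(n_eyes = n_eyes, seed = seed, methods = methods,
                     grader_noise_sd = grader_noise_sd,
                     icc = icc$icc,
                     package_version = as.character(utils::packageVersion("octathresh")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
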