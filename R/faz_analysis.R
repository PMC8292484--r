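# FAZ detection on binarized SCP/DCP images and cohort-level stratification
# of FAZ overlap.

#' Detect the foveal avascular zone on a binarized image
#'
#' The vessel mask is morphologically closed (disc of radius `r_close`) to
#' seal 1--2 px capillary gaps, then the background is flood filled from
#' the foveal `center`; the filled connected component is the FAZ
#' candidate.  A flood that reaches the image border means the vessel ring
#' did not enclose the fovea: the detection is flagged `unbounded` (the
#' failure mode of sparse masks).
#'
#' @param mask logical vessel mask (SCP or DCP).
#' @param center pixel (row, col) of the foveal center.
#' @param r_close closing radius in pixels (default 2).
#' @return a `faz_region`: list with `mask`, `contains_center`, `area_px`,
#'   `unbounded`.
#' @export
detect_faz <- function(mask, center, r_close = 2) {
  if (center[1] < 1 || center[1] > nrow(mask) ||
      center[2] < 1 || center[2] > ncol(mask))
    stop("center lies outside the image")
  closed <- if (r_close > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(r_close) + 1L, shape = "disc")
    as.matrix(EBImage::closing(EBImage::Image(mask * 1), brush)) > 0.5
  } else mask
  bg <- !closed
  cen <- as.integer(round(center))
  if (!bg[cen[1], cen[2]]) {
    # center fell on a (closed) vessel pixel: take nearest background
    # pixel within 10 px
    cand <- which(bg, arr.ind = TRUE)
    if (nrow(cand) == 0L) stop("no background pixel: vessel mask is full")
    dd <- sqrt((cand[, 1] - cen[1])^2 + (cand[, 2] - cen[2])^2)
    if (min(dd) > 10) stop("no background pixel within 10 px of the center")
    cen <- cand[which.min(dd), ]
  }
  lab <- EBImage::bwlabel(EBImage::Image(bg * 1))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  comp <- lab == lab[cen[1], cen[2]]
  unbounded <- any(comp[1, ]) || any(comp[nrow(comp), ]) ||
    any(comp[, 1]) || any(comp[, ncol(comp)])
  structure(list(mask = comp, contains_center = TRUE,
                 area_px = sum(comp), unbounded = unbounded),
            class = "faz_region")
}

#' @export
print.faz_region <- function(x, ...) {
  cat(sprintf("<faz_region> %d px%s\n", x$area_px,
              if (isTRUE(x$unbounded)) " (unbounded: leaked to border)" else ""))
  invisible(x)
}

#' FAZ overlap categories
#' @return the ordered category labels used in cohort summaries.
#' @export
faz_categories <- function() c("<20%", "<80%", ">80%")

#' Overlap between a detected FAZ and a reference mask
#'
#' Symmetric Jaccard overlap, `100 * |A & B| / |A | B|`; an unbounded
#' detection scores 0.  The percentage is banded into the categories
#' `"<20%"`, `"<80%"` (20--80) and `">80%"` (>= 80).
#'
#' @param detected a `faz_region` (or a logical mask).
#' @param reference logical reference FAZ mask.
#' @param mode `"jaccard"` (default) or `"reference"` (one-sided fraction
#'   of the reference covered).
#' @return list with `overlap_pct` and `category`.
#' @export
faz_overlap <- function(detected, reference, mode = c("jaccard", "reference")) {
  mode <- match.arg(mode)
  unbounded <- FALSE
  if (inherits(detected, "faz_region")) {
    unbounded <- isTRUE(detected$unbounded)
    detected <- detected$mask
  }
  if (!all(dim(detected) == dim(reference))) stop("mask dimensions differ")
  pct <- if (unbounded) 0 else {
    inter <- sum(detected & reference)
    denom <- if (mode == "jaccard") sum(detected | reference) else sum(reference)
    if (denom == 0) stop("empty reference and detection; overlap undefined")
    100 * inter / denom
  }
  cat_lab <- if (pct >= 80) ">80%" else if (pct >= 20) "<80%" else "<20%"
  list(overlap_pct = pct, category = cat_lab)
}

#' Summarize FAZ overlap categories over a cohort
#'
#' Counts eyes per overlap category and assigns the cohort color bins:
#' red when no eye falls in a category, yellow when more than 20% of eyes
#' do, green when more than 60% do (gaps fall to the lower color).
#'
#' @param categories character vector of per-eye categories (values of
#'   [faz_categories()]).
#' @return a `faz_cohort_summary` data frame with columns `category`,
#'   `n_eyes`, `pct_eyes`, `color`.
#' @export
summarize_faz_cohort <- function(categories) {
  lev <- faz_categories()
  if (!all(categories %in% lev))
    stop("unknown category; expected one of: ", paste(lev, collapse = ", "))
  n <- length(categories)
  cnt <- table(factor(categories, levels = lev))
  pct <- 100 * as.numeric(cnt) / n
  color <- ifelse(pct > 60, "green", ifelse(pct > 20, "yellow", "red"))
  color[as.numeric(cnt) == 0] <- "red"
  structure(data.frame(category = lev, n_eyes = as.integer(cnt),
                       pct_eyes = pct, color = color,
                       stringsAsFactors = FALSE),
            class = c("faz_cohort_summary", "data.frame"))
}
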