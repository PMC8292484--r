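# Quantitative OCTA metrics from binarized images: vessel density (VD),
# skeleton-based vessel tortuosity (VT) and orientation dispersion (Vdisp).

#' Vessel density of a binary mask
#'
#' Fraction of evaluable pixels classified as vessel.  Pixels in `exclude`
#' (conventionally the FAZ) are removed from both numerator and
#' denominator.
#'
#' @param mask logical vessel mask.
#' @param exclude optional logical mask of pixels to drop (e.g. FAZ).
#' @return vessel density in [0, 1].
#' @export
vessel_density <- function(mask, exclude = NULL) {
  if (is.null(exclude)) exclude <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!all(dim(mask) == dim(exclude))) stop("mask and exclusion dimensions differ")
  ok <- !exclude
  n <- sum(ok)
  if (n == 0) stop("no evaluable pixels after exclusion")
  sum(mask & ok) / n
}

# Zhang-Suen thinning to 1-px centerlines (8-connected skeleton), with a
# sequential cleanup of remaining 8-simple pixels with >= 3 neighbours
# (diagonal ribbons of width 2 that the parallel passes cannot reduce;
# 1-px-wide paths have exactly 2 neighbours and are never shortened).
# Implemented in C++ (src/thin.cpp): a per-pixel scan the R interpreter
# cannot do at cohort scale.
thin_mask <- function(mask) .zs_thin(mask)

step_lengths <- function(path) {
  if (nrow(path) < 2) return(numeric(0))
  d <- abs(diff(path))
  ifelse(d[, 1] + d[, 2] == 2, sqrt(2), 1)
}

# calibrated digital arc length (Vossepoel-Smeulders weights), never below
# the Euclidean chord
calibrated_arc <- function(path, chord) {
  st <- step_lengths(path)
  n_diag <- sum(st > 1); n_str <- length(st) - n_diag
  max(0.980 * n_str + 1.406 * n_diag, chord)
}

#' Skeletonize a vessel mask into a branch graph
#'
#' Thins the mask to 1-pixel centerlines (Zhang--Suen), removes terminal
#' spurs shorter than `prune_len`, and decomposes the skeleton at junction
#' pixels into branches.  Each branch carries its ordered pixel path, the
#' 8-connected arc length (diagonal steps count sqrt(2)), a
#' corner-calibrated arc length used for tortuosity, and the Euclidean
#' chord between its endpoints.
#'
#' @param mask logical vessel mask.
#' @param prune_len minimum branch arc length (px) kept, default 3.
#' @return a `skeleton_graph`: list with `skeleton` (logical matrix),
#'   `branches` (list of `path`, `arc_length`, `arc_calibrated`,
#'   `chord_length`, `is_loop`), and `n_junctions`.
#' @export
skeletonize <- function(mask, prune_len = 3) {
  sk <- thin_mask(mask)
  for (pass in 1:2) {
    g <- decompose_skeleton(sk)
    drop <- vapply(g$branches, function(b) {
      (b$has_free_end && b$arc_length < prune_len) ||
        (b$chord_length < 1 && b$arc_length <= prune_len)  # junction residue
    }, logical(1))
    if (!any(drop)) break
    for (b in g$branches[drop]) {
      keep_junction <- b$junction_attached
      px <- b$path
      if (nrow(px) > 0) {
        interior <- if (length(keep_junction)) !seq_len(nrow(px)) %in% keep_junction else rep(TRUE, nrow(px))
        sk[px[interior, , drop = FALSE]] <- FALSE
      }
    }
  }
  g <- decompose_skeleton(sk)
  structure(list(skeleton = sk, branches = g$branches,
                 n_junctions = g$n_junctions),
            class = "skeleton_graph")
}

decompose_skeleton <- function(sk) {
  if (sum(sk) == 0) return(list(branches = list(), n_junctions = 0L))
  tr <- .trace_skeleton(sk)
  branches <- lapply(seq_along(tr$paths), function(b) {
    path <- tr$paths[[b]]
    chord <- tr$chord[b]
    n <- nrow(path)
    ja <- integer(0)
    if (tr$head_att[b] == 1L) ja <- c(ja, 1L)
    if (tr$tail_att[b] == 1L) ja <- c(ja, n)
    list(path = path,
         arc_length = tr$arc[b],
         arc_calibrated = max(0.980 * tr$n_straight[b] + 1.406 * tr$n_diag[b],
                              chord),
         chord_length = chord,
         is_loop = n > 3 && max(abs(path[1, ] - path[n, ])) <= 1 &&
           chord <= sqrt(2),
         has_free_end = length(ja) < 2L,
         junction_attached = ja)
  })
  list(branches = branches, n_junctions = tr$n_junctions)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d skeleton px, %d branches, %d junctions\n",
              sum(x$skeleton), length(x$branches), x$n_junctions))
  invisible(x)
}

#' Vessel tortuosity (arc-to-chord ratio)
#'
#' Arc-length-weighted mean of the branch arc/chord ratios, using the
#' corner-calibrated arc length.  Closed loops (zero chord) are excluded.
#'
#' @param skel a `skeleton_graph` from [skeletonize()].
#' @return VT >= 1, or `NA` when no valid branch exists.
#' @export
vessel_tortuosity <- function(skel) {
  br <- Filter(function(b) !isTRUE(b$is_loop) && b$chord_length > 0, skel$branches)
  if (length(br) == 0) return(NA_real_)
  arc <- vapply(br, `[[`, numeric(1), "arc_calibrated")
  chord <- vapply(br, `[[`, numeric(1), "chord_length")
  sum(arc * (arc / chord)) / sum(arc)
}

#' Axial circular dispersion of a set of orientation angles
#'
#' Angles are folded to [0, 180) (an orientation has no direction), doubled
#' onto the circle, and the angular deviation sqrt(2 (1 - R)) of the doubled
#' angles, halved and converted to degrees, is returned.  Zero for parallel
#' orientations; maximal (90 * sqrt(2) / pi ~ 40.51 deg) when the doubled
#' resultant length R is 0, e.g. for equal masses at 0 and 90 degrees or a
#' uniform orientation distribution.
#'
#' @param angles_deg numeric vector of orientation angles in degrees.
#' @return dispersion in degrees.
#' @export
axial_dispersion <- function(angles_deg) {
  if (length(angles_deg) == 0) return(NA_real_)
  th2 <- 2 * (angles_deg %% 180) * pi / 180
  R <- sqrt(mean(cos(th2))^2 + mean(sin(th2))^2)
  (180 / pi) * sqrt(2 * (1 - R)) / 2
}

#' Maximum attainable axial dispersion
#' @return the dispersion (degrees) at zero doubled-angle resultant length.
#' @export
axial_dispersion_max <- function() (180 / pi) * sqrt(2) / 2

#' Vessel dispersion (Vdisp)
#'
#' Local tangent angles are estimated at every skeleton pixel from the
#' branch path over a window of `window` pixels, folded to the axial range
#' [0, 180), and summarized by [axial_dispersion()].
#'
#' @param skel a `skeleton_graph`.
#' @param window tangent estimation window in pixels (default 5).
#' @return Vdisp in degrees, `NA` for an empty skeleton.
#' @export
vessel_dispersion <- function(skel, window = 5) {
  half <- floor(window / 2)
  angs <- unlist(lapply(skel$branches, function(b) {
    p <- b$path
    n <- nrow(p)
    if (n < 2) return(numeric(0))
    vapply(seq_len(n), function(i) {
      j1 <- max(1L, i - half); j2 <- min(n, i + half)
      dr <- p[j2, 1] - p[j1, 1]; dc <- p[j2, 2] - p[j1, 2]
      (atan2(-dr, dc) * 180 / pi) %% 180
    }, numeric(1))
  }))
  axial_dispersion(angs)
}
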