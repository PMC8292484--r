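---
title: "Binarization thresholds for OCTA angiograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binarization thresholds for OCTA angiograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octathresh)
```

## The problem

Quantitative analysis of optical coherence tomography angiography (OCTA)
begins with binarization: an 8-bit en-face reconstruction of a capillary
plexus is turned into a vessel/background mask by a gray-level threshold
$t$, with a pixel classified as vessel when its intensity is strictly
greater than $t$.  Every downstream metric — vessel density (VD), skeleton
tortuosity (VT), orientation dispersion (Vdisp), and the detection of the
foveal avascular zone (FAZ) — inherits whatever the threshold decided, and
different automatic thresholds make very different decisions on the same
image.  `octathresh` implements a full evaluation pipeline: thirteen
thresholding techniques, overlap-based quality grading, the quantitative
metrics, FAZ detection, cohort statistics, and a seeded synthetic
angiogram generator that provides ground truth for all of it.

## The thirteen thresholds

All automatic methods are pure functions of the 256-bin gray histogram
$h_0, \dots, h_{255}$ with class split "background = levels $\le t$".
Criterion ties are broken toward the lowest level, and a histogram with
all mass at one level is returned as that level with a `degenerate` flag —
uniformly across all methods.

* **Default (IsoData)** — the intermeans fixed point
  $t \leftarrow \mathrm{round}\big((\mu_{\le t} + \mu_{> t})/2\big)$,
  iterated from the midpoint of the histogram support.  The iteration
  converges to a crossing of the intermeans map; the returned level always
  satisfies $|t - g(t)| \le 1/2$.  On multimodal histograms the map has
  several crossings and the classical iteration commits to the one reached
  from the midpoint — this is deliberate, matching the method as used in
  practice, rather than a global search over $|t - g(t)|$.
* **Huang** — minimizes Shannon fuzziness: each level gets a membership
  $u = 1/(1 + |x - \mu_c| / C)$ to its class mean, and
  $\sum_x h_x S(u_x)$ is minimized, where $S$ is the binary entropy and
  $C$ the histogram support range.  Note that for two equal delta peaks
  every split between the peaks has zero fuzziness, so the lowest-tie rule
  returns the lower peak itself.
* **Intermodes** — smooths the histogram with a window-3 running average
  until exactly two strict local maxima $j < k$ remain and returns
  $\mathrm{round}((j+k)/2)$.  A histogram that never becomes bimodal
  (10,000-pass cap) raises an explicit error; in cohort runs such an eye
  is recorded as a failed, unusable binarization (quality 0).
* **Li** — minimum cross entropy
  $\eta(t) = -\sum_{x \le t} x h_x \log \mu_{\le t} - \sum_{x > t} x h_x \log \mu_{> t}$,
  minimized by an exhaustive scan over all candidate levels.  Li's
  fast fixed-point update approximates this optimum but can stall in
  local minima on spiky histograms, so the package returns the global
  minimizer of the same criterion.
* **MaxEntropy (Kapur)** — maximizes the sum of the within-class Shannon
  entropies.
* **Mean** — floor of the intensity-weighted mean level.
* **Moments (Tsai)** — matches the first three moments of a two-level
  image; the implied background fraction $p_0$ is realized as the level
  whose cumulative mass is closest to $p_0$.
* **Otsu** — minimizes the weighted within-class variance.
* **Percentile (Doyle)** — the level whose foreground fraction is closest
  to one half.  The criterion is evaluated in exact integer counts
  ($|\,\mathrm{mass}_{\le t} - \mathrm{mass}_{> t}|$), so ties are exact
  and reproducible.
* **RenyiEntropy** — entropy-maximizing levels under Renyi orders 1/2, 1
  and 2, combined by the published three-candidate weighting rule
  (weights depend on whether the sorted candidates lie within 5 levels of
  each other).
* **Shanbhag** — minimizes the absolute difference of the fuzzy
  information measures of the two classes.
* **Yen** — maximizes the maximum-correlation criterion built from the
  squared class masses.
* **Fixed** — 65 for SCP and DCP, 85 for CC, with an override for sweep
  experiments.

Criterion-based methods are verified against independent exhaustive
scans of their criteria on hundreds of random histograms, and Otsu
additionally against `EBImage::otsu`.

## Overlap and the quality score

A common grading pipeline subtracts the binarized image from
the original (8-bit clamped subtraction) and judges the "percentage of
overlapping" in the residual.  Two computable readings are provided:

* `signal_residual` (default for real images): the fraction of total
  image signal captured by the mask,
  $100\,(1 - \sum \mathrm{residual} / \sum \mathrm{original})$.
* `truth_sensitivity` (used on synthetic cohorts): the fraction of
  ground-truth vessel pixels recovered by the mask.

The quality score bands the percentage as 2 ($\ge 80$), 1 ($[20, 80)$),
0 ($< 20$); the bands are closed on the left so they partition $[0,100]$.
On synthetic eyes the ground truth plays the role of the human grader's
knowledge of where the capillaries really are, which is why cohort
scoring uses `truth_sensitivity`: a captured-signal fraction cannot
reach the observed grading of the best thresholds even for a perfectly
matched intensity distribution, because dim background always carries
some signal mass.

## Quantitative metrics

**VD** is the fraction of evaluable pixels classified as vessel; the FAZ
is excluded from the evaluable area for SCP/DCP.

**Skeletons.** Masks are thinned to 1-px centerlines by Zhang–Suen
thinning plus a topology-preserving sequential cleanup (Hilditch crossing
number 1, $\ge 3$ neighbours) that reduces the 2-px diagonal ribbons the
parallel passes cannot handle; both passes are implemented in C++.
Terminal spurs shorter than 3 px are pruned, and the skeleton is
decomposed into branches at junction pixels (8-connectivity; junction =
$\ge 3$ skeleton neighbours).

**VT** is the arc-length-weighted mean of branch arc/chord ratios.  The
stored `arc_length` uses the 8-connected step metric (diagonal =
$\sqrt2$), which systematically overestimates smooth curve length by up
to 8% at intermediate orientations; the ratio therefore uses a
corner-calibrated arc length ($0.980\,n_{\mathrm{straight}} +
1.406\,n_{\mathrm{diag}}$, the Vossepoel–Smeulders estimator), clamped
from below by the chord so VT $\ge 1$ holds exactly for straight
segments.  A digitized quarter circle evaluates to within 0.05 of the
analytic $\pi/(2\sqrt2) \approx 1.1107$.  Closed loops (zero chord) are
excluded.  The absolute scale of published OCTA tortuosity indices
varies between groups; values here are on the natural arc/chord scale
(straight = 1), and comparisons between thresholds — not absolute values
— are the supported use.

**Vdisp** estimates a tangent angle at every skeleton pixel from its
branch path over a 5-px window, folds angles to the axial range
$[0^\circ, 180^\circ)$, doubles them onto the circle, and reports the
angular deviation $\tfrac12\sqrt{2(1-R)}$ (in degrees) of the doubled
angles, where $R$ is the resultant length.  This form is bounded — the
maximum $90\sqrt2/\pi \approx 40.5^\circ$ is attained at $R = 0$, e.g.
for equal orientation mass at 0° and 90° or uniform orientations —
whereas the $\sqrt{-2\log R}$ circular SD diverges at $R = 0$ and cannot
satisfy a finite uniform-orientation reference value.

## FAZ detection

The vessel mask is morphologically closed (disc radius 2 px, enough to
seal 1–2 px capillary gaps) and the background is flood filled from the
foveal center (4-connected); the filled component is the FAZ candidate.
If the flood reaches the image border the mask did not enclose the fovea
and the detection is flagged unbounded — the characteristic failure of
very sparse binarizations — and scores 0% overlap.  Overlap with a
reference FAZ is the symmetric Jaccard percentage, which penalizes both
leakage and shrinkage; a one-sided mode (fraction of reference covered)
is available behind a flag.  Per-eye categories (<20%, <80%, >80%) are
counted over the cohort and colored red (no eyes), yellow (>20% of
eyes), green (>60% of eyes), with gaps falling to the lower color.

## The synthetic angiogram generator

The generator's job is to emulate the properties of real en-face OCTA
that drive threshold behavior, with exact ground truth.

**Geometry.** SCP/DCP capillaries are biased random walkers: they enter
from the image border aimed loosely at the fovea, advance 1 px per step
with wrapped-Gaussian direction noise (SD 0.22 rad — the source of
natural tortuosity) and a mild centripetal pull, branch with probability
0.045 per step, and terminate on the FAZ contour.  The FAZ contour is a
circle (radius 32 px SCP / 36 px DCP at 320 px image size, i.e. ~0.3 mm
at the 3×3 mm field the images represent) perturbed by low-order radial
sinusoids (15% relative amplitude), and is lined by a perifoveal
capillary arcade, the anatomical ring that closes the FAZ border.  A few
large, bright, nearly straight radial vessels cross the field (4 in SCP;
3 dimmer ones in DCP, standing for projections of the superficial
trunks).  The CC is a band-pass filtered noise texture (granular,
non-tubular) thresholded at a 55% density target; it has no FAZ.

**Intensity.** Real en-face OCTA reconstructions have smooth, strongly
right-skewed, heavy-tailed, essentially unimodal gray distributions —
the behavior of automatic thresholds hinges on this.  (Back-fitting a
lognormal to reported fixed-threshold VD sweeps for healthy SCP gives
median ≈ 56 and log-SD ≈ 0.75, and that fit reproduces the whole sweep
to a few percent.)  The generator reaches this family by composition:
per-vessel lognormal brightness (capillary decorrelation varies with
flow), a Gaussian cross-section profile whose edges fill the
intermediate grays, strong multiplicative log-normal speckle (σ = 0.33),
additive sensor noise, and a soft shoulder that compresses grays above
180 toward 255 without creating a saturation spike (a spike at 255 forms
a concentrated class that repels entropy criteria and was avoided
deliberately).  The FAZ interior is attenuated by 0.7: the truly
avascular fovea carries no flow decorrelation at any depth and images
darker than generic background; without this, speckle clusters inside
the FAZ fragment the flood fill.  Ground-truth masks are recorded before
any noise.

**Calibration.** Defaults were set during design so that the Mean
threshold yields SCP vessel densities in the 0.42–0.50 band reported for
healthy cohorts, and so that the documented qualitative contrasts of the
evaluation — mass-based thresholds tracking the bulk of the
distribution, entropy-based thresholds cutting deep into the bright tail
— emerge from the image statistics rather than from anything
method-specific.  The emergent behavior on default cohorts: Fixed ≈ 65
captures ~85–90% of true vessel pixels, Percentile/Huang/Li/Mean follow
closely, while MaxEntropy/RenyiEntropy/Yen select levels around 130–145
keeping under 20%, and Intermodes is erratic because the unimodal
histogram has no stable second mode.

**What passing tests do not show.** The generator emulates gray-level
statistics and gross vascular geometry, not OCT physics: no projection
or motion artifacts, no vessel-caliber-dependent flow signal, no
volumetric context, and speckle is log-normal rather than the true
device statistics.  Agreement of the pipeline with the generator
therefore validates the computational chain and the relative behavior
of thresholds on images with realistic histograms; it does not certify
absolute metric values on any particular device.

## Cohort statistics

Method comparisons on the same eyes use paired two-tailed t-tests at
p < 0.05 without multiple-testing correction (a Holm option exists but
defaults off, keeping the flat significance rule this kind of study
design uses).  Identical paired vectors report t = 0, p = 1; a zero-variance
non-zero difference is flagged degenerate and reported as p = 0.
Inter-grader agreement uses ICC(A,1) — two-way mixed effects, absolute
agreement, single rater — computed from the ANOVA mean squares; this is
the form for two fixed graders rating all eyes.  Since synthetic cohorts
have no human graders, `simulate_graders()` perturbs each per-eye
overlap with seeded Gaussian error before banding, which exercises the
ICC machinery end to end and reproduces the expected monotone decay of
agreement with grader noise.

## Numerical and policy choices

* Thresholds are integers in 0..255; criteria are evaluated in double
  precision except Percentile's, which is exact in integer counts.
* Degenerate inputs: one-level histograms (flagged level), empty masks
  (empty skeleton), all-vessel masks (FAZ detection error), empty
  exclusion complements (VD error) are all explicit.
* The coordinate convention is row-major with 0-based levels; masks are
  logical matrices; images are integer matrices.
* Problem sizes in the shipped tests: 200 random histograms for the
  threshold oracle suite; cohorts of 30 eyes and 3 seeds for the
  ranking reproduction; 10,000 samples for the uniform-orientation
  dispersion check; a 2-eye full pipeline for byte-level determinism.

## Known limitations

Sub-caliber structures (2-px-wide diagonal ribbons) are degenerately
thinned by the Zhang–Suen passes — vessels at the default calibers
(radius ≥ 1.3 px, i.e. ≥ 3 px wide) are unaffected.  The FAZ detector
assumes a fovea-centered field.  VT/Vdisp values depend on the skeleton
discretization and are comparable within, not across, pipelines.  The
Intermodes iteration cap and the Renyi α-orders (1/2, 1, 2) follow the
established published choices but are not tunable per-image.
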