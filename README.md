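# octathresh

Binarization is the gatekeeper of quantitative OCTA: every en-face
angiogram must be turned into a vessel/background mask before vessel
density or any other metric can be computed, and the choice among the
many automatic histogram thresholds changes the result dramatically.
`octathresh` is an R package for studying exactly that. It implements
thirteen thresholding techniques, overlap-based quality grading of the
binarized images, the standard quantitative metrics, foveal avascular
zone (FAZ) detection, and cohort statistics — together with a seeded
synthetic angiogram generator (superficial and deep capillary plexuses
plus choriocapillaris texture, with ground-truth vessel and FAZ masks)
so the entire pipeline is testable end to end without clinical data.

It is aimed at researchers quantifying retinal OCTA who need to choose,
defend, or audit a binarization threshold.

## The methods

Each automatic threshold is a pure function of the 256-bin gray
histogram, returning an integer level `t`; a pixel is vessel iff its
intensity is `> t` (background class = levels `<= t`, ties broken to the
lowest optimal level):

| Method | Criterion |
|---|---|
| Default (IsoData) | fixed point of t ← (μ₀(t) + μ₁(t)) / 2 |
| Huang | minimal Shannon fuzziness of class memberships |
| Intermodes | (j + k)/2 after smoothing to two modes |
| Li | minimal cross entropy −Σ x·h(x)·log μ(x;t) |
| MaxEntropy (Kapur) | maximal sum of class entropies |
| Mean | floor of the weighted mean level |
| Moments (Tsai) | moment-preserving percentile cut |
| Otsu | minimal within-class variance |
| Percentile (Doyle) | foreground fraction closest to 0.5 |
| RenyiEntropy | three Renyi orders (½, 1, 2) combined |
| Shanbhag | balanced fuzzy information measures |
| Yen | maximal correlation criterion |
| Fixed | 65 (SCP/DCP), 85 (CC) |

Downstream: vessel density VD (FAZ excluded for SCP/DCP), skeleton
tortuosity VT (arc-to-chord, corner-calibrated arc length), orientation
dispersion Vdisp (axial circular deviation, degrees), FAZ detection by
morphological closing + flood fill from the fovea, 0/1/2 quality scores
banded at 20%/80% overlap, paired t-tests and two-grader ICC(A,1).

## Worked example

```r
library(octathresh)

eye <- generate_plexus(plexus_params("SCP", seed = 7))
eye
#> <synthetic_eye> SCP 320x320, vessel fraction 0.556, FAZ 3234 px

h <- image_histogram(eye$image)
for (m in c("Fixed", "Mean", "Percentile", "Huang", "MaxEntropy")) {
  lev  <- auto_threshold(h, m, plexus = "SCP")
  mask <- apply_threshold(eye$image, lev)
  ov   <- truth_overlap(eye$vessel_truth, mask)
  cat(sprintf("%-11s t = %3d  VD = %.3f  overlap = %5.1f%%  score = %d\n",
              m, lev$t, vessel_density(mask, eye$faz_truth),
              ov$overlap_pct, quality_score(ov)))
}
#> Fixed       t =  65  VD = 0.579  overlap =  86.8%  score = 2
#> Mean        t =  80  VD = 0.451  overlap =  71.7%  score = 1
#> Percentile  t =  72  VD = 0.519  overlap =  80.3%  score = 2
#> Huang       t =  73  VD = 0.510  overlap =  79.2%  score = 1
#> MaxEntropy  t = 142  VD = 0.101  overlap =  17.2%  score = 0
```

The pattern on this one eye is the headline finding at cohort scale:
mass-based thresholds (Mean, Percentile, Huang, Li) track the bulk of
the heavy-tailed gray distribution and recover most capillaries, the
fixed level 65 recovers slightly more, and entropy-maximizing methods
cut deep into the bright tail, keeping only ~10% vessel density and
failing the quality grading.

FAZ detection and skeleton metrics on the same eye:

```r
mask <- apply_threshold(eye$image, 65)
faz  <- detect_faz(mask, eye$center)
faz_overlap(faz, eye$faz_truth)$overlap_pct
#> [1] 95.3          # Jaccard %, category ">80%"

g <- skeletonize(mask)
c(VT = vessel_tortuosity(g), Vdisp = vessel_dispersion(g))
#>     VT    Vdisp
#>  1.334   36.7          # arc/chord ratio; axial dispersion in degrees
```

Whole-study orchestration (30 eyes, all methods, CSV tables):

```r
res <- run_study(n_eyes = 30, seed = 1, out_dir = "results/study")
```

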