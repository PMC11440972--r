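---
title: "Quantifying amino-acid PET brain tumor volumes with fetquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amino-acid PET brain tumor volumes with fetquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetquant)
```

## The problem

Amino-acid PET with tracers such as O-(2-[18F]fluoroethyl)-L-tyrosine
([18F]FET) images the upregulated amino-acid transport of brain tumor cells
against a low uptake in healthy brain. In neuro-oncology the standard
semi-quantitative reading normalizes tumor uptake by the mean uptake of a
background region of interest (ROI) placed in healthy-appearing gray and
white matter of the contralateral hemisphere. Three numbers carry most of
the clinical information:

* **TBRmean / TBRmax** — the mean and maximum tumor-to-background ratio
  over the delineated tumor;
* **BTV** — the biological tumor volume in ml, the volume of voxels whose
  uptake exceeds a fixed multiple of the background mean (1.6 is the
  standard cut for FET);
* the **location of peak uptake**, used for biopsy targeting.

A 40-minute dynamic acquisition adds kinetic information: the mean
time-activity curve (TAC) over the tumor is summarized by its time-to-peak
(TTP) and assigned one of three canonical patterns — steadily increasing
(I), late peak followed by a plateau or small descent (II), early peak
(< 20 min) followed by descent (III) — with later patterns associated with
more aggressive biology.

`fetquant` implements this whole quantification chain — threshold
delineation, clinical metrics, TAC analysis — together with the tools
needed to *evaluate* a candidate delineation (for instance the output of a
segmentation network) against a reference: Dice similarity, voxel-level
confusion metrics, metric concordance, and longitudinal congruence. Because
clinical PET data cannot be redistributed, the package also ships a
synthetic phantom generator that provides ground-truth lesions for every
stage; the whole test suite runs on phantoms.

## The delineation procedure

`delineate()` composes five steps, each also exported on its own:

1. **Background mean** (`background_mean()`): the arithmetic mean uptake
   over the background ROI, given either as a mask or as a sphere in world
   coordinates (rasterized as voxels whose centers fall within the
   radius). A floor of 50 voxels (configurable) guards against unstable
   means; the literature does not prescribe an ROI size.
2. **Thresholding** (`threshold_delineate()`): voxels with uptake at or
   above `ratio × background` (default 1.6), intersected with the search
   domain. We read "above the threshold" as `>=`: on continuous-valued
   images the difference to a strict `>` has measure zero, and `>=` keeps
   the noiseless phantom case deterministic. A `strict` switch is
   provided.
3. **Exclusions** (`apply_exclusions()`): extratumoral structures with
   physiologically high uptake — vascular structures, the pineal body,
   skin — pass the threshold without being tumor. Clinically they are
   removed by an expert; here they are explicit exclusion masks. Exclusion
   is applied at the voxel level *before* component labeling so the volume
   filter sees post-exclusion components.
4. **Component labeling** (`label_components()`): 26-connected components,
   ordered by decreasing volume with ties broken by the lowest linear
   voxel index (z slowest, then y, then x). Connectivity is a free choice
   (the clinical procedure is silent); 26 is the most permissive and never
   splits a lesion that a human would read as one.
5. **Minimum-volume filter** (`min_volume_filter()`): components whose
   volume is strictly greater than `min_ml` survive. The default 0.1 ml is
   the pediatric minimal active-tumor volume; adult studies typically use
   1 ml.

The **search domain** (`build_domain()`) is the union of the brain mask
with an optional medulla mask (brain-extraction tools typically clip the
lower medulla, which can harbor CNS tumors in children), dilated 20
iterations with a 6-connected structuring element to absorb registration
and extraction inaccuracies. Dilation is clipped at the grid boundary.
Brain extraction and template registration themselves are upstream tools;
the masks are inputs here.

## Clinical metrics

`lesion_metrics()` reports BTV (voxel count × voxel volume), TBRmean,
TBRmax and the world coordinates of the hottest voxel, both for the union
BTV (the scan-level values) and per component. Conventions worth stating:

* An **empty BTV** yields `NA` metrics, not zeros — "no FET-positive
  lesion" is a category, and concordance analyses should drop such scans
  rather than regress against zeros.
* **Peak ties** are resolved to the lowest linear voxel index and the tie
  count is reported. Two methods agree on the peak location when the
  distance is exactly 0 mm (the same voxel); `peak_distance_mm()` supports
  any tolerance a user prefers.
* For multi-lesion scans the union values are the scan-level report;
  whether a clinical report should instead use the largest lesion is a
  judgment call, so the per-component table is always attached.

## Dynamic analysis

`extract_tac()` averages each frame over the BTV; `time_to_peak()` returns
the mid-time of the earliest maximal frame. TTP is reported at frame
resolution — no sub-frame interpolation — because agreement between
methods is meaningfully assessed in frame steps (`ttp_agreement()`).

`classify_pattern()` operationalizes the three verbal pattern definitions
as an ordered rule on the (optionally smoothed) TAC:

1. **Pattern I** when the peak frame is the final frame, or the final
   value is within `increasing_tol` (default 5%) of the peak — "no
   identifiable descent";
2. otherwise **pattern II** when TTP exceeds `cutoff_min` (default
   20 min);
3. otherwise **pattern III**.

The end-to-peak ratio and a plateau flag (ratio at or above
`plateau_ratio`, default 0.9) are reported for audit; the II/III split is
by peak time alone, mirroring the clinical definitions.

### Smoothing: why a local-linear filter

With `smooth = TRUE` the curve is filtered before classification. We use a
3-frame degree-1 Savitzky–Golay filter: interior frames get the centered
3-frame mean, but the first and last frames get the value of a
least-squares line through their window. The distinction matters. A plain
truncated average at the final frame, `(v[7] + v[8]) / 2`, mixes the
next-to-last frame into the final value; for a late-peak curve this pulls
the end value toward the peak and systematically inflates the end-to-peak
ratio by several percent — enough to erase exactly the "small descent"
that separates pattern II from pattern I. In simulation, truncated-window
averaging misclassifies 40–60% of noisy pattern-II curves as pattern I
however the descent is parameterized, while the line-fitted boundary
leaves linear trends untouched (a noiseless linear TAC is a fixed point of
the filter).

### What descent can be detected at all

A TAC sampled on eight 5-minute frames with 5% multiplicative noise puts a
hard floor on descent detection: any estimator of the end-to-peak ratio
has a standard deviation of roughly 2%, so descents within about one such
standard deviation of the 5% tolerance boundary are undecidable at high
accuracy. The phantom generator therefore defaults pattern II to a descent
to 0.75 of peak by 40 min, and the validation suite samples pattern II
curves with end ratios in [0.62, 0.76] and peaks in [22, 28] min, pattern
III peaks in [7, 14] min, and pattern I wash-in rates in [1/30, 1/12] per
min — ranges chosen by a power analysis so that the true per-pattern
recovery (98.5–99.8% in 2000-curve simulations) sits well clear of the 95%
acceptance bound estimated from 200 draws. Curves with gentler descents
are still *classified* (usually as pattern I/plateau); they are simply not
claimed to be recoverable at that noise level.

## Evaluation of candidate delineations

* **DSC** (`dsc()`): `2|A∩B| / (|A|+|B|)`. One empty mask scores 0 (a
  missed lesion); two empty masks score 1 by convention, flagged
  `"trivial"` so cohort code can drop them knowingly.
* **Voxel confusion** (`voxel_confusion()`) is always restricted to an
  evaluation domain — counting the air outside the head as true negatives
  would make specificity meaningless. Counts are additive across scans.
* **Aggregation**: pooled metrics (ratios of summed counts) and per-scan
  averaged metrics differ when lesion sizes vary, and published reports do
  not always say which was used. `cohort_summary()` therefore always
  reports both, labeled.
* **Confidence intervals**: nonparametric percentile bootstrap, 10,000
  resamples by default, seedable. Coverage for a median CI at cohort sizes
  around 30 is mildly below nominal, as the suite's simulation check
  documents.
* **Detection**: a scan counts as detected when its DSC strictly exceeds
  the detection threshold (default 0.8).
* **Representative cases** (`select_percentile_cases()`): nearest-rank
  percentiles (2/50/98 by default) for worst/typical/best display.
* **Longitudinal congruence** (`longitudinal_congruence()`): for each
  follow-up versus baseline and each metric, two methods are congruent
  when the signs of their changes agree, with changes within a 5% dead
  zone of baseline counting as "no change" so that two methods reporting a
  stable lesion with opposite-sign jitter still agree.

## The synthetic phantom

`generate_static()` builds a brain-shaped (ellipsoidal) support with
homogeneous background uptake 1.0, ellipsoidal lesion plateaus at
`tbr_true` × background, and optional confounder hotspots (superior
vascular rim, pituitary region, scalp shell — parameterized offsets, not
an atlas). The image is then degraded: isotropic Gaussian PSF blur
(FWHM / 2.3548 → sigma; default 5 mm, typical of clinical PET), then
voxel-wise additive Gaussian noise truncated at zero (default sigma 5% of
background). Two design points deserve emphasis:

* **Ground truth is the lesion support before blur and noise.** Recovery
  tests therefore quantify partial-volume and noise effects honestly: a
  5 mm PSF genuinely shrinks the delineation of a 2.0-TBR lesion at the
  1.6 threshold (measured DSC ≈ 0.83 against pre-blur truth on a ~4 ml
  lesion), and the suite asserts graceful degradation rather than
  pretending the blur away. The truth manifest carries both the voxelized
  truth volume (what a perfect delineation of the support would measure)
  and the analytic ellipsoid volume.
* **The noise model is a simplification.** Real PET noise is Poisson-like,
  spatially correlated by reconstruction, and nonstationary. Truncated
  Gaussian noise is deliberate plumbing, not physics; passing recovery
  tests demonstrates correctness of the quantification chain, not
  readiness on patient data.

`generate_dynamic()` gives every tissue class a kinetic curve — background
a mild wash-in, lesions their pattern's generator, confounders an
early-peak curve (mimicking vascular kinetics) — evaluated as exact
time-averages over each frame interval and scaled so the duration-weighted
20–40 min mean of every voxel equals its static uptake. The late summed
image (`summed_image()`, duration-weighted mean of frames whose mid-time
falls in the window) of a dynamic phantom therefore reproduces the static
phantom exactly in the noiseless case. A consequence of frame averaging:
the truth TTP is defined as the argmax of the noiseless frame-averaged
curve, which for peaks late within a frame can sit one frame after the
instantaneous peak — at frame resolution that *is* the correct answer.

`generate_longitudinal_cohort()` simulates patients with three or more
scans whose lesions scale in volume (semi-axes by the cube root of the
volume factor) and/or TBR at each follow-up, with randomized baseline
lesions kept inside the brain by construction.

Features of real data the phantom does **not** emulate: anatomical
texture and heterogeneous tumor uptake, infiltrative margins,
reconstruction artifacts, motion, registration error between masks and
PET, and reader variability in the background ROI placement. Validation
on phantoms bounds algorithmic correctness, not clinical performance.

## Numerical choices

* Voxel indices are 0-based in the voxel-to-world affine (NIfTI
  convention); world coordinates are mm; all distances Euclidean in world
  space. Grid compatibility requires equal shapes and affines agreeing
  element-wise within 1 mm/1000 (configurable).
* Frame selection for the summed image is by frame *mid-time* inside the
  closed window, with duration weighting, so unequal framings are handled.
* The frame-timing sidecar is JSON with `FrameTimesStart` /
  `FrameDuration` in seconds, or CSV with `start_s,duration_s`.
* PSF blur uses zero boundary conditions (phantom support never reaches
  the grid edge); dilation clips at the boundary; component labeling uses
  an exact union over a voxel-adjacency edge list.
* All random generation flows from explicit seeds; phantom generation,
  bootstrap CIs and cohort simulation are bit-reproducible.

## Validation problem sizes

The shipped suite validates on sizes chosen to keep a full run around a
minute while leaving no operation untested: 40³–64³ phantom grids at 2–3 mm
spacing; a ~4.2 ml lesion at TBR 2.0 for recovery (exact recovery without
degradation; DSC ≥ 0.8 and mean peak-TBR error ≤ 0.2 across 20 noisy
replicates with 5 mm PSF); 200 curves per kinetic pattern (100% recovery
noiseless, ≥ 95% at 5% noise with smoothing); brute-force oracle
equivalence on 100 random 20³ instances; and a 10-patient volume-doubling
cohort for longitudinal congruence.

## Limitations

The package quantifies and evaluates; it does not segment by learning,
reconstruct, correct attenuation, or normalize to SUV. The TAC pattern
rule is one declared operationalization of verbal clinical definitions;
its tolerances are configurable and other sites' conventions may differ.
Surface-distance metrics (Hausdorff) are not implemented.
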