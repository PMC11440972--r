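# fetquant

Quantification and evaluation of amino-acid PET brain tumor volumes in R.

Amino-acid PET (e.g. O-(2-[18F]fluoroethyl)-L-tyrosine, [18F]FET) images
the elevated amino-acid transport of brain tumor cells. Clinical reading
rests on a handful of semi-quantitative numbers: the **biological tumor
volume** (BTV) delineated by thresholding at a fixed multiple of the mean
uptake in a healthy-brain background ROI,

    BTV = volume{ v : uptake(v) >= 1.6 * background_mean },

the tumor-to-background ratios **TBRmean** and **TBRmax** over that
volume, the world-space **location of peak uptake** (biopsy targeting),
and — from a 40-min dynamic acquisition — the time-activity curve's
**time-to-peak** (TTP) and kinetic **pattern I/II/III** (steadily
increasing / late peak then plateau or small descent / early peak then
descent). When an automatic method (e.g. a segmentation network) proposes
a delineation, it is judged against a reference with the **Dice
similarity coefficient** DSC = 2|A∩B|/(|A|+|B|), voxel-level
sensitivity/specificity/PPV/NPV inside a brain-plus-medulla evaluation
domain, concordance of the clinical metrics, and the congruence of
longitudinal metric changes.

`fetquant` implements this entire chain for researchers in PET
neuro-oncology and medical image analysis:

- **I/O**: NIfTI-1 volumes, masks and 4D series with BIDS-PET-style JSON
  (or CSV) frame timing; late summed images by duration-weighted frame
  averaging (`read_volume`, `read_series`, `summed_image`, ...).
- **Masking**: mask merging, 6-connected iterative dilation, domain
  restriction (`build_domain`, `dilate_mask`, ...).
- **Delineation**: background ROI mean, ratio thresholding, 26-connected
  components, hotspot exclusions, minimum-volume filtering
  (`delineate` and its stages).
- **Clinical metrics**: BTV, TBRmean/TBRmax, peak location with
  deterministic tie handling (`lesion_metrics`, `peak_distance_mm`).
- **Dynamics**: TAC extraction, TTP, frame-level TTP agreement, pattern
  classification with optional Savitzky–Golay smoothing
  (`extract_tac`, `classify_pattern`).
- **Evaluation**: DSC, domain-restricted voxel confusion, pooled and
  per-scan cohort summaries with bootstrap CIs, percentile case
  selection, metric concordance, longitudinal congruence
  (`dsc`, `voxel_confusion`, `cohort_summary`, ...).
- **Synthetic phantoms**: static and dynamic brain phantoms with
  ground-truth lesion masks, PSF blur, noise, extratumoral confounders
  and per-voxel kinetics, plus longitudinal cohorts
  (`generate_static`, `generate_dynamic`,
  `generate_longitudinal_cohort`).

A thin command-line wrapper with `simulate` / `delineate` / `metrics` /
`tac` / `evaluate` subcommands ships in `inst/cli/fetquant.R`.

## Worked example

Simulate a dynamic phantom with a 4.2 ml lesion at true TBR 2.0 and
pattern-II kinetics, degraded by a 5 mm PSF and 5% noise; then run the
full quantification chain:

```r
library(fetquant)

spec <- phantom_spec(
  lesions = list(lesion_spec(center = c(25, 15, 5), semi_axes = 10,
                             tbr_true = 2.0, kinetic_pattern = "II")),
  noise_sigma = 0.05, psf_fwhm = 5, seed = 7)
dyn <- generate_dynamic(spec)

pet    <- summed_image(dyn$series)                 # late 20-40 min image
domain <- build_domain(dyn$brain_mask, iterations = 20)
roi    <- background_roi(center = c(-40, 0, 0), radius = 12)

del <- delineate(pet, roi, domain)
del
#> <delineation> ratio 1.60 x background 1.001; BTV 3.016 ml in 1 component(s); 0.000 ml excluded

lesion_metrics(pet, del)
#> <lesion_metrics> BTV 3.016 ml, TBRmean 1.836, TBRmax 2.052, peak (27.0, 13.0, 7.0) mm, 1 component(s)

classify_pattern(extract_tac(dyn$series, del$btv_mask), smooth = TRUE)
#> <tac pattern II> TTP 32.5 min, end/peak 0.922 (smoothed)

dsc(del$btv_mask, dyn$truth_mask)
#> [1] 0.8452915
```

Reading the numbers: the background mean is recovered at 1.001 (truth
1.0) and the peak TBR at 2.05 (truth 2.0, plus the maximum of the noise).
The delineated BTV (3.0 ml) is smaller than the 4.1 ml ground truth and
the Dice overlap against the pre-blur truth is 0.85 — that is the
partial-volume effect of a 5 mm PSF on a 2.0-TBR lesion thresholded at
1.6, quantified rather than hidden (ground truth is defined before
degradation). The kinetic pattern is recovered (II), with the TTP one
frame after the instantaneous 27.5 min truth, as frame averaging
predicts. With `noise_sigma = 0` and `psf_fwhm = 0` the same pipeline
recovers DSC = 1.0, TBRmax = 2.0 and the truth BTV exactly.

## Further reading

The methods vignette (`vignettes/fetquant-methods.Rmd`) documents the
model and conventions in detail: threshold and connectivity choices, the
pattern-classification rule and why its smoother is a local-linear
filter, what descent is statistically detectable on an 8-frame TAC, what
the phantom does and does not emulate, and all numerical tie-breaks.
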