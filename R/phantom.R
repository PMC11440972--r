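# Synthetic static and dynamic brain PET phantoms with ground-truth lesion
# masks, kinetics and extratumoral confounders. Ground truth is defined as
# the lesion support BEFORE blurring and noise, so recovery tests quantify
# partial-volume and noise effects honestly rather than circularly.

# ---- specs ------------------------------------------------------------------

#' Specify a synthetic lesion
#'
#' An ellipsoidal lesion with a uniform uptake plateau at `tbr_true` times
#' the background, and a per-voxel 40-min kinetic class:
#' \describe{
#'   \item{I}{saturating wash-in `1 - exp(-k t)` (steadily increasing);}
#'   \item{II}{linear rise to a late peak (`peak_min` > 20) then linear
#'     descent to `end_ratio` of the peak at the end of the acquisition;}
#'   \item{III}{early peak (`peak_min` < 20) then constant descent to
#'     `end_ratio` of the peak.}
#' }
#'
#' @param center Lesion center, world mm.
#' @param semi_axes Ellipsoid semi-axes in mm (scalar recycled to 3).
#' @param tbr_true True tumor-to-background ratio of the plateau (> 1 for a
#'   FET-positive lesion); default 2.0.
#' @param kinetic_pattern `"I"`, `"II"` or `"III"`.
#' @param kinetic_params Named list overriding the pattern defaults:
#'   `wash_in_rate` (1/min, pattern I; default 0.05), `peak_min` (patterns
#'   II/III; defaults 27.5 and 10), `end_ratio` (end-of-acquisition value as
#'   a fraction of peak; defaults 0.75 and 0.6).
#' @return A `lesion_spec`.
#' @export
lesion_spec <- function(center = c(25, 15, 5), semi_axes = 10, tbr_true = 2.0,
                        kinetic_pattern = c("II", "I", "III"),
                        kinetic_params = list()) {
  kinetic_pattern <- match.arg(kinetic_pattern)
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3)
  if (tbr_true <= 0) stop("'tbr_true' must be positive", call. = FALSE)
  defaults <- switch(kinetic_pattern,
                     I = list(wash_in_rate = 0.05),
                     II = list(peak_min = 27.5, end_ratio = 0.75),
                     III = list(peak_min = 10, end_ratio = 0.6))
  kp <- utils::modifyList(defaults, kinetic_params)
  if (kinetic_pattern == "II" && kp$peak_min <= 20)
    stop("pattern II requires a late peak (peak_min > 20)", call. = FALSE)
  if (kinetic_pattern == "III" && kp$peak_min >= 20)
    stop("pattern III requires an early peak (peak_min < 20)", call. = FALSE)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 tbr_true = tbr_true, kinetic_pattern = kinetic_pattern,
                 kinetic_params = kp),
            class = "lesion_spec")
}

#' Specify an extratumoral confounding hotspot
#'
#' Parameterized hotspots at canonical anatomical offsets (not atlas-based):
#' `"vascular_rim"` near the superior brain edge, `"pituitary"`
#' inferior-central, `"skin"` as a scalp shell outside the brain. They take
#' up tracer above the TBR threshold without being tumor, emulating the
#' structures an expert excludes manually.
#'
#' @param class One of `"vascular_rim"`, `"pituitary"`, `"skin"`.
#' @param intensity_ratio Hotspot uptake as a multiple of background;
#'   default 2.5.
#' @param radius Hotspot radius (mm); for `"skin"`, the shell thickness.
#' @return A `confounder_spec`.
#' @export
confounder_spec <- function(class = c("vascular_rim", "pituitary", "skin"),
                            intensity_ratio = 2.5, radius = 5) {
  class <- match.arg(class)
  structure(list(class = class, intensity_ratio = intensity_ratio,
                 radius = radius),
            class = "confounder_spec")
}

#' Specify a synthetic brain PET phantom
#'
#' @param grid_shape Grid dimensions; default `c(96, 96, 96)`.
#' @param spacing Voxel spacing in mm; default 2 mm isotropic (PET-like
#'   resolution). The world origin sits at the grid center.
#' @param brain_semi_axes Brain ellipsoid semi-axes in mm.
#' @param background_mean Background uptake level (activity units);
#'   default 1.
#' @param noise_sigma Voxel noise standard deviation as a fraction of the
#'   background mean; default 0.05. Additive Gaussian truncated at zero - a
#'   deliberate simplification of PET Poisson statistics.
#' @param psf_fwhm Scanner point-spread FWHM in mm (isotropic Gaussian);
#'   default 5, `0` disables blurring.
#' @param lesions List of [lesion_spec()]s; default one pattern-II lesion of
#'   10 mm semi-axes at TBR 2.
#' @param confounders List of [confounder_spec()]s; default none.
#' @param seed Optional RNG seed; generation is bit-reproducible under a
#'   fixed seed.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), spacing = c(2, 2, 2),
                         brain_semi_axes = c(65, 80, 60),
                         background_mean = 1.0, noise_sigma = 0.05,
                         psf_fwhm = 5.0, lesions = list(lesion_spec()),
                         confounders = list(), seed = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (noise_sigma < 0 || psf_fwhm < 0)
    stop("'noise_sigma' and 'psf_fwhm' must be >= 0", call. = FALSE)
  if (background_mean <= 0)
    stop("'background_mean' must be positive", call. = FALSE)
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  if (inherits(confounders, "confounder_spec")) confounders <- list(confounders)
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 brain_semi_axes = as.numeric(brain_semi_axes),
                 background_mean = background_mean,
                 noise_sigma = noise_sigma, psf_fwhm = psf_fwhm,
                 lesions = lesions, confounders = confounders, seed = seed),
            class = "phantom_spec")
}

# grid with the world origin at the volume center
.phantom_affine <- function(spec) {
  .affine_from_spacing(spec$spacing,
                       -(spec$grid_shape - 1) / 2 * spec$spacing)
}

# ellipsoid support as a logical array, via per-axis normalized coordinates
.ellipsoid_mask <- function(ax, center, semi_axes) {
  outer(outer(((ax[[1]] - center[1]) / semi_axes[1])^2,
              ((ax[[2]] - center[2]) / semi_axes[2])^2, "+"),
        ((ax[[3]] - center[3]) / semi_axes[3])^2, "+") <= 1
}

.confounder_geometry <- function(cf, spec, ax) {
  b <- spec$brain_semi_axes
  switch(cf$class,
         vascular_rim = .ellipsoid_mask(ax, c(0, 0, 0.92 * b[3]),
                                        rep(cf$radius, 3)),
         pituitary = .ellipsoid_mask(ax, c(0, 0.25 * b[2], -0.75 * b[3]),
                                     rep(cf$radius, 3)),
         skin = {
           t <- cf$radius / mean(b)
           .ellipsoid_mask(ax, c(0, 0, 0), b * (1.05 + t)) &
             !.ellipsoid_mask(ax, c(0, 0, 0), b * 1.05)
         })
}

# ---- PSF blur ---------------------------------------------------------------

.gauss_kernel <- function(sigma_vox) {
  if (sigma_vox < 1e-8) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- dnorm(-r:r, sd = sigma_vox)
  k / sum(k)
}

# 1D convolution along one array axis via a banded matrix product;
# zero boundary (phantom support never touches the grid edge)
.blur_axis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  n <- dim(arr)[axis]
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- k[ok]
  }
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  aperm(array(M %*% m, dim(arr)[perm]), order(perm))
}

#' Apply an isotropic Gaussian point-spread blur
#'
#' Separable Gaussian convolution with `sigma = fwhm / 2.3548` (mm),
#' converted to voxels per axis. Used by the phantom generator to emulate
#' scanner resolution; exported because it is also handy for experiments on
#' partial-volume effects.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm Full width at half maximum in mm; `0` is a no-op.
#' @param spacing Per-axis voxel spacing in mm.
#' @return The blurred array.
#' @export
psf_blur <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  sigma_mm <- fwhm_mm / 2.3548
  for (axis in 1:3)
    arr <- .blur_axis(arr, .gauss_kernel(sigma_mm / spacing[axis]), axis)
  arr
}

# ---- kinetic generators -----------------------------------------------------

# instantaneous kinetic curves, peak-normalized to ~1
.kin_fun <- function(pattern, kp, t_end = 40) {
  switch(pattern,
         I = function(t) 1 - exp(-kp$wash_in_rate * t),
         II = ,
         III = function(t) {
           tp <- kp$peak_min; r <- kp$end_ratio
           ifelse(t <= tp, t / tp,
                  1 - (1 - r) * (t - tp) / (t_end - tp))
         })
}

# exact time-average of the kinetic curve over [a, b] (minutes)
.kin_frame_avg <- function(pattern, kp, a, b, t_end = 40) {
  if (pattern == "I") {
    k <- kp$wash_in_rate
    return(1 - (exp(-k * a) - exp(-k * b)) / (k * (b - a)))
  }
  tp <- kp$peak_min; r <- kp$end_ratio
  slope <- (1 - r) / (t_end - tp)
  seg <- function(a, b) {           # integral of the piecewise-linear curve
    lo <- min(b, tp); up <- max(a, tp)
    rise <- if (a < tp) (lo^2 - a^2) / (2 * tp) else 0
    desc <- if (b > tp) {
      h <- function(t) t - slope * (t - tp)^2 / 2
      h(b) - h(up)
    } else 0
    rise + desc
  }
  seg(a, b) / (b - a)
}

#' Frame-averaged kinetic curve for a lesion pattern
#'
#' Evaluates the pattern's generator as exact time-averages over each frame
#' interval of the schedule - the noiseless TAC a dynamic phantom voxel of
#' that class produces.
#'
#' @param pattern `"I"`, `"II"` or `"III"`.
#' @param params Kinetic parameter list (see [lesion_spec()]); missing
#'   entries take the pattern defaults.
#' @param timing A [frame_timing()].
#' @param normalize_late Rescale so the duration-weighted mean over the
#'   frames with mid-times in 20-40 min equals 1 (the convention the
#'   phantom uses so that the late summed image reproduces the static
#'   uptake level). Default `FALSE`.
#' @return Numeric vector of per-frame values.
#' @export
kinetic_curve <- function(pattern, params = list(), timing = default_timing(),
                          normalize_late = FALSE) {
  pattern <- match.arg(pattern, c("I", "II", "III"))
  defaults <- switch(pattern,
                     I = list(wash_in_rate = 0.05),
                     II = list(peak_min = 27.5, end_ratio = 0.75),
                     III = list(peak_min = 10, end_ratio = 0.6))
  kp <- utils::modifyList(defaults, params)
  t_end <- max(timing$start_s + timing$duration_s) / 60
  a <- timing$start_s / 60
  b <- (timing$start_s + timing$duration_s) / 60
  v <- vapply(seq_along(a), function(i)
    .kin_frame_avg(pattern, kp, a[i], b[i], t_end), numeric(1))
  if (normalize_late) {
    sel <- timing$mid_min >= 20 - 1e-9 & timing$mid_min <= 40 + 1e-9
    if (!any(sel)) stop("no frame mid-time in the 20-40 min window",
                        call. = FALSE)
    w <- timing$duration_s[sel] / sum(timing$duration_s[sel])
    v <- v / sum(w * v[sel])
  }
  v
}

# ---- static phantom ---------------------------------------------------------

# noiseless, unblurred tissue decomposition shared by the static and dynamic
# generators: disjoint support masks and their uptake levels
# (priority: confounder > lesion > background)
.phantom_parts <- function(spec) {
  ax <- lapply(1:3, function(axis)
    (seq_len(spec$grid_shape[axis]) - 1 - (spec$grid_shape[axis] - 1) / 2) *
      spec$spacing[axis])
  brain <- .ellipsoid_mask(ax, c(0, 0, 0), spec$brain_semi_axes)
  lesion_masks <- lapply(spec$lesions, function(ls) {
    m <- .ellipsoid_mask(ax, ls$center, ls$semi_axes)
    if (!any(m)) stop("lesion rasterizes to zero voxels", call. = FALSE)
    if (any(m & !brain))
      stop("lesion extends outside the brain ellipsoid", call. = FALSE)
    m
  })
  conf_masks <- lapply(spec$confounders, .confounder_geometry, spec = spec,
                       ax = ax)
  conf_union <- Reduce(`|`, conf_masks, array(FALSE, dim = spec$grid_shape))
  lesion_excl <- lapply(lesion_masks, function(m) m & !conf_union)
  lesion_union <- Reduce(`|`, lesion_excl,
                         array(FALSE, dim = spec$grid_shape))
  bg_mask <- brain & !lesion_union & !conf_union
  parts <- c(list(list(mask = bg_mask, level = spec$background_mean,
                       pattern = "I",
                       params = list(wash_in_rate = 0.04))),
             lapply(seq_along(spec$lesions), function(i)
               list(mask = lesion_excl[[i]],
                    level = spec$lesions[[i]]$tbr_true * spec$background_mean,
                    pattern = spec$lesions[[i]]$kinetic_pattern,
                    params = spec$lesions[[i]]$kinetic_params)),
             lapply(seq_along(spec$confounders), function(i)
               list(mask = conf_masks[[i]],
                    level = spec$confounders[[i]]$intensity_ratio *
                      spec$background_mean,
                    pattern = "III",
                    params = list(peak_min = 5, end_ratio = 0.5))))
  list(ax = ax, brain = brain, lesion_masks = lesion_masks,
       conf_union = conf_union, parts = parts)
}

.lesion_truth <- function(spec, lesion_masks, affine, timing = NULL) {
  vv <- prod(spec$spacing) / 1000
  do.call(rbind, lapply(seq_along(spec$lesions), function(i) {
    ls <- spec$lesions[[i]]
    ttp <- NA_real_
    if (!is.null(timing)) {
      g <- kinetic_curve(ls$kinetic_pattern, ls$kinetic_params, timing)
      ttp <- timing$mid_min[which.max(g)]
    }
    data.frame(lesion = i,
               center_x = ls$center[1], center_y = ls$center[2],
               center_z = ls$center[3],
               tbr_true = ls$tbr_true,
               btv_ml = sum(lesion_masks[[i]]) * vv,
               btv_ml_analytic = 4 / 3 * pi * prod(ls$semi_axes) / 1000,
               pattern = ls$kinetic_pattern,
               ttp_min = ttp)
  }))
}

#' Generate a static brain PET phantom
#'
#' Builds a brain-shaped support with homogeneous background uptake, adds
#' lesion plateaus at `tbr_true` times the background and any confounder
#' hotspots, then applies the optional Gaussian PSF blur and voxel-wise
#' truncated Gaussian noise. Ground-truth lesion masks are the ellipsoid
#' supports before blurring and noise.
#'
#' @param spec A [phantom_spec()].
#' @return A `fet_phantom` list: `image` ([image_volume()]), `brain_mask`,
#'   `truth_mask` (union of lesions), `lesion_masks` (list), and
#'   `confounder_mask` ([binary_mask()]s), `truth` (per-lesion data frame
#'   with voxelized and analytic BTV), and the `spec`.
#' @export
#' @examples
#' ph <- generate_static(phantom_spec(grid_shape = c(48, 48, 48),
#'                                    noise_sigma = 0, psf_fwhm = 0))
#' ph$truth
generate_static <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  geo <- .phantom_parts(spec)
  img <- array(0, dim = spec$grid_shape)
  for (p in geo$parts) img[p$mask] <- p$level
  img <- psf_blur(img, spec$psf_fwhm, spec$spacing)
  if (spec$noise_sigma > 0) {
    img <- img + array(rnorm(length(img), 0,
                             spec$noise_sigma * spec$background_mean),
                       dim = spec$grid_shape)
    img <- pmax(img, 0)
  }
  affine <- .phantom_affine(spec)
  lesion_masks <- lapply(geo$lesion_masks, binary_mask, affine = affine)
  truth_union <- Reduce(`|`, geo$lesion_masks,
                        array(FALSE, dim = spec$grid_shape))
  structure(list(
    image = image_volume(img, affine = affine),
    brain_mask = binary_mask(geo$brain, affine = affine),
    truth_mask = binary_mask(truth_union, affine = affine),
    lesion_masks = lesion_masks,
    confounder_mask = binary_mask(geo$conf_union, affine = affine),
    truth = .lesion_truth(spec, geo$lesion_masks, affine),
    spec = spec),
    class = "fet_phantom")
}

#' @export
print.fet_phantom <- function(x, ...) {
  cat(sprintf(paste0("<fet_phantom> %s grid, %d lesion(s), %d confounder(s),",
                     " psf %.1f mm, noise %.0f%%\n"),
              paste(x$spec$grid_shape, collapse = "x"),
              length(x$lesion_masks), length(x$spec$confounders),
              x$spec$psf_fwhm, 100 * x$spec$noise_sigma))
  invisible(x)
}

# ---- dynamic phantom --------------------------------------------------------

#' Generate a dynamic brain PET phantom
#'
#' Per-voxel 40-min kinetics: background voxels follow a mild saturating
#' wash-in (pattern I), lesion voxels follow their pattern's generator, and
#' confounder voxels an early-peak curve. Frame values are exact
#' time-averages of the generator over each frame interval, scaled so that
#' the duration-weighted 20-40 min mean of every voxel equals its static
#' uptake level - the late summed image of the series therefore reproduces
#' [generate_static()] at matched parameters (exactly so without noise).
#' Blur and noise are applied per frame as in the static generator.
#'
#' @param spec A [phantom_spec()].
#' @param timing A [frame_timing()] schedule; default 8 x 300 s.
#' @return A `fet_dynamic_phantom`: `series` ([dynamic_series()]), the same
#'   masks as [generate_static()], and `truth` including the per-lesion
#'   noiseless TTP (`ttp_min`, the argmax mid-time of the frame-averaged
#'   generator).
#' @export
generate_dynamic <- function(spec, timing = default_timing()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(timing, "frame_timing"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  geo <- .phantom_parts(spec)
  curves <- lapply(geo$parts, function(p)
    kinetic_curve(p$pattern, p$params, timing, normalize_late = TRUE))
  data <- array(0, dim = c(spec$grid_shape, timing$n_frames))
  for (f in seq_len(timing$n_frames)) {
    fr <- array(0, dim = spec$grid_shape)
    for (i in seq_along(geo$parts))
      fr[geo$parts[[i]]$mask] <- geo$parts[[i]]$level * curves[[i]][f]
    fr <- psf_blur(fr, spec$psf_fwhm, spec$spacing)
    if (spec$noise_sigma > 0)
      fr <- pmax(fr + array(rnorm(length(fr), 0,
                                  spec$noise_sigma * spec$background_mean),
                            dim = spec$grid_shape), 0)
    data[, , , f] <- fr
  }
  affine <- .phantom_affine(spec)
  truth_union <- Reduce(`|`, geo$lesion_masks,
                        array(FALSE, dim = spec$grid_shape))
  structure(list(
    series = dynamic_series(data, timing, affine = affine),
    brain_mask = binary_mask(geo$brain, affine = affine),
    truth_mask = binary_mask(truth_union, affine = affine),
    lesion_masks = lapply(geo$lesion_masks, binary_mask, affine = affine),
    confounder_mask = binary_mask(geo$conf_union, affine = affine),
    truth = .lesion_truth(spec, geo$lesion_masks, affine, timing),
    spec = spec),
    class = "fet_dynamic_phantom")
}

# ---- longitudinal cohort ----------------------------------------------------

#' Generate a longitudinal phantom cohort
#'
#' Simulates `n_patients` patients with `n_timepoints` scans each (baseline
#' plus follow-ups). Baseline lesions are randomized within clinically
#' plausible ranges; at each follow-up the lesion volume and TBR are scaled
#' by the change-model factors (volume factors act on the ellipsoid volume,
#' i.e. semi-axes scale with the cube root). Factors apply cumulatively
#' across successive follow-ups.
#'
#' @param n_patients Number of patients; default 10.
#' @param n_timepoints Scans per patient; default 3 (the usual minimum for
#'   longitudinal evaluation).
#' @param change_model List with `volume_factor` and `tbr_factor`
#'   (per-interval multiplicative change); defaults 2 and 1.
#' @param seed RNG seed for the cohort.
#' @param base_spec Template [phantom_spec()] supplying grid, noise and PSF
#'   settings (its lesion list is replaced per patient).
#' @return A list of patients, each a list with `patient_id` and `scans`
#'   (list of `fet_phantom`s with per-scan `truth`).
#' @export
generate_longitudinal_cohort <- function(n_patients = 10, n_timepoints = 3,
                                         change_model = list(volume_factor = 2,
                                                             tbr_factor = 1),
                                         seed = NULL,
                                         base_spec = phantom_spec()) {
  if (n_patients < 1L) stop("'n_patients' must be >= 1", call. = FALSE)
  vf <- change_model$volume_factor %||% 1
  tf <- change_model$tbr_factor %||% 1
  if (vf <= 0 || tf <= 0)
    stop("change-model factors must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_patients), function(pid) {
    b <- base_spec$brain_semi_axes
    center <- runif(3, -0.35, 0.35) * b
    semi <- rep(runif(1, 8, 12), 3)
    # keep the fully grown lesion inside the brain ellipsoid: bound the
    # brain-normalized center norm by the worst-case final semi-axis
    grown <- max(semi) * max(vf, 1)^((n_timepoints - 1) / 3)
    lim <- 0.95 - grown * max(1 / b)
    nrm <- sqrt(sum((center / b)^2))
    if (nrm > lim) center <- center * lim / nrm
    tbr <- runif(1, 1.8, 2.4)
    pattern <- sample(c("I", "II", "III"), 1)
    scans <- lapply(seq_len(n_timepoints), function(t) {
      ls <- lesion_spec(center = center,
                        semi_axes = semi * vf^((t - 1) / 3),
                        tbr_true = tbr * tf^(t - 1),
                        kinetic_pattern = pattern)
      sp <- base_spec
      sp$lesions <- list(ls)
      sp$seed <- NULL                  # draw from the cohort RNG stream
      generate_static(sp)
    })
    list(patient_id = pid, scans = scans)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
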