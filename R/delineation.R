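# Reference delineation: auto-contour at a fixed ratio above the mean uptake
# of a background ROI in healthy-appearing contralateral brain, with removal
# of extratumoral hotspots and a minimum-volume filter.

# ---- background ROI ---------------------------------------------------------

#' Define a background region of interest
#'
#' The background ROI sits in healthy-appearing gray and white matter,
#' typically in the hemisphere contralateral to the tumor; its mean uptake
#' normalizes all tumor-to-background ratios. The ROI is either an explicit
#' mask or a sphere given in world coordinates (rasterized as the voxels
#' whose centers lie within `radius` of `center`).
#'
#' @param mask A [binary_mask()] (mutually exclusive with `center`/`radius`).
#' @param center Sphere center, world mm (length 3).
#' @param radius Sphere radius, mm.
#' @return A `background_roi` object.
#' @export
background_roi <- function(mask = NULL, center = NULL, radius = NULL) {
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "binary_mask"))
    return(structure(list(type = "mask", mask = mask), class = "background_roi"))
  }
  if (is.null(center) || is.null(radius))
    stop("supply either 'mask' or both 'center' and 'radius'", call. = FALSE)
  if (length(center) != 3L || !is.finite(radius) || radius <= 0)
    stop("'center' must be length-3 world mm and 'radius' positive mm",
         call. = FALSE)
  structure(list(type = "sphere", center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = "background_roi")
}

#' Rasterize a background ROI on an image grid
#'
#' @param roi A [background_roi()].
#' @param vol Grid-bearing object defining the target grid.
#' @return A [binary_mask()] of the ROI voxels.
#' @export
rasterize_roi <- function(roi, vol) {
  stopifnot(inherits(roi, "background_roi"))
  vol <- .as_grid(vol)
  if (roi$type == "mask") {
    .stop_incompatible(roi$mask, vol, "ROI mask and image")
    return(roi$mask)
  }
  ax <- .axis_coords(vol)
  if (!is.null(ax)) {
    d2 <- outer(outer((ax[[1]] - roi$center[1])^2,
                      (ax[[2]] - roi$center[2])^2, "+"),
                (ax[[3]] - roi$center[3])^2, "+")
  } else {
    w <- .world_coords_matrix(vol)
    d2 <- array(rowSums(sweep(w, 2, roi$center)^2), dim = vol$grid_shape)
  }
  binary_mask(d2 <= roi$radius^2, affine = vol$affine)
}

#' Mean uptake in the background ROI
#'
#' @param image An [image_volume()].
#' @param roi A [background_roi()] (or a [binary_mask()], used directly).
#' @param min_voxels Minimum ROI size for a stable mean; default 50.
#' @return The arithmetic mean uptake over the ROI voxels (must be positive).
#' @export
background_mean <- function(image, roi, min_voxels = 50) {
  if (inherits(roi, "binary_mask")) roi <- background_roi(mask = roi)
  m <- rasterize_roi(roi, image)
  n <- sum(m$data)
  if (n == 0L) stop("background ROI rasterizes to zero voxels", call. = FALSE)
  if (n < min_voxels)
    stop("background ROI has only ", n, " voxels (< ", min_voxels,
         "); enlarge it for a stable mean", call. = FALSE)
  mu <- mean(image$data[m$data])
  if (!is.finite(mu) || mu <= 0)
    stop("background mean must be positive; got ", format(mu), call. = FALSE)
  mu
}

# ---- thresholding -----------------------------------------------------------

#' Threshold an image at a ratio of the background mean
#'
#' Marks the voxels whose uptake reaches `ratio` times the background mean
#' (at-or-above by default; set `strict = TRUE` for strictly above), then
#' intersects with the domain mask. The default ratio of 1.6 is the standard
#' cut separating metabolically active tumor from background on FET PET.
#'
#' @param image An [image_volume()].
#' @param bg_mean Positive background mean uptake.
#' @param ratio Positive threshold ratio; default 1.6.
#' @param domain A domain mask ([build_domain()] or [binary_mask()]), or
#'   `NULL` for the full grid.
#' @param strict Use a strict `>` comparison instead of `>=`.
#' @return A [binary_mask()] of supra-threshold voxels.
#' @export
threshold_delineate <- function(image, bg_mean, ratio = 1.6, domain = NULL,
                                strict = FALSE) {
  if (!is.finite(bg_mean) || bg_mean <= 0)
    stop("'bg_mean' must be positive", call. = FALSE)
  if (!is.finite(ratio) || ratio <= 0)
    stop("'ratio' must be positive", call. = FALSE)
  thr <- ratio * bg_mean
  sel <- if (strict) image$data > thr else image$data >= thr
  m <- binary_mask(sel, affine = image$affine)
  if (!is.null(domain)) m <- restrict_to_domain(m, domain)
  m
}

# ---- connected components ---------------------------------------------------

# offsets covering half of the 26-neighborhood (each unordered pair once)
.half_offsets_26 <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  o <- o[o$dz > 0 | (o$dz == 0 & o$dy > 0) |
           (o$dz == 0 & o$dy == 0 & o$dx > 0), ]
  as.matrix(o)
}

.shift_ranges <- function(n, d) {
  if (d >= 0) list(a = seq_len(n - d), b = seq_len(n - d) + d)
  else list(a = seq_len(n + d) - d, b = seq_len(n + d))
}

# membership labels (1..n_components) for the TRUE voxels of a 3D logical
# array, 26-connected, via an igraph components pass over the adjacency edges
.label_array26 <- function(arr) {
  vox <- which(arr)
  if (length(vox) == 0L)
    return(list(vox = integer(0), membership = integer(0), n = 0L))
  dm <- dim(arr)
  vid <- integer(length(arr))
  vid[vox] <- seq_along(vox)
  lin <- array(seq_along(arr), dm)
  offs <- .half_offsets_26()
  e_from <- integer(0); e_to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    rx <- .shift_ranges(dm[1], offs[r, 1])
    ry <- .shift_ranges(dm[2], offs[r, 2])
    rz <- .shift_ranges(dm[3], offs[r, 3])
    both <- arr[rx$a, ry$a, rz$a] & arr[rx$b, ry$b, rz$b]
    if (any(both)) {
      e_from <- c(e_from, vid[lin[rx$a, ry$a, rz$a][both]])
      e_to   <- c(e_to,   vid[lin[rx$b, ry$b, rz$b][both]])
    }
  }
  g <- igraph::make_graph(as.vector(rbind(e_from, e_to)), n = length(vox),
                          directed = FALSE)
  comp <- igraph::components(g)
  list(vox = vox, membership = comp$membership, n = comp$no)
}

#' Label 26-connected components of a mask
#'
#' Components are returned in decreasing order of volume; ties are broken by
#' the lowest linear voxel index of each component's first voxel (scan order
#' with z slowest, then y, then x).
#'
#' @param mask A [binary_mask()].
#' @return A list of component [binary_mask()]s, each carrying attributes
#'   `volume_ml`, `n_voxels` and `first_voxel` (linear index). An empty mask
#'   yields an empty list.
#' @export
label_components <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- .label_array26(mask$data)
  if (lab$n == 0L) return(list())
  vv <- .voxel_volume_ml(mask)
  sizes <- tabulate(lab$membership, nbins = lab$n)
  firsts <- vapply(seq_len(lab$n),
                   function(i) min(lab$vox[lab$membership == i]), integer(1))
  ord <- order(-sizes, firsts)
  lapply(ord, function(i) {
    a <- array(FALSE, dim = mask$grid_shape)
    a[lab$vox[lab$membership == i]] <- TRUE
    cm <- binary_mask(a, affine = mask$affine)
    attr(cm, "volume_ml") <- sizes[i] * vv
    attr(cm, "n_voxels") <- sizes[i]
    attr(cm, "first_voxel") <- firsts[i]
    cm
  })
}

# ---- exclusions and size filter --------------------------------------------

#' Remove extratumoral hotspot voxels from a mask
#'
#' Areas of physiologically high uptake (vascular structures, pineal body,
#' venous sinuses, skin) pass the TBR threshold without being tumor; they are
#' removed here via explicit exclusion masks.
#'
#' @param mask A [binary_mask()] (e.g. the thresholded candidate mask).
#' @param exclusion_masks List of grid-compatible [binary_mask()]s; may be
#'   empty.
#' @return The cleaned [binary_mask()] with attribute `excluded_volume_ml`
#'   recording the removed volume.
#' @export
apply_exclusions <- function(mask, exclusion_masks = list()) {
  stopifnot(inherits(mask, "binary_mask"))
  if (inherits(exclusion_masks, "binary_mask"))
    exclusion_masks <- list(exclusion_masks)
  out <- mask$data
  for (ex in exclusion_masks) {
    .stop_incompatible(mask, ex, "mask and exclusion")
    out <- out & !ex$data
  }
  res <- binary_mask(out, affine = mask$affine)
  attr(res, "excluded_volume_ml") <- (sum(mask$data) - sum(out)) *
    .voxel_volume_ml(mask)
  res
}

#' Drop components at or below a minimum volume
#'
#' Keeps the components whose volume is strictly greater than `min_ml`
#' (default 0.1 ml, the pediatric minimal active-tumor volume; use 1 ml for
#' the adult criterion).
#'
#' @param components List of component masks from [label_components()].
#' @param min_ml Non-negative volume floor in ml.
#' @return A list with `mask` (union [binary_mask()] of the surviving
#'   components), `components` (the survivors), and `removed_volume_ml`.
#' @export
min_volume_filter <- function(components, min_ml = 0.1) {
  if (min_ml < 0) stop("'min_ml' must be >= 0", call. = FALSE)
  if (length(components) == 0L)
    return(list(mask = NULL, components = list(), removed_volume_ml = 0))
  vols <- vapply(components, attr, numeric(1), "volume_ml")
  keep <- vols > min_ml
  template <- components[[1]]
  a <- array(FALSE, dim = template$grid_shape)
  for (cm in components[keep]) a <- a | cm$data
  list(mask = binary_mask(a, affine = template$affine),
       components = components[keep],
       removed_volume_ml = sum(vols[!keep]))
}

# ---- full reference procedure ----------------------------------------------

#' Threshold-based biological tumor volume delineation
#'
#' The full reference procedure: measure the background-ROI mean, threshold
#' the image at `ratio` times that mean within the search domain, remove
#' extratumoral hotspots, label 26-connected components, and drop components
#' at or below the minimum volume. The surviving union is the biological
#' tumor volume (BTV) mask.
#'
#' @param image Static uptake [image_volume()] (e.g. a 20-40 min summed
#'   image).
#' @param roi A [background_roi()] or background [binary_mask()].
#' @param domain Search domain ([build_domain()] result or [binary_mask()]).
#' @param exclusions List of exclusion [binary_mask()]s; default none.
#' @param ratio Threshold ratio over background; default 1.6.
#' @param min_ml Minimum component volume in ml (strict `>`); default 0.1.
#' @param strict Strict `>` thresholding; default `FALSE` (at-or-above).
#' @param min_roi_voxels Background ROI size floor; default 50.
#' @return A `delineation_result`: `btv_mask`, `threshold_ratio`,
#'   `background_mean`, `components` (list of component masks with volumes),
#'   `component_volumes_ml`, `excluded_volume_ml` (exclusion masks + size
#'   filter), `btv_ml`.
#' @export
#' @examples
#' ph <- generate_static(phantom_spec(grid_shape = c(48, 48, 48),
#'                                    noise_sigma = 0, psf_fwhm = 0))
#' dom <- build_domain(ph$brain_mask, iterations = 2)
#' roi <- background_roi(center = c(-30, 0, 0), radius = 12)
#' del <- delineate(ph$image, roi, dom)
#' del$btv_ml
delineate <- function(image, roi, domain, exclusions = list(), ratio = 1.6,
                      min_ml = 0.1, strict = FALSE, min_roi_voxels = 50) {
  bg <- background_mean(image, roi, min_voxels = min_roi_voxels)
  thr <- threshold_delineate(image, bg, ratio = ratio, domain = domain,
                             strict = strict)
  cleaned <- apply_exclusions(thr, exclusions)
  excl_ml <- attr(cleaned, "excluded_volume_ml")
  comps <- label_components(cleaned)
  filt <- min_volume_filter(comps, min_ml = min_ml)
  btv <- if (is.null(filt$mask))
    binary_mask(array(FALSE, dim = image$grid_shape), affine = image$affine)
  else filt$mask
  structure(list(
    btv_mask = btv,
    threshold_ratio = ratio,
    background_mean = bg,
    components = filt$components,
    component_volumes_ml = vapply(filt$components, attr, numeric(1),
                                  "volume_ml"),
    excluded_volume_ml = excl_ml + filt$removed_volume_ml,
    btv_ml = btv_ml(btv)),
    class = "delineation_result")
}

#' @export
print.delineation_result <- function(x, ...) {
  cat(sprintf(paste0("<delineation> ratio %.2f x background %.4g; BTV %.3f ml",
                     " in %d component(s); %.3f ml excluded\n"),
              x$threshold_ratio, x$background_mean, x$btv_ml,
              length(x$components), x$excluded_volume_ml))
  invisible(x)
}
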