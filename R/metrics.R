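# Semi-quantitative clinical metrics extracted from an image + BTV mask pair:
# BTV (ml), TBRmean, TBRmax, and the world-space location of peak uptake.

#' Volume of a binary mask in milliliters
#'
#' @param mask A [binary_mask()].
#' @return True-voxel count times voxel volume (mm^3) / 1000; 0 for an empty
#'   mask.
#' @export
btv_ml <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * .voxel_volume_ml(mask)
}

#' Mean and maximum tumor-to-background ratio within a mask
#'
#' An empty mask yields `NA` values (a defined-missing result signalling "no
#' FET-positive lesion"), not zeros, so that concordance analyses can drop
#' non-detections instead of biasing fits.
#'
#' @param image An [image_volume()].
#' @param mask A grid-compatible [binary_mask()] (the BTV).
#' @param bg_mean Positive background mean uptake.
#' @return A list with `tbr_mean`, `tbr_max` and `n_voxels`.
#' @export
tbr_metrics <- function(image, mask, bg_mean) {
  .stop_incompatible(image, mask, "image and mask")
  if (!is.finite(bg_mean) || bg_mean <= 0)
    stop("'bg_mean' must be positive", call. = FALSE)
  n <- sum(mask$data)
  if (n == 0L)
    return(list(tbr_mean = NA_real_, tbr_max = NA_real_, n_voxels = 0L))
  u <- image$data[mask$data]
  list(tbr_mean = mean(u) / bg_mean, tbr_max = max(u) / bg_mean,
       n_voxels = n)
}

#' World-space location of the peak uptake voxel within a mask
#'
#' Returns the world coordinates (mm) of the voxel center with the highest
#' uptake inside the mask. Ties are broken deterministically by the lowest
#' linear voxel index (scan order with z slowest, then y, then x); the tie
#' count is reported.
#'
#' @param image An [image_volume()].
#' @param mask A non-empty grid-compatible [binary_mask()].
#' @return A list with `world_mm` (length-3), `voxel` (0-based ijk),
#'   `peak_ties` and `peak_value`.
#' @export
peak_location <- function(image, mask) {
  .stop_incompatible(image, mask, "image and mask")
  vox <- which(mask$data)
  if (length(vox) == 0L) stop("mask is empty; no peak location", call. = FALSE)
  u <- image$data[vox]
  mx <- max(u)
  hits <- vox[u == mx]
  lin <- min(hits) - 1L                      # 0-based linear index
  dm <- image$grid_shape
  i <- lin %% dm[1]
  j <- (lin %/% dm[1]) %% dm[2]
  k <- lin %/% (dm[1] * dm[2])
  list(world_mm = as.numeric(voxel_to_world(image, c(i, j, k))),
       voxel = c(i, j, k), peak_ties = length(hits), peak_value = mx)
}

#' Euclidean distance between two world-space points
#'
#' @param a,b Length-3 world coordinates in mm.
#' @return Distance in mm; 0 means "identical location".
#' @export
peak_distance_mm <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Scan-level clinical metrics for a delineation
#'
#' Computes BTV, TBRmean, TBRmax and the peak location for the union BTV
#' mask (the scan-level values) and per connected component. For multi-lesion
#' scans the union values are the scan-level report.
#'
#' @param image Static uptake [image_volume()].
#' @param delineation A `delineation_result` from [delineate()], or a
#'   [binary_mask()].
#' @param bg_mean Background mean; taken from the delineation result when
#'   omitted.
#' @return A `lesion_metrics` list: `btv_ml`, `tbr_mean`, `tbr_max`,
#'   `peak_mm`, `peak_ties`, `n_components`, and `per_component` (data frame).
#' @export
lesion_metrics <- function(image, delineation, bg_mean = NULL) {
  if (inherits(delineation, "delineation_result")) {
    mask <- delineation$btv_mask
    comps <- delineation$components
    if (is.null(bg_mean)) bg_mean <- delineation$background_mean
  } else if (inherits(delineation, "binary_mask")) {
    mask <- delineation
    comps <- label_components(mask)
  } else stop("'delineation' must be a delineation_result or binary_mask",
              call. = FALSE)
  if (is.null(bg_mean))
    stop("'bg_mean' required when passing a bare mask", call. = FALSE)
  un <- tbr_metrics(image, mask, bg_mean)
  pk <- if (un$n_voxels > 0L) peak_location(image, mask) else NULL
  per <- if (length(comps)) {
    do.call(rbind, lapply(seq_along(comps), function(i) {
      tm <- tbr_metrics(image, comps[[i]], bg_mean)
      p <- peak_location(image, comps[[i]])
      data.frame(component = i, btv_ml = attr(comps[[i]], "volume_ml"),
                 tbr_mean = tm$tbr_mean, tbr_max = tm$tbr_max,
                 peak_x_mm = p$world_mm[1], peak_y_mm = p$world_mm[2],
                 peak_z_mm = p$world_mm[3])
    }))
  } else data.frame(component = integer(0), btv_ml = numeric(0),
                    tbr_mean = numeric(0), tbr_max = numeric(0),
                    peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                    peak_z_mm = numeric(0))
  structure(list(btv_ml = btv_ml(mask), tbr_mean = un$tbr_mean,
                 tbr_max = un$tbr_max,
                 peak_mm = if (is.null(pk)) rep(NA_real_, 3) else pk$world_mm,
                 peak_ties = if (is.null(pk)) NA_integer_ else pk$peak_ties,
                 n_components = length(comps), per_component = per,
                 background_mean = bg_mean),
            class = "lesion_metrics")
}

#' @export
print.lesion_metrics <- function(x, ...) {
  if (x$btv_ml == 0) {
    cat("<lesion_metrics> no FET-positive lesion (empty BTV)\n")
  } else {
    cat(sprintf(paste0("<lesion_metrics> BTV %.3f ml, TBRmean %.3f,",
                       " TBRmax %.3f, peak (%.1f, %.1f, %.1f) mm, %d",
                       " component(s)\n"),
                x$btv_ml, x$tbr_mean, x$tbr_max,
                x$peak_mm[1], x$peak_mm[2], x$peak_mm[3], x$n_components))
  }
  invisible(x)
}
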