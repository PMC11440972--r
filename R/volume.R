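#' @importFrom stats dnorm rnorm runif median quantile sd cor lm coef setNames
#' @importFrom utils read.csv write.csv
NULL

# ---- constructors -----------------------------------------------------------

.affine_from_spacing <- function(spacing, origin = c(0, 0, 0)) {
  rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
}

.validate_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stop("'affine' must be a 4x4 matrix", call. = FALSE)
  if (any(!is.finite(affine)))
    stop("'affine' contains non-finite entries", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("degenerate affine: voxel-to-world map is not invertible", call. = FALSE)
  invisible(affine)
}

#' Construct a 3D image volume
#'
#' An `image_volume` carries a 3D scalar uptake grid together with its voxel
#' spacing (mm) and a voxel-index-to-world-mm affine (0-based voxel indices,
#' NIfTI convention). Spacing is always derived from the affine so the two
#' cannot disagree.
#'
#' @param data Numeric 3D array of uptake values (arbitrary
#'   activity-concentration units).
#' @param spacing Per-axis voxel edge length in mm (used only when `affine`
#'   is `NULL`).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   affine built from `spacing` with the world origin at voxel (0,0,0).
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `affine` and `grid_shape`.
#' @export
#' @examples
#' v <- image_volume(array(1, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
#' v$grid_shape
image_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim = dim(data)[1:3])
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array; got ", length(dim(data)),
         " dimensions (use read_series()/dynamic_series() for 4D data)",
         call. = FALSE)
  if (is.null(affine)) {
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("'spacing' must be 3 strictly positive values (mm)", call. = FALSE)
    affine <- .affine_from_spacing(spacing)
  }
  .validate_affine(affine)
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0))
    stop("voxel spacing derived from affine must be strictly positive",
         call. = FALSE)
  structure(list(data = data, spacing = spacing,
                 affine = unname(affine[, , drop = FALSE]),
                 grid_shape = dim(data)),
            class = "image_volume")
}

#' Construct a binary mask on an image grid
#'
#' A `binary_mask` is an `image_volume` whose data are logical; it marks a
#' voxel set (brain mask, delineation, ...) on a PET grid.
#'
#' @param data Logical (or coercible) 3D array.
#' @param spacing,affine As in [image_volume()].
#' @param like Optional grid-bearing object whose spacing/affine are reused.
#' @return An object of class `c("binary_mask", "image_volume")`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), affine = NULL, like = NULL) {
  if (!is.null(like)) {
    affine <- like$affine
    if (is.logical(data) && is.null(dim(data)))
      data <- array(data, dim = like$grid_shape)
  }
  storage.mode(data) <- "logical"
  v <- image_volume(data, spacing = spacing, affine = affine)
  class(v) <- c("binary_mask", "image_volume")
  v
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  cat(sprintf("  uptake range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s grid, %d true voxels (%.3f ml)\n",
              paste(x$grid_shape, collapse = "x"),
              sum(x$data), btv_ml(x)))
  invisible(x)
}

# ---- grid compatibility and coordinates ------------------------------------

#' Check that two grid-bearing objects live on the same grid
#'
#' Two objects are grid-compatible when their shapes are equal and their
#' affines agree element-wise within `tol` mm.
#'
#' @param a,b Objects with `grid_shape` and `affine` fields
#'   ([image_volume()], [binary_mask()], [dynamic_series()], domain masks).
#' @param tol Tolerance (mm) on affine entries; default `1e-3`.
#' @return `TRUE` or `FALSE`.
#' @export
check_grid_compatible <- function(a, b, tol = 1e-3) {
  a <- .as_grid(a); b <- .as_grid(b)
  identical(as.integer(a$grid_shape), as.integer(b$grid_shape)) &&
    max(abs(a$affine - b$affine)) <= tol
}

.as_grid <- function(x) {
  if (inherits(x, "fet_domain_mask")) return(x$mask)
  x
}

.stop_incompatible <- function(a, b, what = "inputs") {
  if (!check_grid_compatible(a, b))
    stop(what, " are not grid-compatible (shape or affine mismatch)",
         call. = FALSE)
  invisible(TRUE)
}

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param vol A grid-bearing object.
#' @param ijk Integer matrix (n x 3) or length-3 vector of 0-based voxel
#'   indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  vol <- .as_grid(vol)
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

# per-axis world coordinates when the affine has no off-diagonal rotation;
# NULL otherwise (callers then fall back to the full coordinate matrix)
.axis_coords <- function(vol) {
  vol <- .as_grid(vol)
  R <- vol$affine[1:3, 1:3]
  if (max(abs(R - diag(diag(R)))) > 1e-9) return(NULL)
  lapply(1:3, function(ax)
    vol$affine[ax, 4] + (seq_len(vol$grid_shape[ax]) - 1) * R[ax, ax])
}

.world_coords_matrix <- function(vol) {
  vol <- .as_grid(vol)
  dm <- vol$grid_shape
  ijk <- cbind(
    rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3]),
    rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
    rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2]))
  voxel_to_world(vol, ijk)
}

.voxel_volume_ml <- function(vol) prod(.as_grid(vol)$spacing) / 1000

# ---- frame timing -----------------------------------------------------------

#' Frame timing of a dynamic acquisition
#'
#' @param start_s Per-frame acquisition start, seconds post-injection;
#'   strictly increasing.
#' @param duration_s Per-frame length in seconds; positive, non-overlapping.
#' @param max_span_min Configured acquisition length (minutes); frames must
#'   end within it. Default 40.
#' @return A `frame_timing` object with derived `mid_min` (frame mid-times in
#'   minutes).
#' @export
#' @examples
#' ft <- frame_timing(seq(0, 2100, by = 300), rep(300, 8))
#' ft$mid_min
frame_timing <- function(start_s, duration_s, max_span_min = 40) {
  start_s <- as.numeric(start_s); duration_s <- as.numeric(duration_s)
  if (length(start_s) != length(duration_s))
    stop("start and duration must have equal length", call. = FALSE)
  if (length(start_s) < 1L) stop("at least one frame required", call. = FALSE)
  if (any(duration_s <= 0)) stop("frame durations must be positive", call. = FALSE)
  if (is.unsorted(start_s, strictly = TRUE))
    stop("frame starts must be strictly increasing", call. = FALSE)
  n <- length(start_s)
  if (n > 1L && any(start_s[-1] < (start_s + duration_s)[-n] - 1e-9))
    stop("frames overlap", call. = FALSE)
  if (max(start_s + duration_s) > max_span_min * 60 + 1e-9)
    stop("frames extend beyond the configured acquisition length of ",
         max_span_min, " min", call. = FALSE)
  structure(list(start_s = start_s, duration_s = duration_s,
                 mid_min = (start_s + duration_s / 2) / 60,
                 n_frames = n, max_span_min = max_span_min),
            class = "frame_timing")
}

#' Default dynamic framing schedule
#'
#' Eight 5-minute frames covering a 40-minute acquisition (mid-times 2.5,
#' 7.5, ..., 37.5 min). The true clinical framing scheme varies by site; this
#' schedule is a configurable stand-in.
#'
#' @param n_frames Number of frames.
#' @param frame_s Frame duration in seconds.
#' @return A [frame_timing()] object.
#' @export
default_timing <- function(n_frames = 8, frame_s = 300) {
  frame_timing(seq(0, by = frame_s, length.out = n_frames),
               rep(frame_s, n_frames),
               max_span_min = n_frames * frame_s / 60)
}

#' @export
print.frame_timing <- function(x, ...) {
  cat(sprintf("<frame_timing> %d frames, %.1f-%.1f min, mid-times %s min\n",
              x$n_frames, min(x$start_s) / 60,
              max(x$start_s + x$duration_s) / 60,
              paste(signif(x$mid_min, 4), collapse = ", ")))
  invisible(x)
}

#' Read a frame-timing sidecar
#'
#' Accepts a BIDS-PET-style JSON sidecar with arrays `FrameTimesStart` and
#' `FrameDuration` (seconds), or a CSV file with columns `start_s,duration_s`.
#'
#' @param path Path to `.json` or `.csv` sidecar.
#' @param max_span_min Passed to [frame_timing()].
#' @return A [frame_timing()] object.
#' @export
read_frame_timing <- function(path, max_span_min = 40) {
  if (!file.exists(path)) stop("timing sidecar not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::fromJSON(path)
    if (is.null(j$FrameTimesStart) || is.null(j$FrameDuration))
      stop("JSON sidecar must contain 'FrameTimesStart' and 'FrameDuration'",
           call. = FALSE)
    frame_timing(j$FrameTimesStart, j$FrameDuration, max_span_min)
  } else {
    d <- read.csv(path)
    if (!all(c("start_s", "duration_s") %in% names(d)))
      stop("CSV sidecar must have columns 'start_s' and 'duration_s'",
           call. = FALSE)
    frame_timing(d$start_s, d$duration_s, max_span_min)
  }
}

#' Write a frame-timing sidecar (BIDS-PET-style JSON)
#'
#' @param timing A [frame_timing()] object.
#' @param path Output `.json` path.
#' @export
write_frame_timing <- function(timing, path) {
  jsonlite::write_json(list(FrameTimesStart = timing$start_s,
                            FrameDuration = timing$duration_s),
                       path, digits = NA)
  invisible(path)
}

# ---- dynamic series ---------------------------------------------------------

#' Construct a dynamic PET series
#'
#' An ordered stack of frames on one shared grid, plus frame timing. Frames
#' are stored as a 4D array (x, y, z, frame); [series_frame()] extracts a
#' single frame as an [image_volume()].
#'
#' @param data 4D numeric array or a list of grid-compatible
#'   [image_volume()]s.
#' @param timing A [frame_timing()] whose length matches the frame count.
#' @param spacing,affine Grid metadata (as in [image_volume()]); ignored when
#'   `data` is a list of volumes.
#' @return A `dynamic_series` object.
#' @export
dynamic_series <- function(data, timing, spacing = c(1, 1, 1), affine = NULL) {
  if (is.list(data)) {
    frames <- data
    for (f in frames[-1]) .stop_incompatible(frames[[1]], f, "series frames")
    affine <- frames[[1]]$affine
    data <- array(unlist(lapply(frames, `[[`, "data"), use.names = FALSE),
                  dim = c(frames[[1]]$grid_shape, length(frames)))
  }
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, frame)", call. = FALSE)
  if (!inherits(timing, "frame_timing"))
    stop("'timing' must be a frame_timing object", call. = FALSE)
  if (dim(data)[4] != timing$n_frames)
    stop("frame-count mismatch: image has ", dim(data)[4],
         " frames but timing lists ", timing$n_frames, call. = FALSE)
  if (is.null(affine)) affine <- .affine_from_spacing(spacing)
  .validate_affine(affine)
  structure(list(data = data, timing = timing,
                 spacing = sqrt(colSums(affine[1:3, 1:3]^2)),
                 affine = unname(affine), grid_shape = dim(data)[1:3],
                 n_frames = dim(data)[4]),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %s grid, %d frames over %.1f min\n",
              paste(x$grid_shape, collapse = "x"), x$n_frames,
              max(x$timing$start_s + x$timing$duration_s) / 60))
  invisible(x)
}

#' Extract one frame of a dynamic series as an image volume
#'
#' @param series A [dynamic_series()].
#' @param i Frame index (1-based).
#' @return An [image_volume()].
#' @export
series_frame <- function(series, i) {
  stopifnot(inherits(series, "dynamic_series"))
  if (i < 1 || i > series$n_frames) stop("frame index out of range", call. = FALSE)
  image_volume(series$data[, , , i, drop = FALSE], affine = series$affine)
}

#' Collapse a dynamic series to a late summed image
#'
#' Computes the duration-weighted mean of the frames whose mid-time falls in
#' the closed window `[window_start, window_end]`. With the defaults this is
#' the standard late (20-40 min) summed image of a 40-min acquisition.
#'
#' @param series A [dynamic_series()].
#' @param window_start,window_end Window bounds in minutes; defaults 20 and 40.
#' @return An [image_volume()] on the series grid.
#' @export
summed_image <- function(series, window_start = 20, window_end = 40) {
  stopifnot(inherits(series, "dynamic_series"))
  mid <- series$timing$mid_min
  sel <- which(mid >= window_start - 1e-9 & mid <= window_end + 1e-9)
  if (length(sel) == 0L)
    stop("no frame mid-time falls in [", window_start, ", ", window_end,
         "] min", call. = FALSE)
  w <- series$timing$duration_s[sel]
  w <- w / sum(w)
  acc <- array(0, dim = series$grid_shape)
  for (k in seq_along(sel)) acc <- acc + w[k] * series$data[, , , sel[k]]
  image_volume(acc, affine = series$affine)
}

# ---- NIfTI I/O --------------------------------------------------------------

.affine_of_nifti <- function(img) {
  m <- RNifti::xform(img)
  m <- matrix(as.numeric(m), 4, 4)
  m
}

#' Read a 3D NIfTI volume
#'
#' @param path Path to a NIfTI-1 file (`.nii`/`.nii.gz`) with 3 spatial
#'   dimensions.
#' @return An [image_volume()] with affine and spacing taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] > 1L)
    stop("'", path, "' is a 4D image; use read_series() for dynamic data",
         call. = FALSE)
  if (length(d) > 4L || length(d) < 3L)
    stop("'", path, "' does not have 3 spatial dimensions", call. = FALSE)
  arr <- array(as.numeric(img), dim = d[1:3])
  image_volume(arr, affine = .affine_of_nifti(img))
}

#' Read a binary mask from NIfTI
#'
#' Any non-zero voxel is treated as inside the mask.
#'
#' @param path Path to a NIfTI-1 mask file.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$data != 0, affine = v$affine)
}

#' Read a 4D dynamic NIfTI series with its timing sidecar
#'
#' @param path Path to a 4D NIfTI-1 file.
#' @param timing Either a path to a timing sidecar (see
#'   [read_frame_timing()]) or a [frame_timing()] object.
#' @param max_span_min Passed to [read_frame_timing()] when `timing` is a
#'   path.
#' @return A [dynamic_series()] with validated timing.
#' @export
read_series <- function(path, timing, max_span_min = 40) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("'", path, "' is not a 4D image; use read_volume() for static data",
         call. = FALSE)
  if (is.character(timing)) timing <- read_frame_timing(timing, max_span_min)
  arr <- array(as.numeric(img), dim = d)
  dynamic_series(arr, timing, affine = .affine_of_nifti(img))
}

.write_nifti <- function(data, affine, path, datatype) {
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(data, pixdim = spacing, datatype = datatype)
  # sform only: this RNifti's qform assignment resets pixdim, and readers
  # (including xform()) fall back to the sform when the qform code is unset
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a volume or mask to NIfTI-1
#'
#' Volumes are written as double-precision data, masks as integer 0/1
#' volumes. The affine is stored in both the sform and qform.
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_mask"))
    .write_nifti(array(as.integer(vol$data), dim = vol$grid_shape),
                 vol$affine, path, "uint8")
  else
    .write_nifti(vol$data, vol$affine, path, "double")
}

#' @rdname write_volume
#' @export
write_mask <- function(vol, path) {
  stopifnot(inherits(vol, "binary_mask"))
  write_volume(vol, path)
}

#' Write a dynamic series to 4D NIfTI plus JSON timing sidecar
#'
#' @param series A [dynamic_series()].
#' @param path Output 4D NIfTI path.
#' @param timing_path Optional path for a BIDS-PET-style JSON timing sidecar.
#' @export
write_series <- function(series, path, timing_path = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  .write_nifti(series$data, series$affine, path, "double")
  if (!is.null(timing_path)) write_frame_timing(series$timing, timing_path)
  invisible(path)
}
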