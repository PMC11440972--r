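# Time-activity-curve analysis of dynamic FET PET: TAC extraction, time to
# peak, and kinetic pattern classification (patterns I-III). Later patterns
# (early peak then descent) are associated with more aggressive biology.

#' Extract a time-activity curve from a dynamic series
#'
#' Per-frame arithmetic mean of the uptake over a mask, optionally with a
#' parallel background-ROI curve.
#'
#' @param series A [dynamic_series()].
#' @param mask Non-empty grid-compatible [binary_mask()] (typically the BTV).
#' @param background Optional [background_roi()] or [binary_mask()]
#'   whose per-frame mean is reported alongside.
#' @return A `tac` object: `mid_min`, `values`, optional
#'   `background_values`, and the `timing`.
#' @export
extract_tac <- function(series, mask, background = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  .stop_incompatible(series, mask, "series and mask")
  idx <- which(mask$data)
  if (length(idx) == 0L) stop("mask is empty; no TAC to extract", call. = FALSE)
  nvox <- prod(series$grid_shape)
  vals <- vapply(seq_len(series$n_frames), function(f)
    mean(series$data[(f - 1) * nvox + idx]), numeric(1))
  bgv <- NULL
  if (!is.null(background)) {
    if (inherits(background, "binary_mask"))
      background <- background_roi(mask = background)
    bm <- rasterize_roi(background, series)
    bidx <- which(bm$data)
    bgv <- vapply(seq_len(series$n_frames), function(f)
      mean(series$data[(f - 1) * nvox + bidx]), numeric(1))
  }
  structure(list(mid_min = series$timing$mid_min, values = vals,
                 background_values = bgv, timing = series$timing),
            class = "tac")
}

#' Construct a TAC from bare vectors
#'
#' @param mid_min Strictly increasing frame mid-times in minutes.
#' @param values Non-negative mean uptake per frame.
#' @param timing Optional [frame_timing()] the mid-times came from.
#' @return A `tac` object.
#' @export
tac <- function(mid_min, values, timing = NULL) {
  if (length(mid_min) != length(values))
    stop("'mid_min' and 'values' must have equal length", call. = FALSE)
  if (is.unsorted(mid_min, strictly = TRUE))
    stop("'mid_min' must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("TAC values must be non-negative", call. = FALSE)
  structure(list(mid_min = as.numeric(mid_min), values = as.numeric(values),
                 background_values = NULL, timing = timing),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, %.1f-%.1f min, peak %.4g at %.1f min\n",
              length(x$values), min(x$mid_min), max(x$mid_min),
              max(x$values), time_to_peak(x)))
  invisible(x)
}

#' Time-to-peak of a time-activity curve
#'
#' The mid-time of the frame with the maximum value; ties resolve to the
#' earliest frame. No sub-frame interpolation is attempted - TTP is reported
#' at frame mid-time resolution.
#'
#' @param tac A `tac` with at least 2 frames.
#' @return TTP in minutes.
#' @export
time_to_peak <- function(tac) {
  stopifnot(inherits(tac, "tac"))
  if (length(tac$values) < 2L)
    stop("TTP needs at least 2 frames", call. = FALSE)
  tac$mid_min[which.max(tac$values)]
}

#' Frame-level agreement between two TTP estimates
#'
#' @param a,b TTP values in minutes; each must be a frame mid-time of the
#'   schedule.
#' @param timing The [frame_timing()] defining the schedule.
#' @return `"identical"` (same frame), `"within_one_frame"` (adjacent
#'   frames), or `"discordant"`.
#' @export
ttp_agreement <- function(a, b, timing) {
  stopifnot(inherits(timing, "frame_timing"))
  ia <- which(abs(timing$mid_min - a) < 1e-6)
  ib <- which(abs(timing$mid_min - b) < 1e-6)
  if (length(ia) != 1L || length(ib) != 1L)
    stop("TTP value is not a frame mid-time of the schedule", call. = FALSE)
  d <- abs(ia - ib)
  if (d == 0L) "identical" else if (d == 1L) "within_one_frame" else "discordant"
}

# 3-frame local-linear (degree-1 Savitzky-Golay) smoother. Interior frames
# get the centered 3-frame mean; the first and last frames get the value of
# a least-squares line through their 3-frame window. A plain truncated
# average at the final frame would pull it toward the peak and erase the
# small descents that separate late-peak curves from steadily rising ones.
.smooth_tac <- function(v) {
  n <- length(v)
  s <- vapply(seq_len(n), function(i)
    mean(v[max(1, i - 1):min(n, i + 1)]), numeric(1))
  if (n >= 3) {
    s[1] <- (5 * v[1] + 2 * v[2] - v[3]) / 6
    s[n] <- (5 * v[n] + 2 * v[n - 1] - v[n - 2]) / 6
  }
  s
}

#' Classify a TAC into kinetic pattern I, II or III
#'
#' Operationalizes the standard three-class FET kinetics reading:
#' \describe{
#'   \item{I}{constantly increasing without an identifiable peak - the peak
#'     frame is the final frame, or the final value is within
#'     `increasing_tol` of the peak value;}
#'   \item{II}{peak past the midway cutoff (TTP > `cutoff_min`, default
#'     20 min) followed by a plateau or small descent;}
#'   \item{III}{early peak (TTP below the cutoff) followed by descent.}
#' }
#' The rules are applied in that order; the II/III split is by peak time.
#' The end-to-peak ratio and a plateau flag (`end/peak >= plateau_ratio`)
#' are reported for audit but the ratio cutoff `plateau_ratio` is not itself
#' a discriminator.
#'
#' @param tac A `tac` with at least 3 frames.
#' @param cutoff_min Early/late peak cutoff in minutes; default 20.
#' @param plateau_ratio Reported plateau threshold; default 0.9.
#' @param increasing_tol Fractional tolerance under which the final value
#'   counts as "no identifiable descent"; default 0.05.
#' @param smooth Apply a 3-frame local-linear (Savitzky-Golay) smoother
#'   before classification (off by default; useful on noisy curves). The
#'   end frames are fitted, not averaged with a truncated window, so small
#'   terminal descents survive smoothing.
#' @return A `tac_classification`: `ttp_min`, `pattern` ("I"/"II"/"III"),
#'   `peak_value`, `end_to_peak_ratio`, `plateau` flag, `smoothed` flag.
#' @export
classify_pattern <- function(tac, cutoff_min = 20, plateau_ratio = 0.9,
                             increasing_tol = 0.05, smooth = FALSE) {
  stopifnot(inherits(tac, "tac"))
  v <- tac$values
  if (length(v) < 3L)
    stop("pattern classification needs at least 3 frames", call. = FALSE)
  if (smooth) v <- .smooth_tac(v)
  pk <- which.max(v)                       # earliest frame on ties
  ttp <- tac$mid_min[pk]
  ratio <- if (v[pk] > 0) v[length(v)] / v[pk] else 1
  pattern <- if (pk == length(v) || ratio >= 1 - increasing_tol) "I"
  else if (ttp > cutoff_min) "II"
  else "III"
  structure(list(ttp_min = ttp, pattern = pattern, peak_value = v[pk],
                 end_to_peak_ratio = ratio,
                 plateau = ratio >= plateau_ratio, smoothed = smooth),
            class = "tac_classification")
}

#' @export
print.tac_classification <- function(x, ...) {
  cat(sprintf("<tac pattern %s> TTP %.1f min, end/peak %.3f%s\n",
              x$pattern, x$ttp_min, x$end_to_peak_ratio,
              if (x$smoothed) " (smoothed)" else ""))
  invisible(x)
}
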