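# End-to-end orchestration: per-scan reports (delineation + clinical metrics
# + TAC classification) and cohort-level evaluation, with the resolved
# configuration embedded in every report for auditability.

#' Pipeline configuration
#'
#' Collects the tunable constants of the whole pipeline. The defaults are
#' the standard clinical values: TBR threshold 1.6 over background, 0.1 ml
#' minimum active-tumor volume, 20 dilation iterations for the search
#' domain, the 20-40 min late summed window, a 20-min early/late TTP
#' cutoff, and a DSC detection threshold of 0.8.
#'
#' @param threshold_ratio TBR threshold over background; default 1.6.
#' @param min_ml Minimum component volume (ml, strict `>`); default 0.1.
#' @param dilation_iterations Domain dilation iterations; default 20.
#' @param summed_window Late summed-image window, minutes; default
#'   `c(20, 40)`.
#' @param ttp_cutoff Early/late peak cutoff for TAC patterns (min);
#'   default 20.
#' @param detection_threshold DSC detection cut; default 0.8.
#' @param bootstrap_resamples Bootstrap resamples for cohort CIs; default
#'   10000.
#' @param seed RNG seed used wherever the pipeline draws random numbers.
#' @param tac_smooth Smooth TACs before classification; default `FALSE`.
#' @param min_roi_voxels Background ROI size floor; default 50.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold_ratio = 1.6, min_ml = 0.1,
                            dilation_iterations = 20,
                            summed_window = c(20, 40), ttp_cutoff = 20,
                            detection_threshold = 0.8,
                            bootstrap_resamples = 10000, seed = NULL,
                            tac_smooth = FALSE, min_roi_voxels = 50) {
  structure(list(threshold_ratio = threshold_ratio, min_ml = min_ml,
                 dilation_iterations = dilation_iterations,
                 summed_window = summed_window, ttp_cutoff = ttp_cutoff,
                 detection_threshold = detection_threshold,
                 bootstrap_resamples = bootstrap_resamples, seed = seed,
                 tac_smooth = tac_smooth, min_roi_voxels = min_roi_voxels),
            class = "pipeline_config")
}

#' Run the full pipeline on one scan
#'
#' Builds the search domain from the anatomical masks, delineates the BTV on
#' the static image (derived from the dynamic series' late summed image when
#' no static image is given), extracts the clinical metrics, and - when a
#' dynamic series is available and the BTV is non-empty - the TAC with its
#' TTP and kinetic pattern.
#'
#' @param pet Static uptake [image_volume()], or `NULL` to derive it from
#'   `series`.
#' @param brain_mask Brain [binary_mask()].
#' @param roi [background_roi()] (or background [binary_mask()]).
#' @param medulla_mask Optional medulla [binary_mask()].
#' @param series Optional [dynamic_series()] for TAC analysis.
#' @param exclusions List of exclusion [binary_mask()]s.
#' @param config A [pipeline_config()].
#' @param scan_id Identifier stored in the report.
#' @return A `scan_report` list: `scan_id`, `delineation`, `metrics`,
#'   `tac`, `tac_classification` (both `NULL` without dynamic data), and
#'   `config`.
#' @export
run_scan <- function(pet = NULL, brain_mask, roi, medulla_mask = NULL,
                     series = NULL, exclusions = list(),
                     config = pipeline_config(), scan_id = "scan") {
  if (is.null(pet)) {
    if (is.null(series))
      stop("supply a static image or a dynamic series", call. = FALSE)
    pet <- summed_image(series, config$summed_window[1],
                        config$summed_window[2])
  }
  domain <- build_domain(brain_mask, medulla_mask,
                         iterations = config$dilation_iterations)
  del <- delineate(pet, roi, domain, exclusions = exclusions,
                   ratio = config$threshold_ratio, min_ml = config$min_ml,
                   min_roi_voxels = config$min_roi_voxels)
  met <- lesion_metrics(pet, del)
  curve <- NULL; cls <- NULL
  if (!is.null(series) && del$btv_ml > 0) {
    curve <- extract_tac(series, del$btv_mask)
    cls <- classify_pattern(curve, cutoff_min = config$ttp_cutoff,
                            smooth = config$tac_smooth)
  }
  structure(list(scan_id = scan_id, delineation = del, metrics = met,
                 tac = curve, tac_classification = cls, config = config),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("<scan_report> %s\n", x$scan_id))
  print(x$delineation)
  print(x$metrics)
  if (!is.null(x$tac_classification)) print(x$tac_classification)
  else cat("  no dynamic data: TAC fields absent\n")
  invisible(x)
}

# JSON-serializable view of a scan report (no voxel data)
.report_record <- function(x) {
  m <- x$metrics
  rec <- list(scan_id = x$scan_id,
              background_mean = x$delineation$background_mean,
              threshold_ratio = x$delineation$threshold_ratio,
              btv_ml = m$btv_ml, tbr_mean = m$tbr_mean, tbr_max = m$tbr_max,
              peak_x_mm = m$peak_mm[1], peak_y_mm = m$peak_mm[2],
              peak_z_mm = m$peak_mm[3], peak_ties = m$peak_ties,
              n_components = m$n_components,
              component_volumes_ml = x$delineation$component_volumes_ml,
              excluded_volume_ml = x$delineation$excluded_volume_ml,
              config = unclass(x$config))
  if (!is.null(x$tac_classification)) {
    rec$ttp_min <- x$tac_classification$ttp_min
    rec$tac_pattern <- x$tac_classification$pattern
    rec$end_to_peak_ratio <- x$tac_classification$end_to_peak_ratio
  }
  rec
}

#' Write a scan report to JSON (and the TAC to CSV)
#'
#' @param report A `scan_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_scan_report <- function(report, dir) {
  stopifnot(inherits(report, "scan_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jp <- file.path(dir, paste0(report$scan_id, "_report.json"))
  jsonlite::write_json(.report_record(report), jp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  paths <- jp
  if (!is.null(report$tac)) {
    cp <- file.path(dir, paste0(report$scan_id, "_tac.csv"))
    write.csv(data.frame(mid_time_min = report$tac$mid_min,
                         mean_uptake = report$tac$values),
              cp, row.names = FALSE)
    paths <- c(paths, cp)
  }
  invisible(paths)
}

#' Run the pipeline over a cohort of scans
#'
#' Each manifest entry is a list of [run_scan()] arguments (`pet`,
#' `brain_mask`, `roi`, optionally `medulla_mask`, `series`, `exclusions`,
#' `scan_id`) plus an optional `ref_mask` - a reference delineation to
#' evaluate against. With references present the result includes per-scan
#' DSC/confusion scores, a [cohort_summary()], and the concordance of
#' TBRmean/TBRmax/BTV between the pipeline delineation and the reference
#' masks.
#'
#' @param manifest Non-empty list of scan entries.
#' @param config A [pipeline_config()].
#' @return A `cohort_report`: `per_scan` (data frame), `reports` (list of
#'   `scan_report`s), and with references `scores`, `summary`,
#'   `concordance`.
#' @export
run_cohort <- function(manifest, config = pipeline_config()) {
  if (length(manifest) < 1L) stop("empty cohort manifest", call. = FALSE)
  reports <- vector("list", length(manifest))
  scores <- NULL
  conc_rows <- list()
  for (i in seq_along(manifest)) {
    e <- manifest[[i]]
    id <- e$scan_id %||% paste0("scan", i)
    if (is.null(e$pet) && !is.null(e$series))
      e$pet <- summed_image(e$series, config$summed_window[1],
                            config$summed_window[2])
    rep_i <- run_scan(pet = e$pet, brain_mask = e$brain_mask, roi = e$roi,
                      medulla_mask = e$medulla_mask, series = e$series,
                      exclusions = e$exclusions %||% list(),
                      config = config, scan_id = id)
    reports[[i]] <- rep_i
    if (!is.null(e$ref_mask)) {
      domain <- build_domain(e$brain_mask, e$medulla_mask,
                             iterations = config$dilation_iterations)
      scores <- rbind(scores,
                      scan_score(id, rep_i$delineation$btv_mask, e$ref_mask,
                                 domain, config$detection_threshold))
      ref_met <- lesion_metrics(e$pet, e$ref_mask,
                                bg_mean = rep_i$delineation$background_mean)
      conc_rows[[length(conc_rows) + 1L]] <- data.frame(
        scan_id = id,
        auto_tbr_mean = rep_i$metrics$tbr_mean,
        auto_tbr_max = rep_i$metrics$tbr_max,
        auto_btv_ml = rep_i$metrics$btv_ml,
        ref_tbr_mean = ref_met$tbr_mean,
        ref_tbr_max = ref_met$tbr_max,
        ref_btv_ml = ref_met$btv_ml)
    }
  }
  per_scan <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(.report_record(r)[c("scan_id", "btv_ml", "tbr_mean",
                                      "tbr_max", "n_components")])))
  out <- list(per_scan = per_scan, reports = reports, config = config)
  if (!is.null(scores)) {
    out$scores <- scores
    out$summary <- cohort_summary(scores, config$detection_threshold,
                                  n_boot = config$bootstrap_resamples,
                                  seed = config$seed)
    conc <- do.call(rbind, conc_rows)
    out$concordance <- list(
      tbr_mean = try_concordance(conc$auto_tbr_mean, conc$ref_tbr_mean),
      tbr_max = try_concordance(conc$auto_tbr_max, conc$ref_tbr_max),
      btv_ml = try_concordance(conc$auto_btv_ml, conc$ref_btv_ml),
      table = conc)
  }
  structure(out, class = "cohort_report")
}

#' Metric concordance that degrades to NULL on too few pairs
#'
#' @param a,b As in [metric_concordance()].
#' @return The concordance list, or `NULL` when fewer than 3 complete pairs
#'   exist.
#' @export
try_concordance <- function(a, b) {
  tryCatch(metric_concordance(a, b), error = function(e) NULL)
}
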