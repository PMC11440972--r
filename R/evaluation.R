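# Comparison of candidate delineations (e.g. from an external segmentation
# model) against references: Dice overlap, voxel-level confusion metrics,
# cohort summaries with bootstrap CIs, representative-case selection, metric
# concordance, and longitudinal congruence.

#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`. A DSC of 1 means complete overlap. If exactly
#' one mask is empty the DSC is 0 (a missed lesion); if both are empty the
#' DSC is 1 by convention, flagged via the `"trivial"` attribute.
#'
#' @param pred,ref Grid-compatible [binary_mask()]s.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(pred, ref) {
  .stop_incompatible(pred, ref, "prediction and reference")
  na <- sum(pred$data); nb <- sum(ref$data)
  if (na + nb == 0L)
    return(structure(1, trivial = TRUE))
  2 * sum(pred$data & ref$data) / (na + nb)
}

#' Voxel-level confusion counts within an evaluation domain
#'
#' Counts true/false positives/negatives of `pred` against `ref`, restricted
#' to the voxels of the evaluation domain (so uninformative air voxels never
#' inflate the negatives).
#'
#' @param pred,ref Grid-compatible [binary_mask()]s.
#' @param domain Evaluation domain ([build_domain()] result or
#'   [binary_mask()]).
#' @return A `voxel_confusion` list: `tp`, `fp`, `fn`, `tn` (their sum is
#'   the domain voxel count).
#' @export
voxel_confusion <- function(pred, ref, domain) {
  dom <- as_domain(domain)$mask
  .stop_incompatible(pred, ref, "prediction and reference")
  .stop_incompatible(pred, dom, "masks and domain")
  d <- dom$data
  p <- pred$data[d]; r <- ref$data[d]
  structure(list(tp = sum(p & r), fp = sum(p & !r),
                 fn = sum(!p & r), tn = sum(!p & !r)),
            class = "voxel_confusion")
}

#' Construct confusion counts directly
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A `voxel_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  structure(as.list(counts), class = "voxel_confusion")
}

#' @export
print.voxel_confusion <- function(x, ...) {
  cat(sprintf("<voxel_confusion> TP %s  FP %s  FN %s  TN %s\n",
              format(x$tp, big.mark = ","), format(x$fp, big.mark = ","),
              format(x$fn, big.mark = ","), format(x$tn, big.mark = ",")))
  invisible(x)
}

#' Sensitivity, specificity, PPV and NPV from confusion counts
#'
#' Metrics with a zero denominator are returned as `NA` (defined-missing)
#' rather than raising an error.
#'
#' @param x A `voxel_confusion` (from [voxel_confusion()] or
#'   [confusion_counts()]).
#' @return Named list: `sensitivity` tp/(tp+fn), `specificity` tn/(tn+fp),
#'   `ppv` tp/(tp+fp), `npv` tn/(tn+fn).
#' @export
confusion_metrics <- function(x) {
  stopifnot(inherits(x, "voxel_confusion"))
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = rate(x$tp, x$tp + x$fn),
       specificity = rate(x$tn, x$tn + x$fp),
       ppv = rate(x$tp, x$tp + x$fp),
       npv = rate(x$tn, x$tn + x$fn))
}

#' Per-scan evaluation score
#'
#' @param scan_id Scan identifier.
#' @param pred,ref,domain As in [voxel_confusion()].
#' @param detection_threshold DSC above which the lesion counts as detected;
#'   default 0.8.
#' @return A one-row data frame: `scan_id`, `dsc`, `tp`, `fp`, `fn`, `tn`,
#'   `detected`.
#' @export
scan_score <- function(scan_id, pred, ref, domain, detection_threshold = 0.8) {
  cf <- voxel_confusion(pred, ref, domain)
  d <- as.numeric(dsc(pred, ref))
  data.frame(scan_id = scan_id, dsc = d, tp = cf$tp, fp = cf$fp,
             fn = cf$fn, tn = cf$tn, detected = d > detection_threshold)
}

# percentile bootstrap CI; assumes the RNG state is already seeded upstream
.boot_ci <- function(x, stat, n_boot, conf) {
  if (length(x) == 1L) return(c(x, x))
  reps <- vapply(seq_len(n_boot),
                 function(i) stat(x[sample.int(length(x), replace = TRUE)]),
                 numeric(1))
  unname(quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                  na.rm = TRUE, names = FALSE))
}

#' Cohort-level evaluation summary
#'
#' Summarizes per-scan scores: median and mean DSC with nonparametric
#' percentile-bootstrap confidence intervals, the detection rate (fraction
#' of scans with DSC strictly above the detection threshold), and
#' sensitivity/specificity/PPV/NPV under BOTH aggregations - pooled (summing
#' the confusion counts over scans) and per-scan averaged (mean of per-scan
#' rates, with bootstrap CIs). The two aggregations can differ appreciably
#' when lesion sizes vary, which is why both are always reported.
#'
#' @param scores Data frame of per-scan scores (rows from [scan_score()]);
#'   confusion columns optional.
#' @param detection_threshold DSC detection cut; default 0.8.
#' @param n_boot Bootstrap resamples; default 10000.
#' @param seed Optional RNG seed making the CIs reproducible.
#' @param conf Confidence level; default 0.95.
#' @return A `cohort_summary` list.
#' @export
cohort_summary <- function(scores, detection_threshold = 0.8, n_boot = 10000,
                           seed = NULL, conf = 0.95) {
  if (!is.data.frame(scores) || nrow(scores) < 1L)
    stop("'scores' must be a data frame with at least one scan", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ds <- scores$dsc
  out <- list(
    n_scans = nrow(scores),
    median_dsc = median(ds),
    median_dsc_ci = .boot_ci(ds, median, n_boot, conf),
    mean_dsc = mean(ds),
    mean_dsc_ci = .boot_ci(ds, mean, n_boot, conf),
    detection_threshold = detection_threshold,
    detection_rate = mean(ds > detection_threshold),
    conf = conf)
  if (all(c("tp", "fp", "fn", "tn") %in% names(scores))) {
    pooled <- confusion_counts(sum(scores$tp), sum(scores$fp),
                               sum(scores$fn), sum(scores$tn))
    out$pooled <- confusion_metrics(pooled)
    per <- lapply(seq_len(nrow(scores)), function(i)
      confusion_metrics(confusion_counts(scores$tp[i], scores$fp[i],
                                         scores$fn[i], scores$tn[i])))
    out$per_scan <- lapply(setNames(nm = c("sensitivity", "specificity",
                                           "ppv", "npv")), function(m) {
      v <- vapply(per, `[[`, numeric(1), m)
      list(mean = mean(v, na.rm = TRUE),
           ci = .boot_ci(v[!is.na(v)], mean, n_boot, conf))
    })
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(paste0("<cohort_summary> n=%d; median DSC %.3f (%.0f%% CI ",
                     "%.3f-%.3f); mean DSC %.3f; detection rate %.0f%% ",
                     "(DSC > %.2f)\n"),
              x$n_scans, x$median_dsc, 100 * x$conf, x$median_dsc_ci[1],
              x$median_dsc_ci[2], x$mean_dsc, 100 * x$detection_rate,
              x$detection_threshold))
  if (!is.null(x$pooled))
    cat(sprintf("  pooled sens %.3f spec %.4f ppv %.3f npv %.4f\n",
                x$pooled$sensitivity, x$pooled$specificity, x$pooled$ppv,
                x$pooled$npv))
  invisible(x)
}

#' Select representative scans at DSC percentiles
#'
#' For each requested percentile, returns the scan whose DSC is nearest the
#' empirical (nearest-rank) percentile value; ties resolve to the lower scan
#' index. Typical use: 2, 50 and 98 percent for worst / typical / best case
#' display.
#'
#' @param scores Data frame with `scan_id` and `dsc` columns.
#' @param percentiles Percentiles in `[0, 100]`; default `c(2, 50, 98)`.
#' @return Data frame with `percentile`, `scan_id`, `dsc`.
#' @export
select_percentile_cases <- function(scores, percentiles = c(2, 50, 98)) {
  if (!is.data.frame(scores) || nrow(scores) < 1L)
    stop("'scores' must be a non-empty data frame", call. = FALSE)
  do.call(rbind, lapply(percentiles, function(p) {
    target <- quantile(scores$dsc, p / 100, type = 1, names = FALSE)
    i <- which.min(abs(scores$dsc - target))    # lowest index on ties
    data.frame(percentile = p, scan_id = scores$scan_id[i],
               dsc = scores$dsc[i])
  }))
}

#' Concordance of a clinical metric between two methods
#'
#' Pearson correlation and ordinary least-squares fit of method B on
#' method A for paired per-scan metric values (e.g. TBRmean by manual
#' reference vs. by an automatic method). Pairs with a missing value in
#' either method are dropped pairwise and counted.
#'
#' @param a,b Numeric vectors of paired metric values.
#' @return List: `r`, `slope`, `intercept`, `n_used`, `n_dropped`.
#' @export
metric_concordance <- function(a, b) {
  if (length(a) != length(b))
    stop("'a' and 'b' must have equal length", call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L)
    stop("concordance needs at least 3 complete pairs; got ", sum(ok),
         call. = FALSE)
  a <- a[ok]; b <- b[ok]
  fit <- lm(b ~ a)
  list(r = as.numeric(cor(a, b)),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_used = sum(ok), n_dropped = sum(!ok))
}

#' Assemble a longitudinal record for one patient
#'
#' Per-timepoint clinical metrics (TBRmean, TBRmax, BTV) for the same scans
#' under two delineation methods.
#'
#' @param patient_id Identifier.
#' @param timepoints Ordered scan times/labels (length >= `min_scans`).
#' @param metrics_a,metrics_b Data frames with columns `tbr_mean`,
#'   `tbr_max`, `btv_ml`, one row per timepoint, same order.
#' @param min_scans Minimum number of scans; default 3 (the usual criterion
#'   for longitudinal evaluation).
#' @return A `longitudinal_record`.
#' @export
longitudinal_record <- function(patient_id, timepoints, metrics_a, metrics_b,
                                min_scans = 3) {
  n <- length(timepoints)
  need <- c("tbr_mean", "tbr_max", "btv_ml")
  if (n < min_scans)
    stop("longitudinal record needs >= ", min_scans, " scans", call. = FALSE)
  if (nrow(metrics_a) != n || nrow(metrics_b) != n)
    stop("metrics must have one row per timepoint", call. = FALSE)
  if (!all(need %in% names(metrics_a)) || !all(need %in% names(metrics_b)))
    stop("metrics need columns ", paste(need, collapse = ", "), call. = FALSE)
  structure(list(patient_id = patient_id, timepoints = timepoints,
                 a = metrics_a[need], b = metrics_b[need]),
            class = "longitudinal_record")
}

.dz_sign <- function(delta, baseline, dead_zone) {
  if (is.finite(baseline) && abs(delta) <= dead_zone * abs(baseline)) 0
  else sign(delta)
}

#' Longitudinal congruence of metric changes between two methods
#'
#' For each follow-up scan versus baseline (the first timepoint) and each
#' metric, computes the change under both methods and flags the interval
#' congruent when the signs agree. Changes within `dead_zone` of the
#' method's own baseline count as "no change", so two methods reporting a
#' stable lesion with opposite-sign jitter still agree.
#'
#' @param record A [longitudinal_record()].
#' @param dead_zone Fractional no-change band; default 0.05.
#' @return Data frame with one row per follow-up x metric: `patient_id`,
#'   `timepoint`, `metric`, `delta_a`, `delta_b`, `sign_a`, `sign_b`,
#'   `congruent`.
#' @export
longitudinal_congruence <- function(record, dead_zone = 0.05) {
  stopifnot(inherits(record, "longitudinal_record"))
  mets <- c("tbr_mean", "tbr_max", "btv_ml")
  rows <- list()
  for (t in seq_along(record$timepoints)[-1]) {
    for (m in mets) {
      da <- record$a[[m]][t] - record$a[[m]][1]
      db <- record$b[[m]][t] - record$b[[m]][1]
      sa <- .dz_sign(da, record$a[[m]][1], dead_zone)
      sb <- .dz_sign(db, record$b[[m]][1], dead_zone)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = record$patient_id, timepoint = record$timepoints[t],
        metric = m, delta_a = da, delta_b = db, sign_a = sa, sign_b = sb,
        congruent = sa == sb)
    }
  }
  do.call(rbind, rows)
}
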