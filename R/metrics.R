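mask_grid <- function(x) {
  g <- if (inherits(x, "chp_volume")) x$grid else as_grid3(x)
  if (!all(g %in% c(0, 1))) stopf("metrics require binary masks")
  g
}

check_aligned <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stopf("masks are not aligned: %s vs %s",
          paste(dim(x), collapse = "x"), paste(dim(y), collapse = "x"))
}

#' Dice overlap of two binary masks
#'
#' `2|X & Y| / (|X| + |Y|)` (equivalently the min formulation of
#' [soft_dice()] on binary input). Two empty masks score 1 by convention,
#' with a warning.
#'
#' @param x predicted [label_mask()] (or 0/1 array).
#' @param y reference mask.
#' @return scalar in \[0, 1\].
#' @export
dice_score <- function(x, y) {
  gx <- mask_grid(x); gy <- mask_grid(y)
  check_aligned(gx, gy)
  s <- sum(gx) + sum(gy)
  if (s == 0) {
    warnf("both masks are empty; Dice = 1 by convention")
    return(1)
  }
  2 * sum(gx * gy) / s
}

#' Recall (sensitivity) of a predicted mask
#'
#' `|X & Y| / |Y|`: the fraction of reference voxels recovered.
#'
#' @inheritParams dice_score
#' @return scalar in \[0, 1\].
#' @export
recall <- function(x, y) {
  gx <- mask_grid(x); gy <- mask_grid(y)
  check_aligned(gx, gy)
  if (sum(gy) == 0) stopf("recall is undefined for an empty reference mask")
  sum(gx * gy) / sum(gy)
}

#' Precision of a predicted mask
#'
#' `|X & Y| / |X|`: the fraction of predicted voxels that are correct.
#'
#' @inheritParams dice_score
#' @return scalar in \[0, 1\].
#' @export
precision <- function(x, y) {
  gx <- mask_grid(x); gy <- mask_grid(y)
  check_aligned(gx, gy)
  if (sum(gx) == 0) stopf("precision is undefined for an empty prediction")
  sum(gx * gy) / sum(gx)
}

#' Signed and absolute volume error rate
#'
#' `VER = (|X| - |Y|) / |Y|` (positive when the prediction over-estimates
#' the volume) and `AVER = |VER|`.
#'
#' @inheritParams dice_score
#' @return list with `ver` and `aver`.
#' @export
volume_error_rate <- function(x, y) {
  gx <- mask_grid(x); gy <- mask_grid(y)
  check_aligned(gx, gy)
  if (sum(gy) == 0) stopf("VER is undefined for an empty reference mask")
  ver <- (sum(gx) - sum(gy)) / sum(gy)
  list(ver = ver, aver = abs(ver))
}

#' Per-subject evaluation row
#'
#' Computes all overlap and volume metrics for one prediction/reference
#' pair. Volumes are reported both as voxel counts and in mm^3 (count times
#' the voxel volume).
#'
#' @inheritParams dice_score
#' @param subject_id identifier carried into the row.
#' @return one-row data frame.
#' @export
evaluate_pair <- function(x, y, subject_id = NA_character_) {
  gx <- mask_grid(x); gy <- mask_grid(y)
  check_aligned(gx, gy)
  vox_mm3 <- if (inherits(y, "chp_volume")) prod(y$spacing) else 1
  ve <- volume_error_rate(gx, gy)
  data.frame(subject_id = subject_id,
             dice = dice_score(gx, gy),
             recall = recall(gx, gy),
             precision = if (sum(gx) > 0) precision(gx, gy) else NA_real_,
             ver = ve$ver, aver = ve$aver,
             predicted_voxels = sum(gx), reference_voxels = sum(gy),
             predicted_mm3 = sum(gx) * vox_mm3,
             reference_mm3 = sum(gy) * vox_mm3)
}

#' Cohort summary: mean +/- SEM and volume correlation
#'
#' Aggregates per-subject rows into per-metric mean and standard error of
#' the mean (sample SD / sqrt(n)) plus Pearson's r between predicted and
#' reference volumes.
#'
#' @param rows data frame of [evaluate_pair()] rows.
#' @param skip_undefined drop rows with undefined metrics (e.g. empty
#'   predictions) instead of erroring; the number skipped is reported.
#' @return A `chp_cohort_report` list with `summary` (data frame of mean and
#'   sem per metric), `pearson_r`, `n_subjects` and `n_skipped`.
#' @export
cohort_summary <- function(rows, skip_undefined = FALSE) {
  keep <- stats::complete.cases(rows[, c("dice", "recall", "precision", "ver", "aver")])
  n_skipped <- sum(!keep)
  if (n_skipped > 0 && !skip_undefined)
    stopf("%d subjects have undefined metrics; set skip_undefined = TRUE to drop them",
          n_skipped)
  rows <- rows[keep, , drop = FALSE]
  n <- nrow(rows)
  if (n < 2) stopf("SEM requires at least 2 subjects (got %d)", n)
  metrics <- c("dice", "recall", "precision", "ver", "aver")
  summ <- data.frame(metric = metrics,
                     mean = vapply(metrics, function(m) mean(rows[[m]]), numeric(1)),
                     sem = vapply(metrics, function(m)
                       stats::sd(rows[[m]]) / sqrt(n), numeric(1)),
                     row.names = NULL)
  pr <- NA_real_
  if (n >= 3 && stats::sd(rows$predicted_voxels) > 0 &&
      stats::sd(rows$reference_voxels) > 0) {
    pr <- stats::cor(rows$predicted_voxels, rows$reference_voxels)
  } else if (n < 3) {
    warnf("Pearson r needs at least 3 subjects; reporting NA")
  } else {
    warnf("Pearson r is undefined for constant volumes; reporting NA")
  }
  structure(list(summary = summ, pearson_r = pr, n_subjects = n,
                 n_skipped = n_skipped),
            class = "chp_cohort_report")
}

#' @export
print.chp_cohort_report <- function(x, ...) {
  cat(sprintf("Cohort of %d subjects (%d skipped)\n", x$n_subjects, x$n_skipped))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sem[i]))
  cat(sprintf("  Pearson r (predicted vs reference volume): %.3f\n", x$pearson_r))
  invisible(x)
}
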