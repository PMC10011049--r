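#' Preprocessing configuration
#'
#' Controls the deterministic preprocessing chain applied before inference:
#' reorientation to the canonical RAS axis order, isotropic resampling,
#' centered crop/pad to a fixed grid, and percentile-based intensity
#' rescaling.
#'
#' @param target_spacing isotropic voxel size in mm.
#' @param target_shape voxel grid after crop/pad; the default (176, 240, 256)
#'   matches a whole-head 1 mm T1-weighted acquisition.
#' @param rescale_interval closed intensity interval the volume is mapped to.
#' @param percentile_exclusion fraction of extreme intensities excluded from
#'   the rescaling range on each tail (robustness to outliers).
#' @return A `chp_preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing = 1,
                              target_shape = c(176, 240, 256),
                              rescale_interval = c(-1, 1),
                              percentile_exclusion = 0.005) {
  if (target_spacing <= 0) stopf("target_spacing must be > 0")
  if (length(target_shape) != 3 || any(target_shape < 1))
    stopf("target_shape must be 3 entries >= 1")
  if (rescale_interval[1] >= rescale_interval[2])
    stopf("rescale_interval lower bound must be below the upper bound")
  if (percentile_exclusion < 0 || percentile_exclusion >= 0.5)
    stopf("percentile_exclusion must be in [0, 0.5)")
  structure(list(target_spacing = target_spacing,
                 target_shape = as.integer(target_shape),
                 rescale_interval = as.numeric(rescale_interval),
                 percentile_exclusion = percentile_exclusion),
            class = "chp_preprocess_config")
}

#' Reorient a volume to canonical RAS axis order
#'
#' Permutes and flips the grid so the first axis runs left to right, the
#' second posterior to anterior and the third inferior to superior
#' (axis codes `R`, `A`, `S`). The returned record stores the permutation and
#' flips so the operation can be inverted exactly.
#'
#' @param v a [volume()] or [label_mask()].
#' @return list with elements `volume` and `record`.
#' @export
to_canonical <- function(v) {
  stopifnot(inherits(v, "chp_volume"))
  check_axis_codes(v$axis_codes)
  fam <- vapply(v$axis_codes, function(cc)
    which(vapply(AXIS_FAMILIES, function(f) cc %in% f, logical(1))), integer(1))
  perm <- match(1:3, fam)              # target axis -> source axis
  grid <- aperm(v$grid, perm)
  codes <- v$axis_codes[perm]
  spacing <- v$spacing[perm]
  flips <- codes %in% c("L", "P", "I")
  if (flips[1]) grid <- grid[dim(grid)[1]:1, , , drop = FALSE]
  if (flips[2]) grid <- grid[, dim(grid)[2]:1, , drop = FALSE]
  if (flips[3]) grid <- grid[, , dim(grid)[3]:1, drop = FALSE]
  out <- v
  out$grid <- grid
  out$spacing <- spacing
  out$axis_codes <- c("R", "A", "S")
  record <- structure(list(perm = perm, flips = flips,
                           orig_axis_codes = v$axis_codes,
                           orig_shape = dim(v$grid)),
                      class = "chp_canonical_record")
  list(volume = out, record = record)
}

undo_canonical <- function(grid, record) {
  if (record$flips[1]) grid <- grid[dim(grid)[1]:1, , , drop = FALSE]
  if (record$flips[2]) grid <- grid[, dim(grid)[2]:1, , drop = FALSE]
  if (record$flips[3]) grid <- grid[, , dim(grid)[3]:1, drop = FALSE]
  aperm(grid, order(record$perm))
}

#' Resample a volume to isotropic spacing
#'
#' The output shape on each axis is `round(shape * spacing / new_spacing)`.
#' Intensities are interpolated trilinearly; masks use nearest neighbour so
#' values stay binary.
#'
#' @param v a [volume()] or [label_mask()].
#' @param spacing target isotropic voxel size in mm.
#' @return the resampled object.
#' @export
resample_isotropic <- function(v, spacing = 1) {
  stopifnot(inherits(v, "chp_volume"))
  if (spacing <= 0) stopf("spacing must be > 0")
  out_shape <- as.integer(round(dim(v$grid) * v$spacing / spacing))
  out_shape <- pmax(out_shape, 1L)
  nearest <- inherits(v, "chp_mask")
  grid <- resize3d_cpp(v$grid, dim(v$grid), out_shape, nearest)
  out <- v
  out$grid <- grid
  out$spacing <- rep(spacing, 3)
  out
}

#' Centered crop or pad to a target shape
#'
#' Each axis is independently cropped or padded so the content stays
#' centered; odd remainders put the extra voxel on the high-index side. The
#' pad fill value is the grid minimum (background) for volumes and 0 for
#' masks. The returned record makes the operation invertible on the retained
#' region.
#'
#' @param v a [volume()] or [label_mask()].
#' @param target_shape integer length-3.
#' @return list with elements `volume` and `record`.
#' @export
crop_or_pad <- function(v, target_shape) {
  stopifnot(inherits(v, "chp_volume"))
  target_shape <- as.integer(target_shape)
  d <- dim(v$grid)
  fill <- if (inherits(v, "chp_mask")) 0 else min(v$grid)
  crop_lo <- crop_hi <- pad_lo <- pad_hi <- integer(3)
  for (ax in 1:3) {
    diff <- target_shape[ax] - d[ax]
    if (diff >= 0) {
      pad_lo[ax] <- diff %/% 2L
      pad_hi[ax] <- diff - pad_lo[ax]
    } else {
      crop_lo[ax] <- (-diff) %/% 2L
      crop_hi[ax] <- -diff - crop_lo[ax]
    }
  }
  grid <- array(fill, target_shape)
  src <- lapply(1:3, function(ax) (1L + crop_lo[ax]):(d[ax] - crop_hi[ax]))
  dst <- lapply(1:3, function(ax) (1L + pad_lo[ax]):(target_shape[ax] - pad_hi[ax]))
  grid[dst[[1]], dst[[2]], dst[[3]]] <- v$grid[src[[1]], src[[2]], src[[3]]]
  out <- v
  out$grid <- grid
  record <- structure(list(pre_shape = d, target_shape = target_shape,
                           crop_lo = crop_lo, crop_hi = crop_hi,
                           pad_lo = pad_lo, pad_hi = pad_hi, fill = fill),
                      class = "chp_croppad_record")
  list(volume = out, record = record)
}

undo_crop_or_pad <- function(grid, record, fill = 0) {
  d <- record$pre_shape
  out <- array(fill, d)
  src <- lapply(1:3, function(ax)
    (1L + record$pad_lo[ax]):(record$target_shape[ax] - record$pad_hi[ax]))
  dst <- lapply(1:3, function(ax)
    (1L + record$crop_lo[ax]):(d[ax] - record$crop_hi[ax]))
  out[dst[[1]], dst[[2]], dst[[3]]] <- grid[src[[1]], src[[2]], src[[3]]]
  out
}

#' Percentile-robust intensity rescaling
#'
#' Maps the lower exclusion percentile to the interval's lower end and the
#' upper percentile to its upper end, linearly in between; intensities beyond
#' the percentile band are clipped to the interval ends so the output is
#' always bounded.
#'
#' @param v a [volume()].
#' @param cfg a [preprocess_config()].
#' @return the rescaled volume.
#' @export
rescale_intensity <- function(v, cfg = preprocess_config()) {
  stopifnot(inherits(v, "chp_volume"))
  pe <- cfg$percentile_exclusion
  qs <- stats::quantile(v$grid, c(pe, 1 - pe), names = FALSE)
  if (qs[2] <= qs[1])
    stopf("degenerate intensity distribution: %g%% and %g%% percentiles coincide (constant grid?)",
          100 * pe, 100 * (1 - pe))
  a <- cfg$rescale_interval[1]; b <- cfg$rescale_interval[2]
  out <- v
  out$grid <- (clamp(v$grid, qs[1], qs[2]) - qs[1]) / (qs[2] - qs[1]) * (b - a) + a
  out
}

#' Full preprocessing chain
#'
#' Applies, in order: reorientation to canonical RAS, isotropic resampling,
#' centered crop/pad to the target shape, and (for intensity volumes)
#' percentile rescaling. Masks travel through the spatial steps with
#' nearest-neighbour interpolation and skip the intensity step.
#'
#' @param v a [volume()] or [label_mask()].
#' @param cfg a [preprocess_config()].
#' @return list with elements `volume` and `record`; the record allows
#'   [invert_preprocess()] to map predictions back to the native grid.
#' @export
preprocess <- function(v, cfg = preprocess_config()) {
  stopifnot(inherits(v, "chp_volume"))
  can <- to_canonical(v)
  res <- resample_isotropic(can$volume, cfg$target_spacing)
  resample_rec <- list(pre_shape = dim(can$volume$grid),
                       pre_spacing = can$volume$spacing,
                       post_shape = dim(res$grid))
  cp <- crop_or_pad(res, cfg$target_shape)
  out <- cp$volume
  if (!inherits(v, "chp_mask")) out <- rescale_intensity(out, cfg)
  record <- structure(list(canonical = can$record, resample = resample_rec,
                           croppad = cp$record,
                           orig_spacing = v$spacing,
                           orig_axis_codes = v$axis_codes,
                           orig_origin = v$origin,
                           orig_shape = dim(v$grid)),
                      class = "chp_preprocess_record")
  list(volume = out, record = record)
}

#' Map a preprocessed-space grid back to the native grid
#'
#' Inverts crop/pad, resampling and reorientation so that a probability map
#' or mask predicted in preprocessed space lands on the original voxel grid.
#' Intensity values themselves are not un-rescaled (predictions are
#' probabilities, not intensities).
#'
#' @param grid 3D array in preprocessed space (e.g. a probability map).
#' @param record a `chp_preprocess_record` from [preprocess()].
#' @param nearest use nearest-neighbour interpolation (for masks).
#' @param fill value for voxels that were cropped away.
#' @return 3D array with the original shape and axis order.
#' @export
invert_preprocess <- function(grid, record, nearest = FALSE, fill = 0) {
  stopifnot(inherits(record, "chp_preprocess_record"))
  g <- undo_crop_or_pad(grid, record$croppad, fill = fill)
  g <- resize3d_cpp(g, dim(g), record$resample$pre_shape, nearest)
  undo_canonical(g, record$canonical)
}
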