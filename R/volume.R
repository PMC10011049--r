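#' 3D image volume
#'
#' A `chp_volume` wraps a rank-3 intensity array together with its physical
#' voxel spacing (mm), anatomical axis codes and origin. Axis codes name the
#' anatomical direction of increasing voxel index on each axis, one from each
#' family: `R`/`L` (left-right), `A`/`P` (antero-posterior), `S`/`I`
#' (infero-superior). The canonical orientation used throughout the pipeline
#' is `c("R", "A", "S")`: left-right on the first axis.
#'
#' @param grid numeric 3D array of intensities.
#' @param spacing numeric length-3, voxel size in mm, all positive.
#' @param axis_codes character length-3, one code per axis.
#' @param origin numeric length-3 physical offset in mm.
#' @return A `chp_volume` object.
#' @export
volume <- function(grid, spacing = c(1, 1, 1), axis_codes = c("R", "A", "S"),
                   origin = c(0, 0, 0)) {
  grid <- as_grid3(grid)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive values")
  check_axis_codes(axis_codes)
  structure(list(grid = grid, spacing = spacing,
                 axis_codes = as.character(axis_codes),
                 origin = as.numeric(origin)),
            class = "chp_volume")
}

#' Binary label mask
#'
#' A `chp_mask` is geometrically identical to [volume()] but every voxel is
#' exactly 0 or 1 (ground truth or thresholded prediction).
#'
#' @inheritParams volume
#' @return A `chp_mask` object.
#' @export
label_mask <- function(grid, spacing = c(1, 1, 1), axis_codes = c("R", "A", "S"),
                       origin = c(0, 0, 0)) {
  v <- volume(grid, spacing, axis_codes, origin)
  if (!all(v$grid %in% c(0, 1)))
    stopf("mask voxels must be exactly 0 or 1")
  class(v) <- c("chp_mask", "chp_volume")
  v
}

#' Probability map
#'
#' Output of a segmentation stage: values in \[0, 1\] on the same geometry as
#' a [volume()].
#'
#' @inheritParams volume
#' @return A `chp_probmap` object.
#' @export
prob_map <- function(grid, spacing = c(1, 1, 1), axis_codes = c("R", "A", "S"),
                     origin = c(0, 0, 0)) {
  v <- volume(grid, spacing, axis_codes, origin)
  rng <- range(v$grid)
  if (rng[1] < 0 || rng[2] > 1)
    stopf("probability map values must lie in [0, 1] (found range %g..%g)",
          rng[1], rng[2])
  class(v) <- c("chp_probmap", "chp_volume")
  v
}

as_grid3 <- function(x) {
  if (inherits(x, "chp_volume")) return(x$grid)
  if (is.null(dim(x)) || length(dim(x)) != 3)
    stopf("expected a rank-3 array, got rank %d",
          if (is.null(dim(x))) 1L else length(dim(x)))
  if (any(dim(x) < 1)) stopf("every axis must have length >= 1")
  storage.mode(x) <- "double"
  x
}

AXIS_FAMILIES <- list(c("R", "L"), c("A", "P"), c("S", "I"))

check_axis_codes <- function(codes) {
  codes <- as.character(codes)
  if (length(codes) != 3 || !all(codes %in% unlist(AXIS_FAMILIES)))
    stopf("axis_codes must be 3 values drawn from R/L, A/P, S/I (got: %s)",
          paste(codes, collapse = ", "))
  fam <- vapply(codes, function(cc)
    which(vapply(AXIS_FAMILIES, function(f) cc %in% f, logical(1))), integer(1))
  if (length(unique(fam)) != 3)
    stopf("axis_codes must contain one code from each anatomical family (got: %s)",
          paste(codes, collapse = ", "))
  invisible(codes)
}

# geometry carried over to a derived grid
same_geometry <- function(template, grid, cls = NULL) {
  out <- template
  out$grid <- grid
  if (!is.null(cls)) class(out) <- cls
  out
}

#' @export
print.chp_volume <- function(x, ...) {
  kind <- if (inherits(x, "chp_mask")) "label mask"
          else if (inherits(x, "chp_probmap")) "probability map"
          else "volume"
  cat(sprintf("<chp %s> %s voxels, spacing %s mm, orientation %s\n",
              kind, paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(x$axis_codes, collapse = "")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.chp_volume <- function(x) dim(x$grid)
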