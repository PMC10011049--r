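#' Read a NIfTI-1 volume
#'
#' Reads a `.nii` / `.nii.gz` file and populates grid, spacing, axis codes and
#' origin from the header. 4D images with a trailing singleton dimension are
#' squeezed to 3D with a message; any other non-3D image is rejected.
#'
#' @param path path to a NIfTI-1 file.
#' @param mask logical; read as a binary [label_mask()] (values are checked).
#' @return A [volume()] (or [label_mask()] when `mask = TRUE`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  d <- dim(arr)
  if (length(d) == 4 && d[4] == 1) {
    message("squeezing 4D image with trailing singleton dimension to 3D")
    arr <- array(arr, d[1:3])
    d <- dim(arr)
  }
  if (length(d) != 3)
    stopf("expected a 3D image, got rank %d", length(d))
  xf <- RNifti::xform(img)
  codes <- axis_codes_from_xform(xf)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- xf[1:3, 4]
  if (mask) {
    u <- unique(as.vector(arr))
    if (!all(u %in% c(0, 1)))
      stopf("mask file contains values other than 0/1: %s",
            paste(utils::head(setdiff(u, c(0, 1)), 3), collapse = ", "))
    label_mask(arr, spacing, codes, origin)
  } else {
    volume(arr, spacing, codes, origin)
  }
}

#' Write a volume or mask as NIfTI-1
#'
#' Spacing and orientation are encoded in the qform/sform; masks are written
#' with an unsigned 8-bit integer datatype.
#'
#' @param v a [volume()], [label_mask()] or [prob_map()].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "chp_volume"))
  if (!dir.exists(dirname(path)))
    stopf("parent directory does not exist: %s", dirname(path))
  is_mask <- inherits(v, "chp_mask")
  arr <- v$grid
  if (is_mask) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  aff <- xform_from_axis_codes(v$axis_codes, v$spacing, v$origin)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "auto")
  invisible(path)
}

# direction vector (world space) of each axis code
AXIS_VECTORS <- list(R = c(1, 0, 0), L = c(-1, 0, 0),
                     A = c(0, 1, 0), P = c(0, -1, 0),
                     S = c(0, 0, 1), I = c(0, 0, -1))

axis_codes_from_xform <- function(xf) {
  R3 <- xf[1:3, 1:3]
  codes <- character(3)
  for (j in 1:3) {
    col <- R3[, j]
    if (all(col == 0)) stopf("degenerate orientation matrix in NIfTI header")
    world <- which.max(abs(col))
    pos <- col[world] > 0
    codes[j] <- switch(world,
                       if (pos) "R" else "L",
                       if (pos) "A" else "P",
                       if (pos) "S" else "I")
  }
  check_axis_codes(codes)
  codes
}

xform_from_axis_codes <- function(codes, spacing, origin) {
  aff <- diag(4)
  for (j in 1:3) aff[1:3, j] <- AXIS_VECTORS[[codes[j]]] * spacing[j]
  aff[1:3, 4] <- origin
  aff
}
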