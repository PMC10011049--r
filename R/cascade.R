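#' Cascade configuration
#'
#' Parameters of the two-stage coarse-to-fine pipeline: the coarse stage runs
#' on the whole volume downsampled to `lowres_shape`; voxels whose coarse
#' probability exceeds `seed_threshold` (strictly) seed full-resolution cubic
#' patches of edge `patch_size`, capped at `max_patches` (uniformly
#' subsampled beyond the cap, overlaps allowed); fine-stage patch predictions
#' are blended with a Hann-windowed weighted merge and binarized at
#' `binarize_threshold` (strictly).
#'
#' @param lowres_shape voxel triple of the coarse-stage grid.
#' @param patch_size cubic patch edge length.
#' @param seed_threshold coarse probability above which a voxel seeds a patch.
#' @param max_patches cap on the number of patches per volume.
#' @param binarize_threshold probability threshold for the final mask.
#' @return A `chp_cascade_config` list.
#' @export
cascade_config <- function(lowres_shape = c(72, 96, 104), patch_size = 48,
                           seed_threshold = 0.8, max_patches = 500,
                           binarize_threshold = 0.5) {
  if (seed_threshold <= 0 || seed_threshold >= 1)
    stopf("seed_threshold must be in (0, 1)")
  if (max_patches < 1) stopf("max_patches must be >= 1")
  if (binarize_threshold < 0 || binarize_threshold >= 1)
    stopf("binarize_threshold must be in [0, 1)")
  structure(list(lowres_shape = as.integer(lowres_shape),
                 patch_size = as.integer(patch_size),
                 seed_threshold = seed_threshold,
                 max_patches = as.integer(max_patches),
                 binarize_threshold = binarize_threshold),
            class = "chp_cascade_config")
}

#' Downsample a volume to the coarse-stage grid
#'
#' Trilinear interpolation; per-axis scale factors need not be integer
#' (e.g. 176/72, 240/96, 256/104 under the full-size defaults).
#'
#' @param v a [volume()] or 3D array.
#' @param lowres_shape integer length-3, no larger than the input per axis.
#' @return 3D array of shape `lowres_shape`.
#' @export
downsample <- function(v, lowres_shape) {
  g <- if (inherits(v, "chp_volume")) v$grid else as_grid3(v)
  lowres_shape <- as.integer(lowres_shape)
  if (any(lowres_shape > dim(g)))
    stopf("lowres_shape exceeds the input shape on axis %d",
          which(lowres_shape > dim(g))[1])
  resize3d_cpp(g, dim(g), lowres_shape, FALSE)
}

#' Find patch seed voxels from a coarse probability map
#'
#' Every low-resolution voxel with probability strictly greater than
#' `threshold` yields one candidate, mapped to the full-resolution grid by
#' scaling its (0-based) index by the per-axis extent ratio and rounding.
#' Candidates are returned in lexicographic voxel order (1-based indices).
#'
#' @param p 3D probability array at the coarse resolution.
#' @param highres_shape full-resolution grid shape.
#' @param threshold seeding threshold (strict inequality).
#' @return integer matrix, one row per candidate, columns = voxel index.
#' @export
find_seed_voxels <- function(p, highres_shape, threshold = 0.8) {
  g <- if (inherits(p, "chp_volume")) p$grid else as_grid3(p)
  d <- dim(g)
  idx <- which(g > threshold)          # column-major = lexicographic (i,j,k)
  if (length(idx) == 0)
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "k"))))
  sub <- arrayInd(idx, d)
  scale <- highres_shape / d
  hi <- round(sweep(sub - 1, 2, scale, "*")) + 1
  hi <- pmin(pmax(hi, 1L), matrix(highres_shape, nrow(hi), 3, byrow = TRUE))
  storage.mode(hi) <- "integer"
  colnames(hi) <- c("i", "j", "k")
  hi
}

#' Cap the candidate list at the patch budget
#'
#' All candidates are kept when they fit the budget; otherwise a uniform
#' random subset without replacement is drawn (order preserved). Nearby
#' seeds may produce spatially overlapping patches.
#'
#' @param candidates integer matrix from [find_seed_voxels()].
#' @param max_patches cap.
#' @param seed RNG seed for the subsample (NULL = use the current stream).
#' @return integer matrix of at most `max_patches` rows.
#' @export
sample_patch_locations <- function(candidates, max_patches = 500, seed = NULL) {
  n <- nrow(candidates)
  if (n <= max_patches) return(candidates)
  keep <- with_seed(seed, sort(sample.int(n, max_patches)))
  candidates[keep, , drop = FALSE]
}

#' Extract a cubic patch around a seed voxel
#'
#' The patch is nominally centered on the seed; near the volume border the
#' origin is clamped so the patch lies fully inside (the patch keeps its
#' full size).
#'
#' @param v a [volume()] or 3D array at full resolution.
#' @param center integer length-3 voxel index (1-based).
#' @param patch_size cubic edge length.
#' @return list with `origin` (1-based low corner) and `data`
#'   (`patch_size^3` array).
#' @export
extract_patch <- function(v, center, patch_size) {
  g <- if (inherits(v, "chp_volume")) v$grid else as_grid3(v)
  d <- dim(g)
  if (any(patch_size > d))
    stopf("patch_size %d exceeds the volume extent on axis %d",
          patch_size, which(patch_size > d)[1])
  origin <- as.integer(center) - patch_size %/% 2L
  origin <- pmin(pmax(origin, 1L), d - patch_size + 1L)
  data <- g[origin[1]:(origin[1] + patch_size - 1L),
            origin[2]:(origin[2] + patch_size - 1L),
            origin[3]:(origin[3] + patch_size - 1L)]
  list(origin = origin, data = data)
}

#' Separable 3D Hann weighting window
#'
#' Product of three 1D raised-cosine profiles sampled at interior points,
#' `0.5 * (1 - cos(2 * pi * (i + 1) / (n + 1)))` for `i = 0..n-1`, so edge
#' weights are strictly positive and the divide-by-weight merge is defined on
#' every covered voxel.
#'
#' @param patch_size cubic edge length (>= 2).
#' @return `patch_size^3` array of weights in (0, 1].
#' @export
hann_window <- function(patch_size) {
  if (patch_size < 2) stopf("patch_size must be >= 2")
  i <- seq_len(patch_size)
  w1 <- 0.5 * (1 - cos(2 * pi * i / (patch_size + 1)))
  outer(outer(w1, w1), w1)
}

#' Merge patch predictions with Hann-weight normalization
#'
#' Each patch is multiplied by the Hann window and accumulated into the
#' output; in parallel the windows themselves accumulate into a weight mask
#' that divides the result. Uncovered voxels are 0.
#'
#' @param patches list of patches (`origin`, `data`) as from
#'   [extract_patch()].
#' @param output_shape full-resolution grid shape.
#' @return 3D array of merged values.
#' @export
merge_patches <- function(patches, output_shape) {
  acc <- array(0, output_shape)
  wsum <- array(0, output_shape)
  if (length(patches) == 0) return(acc)
  ps <- dim(patches[[1]]$data)[1]
  win <- hann_window(ps)
  for (p in patches) {
    ix <- p$origin[1]:(p$origin[1] + ps - 1L)
    iy <- p$origin[2]:(p$origin[2] + ps - 1L)
    iz <- p$origin[3]:(p$origin[3] + ps - 1L)
    if (p$origin[1] < 1 || utils::tail(ix, 1) > output_shape[1] ||
        p$origin[2] < 1 || utils::tail(iy, 1) > output_shape[2] ||
        p$origin[3] < 1 || utils::tail(iz, 1) > output_shape[3])
      stopf("patch at origin (%s) does not fit inside the output grid",
            paste(p$origin, collapse = ", "))
    acc[ix, iy, iz] <- acc[ix, iy, iz] + win * p$data
    wsum[ix, iy, iz] <- wsum[ix, iy, iz] + win
  }
  covered <- wsum > 0
  acc[covered] <- acc[covered] / wsum[covered]
  acc
}

#' Binarize a probability map
#'
#' Voxels become foreground iff their probability is strictly greater than
#' the threshold (a voxel exactly at the threshold stays background).
#'
#' @param p a [prob_map()] or 3D array.
#' @param threshold in `[0, 1)`.
#' @return a [label_mask()] when `p` carries geometry, else a 0/1 array.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (threshold < 0 || threshold >= 1) stopf("threshold must be in [0, 1)")
  g <- if (inherits(p, "chp_volume")) p$grid else as_grid3(p)
  m <- array(as.double(g > threshold), dim(g))
  if (inherits(p, "chp_volume"))
    label_mask(m, p$spacing, p$axis_codes, p$origin)
  else m
}

# Run a stage predictor: either a trained chp_network or any function. Plain
# functions receive (array) or (array, origin) so ground-truth oracles can
# look up their own patch.
run_stage <- function(net, x, origin = NULL) {
  if (inherits(net, "chp_network")) return(network_forward(net, x))
  if (is.function(net)) {
    if (length(formals(net)) >= 2) return(net(x, origin))
    return(net(x))
  }
  stopf("a stage predictor must be a chp_network or a function")
}

#' Two-stage coarse-to-fine prediction
#'
#' Runs: downsample to the coarse grid, coarse stage, seed detection, patch
#' sampling, fine stage per patch, Hann-weighted merge, binarization. When
#' the coarse stage finds no seed, an all-zero map and empty mask are
#' returned with a warning.
#'
#' @param v a preprocessed [volume()].
#' @param net1,net2 stage predictors: `chp_network` objects or functions (see
#'   Details in [cascade_config()]); functions may take `(array)` or
#'   `(array, origin)`.
#' @param cfg a [cascade_config()].
#' @param seed RNG seed controlling patch subsampling.
#' @return list with `prob` ([prob_map()]) and `mask` ([label_mask()]).
#' @export
predict_two_step <- function(v, net1, net2, cfg = cascade_config(), seed = 1) {
  stopifnot(inherits(v, "chp_volume"))
  d <- dim(v$grid)
  low <- downsample(v, cfg$lowres_shape)
  p1 <- run_stage(net1, low)
  cand <- find_seed_voxels(p1, d, cfg$seed_threshold)
  if (nrow(cand) == 0) {
    warnf("coarse stage found no seed voxel above %.2f; returning an empty mask",
          cfg$seed_threshold)
    zero <- array(0, d)
    return(list(prob = prob_map(zero, v$spacing, v$axis_codes, v$origin),
                mask = label_mask(zero, v$spacing, v$axis_codes, v$origin)))
  }
  locs <- sample_patch_locations(cand, cfg$max_patches, seed = seed)
  patches <- vector("list", nrow(locs))
  for (t in seq_len(nrow(locs))) {
    pt <- extract_patch(v, locs[t, ], cfg$patch_size)
    pred <- run_stage(net2, pt$data, origin = pt$origin)
    patches[[t]] <- list(origin = pt$origin, data = pred)
  }
  merged <- merge_patches(patches, d)
  prob <- prob_map(clamp(merged, 0, 1), v$spacing, v$axis_codes, v$origin)
  list(prob = prob, mask = binarize(prob, cfg$binarize_threshold))
}

#' Single-stage whole-volume prediction (baseline)
#'
#' One forward pass of the network on the full preprocessed grid, then
#' binarization.
#'
#' @inheritParams predict_two_step
#' @param net stage predictor (`chp_network` or function).
#' @return list with `prob` and `mask` as in [predict_two_step()].
#' @export
predict_one_step <- function(v, net, cfg = cascade_config()) {
  stopifnot(inherits(v, "chp_volume"))
  p <- run_stage(net, v$grid)
  prob <- prob_map(clamp(p, 0, 1), v$spacing, v$axis_codes, v$origin)
  list(prob = prob, mask = binarize(prob, cfg$binarize_threshold))
}
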