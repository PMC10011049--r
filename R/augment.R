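#' Augmentation configuration
#'
#' Per-transform trigger probabilities and magnitude bounds for the MRI
#' augmentation battery: left-right flip, random affine, simulated
#' anisotropy, k-space motion/ghosting/spike artifacts, multiplicative
#' polynomial bias field, additive Gaussian noise and gamma contrast
#' modification. Magnitudes without a stated distribution are drawn
#' uniformly within their bounds. Elastic deformation is deliberately not
#' part of the battery.
#'
#' @param flip_p probability of a left-right flip.
#' @param affine_p,affine_max_scale,affine_max_rotation random affine:
#'   uniform scale factor in `1 +/- affine_max_scale`, per-axis rotations
#'   within `+/- affine_max_rotation` degrees.
#' @param anisotropy_p,anisotropy_max_downsampling downsample one random
#'   axis by a factor up to the bound, then upsample back.
#' @param motion_p,motion_max_rotation,motion_max_translation,motion_max_movements
#'   k-space composite of up to `motion_max_movements` rigidly displaced
#'   copies (degrees / mm bounds).
#' @param ghosting_p,ghosting_n_ghosts,ghosting_intensity modulation of every
#'   n-th frequency plane along a random axis; modulation depth drawn in
#'   `[0, ghosting_intensity]`.
#' @param spike_p,spike_n_spikes,spike_intensity addition of high-magnitude
#'   points in the frequency domain; relative amplitude bound.
#' @param bias_p,bias_max_magnitude,bias_order multiplicative `exp(P)` with
#'   `P` a random polynomial of the given order, coefficients within
#'   `+/- bias_max_magnitude`.
#' @param noise_p,noise_mean,noise_std additive Gaussian noise.
#' @param contrast_p,contrast_max_log_gamma power-law intensity remap with
#'   exponent `exp(u)`, `u` uniform within the bound.
#' @return A `chp_augment_config` list.
#' @export
augment_config <- function(flip_p = 0.5,
                           affine_p = 0.3, affine_max_scale = 0.3,
                           affine_max_rotation = 15,
                           anisotropy_p = 0.3, anisotropy_max_downsampling = 2,
                           motion_p = 0.3, motion_max_rotation = 15,
                           motion_max_translation = 15, motion_max_movements = 2,
                           ghosting_p = 0.3, ghosting_n_ghosts = 2,
                           ghosting_intensity = 1,
                           spike_p = 0.3, spike_n_spikes = 1, spike_intensity = 1,
                           bias_p = 0.3, bias_max_magnitude = 0.5, bias_order = 3,
                           noise_p = 0.3, noise_mean = 0, noise_std = 1,
                           contrast_p = 0.3, contrast_max_log_gamma = 0.3) {
  cfg <- as.list(environment())
  probs <- cfg[grepl("_p$", names(cfg))]
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stopf("all probabilities must lie in [0, 1]")
  mags <- cfg[grepl("max|intensity|std|n_ghosts|n_spikes|order", names(cfg))]
  if (any(unlist(mags) < 0)) stopf("all magnitude bounds must be >= 0")
  structure(cfg, class = "chp_augment_config")
}

rot3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

apply_rigid <- function(grid, angles_deg, translation, nearest = FALSE,
                        fill = 0, scale = 1) {
  # resampling uses the inverse (output -> input) map
  M <- rot3(angles_deg) %*% diag(rep(scale, 3))
  A <- solve(M)
  t_in <- -A %*% as.numeric(translation)
  affine3d_cpp(grid, dim(grid), A, as.numeric(t_in), nearest, fill)
}

#' Spatial augmentations (applied jointly to volume and mask)
#'
#' Left-right flip, random affine (uniform scale, per-axis rotations) and
#' simulated acquisition anisotropy (down- then re-upsampling along one
#' random axis), each triggered independently with its configured
#' probability. The identical geometric map is applied to the mask with
#' nearest-neighbour interpolation.
#'
#' @param v a [volume()].
#' @param m the aligned [label_mask()].
#' @param cfg an [augment_config()].
#' @param seed optional RNG seed.
#' @return list `(volume, mask)` with an `applied` attribute naming the
#'   triggered transforms.
#' @export
spatial_transforms <- function(v, m, cfg = augment_config(), seed = NULL) {
  stopifnot(inherits(v, "chp_volume"), inherits(m, "chp_mask"))
  if (!identical(dim(v$grid), dim(m$grid)))
    stopf("volume and mask are not aligned")
  with_seed(seed, {
    applied <- c(flip = FALSE, affine = FALSE, anisotropy = FALSE)
    gv <- v$grid; gm <- m$grid
    if (stats::runif(1) < cfg$flip_p) {
      applied["flip"] <- TRUE
      gv <- gv[dim(gv)[1]:1, , , drop = FALSE]
      gm <- gm[dim(gm)[1]:1, , , drop = FALSE]
    }
    if (stats::runif(1) < cfg$affine_p) {
      applied["affine"] <- TRUE
      ang <- stats::runif(3, -cfg$affine_max_rotation, cfg$affine_max_rotation)
      sc <- stats::runif(1, 1 - cfg$affine_max_scale, 1 + cfg$affine_max_scale)
      gv <- apply_rigid(gv, ang, c(0, 0, 0), FALSE, min(gv), sc)
      gm <- apply_rigid(gm, ang, c(0, 0, 0), TRUE, 0, sc)
    }
    if (stats::runif(1) < cfg$anisotropy_p) {
      applied["anisotropy"] <- TRUE
      ax <- sample.int(3, 1)
      f <- stats::runif(1, 1, cfg$anisotropy_max_downsampling)
      lowdim <- dim(gv); lowdim[ax] <- max(1L, as.integer(round(lowdim[ax] / f)))
      gv <- resize3d_cpp(resize3d_cpp(gv, dim(gv), lowdim, FALSE), lowdim, dim(v$grid), FALSE)
      gm <- resize3d_cpp(resize3d_cpp(gm, dim(gm), lowdim, TRUE), lowdim, dim(m$grid), TRUE)
    }
    out <- list(volume = same_geometry(v, gv),
                mask = same_geometry(m, gm))
    attr(out, "applied") <- applied
    out
  })
}

fft3 <- function(x) stats::fft(x)
ifft3_re <- function(z) Re(stats::fft(z, inverse = TRUE)) / length(z)

#' k-space artifact augmentations (volume only)
#'
#' Motion: the frequency domain is assembled from contiguous segments (along
#' one random axis) of up to `motion_max_movements` rigidly displaced copies
#' of the volume. Ghosting: every `n_ghosts`-th frequency plane along a
#' random axis is attenuated. Spike: a high-magnitude point (plus random
#' phase) is added in the frequency domain. All via forward/inverse discrete
#' Fourier transform with the real part retained.
#'
#' @inheritParams spatial_transforms
#' @return a [volume()] with an `applied` attribute.
#' @export
kspace_artifacts <- function(v, cfg = augment_config(), seed = NULL) {
  stopifnot(inherits(v, "chp_volume"))
  with_seed(seed, {
    applied <- c(motion = FALSE, ghosting = FALSE, spike = FALSE)
    g <- v$grid
    if (stats::runif(1) < cfg$motion_p) {
      applied["motion"] <- TRUE
      n_mov <- sample.int(max(1, cfg$motion_max_movements), 1)
      ffts <- vector("list", n_mov + 1)
      ffts[[1]] <- fft3(g)
      for (t in seq_len(n_mov)) {
        ang <- stats::runif(3, -cfg$motion_max_rotation, cfg$motion_max_rotation)
        tr <- stats::runif(3, -cfg$motion_max_translation, cfg$motion_max_translation)
        ffts[[t + 1]] <- fft3(apply_rigid(g, ang, tr, FALSE, min(g)))
      }
      ax <- sample.int(3, 1)
      n <- dim(g)[ax]
      cuts <- sort(sample.int(n - 1, n_mov))
      bounds <- c(0, cuts, n)
      comp <- ffts[[1]]
      for (t in seq_len(n_mov)) {
        idx <- (bounds[t + 1] + 1):bounds[t + 2]
        if (ax == 1) comp[idx, , ] <- ffts[[t + 1]][idx, , ]
        if (ax == 2) comp[, idx, ] <- ffts[[t + 1]][, idx, ]
        if (ax == 3) comp[, , idx] <- ffts[[t + 1]][, , idx]
      }
      g <- ifft3_re(comp)
    }
    if (stats::runif(1) < cfg$ghosting_p) {
      applied["ghosting"] <- TRUE
      ax <- sample.int(3, 1)
      depth <- stats::runif(1, 0, cfg$ghosting_intensity)
      n <- dim(g)[ax]
      kk <- fft3(g)
      idx <- which((seq_len(n) - 1) %% max(1, cfg$ghosting_n_ghosts) == 0)
      idx <- setdiff(idx, 1L)        # keep the DC plane
      if (length(idx)) {
        if (ax == 1) kk[idx, , ] <- kk[idx, , ] * (1 - depth)
        if (ax == 2) kk[, idx, ] <- kk[, idx, ] * (1 - depth)
        if (ax == 3) kk[, , idx] <- kk[, , idx] * (1 - depth)
        g <- ifft3_re(kk)
      }
    }
    if (stats::runif(1) < cfg$spike_p) {
      applied["spike"] <- TRUE
      kk <- fft3(g)
      amp_scale <- max(Mod(kk))
      for (t in seq_len(max(1, cfg$spike_n_spikes))) {
        pos <- vapply(dim(g), function(n) sample.int(n, 1), integer(1))
        if (all(pos == 1)) pos[1] <- 2   # avoid the DC component
        amp <- stats::runif(1, 0.1, 1) * cfg$spike_intensity * amp_scale
        phase <- stats::runif(1, 0, 2 * pi)
        kk[pos[1], pos[2], pos[3]] <- kk[pos[1], pos[2], pos[3]] +
          amp * exp(1i * phase)
      }
      g <- ifft3_re(kk)
    }
    out <- same_geometry(v, g)
    attr(out, "applied") <- applied
    out
  })
}

#' Intensity augmentations (volume only)
#'
#' Bias field: multiplication by `exp(P)` with `P` a random polynomial over
#' normalized coordinates. Noise: additive Gaussian. Contrast: power-law
#' remap with exponent `exp(u)` applied on intensities shifted to a
#' non-negative range and shifted back.
#'
#' @inheritParams spatial_transforms
#' @return a [volume()] with an `applied` attribute.
#' @export
intensity_transforms <- function(v, cfg = augment_config(), seed = NULL) {
  stopifnot(inherits(v, "chp_volume"))
  with_seed(seed, {
    applied <- c(bias = FALSE, noise = FALSE, contrast = FALSE)
    g <- v$grid
    if (stats::runif(1) < cfg$bias_p) {
      applied["bias"] <- TRUE
      g <- g * exp(random_polynomial_field(dim(g), cfg$bias_order,
                                           cfg$bias_max_magnitude))
    }
    if (stats::runif(1) < cfg$noise_p) {
      applied["noise"] <- TRUE
      g <- g + array(stats::rnorm(length(g), cfg$noise_mean, cfg$noise_std), dim(g))
    }
    if (stats::runif(1) < cfg$contrast_p) {
      applied["contrast"] <- TRUE
      u <- stats::runif(1, -cfg$contrast_max_log_gamma, cfg$contrast_max_log_gamma)
      rng <- range(g)
      if (rng[2] > rng[1]) {
        xn <- (g - rng[1]) / (rng[2] - rng[1])
        g <- rng[1] + (rng[2] - rng[1]) * xn^exp(u)
      }
    }
    out <- same_geometry(v, g)
    attr(out, "applied") <- applied
    out
  })
}

# random polynomial over coordinates normalized to [-1, 1]; the constant
# term is excluded so the field averages near unit gain
random_polynomial_field <- function(d, order, magnitude) {
  xs <- lapply(d, function(n) if (n > 1) seq(-1, 1, length.out = n) else 0)
  P <- array(0, d)
  for (a in 0:order) for (b in 0:(order - a)) for (cc in 0:(order - a - b)) {
    if (a + b + cc == 0) next
    coef <- stats::runif(1, -magnitude, magnitude)
    P <- P + coef * outer(outer(xs[[1]]^a, xs[[2]]^b), xs[[3]]^cc)
  }
  P
}

#' Apply the full augmentation battery to a volume/mask pair
#'
#' Each transform triggers independently at its configured probability;
#' spatial transforms act on both members, k-space and intensity transforms
#' on the volume only. Composition order is spatial, then k-space, then
#' intensity (the order of physical acquisition).
#'
#' @inheritParams spatial_transforms
#' @return list `(volume, mask)` with an `applied` attribute (named logical
#'   over all nine transforms).
#' @export
augment_pair <- function(v, m, cfg = augment_config(), seed = NULL) {
  with_seed(seed, {
    sp <- spatial_transforms(v, m, cfg)
    kv <- kspace_artifacts(sp$volume, cfg)
    iv <- intensity_transforms(kv, cfg)
    out <- list(volume = iv, mask = sp$mask)
    attr(out$volume, "applied") <- NULL
    attr(out, "applied") <- c(attr(sp, "applied"), attr(kv, "applied"),
                              attr(iv, "applied"))
    out
  })
}
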