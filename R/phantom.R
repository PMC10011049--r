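#' Phantom generation parameters
#'
#' The phantom emulates the geometry that makes choroid plexus segmentation
#' hard: a bright, thin, curvilinear structure occupying a fraction of a
#' percent of the volume, lying inside dark CSF-filled cavities within
#' brighter brain tissue. It is not anatomically realistic; it carries the
#' contrast ordering (cavity < brain < target), the sparsity and the thin
#' tubular geometry that the cascade must learn.
#'
#' @param shape voxel triple; 96^3 keeps desk-scale training fast while
#'   remaining divisible by 8 (4-level network).
#' @param cavity_count number of dark cavities (lateral-ventricle stand-ins).
#' @param target_volume_fraction fraction of all voxels occupied by the
#'   bright target (choroid-plexus-like sparsity, defaults to 0.2%).
#' @param background,brain,cavity,target intensity levels; must satisfy
#'   cavity < brain < target.
#' @param smoothing_mm Gaussian smoothing width applied to the intensity
#'   field (partial-volume blur).
#' @param noise_std additive Gaussian noise standard deviation.
#' @param dilation_radius tube radius in voxels (1 or 2).
#' @param seed RNG seed; generation is fully reproducible.
#' @return A `chp_phantom_params` list.
#' @export
phantom_params <- function(shape = c(96, 96, 96), cavity_count = 2,
                           target_volume_fraction = 0.002,
                           background = 0.05, brain = 0.6, cavity = 0.15,
                           target = 1.0, smoothing_mm = 0.8, noise_std = 0.05,
                           dilation_radius = 1, seed = 1) {
  if (target_volume_fraction <= 0 || target_volume_fraction >= 0.05)
    stopf("target_volume_fraction must be in (0, 5%%)")
  if (!(cavity < brain && brain < target))
    stopf("contrast ordering must be cavity < brain < target")
  structure(list(shape = as.integer(shape), cavity_count = as.integer(cavity_count),
                 target_volume_fraction = target_volume_fraction,
                 background = background, brain = brain, cavity = cavity,
                 target = target, smoothing_mm = smoothing_mm,
                 noise_std = noise_std,
                 dilation_radius = as.integer(dilation_radius),
                 seed = as.integer(seed)),
            class = "chp_phantom_params")
}

# voxels of an axis-aligned ellipsoid as a logical array
ellipsoid_mask <- function(shape, center, semi) {
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  di <- (i - center[1]) / semi[1]
  dj <- (j - center[2]) / semi[2]
  dk <- (k - center[3]) / semi[3]
  r2 <- outer(outer(di^2, dj^2, "+"), dk^2, "+")
  r2 <= 1
}

#' Generate one synthetic phantom
#'
#' An ellipsoidal "brain" over a dark background contains `cavity_count`
#' dark ellipsoidal cavities placed symmetrically about the midline; inside
#' each cavity a thin bright tube is grown by a persistent random walk,
#' dilated to the configured radius and clipped to the cavity. The intensity
#' field is Gaussian-smoothed and corrupted with additive noise; the ground
#' truth mask records the pre-smoothing tube voxels.
#'
#' @param p a [phantom_params()].
#' @return list with `volume` (a [volume()], 1 mm RAS) and `mask`
#'   (a [label_mask()]).
#' @export
generate_phantom <- function(p = phantom_params()) {
  stopifnot(inherits(p, "chp_phantom_params"))
  with_seed(p$seed, generate_phantom_impl(p))
}

generate_phantom_impl <- function(p) {
  s <- p$shape
  brain_mask <- ellipsoid_mask(s, s / 2, 0.44 * s)
  img <- array(p$background, s)
  img[brain_mask] <- p$brain

  # cavities alternate left/right of the midline
  cav <- array(FALSE, s)
  cav_list <- vector("list", p$cavity_count)
  for (ci in seq_len(p$cavity_count)) {
    side <- if (ci %% 2 == 1) 0.34 else 0.66
    depth <- 0.45 + 0.1 * ((ci - 1) %/% 2)
    center <- c(side * s[1], 0.5 * s[2], depth * s[3])
    semi <- c(0.12, 0.22, 0.18) * s
    cm <- ellipsoid_mask(s, center, semi)
    cav_list[[ci]] <- list(center = center, semi = semi)
    cav <- cav | cm
  }
  img[cav] <- p$cavity

  target_total <- round(p$target_volume_fraction * prod(s))
  if (target_total > 0.8 * sum(cav))
    stopf("requested target volume (%d voxels) does not fit the cavities (%d voxels); enlarge the cavities or lower the fraction",
          target_total, sum(cav))
  per_cavity <- ceiling(target_total / p$cavity_count)
  mask <- array(0, s)
  rad <- p$dilation_radius
  ball <- as.matrix(expand.grid(di = -rad:rad, dj = -rad:rad, dk = -rad:rad))
  ball <- ball[rowSums(ball^2) <= rad^2 + 0.5, , drop = FALSE]
  for (ci in seq_len(p$cavity_count)) {
    info <- cav_list[[ci]]
    pos <- info$center
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    placed <- 0; steps <- 0
    max_steps <- 40 * per_cavity
    while (placed < per_cavity && steps < max_steps) {
      steps <- steps + 1
      dir <- dir + 0.45 * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- pos + dir
      # reflect towards the cavity center when about to leave it
      rel <- (cand - info$center) / info$semi
      if (sum(rel^2) > 0.85^2) {
        dir <- (info$center - pos) + 0.5 * stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        cand <- pos + dir
      }
      pos <- cand
      vc <- round(pos)
      pts <- sweep(ball, 2, vc, "+")
      ok <- pts[, 1] >= 1 & pts[, 1] <= s[1] &
            pts[, 2] >= 1 & pts[, 2] <= s[2] &
            pts[, 3] >= 1 & pts[, 3] <= s[3]
      pts <- pts[ok, , drop = FALSE]
      lin <- pts[, 1] + s[1] * (pts[, 2] - 1) + s[1] * s[2] * (pts[, 3] - 1)
      lin <- lin[cav[lin]]          # clip to the cavity
      new <- lin[mask[lin] == 0]
      # never overshoot the per-cavity budget (matters for tiny phantoms)
      new <- new[seq_len(min(length(new), per_cavity - placed))]
      mask[new] <- 1
      placed <- placed + length(new)
    }
  }
  achieved <- sum(mask) / prod(s)
  if (achieved < 0.5 * p$target_volume_fraction ||
      achieved > 1.5 * p$target_volume_fraction)
    stopf("achieved target fraction %.4f%% is outside +/-50%% of the requested %.4f%%; enlarge the cavities",
          100 * achieved, 100 * p$target_volume_fraction)
  img[mask == 1] <- p$target
  if (p$smoothing_mm > 0)
    img <- gauss3d_cpp(img, dim(img), p$smoothing_mm)  # 1 mm voxels
  if (p$noise_std > 0)
    img <- img + array(stats::rnorm(prod(s), sd = p$noise_std), s)
  list(volume = volume(img), mask = label_mask(mask))
}

#' Generate a phantom cohort with varied target volumes
#'
#' Target volume fractions are drawn uniformly from `fraction_range` so
#' ground-truth volumes vary across subjects (needed for volume-correlation
#' statistics); per-subject seeds are derived deterministically from the
#' cohort seed.
#'
#' @param n number of phantoms.
#' @param base a [phantom_params()] template.
#' @param seed cohort seed.
#' @param fraction_range range of target volume fractions.
#' @return list of `list(volume =, mask =)` pairs.
#' @export
generate_cohort <- function(n, base = phantom_params(), seed = 1,
                            fraction_range = c(0.001, 0.003)) {
  if (n < 1) stopf("n must be >= 1")
  fracs <- with_seed(derive_seed(seed, 0),
                     stats::runif(n, fraction_range[1], fraction_range[2]))
  lapply(seq_len(n), function(i) {
    p <- base
    p$target_volume_fraction <- fracs[i]
    p$seed <- derive_seed(seed, i)
    generate_phantom(p)
  })
}
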