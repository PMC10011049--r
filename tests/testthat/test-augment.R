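zero_cfg <- function(...) {
  # all probabilities 0 unless overridden
  base <- list(flip_p = 0, affine_p = 0, anisotropy_p = 0, motion_p = 0,
               ghosting_p = 0, spike_p = 0, bias_p = 0, noise_p = 0,
               contrast_p = 0)
  do.call(augment_config, utils::modifyList(base, list(...)))
}

small_pair <- function(seed = 1, shape = c(12, 12, 12)) {
  set.seed(seed)
  v <- volume(array(rnorm(prod(shape)), shape))
  m <- label_mask(array(rbinom(prod(shape), 1, 0.1), shape))
  list(v = v, m = m)
}

test_that("with all probabilities zero every stage is the identity", {
  pr <- small_pair()
  out <- augment_pair(pr$v, pr$m, zero_cfg(), seed = 5)
  expect_identical(out$volume$grid, pr$v$grid)
  expect_identical(out$mask$grid, pr$m$grid)
  expect_true(all(!attr(out, "applied")))
})

test_that("spatial transforms are involutive / tolerance-identities", {
  pr <- small_pair(2)
  flip_once <- spatial_transforms(pr$v, pr$m, zero_cfg(flip_p = 1), seed = 1)
  flip_twice <- spatial_transforms(flip_once$volume, flip_once$mask,
                                   zero_cfg(flip_p = 1), seed = 2)
  expect_identical(flip_twice$volume$grid, pr$v$grid)
  expect_identical(flip_twice$mask$grid, pr$m$grid)

  # affine with zero rotation and zero scale jitter is the identity
  ident <- spatial_transforms(pr$v, pr$m,
                              zero_cfg(affine_p = 1, affine_max_scale = 0,
                                       affine_max_rotation = 0), seed = 3)
  expect_equal(ident$volume$grid, pr$v$grid, tolerance = 1e-12)
  expect_equal(ident$mask$grid, pr$m$grid)

  aniso <- spatial_transforms(pr$v, pr$m, zero_cfg(anisotropy_p = 1), seed = 4)
  expect_true(all(aniso$mask$grid %in% c(0, 1)))
})

test_that("k-space transforms at zero magnitude are identities within 1e-5", {
  pr <- small_pair(3)
  spike0 <- kspace_artifacts(pr$v, zero_cfg(spike_p = 1, spike_intensity = 0), seed = 1)
  expect_lt(max(abs(spike0$grid - pr$v$grid)), 1e-5)
  ghost0 <- kspace_artifacts(pr$v, zero_cfg(ghosting_p = 1, ghosting_intensity = 0), seed = 2)
  expect_lt(max(abs(ghost0$grid - pr$v$grid)), 1e-5)
  motion0 <- kspace_artifacts(pr$v, zero_cfg(motion_p = 1, motion_max_rotation = 0,
                                             motion_max_translation = 0), seed = 3)
  expect_lt(max(abs(motion0$grid - pr$v$grid)), 1e-5)
})

test_that("a spike writes a single plane wave into the image", {
  v <- volume(array(1, c(8, 8, 8)))   # constant so only the DC term is present
  out <- kspace_artifacts(v, zero_cfg(spike_p = 1), seed = 11)
  resid <- out$grid - v$grid
  kk <- fft(resid)
  mag <- Mod(kk)
  hot <- which(mag > 1e-6 * max(mag))
  expect_lte(length(hot), 2)           # the spike frequency (+ its mirror)
  # reconstruct the plane wave directly from the hot coefficient and compare
  sub <- arrayInd(hot[1], dim(resid)) - 1
  amp <- kk[hot[1]]
  n <- prod(dim(resid))
  idx <- as.matrix(expand.grid(i = 0:7, j = 0:7, k = 0:7))
  phase <- 2 * pi * (idx %*% (sub[1, ] / 8))
  wave <- array(Re(amp * exp(1i * phase)) / n, dim(resid))
  if (length(hot) == 2) wave <- 2 * wave
  expect_equal(resid, wave, tolerance = 1e-8)
})

test_that("intensity transforms follow their stated parameterizations", {
  pr <- small_pair(4)
  gamma0 <- intensity_transforms(pr$v, zero_cfg(contrast_p = 1,
                                                contrast_max_log_gamma = 0), seed = 1)
  expect_equal(gamma0$grid, pr$v$grid, tolerance = 1e-12)
  bias0 <- intensity_transforms(pr$v, zero_cfg(bias_p = 1, bias_max_magnitude = 0), seed = 2)
  expect_equal(bias0$grid, pr$v$grid, tolerance = 1e-12)

  # noise on a zero volume: sample mean ~ 0 and sd ~ 1 (law of large numbers)
  z <- volume(array(0, c(24, 24, 24)))
  noised <- intensity_transforms(z, zero_cfg(noise_p = 1), seed = 3)
  n <- length(noised$grid)
  expect_lt(abs(mean(noised$grid)), 3 / sqrt(n))
  expect_lt(abs(stats::sd(noised$grid) - 1), 3 / sqrt(n))
})

test_that("the full battery keeps masks binary and is seed-reproducible", {
  pr <- small_pair(6)
  all_on <- augment_config(flip_p = 1, affine_p = 1, anisotropy_p = 1,
                           motion_p = 1, ghosting_p = 1, spike_p = 1,
                           bias_p = 1, noise_p = 1, contrast_p = 1)
  a <- augment_pair(pr$v, pr$m, all_on, seed = 9)
  expect_true(all(a$mask$grid %in% c(0, 1)))
  expect_identical(dim(a$volume$grid), dim(pr$v$grid))
  expect_true(all(attr(a, "applied")))
  b <- augment_pair(pr$v, pr$m, all_on, seed = 9)
  expect_identical(a$volume$grid, b$volume$grid)
  expect_identical(a$mask$grid, b$mask$grid)
})
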