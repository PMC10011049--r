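test_that("downsampling matches an independent interpolation oracle", {
  const <- downsample(array(2.5, c(12, 12, 12)), c(5, 6, 4))
  expect_equal(dim(const), c(5L, 6L, 4L))
  expect_equal(range(const), c(2.5, 2.5))

  # separable cosine field: compare against plain-R trilinear interpolation
  d <- c(10, 8, 12)
  x <- outer(outer(cos(seq_len(d[1])), cos(0.5 * seq_len(d[2]))),
             cos(0.3 * seq_len(d[3])))
  low <- downsample(x, c(5, 4, 6))
  expect_equal(low, resize_oracle(x, c(5, 4, 6)), tolerance = 1e-12)
  # down-then-up reconstruction error is bounded for a smooth field
  back <- resize3d_cpp(low, dim(low), d, FALSE)
  expect_lt(max(abs(back - x)), 0.5)

  expect_error(downsample(x, c(20, 4, 6)), "axis 1")
})

test_that("seed voxels use a strict threshold and index-scaling to full resolution", {
  p <- array(0, c(4, 4, 4))
  expect_equal(nrow(find_seed_voxels(p, c(16, 16, 16))), 0)

  p[2, 3, 4] <- 0.9
  p[1, 1, 1] <- 0.5
  cand <- find_seed_voxels(p, c(16, 16, 16), 0.8)
  expect_equal(nrow(cand), 1)
  # 0-based index scales by 16/4 = 4, rounds, then back to 1-based
  expect_equal(unname(cand[1, ]), round((c(2, 3, 4) - 1) * 4) + 1)

  p[2, 3, 4] <- 0.8        # exactly at threshold: excluded
  expect_equal(nrow(find_seed_voxels(p, c(16, 16, 16), 0.8)), 0)

  # raising the threshold never yields more candidates
  set.seed(31)
  pr <- array(runif(6^3), c(6, 6, 6))
  counts <- vapply(c(0.2, 0.5, 0.8, 0.95),
                   function(th) nrow(find_seed_voxels(pr, c(12, 12, 12), th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("patch budget keeps everything under the cap, subsamples above it", {
  cand <- cbind(i = 1:3, j = 1:3, k = 1:3)
  expect_identical(sample_patch_locations(cand, 500), cand)
  many <- cbind(i = rep(1:10, 10), j = rep(1:10, each = 10), k = 1L)
  sub <- sample_patch_locations(many, 40, seed = 7)
  expect_equal(nrow(sub), 40)
  expect_identical(sub, sample_patch_locations(many, 40, seed = 7))
  expect_equal(nrow(sample_patch_locations(many, nrow(many))), nrow(many))
})

test_that("patch extraction centers on the seed and clamps at borders", {
  v <- array(seq_len(20^3), c(20, 20, 20))
  inner <- extract_patch(v, c(10, 10, 10), 8)
  expect_equal(inner$origin, c(10, 10, 10) - 4L)
  expect_equal(inner$data, v[6:13, 6:13, 6:13], ignore_attr = FALSE,
               tolerance = 0)
  corner <- extract_patch(v, c(1, 1, 20), 8)
  expect_equal(corner$origin, c(1L, 1L, 13L))
  expect_equal(corner$data, v[1:8, 1:8, 13:20], tolerance = 0)
  expect_error(extract_patch(v, c(10, 10, 10), 21), "exceeds")
})

test_that("the Hann window is the interior-sampled raised cosine", {
  n <- 8
  w <- hann_window(n)
  prof <- 0.5 * (1 - cos(2 * pi * (seq_len(n)) / (n + 1)))
  expect_equal(w[, 4, 4] / w[4, 4, 4], prof / prof[4], tolerance = 1e-12)
  expect_equal(w[1, 4, 4], prof[1] * prof[4]^2)
  expect_true(all(w > 0))
  expect_equal(w, w[n:1, , ])            # reflection symmetry
  expect_equal(which.max(w[, 4, 4]), 4L)  # interior maximum
})

test_that("Hann merging normalizes to a weighted average of patch values", {
  out <- merge_patches(list(list(origin = c(3L, 3L, 3L), data = array(0.7, c(4, 4, 4)))),
                       c(10, 10, 10))
  expect_equal(range(out[3:6, 3:6, 3:6]), c(0.7, 0.7), tolerance = 1e-12)
  expect_equal(sum(out) , 0.7 * 64, tolerance = 1e-9)

  # two fully overlapping patches of values a and b average to (a+b)/2
  two <- merge_patches(list(list(origin = c(1L, 1L, 1L), data = array(0.2, c(4, 4, 4))),
                            list(origin = c(1L, 1L, 1L), data = array(0.8, c(4, 4, 4)))),
                       c(4, 4, 4))
  expect_equal(range(two), c(0.5, 0.5), tolerance = 1e-12)

  # patches copied from a source map over a tiling cover reproduce it
  set.seed(17)
  src <- array(runif(16^3), c(16, 16, 16))
  patches <- list()
  for (o3 in c(1L, 9L)) for (o2 in c(1L, 9L)) for (o1 in c(1L, 9L))
    patches <- c(patches, list(list(origin = c(o1, o2, o3),
                                    data = src[o1:(o1 + 7), o2:(o2 + 7), o3:(o3 + 7)])))
  expect_lt(max(abs(merge_patches(patches, c(16, 16, 16)) - src)), 1e-5)

  expect_equal(merge_patches(list(), c(4, 4, 4)), array(0, c(4, 4, 4)))
})

test_that("binarization is strict and monotone in the threshold", {
  expect_equal(sum(binarize(array(0.6, c(3, 3, 3)), 0.5)), 27)
  expect_equal(sum(binarize(array(0.5, c(3, 3, 3)), 0.5)), 0)
  set.seed(5)
  p <- array(runif(6^3), c(6, 6, 6))
  vols <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                 function(th) sum(binarize(p, th)), numeric(1))
  expect_true(all(diff(vols) <= 0))
  expect_error(binarize(p, 1), "threshold")
})

test_that("two-step prediction with ground-truth oracles recovers the phantom", {
  ph <- generate_phantom(phantom_params(shape = c(48, 48, 48), seed = 77))
  nets <- oracle_nets(ph$mask)
  cfg <- cascade_config(lowres_shape = c(16, 16, 16), patch_size = 24)
  pred <- predict_two_step(ph$volume, nets$net1, nets$net2, cfg, seed = 2)
  expect_gt(dice_score(pred$mask, ph$mask), 0.95)
  # deterministic under the same seed
  pred2 <- predict_two_step(ph$volume, nets$net1, nets$net2, cfg, seed = 2)
  expect_identical(pred2$mask$grid, pred$mask$grid)
})

test_that("a seedless coarse stage yields an empty mask with a warning", {
  v <- volume(array(rnorm(16^3), c(16, 16, 16)))
  near_zero <- function(x) array(1e-4, dim(x))
  expect_warning(
    pred <- predict_two_step(v, near_zero, near_zero,
                             cascade_config(lowres_shape = c(8, 8, 8), patch_size = 8)),
    "no seed")
  expect_equal(sum(pred$mask$grid), 0)
  expect_equal(sum(pred$prob$grid), 0)
})

test_that("one-step prediction binarizes a whole-volume forward pass", {
  ph <- generate_phantom(phantom_params(shape = c(24, 24, 24), seed = 3))
  oracle <- function(x) ph$mask$grid
  pred <- predict_one_step(ph$volume, oracle)
  expect_equal(dim(pred$prob$grid), dim(ph$volume$grid))
  expect_identical(pred$mask$grid, ph$mask$grid)
})
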