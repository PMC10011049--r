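test_that("phantom generation is reproducible and hits the requested sparsity", {
  p <- phantom_params(shape = c(48, 48, 48), seed = 5)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$volume$grid, b$volume$grid)
  expect_identical(a$mask$grid, b$mask$grid)
  expect_true(all(a$mask$grid %in% c(0, 1)))

  frac <- sum(a$mask$grid) / prod(dim(a$mask$grid))
  expect_gt(frac, 0.5 * p$target_volume_fraction)
  expect_lt(frac, 1.5 * p$target_volume_fraction)
})

test_that("the target is bright relative to its cavity surroundings", {
  ph <- generate_phantom(phantom_params(shape = c(48, 48, 48), seed = 8))
  mask <- ph$mask$grid == 1
  # cavity neighbourhood: voxels within a 2-voxel shell around the target
  idx <- which(mask)
  sub <- arrayInd(idx, dim(mask))
  shell <- unique(do.call(rbind, lapply(list(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0),
                                             c(0, -2, 0), c(0, 0, 2), c(0, 0, -2)),
                                        function(o) sweep(sub, 2, o, "+"))))
  keep <- shell[, 1] >= 1 & shell[, 1] <= 48 & shell[, 2] >= 1 &
    shell[, 2] <= 48 & shell[, 3] >= 1 & shell[, 3] <= 48
  shell <- shell[keep, , drop = FALSE]
  lin <- shell[, 1] + 48 * (shell[, 2] - 1) + 48 * 48 * (shell[, 3] - 1)
  lin <- setdiff(lin, idx)
  expect_gt(mean(ph$volume$grid[idx]), mean(ph$volume$grid[lin]))
})

test_that("an unachievable target fraction is rejected with guidance", {
  expect_error(generate_phantom(phantom_params(shape = c(24, 24, 24),
                                               target_volume_fraction = 0.04)),
               "cavities")
})

test_that("cohorts vary target volume and regenerate identically", {
  co <- generate_cohort(5, phantom_params(shape = c(24, 24, 24)), seed = 31)
  vols <- vapply(co, function(pr) sum(pr$mask$grid), numeric(1))
  expect_equal(length(co), 5)
  expect_gt(stats::sd(vols), 0)
  expect_gt(length(unique(lapply(co, function(pr) pr$mask$grid))), 1)
  co2 <- generate_cohort(5, phantom_params(shape = c(24, 24, 24)), seed = 31)
  expect_identical(vols, vapply(co2, function(pr) sum(pr$mask$grid), numeric(1)))
})
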