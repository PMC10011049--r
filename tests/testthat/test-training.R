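test_that("soft Dice matches the closed-form examples and the binary oracle", {
  expect_equal(soft_dice(array(1, c(2, 2, 2)), array(1, c(2, 2, 2))), 1)
  expect_equal(soft_dice(c(1, 0), c(0, 1)), 0)
  expect_equal(soft_dice(0.5, 1), 2 * 0.5 / 1.5)
  expect_equal(dice_loss(0.5, 1), 1 - 2 / 3)
  expect_equal(soft_dice(numeric(4), numeric(4)), 1)   # empty-empty convention

  # brute-force counting oracle over random binary pairs
  set.seed(41)
  for (t in 1:100) {
    x <- array(rbinom(6^3, 1, runif(1, 0.05, 0.6)), c(6, 6, 6))
    y <- array(rbinom(6^3, 1, runif(1, 0.05, 0.6)), c(6, 6, 6))
    classic <- if (sum(x) + sum(y) == 0) 1 else
      2 * sum(x == 1 & y == 1) / (sum(x) + sum(y))
    expect_identical(soft_dice(x, y), classic)
  }
})

test_that("binary cross entropy hits its closed forms", {
  y <- array(rbinom(4^3, 1, 0.5), c(4, 4, 4))
  x05 <- array(0.5, c(4, 4, 4))
  expect_equal(bce(x05, x05), log(2), tolerance = 1e-12)
  expect_equal(bce(x05, y), log(2), tolerance = 1e-12)  # 0.5 is target-blind
  expect_lt(bce(y, y), 1e-6)                            # clamped perfect fit
  expect_gte(bce(array(runif(64), c(4, 4, 4)), y), 0)
})

test_that("the combined loss decomposes and the cascade rule is conditional", {
  set.seed(2)
  x <- array(runif(4^3), c(4, 4, 4))
  y <- array(rbinom(4^3, 1, 0.3), c(4, 4, 4))
  cl <- combined_loss(x, y)
  expect_equal(cl$total, cl$dice_loss + cl$bce)
  expect_gte(cl$total, cl$dice_loss)

  # N = 0: bit-equal to the coarse-stage loss
  c0 <- cascade_loss(x, y, list(), list(), 0)
  expect_identical(c0$total, cl$total)
  expect_identical(c0$n_patches, 0L)

  # N > 0 adds a non-negative fine-stage term
  px <- array(runif(2^3), c(2, 2, 2)); py <- array(1, c(2, 2, 2))
  c1 <- cascade_loss(x, y, list(px), list(py), 1)
  expect_gte(c1$total, c0$total)
  expect_equal(c1$n_patches, 1L)
  # perfect patches add (almost) nothing
  cperf <- cascade_loss(x, y, list(py), list(py), 1)
  expect_equal(cperf$total, c0$total, tolerance = 1e-5)
  expect_error(cascade_loss(x, y, list(px), list(), 1), "length")
})

test_that("learning rate halves exactly on consecutive-epoch plateaus", {
  expect_equal(lr_on_plateau(c(0.50, 0.4999), 1e-3), 5e-4)
  expect_equal(lr_on_plateau(c(0.50, 0.40), 1e-3), 1e-3)
  expect_error(lr_on_plateau(0.5, 1e-3), "2 epochs")
  # k triggering epochs give initial * 0.5^k
  history <- c(0.9, 0.5, 0.4999, 0.49985, 0.3, 0.29999)
  lr <- 1e-3; triggers <- 0
  for (e in 2:length(history)) {
    new <- lr_on_plateau(history[1:e], lr)
    if (new < lr) triggers <- triggers + 1
    lr <- new
  }
  expect_equal(lr, 1e-3 * 0.5^triggers)
  expect_equal(triggers, 3)
})

test_that("the coarse-stage target is a binary nearest-neighbour downsample", {
  empty <- label_mask(array(0, c(16, 16, 16)))
  expect_equal(sum(make_step1_target(empty, c(8, 8, 8))), 0)
  full <- label_mask(array(1, c(16, 16, 16)))
  expect_equal(sum(make_step1_target(full, c(8, 8, 8))), 8^3)
  blob <- array(0, c(16, 16, 16)); blob[6:10, 6:10, 6:10] <- 1
  tgt <- make_step1_target(blob, c(8, 8, 8))
  expect_true(all(tgt %in% c(0, 1)))
  expect_gt(sum(tgt), 0)
  # the blob lands at the scaled location (indices 6..10 -> around 3..5)
  expect_equal(sum(tgt[3:5, 3:5, 3:5]), sum(tgt))
})

test_that("a short training run reduces the loss for most seeds", {
  pairs <- make_test_pairs(4, shape = c(32, 32, 32), seed = 500)
  wins <- 0
  for (s in 1:5) {
    cfg <- train_config(mode = "2step", epochs = 2, batch_lowres = 1,
                        max_patches_per_image = 2, seed = s)
    model <- train(pairs, cfg, tiny_cascade(), tiny_spec())
    if (model$log$train_total[2] <= model$log$train_total[1]) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("training is reproducible under a fixed seed with augmentation off", {
  pairs <- make_test_pairs(2, shape = c(32, 32, 32), seed = 501)
  cfg <- train_config(mode = "2step", epochs = 2, batch_lowres = 1,
                      max_patches_per_image = 2, seed = 99)
  m1 <- train(pairs, cfg, tiny_cascade(), tiny_spec())
  m2 <- train(pairs, cfg, tiny_cascade(), tiny_spec())
  expect_identical(m1$log, m2$log)
  expect_identical(m1$net1$enc[[1]]$b1$w, m2$net1$enc[[1]]$b1$w)
  expect_error(train(list(), cfg, tiny_cascade(), tiny_spec()), "empty")
})

test_that("one-step training on whole volumes also runs and logs", {
  pairs <- make_test_pairs(2, shape = c(16, 16, 16), seed = 502)
  cfg <- train_config(mode = "1step", epochs = 2, batch_lowres = 1, seed = 1)
  model <- train(pairs, cfg, tiny_cascade(), tiny_spec())
  expect_null(model$net2)
  expect_equal(nrow(model$log), 2)
  expect_true(all(is.finite(model$log$train_total)))
})
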