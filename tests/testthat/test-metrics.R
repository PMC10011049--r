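test_that("overlap metrics match counting on constructed masks", {
  d <- c(6, 6, 6)
  y <- array(0, d); y[1:4, 1:5, 1] <- 1          # 20 reference voxels
  x_half <- array(0, d); x_half[1:2, 1:5, 1] <- 1 # the correct half
  expect_equal(dice_score(x_half, y), 2 * 10 / 30)
  expect_equal(recall(x_half, y), 0.5)
  expect_equal(precision(x_half, y), 1)

  x_double <- array(0, d); x_double[1:4, 1:5, 1:2] <- 1  # superset, twice the size
  expect_equal(recall(x_double, y), 1)
  expect_equal(precision(x_double, y), 0.5)

  disj <- array(0, d); disj[6, 6, 6] <- 1
  expect_equal(dice_score(disj, y), 0)
  expect_equal(recall(disj, y), 0)

  ve <- volume_error_rate(x_double, y)
  expect_equal(ve$ver, 1)
  under <- volume_error_rate(x_half, y)
  expect_equal(under$ver, -0.5)
  expect_equal(under$aver, 0.5)

  expect_error(recall(x_half, array(0, d)), "empty reference")
  expect_error(precision(array(0, d), y), "empty prediction")
  expect_error(volume_error_rate(x_half, array(0, d)), "empty reference")
  expect_warning(expect_equal(dice_score(array(0, d), array(0, d)), 1), "convention")
})

test_that("Dice is the harmonic mean of recall and precision on random masks", {
  set.seed(77)
  checked <- 0
  for (t in 1:200) {
    x <- array(rbinom(8^3, 1, runif(1, 0.05, 0.5)), c(8, 8, 8))
    y <- array(rbinom(8^3, 1, runif(1, 0.05, 0.5)), c(8, 8, 8))
    if (sum(x) == 0 || sum(y) == 0) next
    r <- recall(x, y); p <- precision(x, y)
    if (r + p > 0)
      expect_equal(dice_score(x, y), 2 * r * p / (r + p), tolerance = 1e-12)
    expect_equal(dice_score(x, y), dice_score(y, x))
    expect_equal(recall(x, y), precision(y, x))
    expect_equal(sign(volume_error_rate(x, y)$ver), sign(sum(x) - sum(y)))
    checked <- checked + 1
  }
  expect_gt(checked, 150)
})

test_that("cohort summary reproduces a hand-computed three-subject fixture", {
  d <- c(6, 6, 6)
  mk <- function(nx, ny) {
    y <- array(0, d); y[seq_len(ny)] <- 1
    x <- array(0, d); x[seq_len(nx)] <- 1
    evaluate_pair(x, y, subject_id = paste0("s", nx))
  }
  rows <- rbind(mk(10, 10), mk(8, 12), mk(15, 11))
  rep <- cohort_summary(rows)

  # independent textbook computation of mean, SEM and Pearson r
  dices <- c(2 * 10 / 20, 2 * 8 / 20, 2 * 11 / 26)
  expect_equal(rep$summary$mean[rep$summary$metric == "dice"], mean(dices))
  m <- sum(dices) / 3
  sem <- sqrt(sum((dices - m)^2) / 2) / sqrt(3)
  expect_equal(rep$summary$sem[rep$summary$metric == "dice"], sem)
  px <- c(10, 8, 15); py <- c(10, 12, 11)
  r_oracle <- sum((px - mean(px)) * (py - mean(py))) /
    sqrt(sum((px - mean(px))^2) * sum((py - mean(py))^2))
  expect_equal(rep$pearson_r, r_oracle)
  expect_equal(rep$n_subjects, 3L)
})

test_that("degenerate cohorts are reported as such", {
  d <- c(4, 4, 4)
  y <- array(0, d); y[1:5] <- 1
  row1 <- evaluate_pair(y, y, "a")
  same <- rbind(row1, row1, row1)
  expect_warning(rep <- cohort_summary(same), "constant")
  expect_true(all(rep$summary$sem == 0))
  expect_true(is.na(rep$pearson_r))

  # predicted == reference volumes across subjects gives r = 1
  x2 <- array(0, d); x2[1:9] <- 1
  x3 <- array(0, d); x3[1:7] <- 1
  rows <- rbind(row1, evaluate_pair(x2, x2, "b"), evaluate_pair(x3, x3, "c"))
  expect_equal(cohort_summary(rows)$pearson_r, 1)

  expect_error(cohort_summary(row1), "2 subjects")
})
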