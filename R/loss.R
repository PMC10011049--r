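#' Soft Dice coefficient (min formulation)
#'
#' `Dice = 2 * sum(min(x_i, y_i)) / (sum(x_i) + sum(y_i))`. On binary inputs
#' this equals the classic overlap Dice `2|X & Y| / (|X| + |Y|)`. When both
#' inputs sum to zero (empty prediction of an empty target) the coefficient
#' is 1 by convention.
#'
#' @param x,y numeric arrays of the same shape with values in \[0, 1\]
#'   (prediction and target).
#' @return scalar in \[0, 1\].
#' @export
soft_dice <- function(x, y) {
  if (!identical(dim(x), dim(y)) && length(x) != length(y))
    stopf("x and y must have the same shape")
  s <- sum(x) + sum(y)
  if (s == 0) return(1)
  2 * sum(pmin(x, y)) / s
}

#' Soft Dice loss
#'
#' `DL = 1 - Dice`, in \[0, 1\].
#'
#' @inheritParams soft_dice
#' @return scalar in \[0, 1\].
#' @export
dice_loss <- function(x, y) 1 - soft_dice(x, y)

BCE_EPS <- 1e-7

#' Binary cross entropy
#'
#' Mean over voxels of `-(y * log(x) + (1 - y) * log(1 - x))`, with
#' predictions clamped to `[1e-7, 1 - 1e-7]` to avoid log(0).
#'
#' @inheritParams soft_dice
#' @return non-negative scalar.
#' @export
bce <- function(x, y) {
  xc <- clamp(x, BCE_EPS, 1 - BCE_EPS)
  -mean(y * log(xc) + (1 - y) * log(1 - xc))
}

#' Compound segmentation loss
#'
#' Sum of the soft Dice loss and binary cross entropy.
#'
#' @inheritParams soft_dice
#' @return A `chp_loss` list with `dice_loss`, `bce`, `total` and
#'   `n_patches` (0 for a plain pair).
#' @export
combined_loss <- function(x, y) {
  dl <- dice_loss(x, y)
  bc <- bce(x, y)
  structure(list(dice_loss = dl, bce = bc, total = dl + bc, n_patches = 0L),
            class = "chp_loss")
}

#' Conditional two-stage cascade loss
#'
#' When the coarse stage yields no patch (`N = 0`) the fine-stage term is
#' skipped and the total equals the coarse loss exactly; otherwise the total
#' is the coarse loss plus the fine loss averaged over the patch batch.
#'
#' @param step1_pred,step1_target coarse-stage prediction and target grids.
#' @param patch_preds,patch_targets lists of fine-stage patch grids, both of
#'   length `n`.
#' @param n number of patch locations found after the coarse stage.
#' @return A `chp_loss` list; `dice_loss` and `bce` are the summed
#'   per-stage components, `total` their sum.
#' @export
cascade_loss <- function(step1_pred, step1_target,
                         patch_preds = list(), patch_targets = list(),
                         n = length(patch_preds)) {
  if (length(patch_preds) != n || length(patch_targets) != n)
    stopf("patch lists must have length n = %d", n)
  l1 <- combined_loss(step1_pred, step1_target)
  if (n == 0) {
    l1$n_patches <- 0L
    return(l1)
  }
  dl2 <- mean(vapply(seq_len(n), function(t)
    dice_loss(patch_preds[[t]], patch_targets[[t]]), numeric(1)))
  bc2 <- mean(vapply(seq_len(n), function(t)
    bce(patch_preds[[t]], patch_targets[[t]]), numeric(1)))
  structure(list(dice_loss = l1$dice_loss + dl2, bce = l1$bce + bc2,
                 total = l1$dice_loss + l1$bce + dl2 + bc2,
                 n_patches = as.integer(n)),
            class = "chp_loss")
}

# loss value + gradient w.r.t. the prediction, for training
combined_loss_grad <- function(x, y) {
  xc <- clamp(x, BCE_EPS, 1 - BCE_EPS)
  n <- length(x)
  s <- sum(xc) + sum(y)
  m <- sum(pmin(xc, y))
  if (s == 0) {
    ddice <- array(0, dim(x))
    dl <- 0
  } else {
    # d/dx of (1 - 2m/s): min is active where x < y (y binary: where y = 1)
    act <- as.double(xc < y)
    ddice <- -(2 * act * s - 2 * m) / s^2
    dim(ddice) <- dim(x)
    dl <- 1 - 2 * m / s
  }
  bc <- -mean(y * log(xc) + (1 - y) * log(1 - xc))
  dbce <- (-(y / xc) + (1 - y) / (1 - xc)) / n
  list(loss = structure(list(dice_loss = dl, bce = bc, total = dl + bc,
                             n_patches = 0L), class = "chp_loss"),
       grad = ddice + dbce)
}

#' Halve the learning rate on a validation-loss plateau
#'
#' A plateau is an absolute change below `delta` between the two most recent
#' consecutive epochs.
#'
#' @param history numeric vector of per-epoch validation losses (>= 2).
#' @param lr current learning rate.
#' @param delta plateau threshold.
#' @param factor multiplicative factor applied on a plateau.
#' @return the (possibly halved) learning rate.
#' @export
lr_on_plateau <- function(history, lr, delta = 1e-3, factor = 0.5) {
  if (length(history) < 2) stopf("need at least 2 epochs of history")
  k <- length(history)
  if (abs(history[k] - history[k - 1]) < delta) lr * factor else lr
}

#' Coarse-stage training target
#'
#' Downsamples a full-resolution binary mask to the coarse grid with
#' nearest-neighbour interpolation, so the target stays binary and uses the
#' same voxel-center coordinate mapping as [downsample()].
#'
#' @param m a [label_mask()] or 0/1 array.
#' @param lowres_shape coarse grid shape.
#' @return 0/1 array of shape `lowres_shape`.
#' @export
make_step1_target <- function(m, lowres_shape) {
  g <- if (inherits(m, "chp_volume")) m$grid else as_grid3(m)
  resize3d_cpp(g, dim(g), as.integer(lowres_shape), TRUE)
}
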