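#' Training configuration
#'
#' Adam optimizer with an initial learning rate of 1e-3, halved whenever the
#' validation loss changes by less than 1e-3 between two consecutive epochs.
#' The coarse stage is trained on whole low-resolution volumes in batches of
#' `batch_lowres`; up to `max_patches_per_image` full-resolution patches per
#' volume feed the fine stage (so the defaults give a 64-patch batch). The
#' single-stage baseline trains on whole high-resolution volumes (batch 1).
#'
#' @param mode `"2step"` (cascade) or `"1step"` (whole-volume baseline).
#' @param epochs training epochs (defaults: 200 for the cascade, 100 for the
#'   baseline).
#' @param initial_lr initial learning rate.
#' @param plateau_factor learning-rate factor applied on a plateau.
#' @param plateau_delta consecutive-epoch loss change defining a plateau.
#' @param batch_lowres coarse-stage batch size (volumes per update).
#' @param max_patches_per_image fine-stage patches drawn per volume.
#' @param augment apply the augmentation battery during training.
#' @param augment_config an [augment_config()] when `augment = TRUE`.
#' @param seed master seed: controls initialization, shuffling, patch
#'   sampling and augmentation.
#' @return A `chp_train_config` list.
#' @export
train_config <- function(mode = c("2step", "1step"),
                         epochs = NULL, initial_lr = 1e-3,
                         plateau_factor = 0.5, plateau_delta = 1e-3,
                         batch_lowres = 4, max_patches_per_image = 16,
                         augment = FALSE, augment_config = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(epochs)) epochs <- if (mode == "2step") 200L else 100L
  if (initial_lr <= 0 || plateau_factor <= 0 || plateau_delta <= 0)
    stopf("rates and thresholds must be positive")
  structure(list(mode = mode, epochs = as.integer(epochs),
                 initial_lr = initial_lr, plateau_factor = plateau_factor,
                 plateau_delta = plateau_delta,
                 batch_lowres = as.integer(batch_lowres),
                 max_patches_per_image = as.integer(max_patches_per_image),
                 batch_patches = as.integer(batch_lowres * max_patches_per_image),
                 augment = isTRUE(augment),
                 augment_config = augment_config,
                 seed = as.integer(seed)),
            class = "chp_train_config")
}

# ---- Adam over a nested parameter list ------------------------------------

adam_init <- function(params) {
  zeros <- function(x) if (is.list(x)) lapply(x, zeros) else array(0, dim(x) %||% length(x))
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in seq_along(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

grads_add <- function(a, b, scale = 1) {
  if (is.null(a)) return(grads_scale(b, scale))
  if (is.list(a)) return(mapply(grads_add, a, b, MoreArgs = list(scale = scale),
                                SIMPLIFY = FALSE))
  a + b * scale
}

grads_scale <- function(g, scale) {
  if (is.list(g)) return(lapply(g, grads_scale, scale = scale))
  g * scale
}

net_params <- function(net) net[c("enc", "dec", "final")]
net_set_params <- function(net, p) { net[c("enc", "dec", "final")] <- p; net }

# forward + loss + parameter gradients for one (input, target) pair
backprop_pair <- function(net, x, y) {
  fw <- network_forward(net, x, want_cache = TRUE)
  lg <- combined_loss_grad(fw$prob, y)
  g <- network_backward(net, fw$cache, lg$grad)
  list(loss = lg$loss, grads = g, prob = fw$prob)
}

#' Train the cascade (or the single-stage baseline)
#'
#' Training pairs must already be preprocessed (canonical, isotropic, fixed
#' shape, rescaled intensities). For the cascade, patch seeds come from the
#' current coarse-stage output on each volume (strict threshold), patch
#' targets are ground-truth mask crops at the sampled locations, and when no
#' seed is found the fine-stage update is skipped for that volume exactly as
#' the conditional loss dictates. The learning-rate schedule watches the
#' validation loss (or the training loss when no validation set is given).
#'
#' @param pairs list of `list(volume =, mask =)` training pairs.
#' @param cfg a [train_config()].
#' @param cascade_cfg a [cascade_config()]; its `lowres_shape` and
#'   `patch_size` must be divisible by `2^(levels - 1)` of `spec`.
#' @param spec a [network_spec()] shared by both stages.
#' @param val_pairs optional validation pairs for the plateau schedule.
#' @return A `chp_model`: trained network(s), config, and a per-epoch log
#'   (data frame of losses and learning rate). Fully reproducible under
#'   `cfg$seed`.
#' @export
train <- function(pairs, cfg = train_config(), cascade_cfg = cascade_config(),
                  spec = network_spec(), val_pairs = NULL) {
  if (length(pairs) == 0) stopf("empty training set")
  with_seed(cfg$seed, train_impl(pairs, cfg, cascade_cfg, spec, val_pairs))
}

train_impl <- function(pairs, cfg, cascade_cfg, spec, val_pairs) {
  two_step <- cfg$mode == "2step"
  nets <- list(net1 = build_network(spec, seed = derive_seed(cfg$seed, 1)))
  if (two_step)
    nets$net2 <- build_network(spec, seed = derive_seed(cfg$seed, 2))
  st1 <- adam_init(net_params(nets$net1))
  st2 <- if (two_step) adam_init(net_params(nets$net2)) else NULL
  lr <- cfg$initial_lr
  log <- list()
  val_hist <- numeric(0)
  ps <- cascade_cfg$patch_size
  low <- cascade_cfg$lowres_shape

  prep_pair <- function(pr) {
    v <- pr$volume; m <- pr$mask
    if (cfg$augment) {
      aug <- augment_pair(v, m, cfg$augment_config %||% augment_config())
      v <- aug$volume; m <- aug$mask
    }
    list(v = v, m = m,
         lowimg = if (two_step) downsample(v, low) else NULL,
         lowtgt = if (two_step) make_step1_target(m, low) else NULL)
  }

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(length(pairs))
    ep <- list(dice = 0, bce = 0, total = 0, n = 0)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_lowres))
    for (bt in batches) {
      g1 <- NULL; g2 <- NULL; npatch_batch <- 0L
      batch_losses <- list()
      for (ii in bt) {
        pp <- prep_pair(pairs[[ii]])
        if (two_step) {
          bp <- backprop_pair(nets$net1, pp$lowimg, pp$lowtgt)
          g1 <- grads_add(g1, bp$grads, 1 / length(bt))
          cand <- find_seed_voxels(bp$prob, dim(pp$v$grid),
                                  cascade_cfg$seed_threshold)
          patch_preds <- list(); patch_tgts <- list()
          if (nrow(cand) > 0) {
            locs <- sample_patch_locations(cand, cfg$max_patches_per_image)
            for (t in seq_len(nrow(locs))) {
              pimg <- extract_patch(pp$v, locs[t, ], ps)
              ptgt <- extract_patch(pp$m, locs[t, ], ps)
              bp2 <- backprop_pair(nets$net2, pimg$data, ptgt$data)
              g2 <- grads_add(g2, bp2$grads, 1)
              npatch_batch <- npatch_batch + 1L
              patch_preds[[t]] <- bp2$prob; patch_tgts[[t]] <- ptgt$data
            }
          }
          ls <- cascade_loss(bp$prob, pp$lowtgt, patch_preds, patch_tgts)
        } else {
          bp <- backprop_pair(nets$net1, pp$v$grid, pp$m$grid)
          g1 <- grads_add(g1, bp$grads, 1 / length(bt))
          ls <- bp$loss
        }
        ep$dice <- ep$dice + ls$dice_loss; ep$bce <- ep$bce + ls$bce
        ep$total <- ep$total + ls$total; ep$n <- ep$n + 1
      }
      a1 <- adam_step(net_params(nets$net1), g1, st1, lr)
      nets$net1 <- net_set_params(nets$net1, a1$params); st1 <- a1$state
      if (two_step && npatch_batch > 0) {
        g2 <- grads_scale(g2, 1 / npatch_batch)
        a2 <- adam_step(net_params(nets$net2), g2, st2, lr)
        nets$net2 <- net_set_params(nets$net2, a2$params); st2 <- a2$state
      }
    }
    vloss <- if (!is.null(val_pairs))
      validation_loss(nets, val_pairs, cfg, cascade_cfg)
    else ep$total / ep$n
    val_hist <- c(val_hist, vloss)
    log[[epoch]] <- data.frame(epoch = epoch,
                               train_dice_loss = ep$dice / ep$n,
                               train_bce = ep$bce / ep$n,
                               train_total = ep$total / ep$n,
                               val_total = vloss, lr = lr)
    if (length(val_hist) >= 2)
      lr <- lr_on_plateau(val_hist, lr, cfg$plateau_delta, cfg$plateau_factor)
  }
  structure(list(net1 = nets$net1, net2 = nets$net2, mode = cfg$mode,
                 spec = spec, cascade_cfg = cascade_cfg, train_cfg = cfg,
                 log = do.call(rbind, log)),
            class = "chp_model")
}

validation_loss <- function(nets, val_pairs, cfg, cascade_cfg) {
  two_step <- cfg$mode == "2step"
  tot <- 0
  for (pr in val_pairs) {
    if (two_step) {
      lowimg <- downsample(pr$volume, cascade_cfg$lowres_shape)
      lowtgt <- make_step1_target(pr$mask, cascade_cfg$lowres_shape)
      p1 <- network_forward(nets$net1, lowimg)
      cand <- find_seed_voxels(p1, dim(pr$volume$grid), cascade_cfg$seed_threshold)
      preds <- list(); tgts <- list()
      if (nrow(cand) > 0) {
        locs <- sample_patch_locations(cand, cfg$max_patches_per_image)
        for (t in seq_len(nrow(locs))) {
          pimg <- extract_patch(pr$volume, locs[t, ], cascade_cfg$patch_size)
          tgts[[t]] <- extract_patch(pr$mask, locs[t, ], cascade_cfg$patch_size)$data
          preds[[t]] <- network_forward(nets$net2, pimg$data)
        }
      }
      tot <- tot + cascade_loss(p1, lowtgt, preds, tgts)$total
    } else {
      p <- network_forward(nets$net1, pr$volume$grid)
      tot <- tot + combined_loss(p, pr$mask$grid)$total
    }
  }
  tot / length(val_pairs)
}

#' Predict with a trained model
#'
#' Dispatches to [predict_two_step()] or [predict_one_step()] according to
#' the model's mode.
#'
#' @param object a `chp_model` from [train()].
#' @param v a preprocessed [volume()].
#' @param seed RNG seed for patch subsampling.
#' @param ... unused.
#' @return list with `prob` and `mask`.
#' @export
predict.chp_model <- function(object, v, seed = 1, ...) {
  if (object$mode == "2step")
    predict_two_step(v, object$net1, object$net2, object$cascade_cfg, seed = seed)
  else
    predict_one_step(v, object$net1, object$cascade_cfg)
}

#' Save / load a trained model
#'
#' The parameter collections of both stages are serialized together with the
#' architecture spec and cascade configuration.
#'
#' @param model a `chp_model`.
#' @param dir directory to create/use.
#' @return `dir` (save) or a `chp_model` (load).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "chp_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  json <- list(mode = model$mode,
               spec = unclass(model$spec),
               cascade = unclass(model$cascade_cfg))
  jsonlite::write_json(json, file.path(dir, "model.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stopf("no model found under %s", dir)
  readRDS(path)
}
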