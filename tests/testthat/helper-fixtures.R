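# shared fixtures and independent oracles, built in code at test time

# small phantom pairs, preprocessed on their own grid (phantoms are already
# canonical and isotropic, so only the intensity rescale has an effect)
make_test_pairs <- function(n, shape = c(32, 32, 32), seed = 404) {
  cohort <- generate_cohort(n, phantom_params(shape = shape), seed = seed)
  pcfg <- preprocess_config(target_shape = shape)
  lapply(cohort, function(pr)
    list(volume = preprocess(pr$volume, pcfg)$volume, mask = pr$mask))
}

tiny_spec <- function() network_spec(levels = 2, base_filters = 4, groups = 2)

tiny_cascade <- function() cascade_config(lowres_shape = c(8, 8, 8),
                                          patch_size = 8, max_patches = 50)

# independent trilinear resize oracle (same voxel-center convention as the
# implementation, written as plain R loops)
resize_oracle <- function(x, odim) {
  d <- dim(x)
  out <- array(0, odim)
  for (k in seq_len(odim[3])) for (j in seq_len(odim[2])) for (i in seq_len(odim[1])) {
    cc <- pmin(pmax((c(i, j, k) - 0.5) * d / odim - 0.5, 0), d - 1)
    f0 <- floor(cc); fr <- cc - f0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      idx <- pmin(f0 + c(dx, dy, dz), d - 1) + 1
      acc <- acc + w * x[idx[1], idx[2], idx[3]]
    }
    out[i, j, k] <- acc
  }
  out
}

# set-counting metric oracle on binary masks
oracle_metrics <- function(x, y) {
  tp <- sum(x == 1 & y == 1)
  list(dice = 2 * tp / (sum(x) + sum(y)),
       recall = tp / sum(y),
       precision = tp / sum(x),
       ver = (sum(x) - sum(y)) / sum(y))
}

# ground-truth oracle predictors for the cascade stages
oracle_nets <- function(mask) {
  list(net1 = function(x) make_step1_target(mask, dim(x)),
       net2 = function(x, origin) extract_patch(mask, origin + dim(x)[1] %/% 2L,
                                                dim(x)[1])$data)
}
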