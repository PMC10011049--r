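#' Network architecture specification
#'
#' Describes the modified 3D encoder-decoder ("3D U-Net") used by both
#' cascade stages and the single-stage baseline: convolution blocks of
#' 3x3x3 convolution, group normalization and leaky activation; 2x max
#' pooling between encoder levels; parameter-free nearest-neighbour
#' upsampling in the decoder (replacing learned up-convolutions, which
#' reduces the trainable parameter count); skip connections by channel
#' concatenation; a final 1x1x1 convolution and logistic sigmoid producing a
#' single-channel probability map.
#'
#' @param levels number of resolution levels (>= 2).
#' @param base_filters channels after the first convolution block; doubled at
#'   each deeper level.
#' @param groups group count for group normalization; must divide every
#'   per-block channel count.
#' @param slope negative slope of the leaky activation.
#' @param in_channels input channels (1 for a single MRI contrast).
#' @return A `chp_network_spec` list.
#' @export
network_spec <- function(levels = 4, base_filters = 16, groups = 8,
                         slope = 0.01, in_channels = 1) {
  if (levels < 2) stopf("levels must be >= 2")
  if (base_filters < 1) stopf("base_filters must be >= 1")
  channels <- base_filters * 2^(seq_len(levels) - 1)
  if (any(channels %% groups != 0))
    stopf("group count %d must divide every channel count (%s)",
          groups, paste(channels, collapse = ", "))
  structure(list(levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 groups = as.integer(groups), slope = slope,
                 in_channels = as.integer(in_channels)),
            class = "chp_network_spec")
}

spec_channels <- function(spec) spec$base_filters * 2^(seq_len(spec$levels) - 1)

new_block <- function(cin, cout, k = 3) {
  # He initialization for the leaky-activated convolutions
  sd <- sqrt(2 / (k^3 * cin))
  list(w = array(stats::rnorm(k^3 * cin * cout, sd = sd), c(k, k, k, cin, cout)),
       b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout))
}

#' Build a network with seeded initialization
#'
#' @param spec a [network_spec()].
#' @param seed integer seed controlling parameter initialization; two
#'   networks built from the same spec and seed are identical.
#' @return A `chp_network` object.
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "chp_network_spec"))
  ch <- spec_channels(spec)
  with_seed(seed, {
    enc <- lapply(seq_len(spec$levels), function(l) {
      cin <- if (l == 1) spec$in_channels else ch[l - 1]
      list(b1 = new_block(cin, ch[l]), b2 = new_block(ch[l], ch[l]))
    })
    dec <- lapply(seq_len(spec$levels - 1), function(l) {
      list(b1 = new_block(ch[l + 1] + ch[l], ch[l]), b2 = new_block(ch[l], ch[l]))
    })
    # the output bias starts at the logit of a 1% foreground prior so that a
    # freshly built network predicts "sparse foreground" instead of spending
    # early updates suppressing the overwhelming background class
    fin <- list(w = array(stats::rnorm(ch[1], sd = sqrt(1 / ch[1])), c(1, 1, 1, ch[1], 1)),
                b = stats::qlogis(0.01))
    structure(list(spec = spec, enc = enc, dec = dec, final = fin, seed = seed),
              class = "chp_network")
  })
}

#' Count trainable parameters
#'
#' @param net a [build_network()] result.
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "chp_network"))
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(net[c("enc", "dec", "final")])
  n
}

# Parameter count of the same architecture with learned 2x2x2 transposed
# convolutions in place of nearest-neighbour upsampling (for comparison).
count_parameters_upconv <- function(net) {
  ch <- spec_channels(net$spec)
  extra <- sum(vapply(seq_len(net$spec$levels - 1), function(l)
    8 * ch[l + 1] * ch[l + 1] + ch[l + 1], numeric(1)))
  count_parameters(net) + extra
}

GN_EPS <- 1e-5

gn_fwd <- function(x, gamma, beta, G) {
  d <- dim(x); S <- prod(d[1:3]); C <- d[4]; Cg <- C %/% G
  m2 <- matrix(x, S * Cg, G)
  mu <- colMeans(m2)
  va <- colMeans(m2 * m2) - mu^2
  inv <- 1 / sqrt(va + GN_EPS)
  xhat <- sweep(sweep(m2, 2, mu, "-"), 2, inv, "*")
  y <- sweep(sweep(matrix(xhat, S, C), 2, gamma, "*"), 2, beta, "+")
  dim(y) <- d
  list(out = y, xhat = xhat, inv = inv, d = d)
}

gn_bwd <- function(dy, cache, gamma) {
  d <- cache$d; S <- prod(d[1:3]); C <- d[4]; G <- length(cache$inv); Cg <- C %/% G
  dym <- matrix(dy, S, C)
  xhat_sc <- matrix(cache$xhat, S, C)
  dgamma <- colSums(dym * xhat_sc)
  dbeta <- colSums(dym)
  dxhat <- matrix(sweep(dym, 2, gamma, "*"), S * Cg, G)
  mdx <- colMeans(dxhat)
  mdxx <- colMeans(dxhat * cache$xhat)
  dx <- sweep(sweep(dxhat, 2, mdx, "-") - sweep(cache$xhat, 2, mdxx, "*"),
              2, cache$inv, "*")
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

block_fwd <- function(blk, x, spec, k = 3) {
  cout <- length(blk$b)
  conv <- conv3d_fwd_cpp(x, blk$w, blk$b, dim(x), k, cout)
  gn <- gn_fwd(conv, blk$gamma, blk$beta, spec$groups)
  act <- gn$out
  neg <- act < 0
  act[neg] <- act[neg] * spec$slope
  list(out = act, cache = list(x = x, gn = gn, neg = neg, k = k))
}

block_bwd <- function(blk, cache, dout, spec) {
  dout[cache$neg] <- dout[cache$neg] * spec$slope
  g <- gn_bwd(dout, cache$gn, blk$gamma)
  cv <- conv3d_bwd_cpp(cache$x, blk$w, g$dx, dim(cache$x), cache$k, length(blk$b))
  list(dx = cv$dx,
       grad = list(w = cv$dw, b = as.numeric(cv$db),
                   gamma = g$dgamma, beta = g$dbeta))
}

check_input_shape <- function(spec, d) {
  div <- 2^(spec$levels - 1)
  bad <- which(d[1:3] %% div != 0)
  if (length(bad))
    stopf("input extent on axis %d (%d) is not divisible by %d (levels = %d)",
          bad[1], d[bad[1]], div, spec$levels)
}

#' Forward pass of the network
#'
#' @param net a `chp_network`.
#' @param x 3D array (single channel) or 4D array `(x, y, z, channels)`;
#'   every spatial extent must be divisible by `2^(levels - 1)`.
#' @param want_cache keep intermediate activations for [network_backward()].
#' @return 3D probability array in (0, 1) with the input's spatial shape;
#'   with `want_cache = TRUE`, a list `(prob, cache)`.
#' @export
network_forward <- function(net, x, want_cache = FALSE) {
  stopifnot(inherits(net, "chp_network"))
  spec <- net$spec
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  check_input_shape(spec, dim(x))
  L <- spec$levels
  caches <- list(enc = vector("list", L), pool = vector("list", L - 1),
                 dec = vector("list", L - 1))
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    f1 <- block_fwd(net$enc[[l]]$b1, h, spec)
    f2 <- block_fwd(net$enc[[l]]$b2, f1$out, spec)
    skips[[l]] <- f2$out
    caches$enc[[l]] <- list(c1 = f1$cache, c2 = f2$cache)
    if (l < L) {
      mp <- maxpool3d_fwd_cpp(f2$out, dim(f2$out))
      caches$pool[[l]] <- list(argmax = mp$argmax, indim = dim(f2$out))
      h <- mp$out
    } else h <- f2$out
  }
  for (l in rev(seq_len(L - 1))) {
    up <- upsample2_fwd_cpp(h, dim(h))
    cat_in <- abind4(up, skips[[l]])
    f1 <- block_fwd(net$dec[[l]]$b1, cat_in, spec)
    f2 <- block_fwd(net$dec[[l]]$b2, f1$out, spec)
    caches$dec[[l]] <- list(c1 = f1$cache, c2 = f2$cache,
                            up_ch = dim(up)[4], updim = dim(h))
    h <- f2$out
  }
  z <- conv3d_fwd_cpp(h, net$final$w, net$final$b, dim(h), 1L, 1L)
  p <- 1 / (1 + exp(-z))
  dim(p) <- dim(z)[1:3]
  if (!want_cache) return(p)
  caches$final_in <- h
  caches$prob <- p
  list(prob = p, cache = caches)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' Backward pass: gradients of a loss w.r.t. all parameters
#'
#' @param net a `chp_network`.
#' @param cache the cache from `network_forward(..., want_cache = TRUE)`.
#' @param dprob gradient of the loss w.r.t. the output probabilities
#'   (3D array).
#' @return nested list of gradients mirroring the parameter structure.
#' @export
network_backward <- function(net, cache, dprob) {
  spec <- net$spec
  L <- spec$levels
  p <- cache$prob
  dz <- dprob * p * (1 - p)
  dim(dz) <- c(dim(p), 1L)
  grads <- list(enc = vector("list", L), dec = vector("list", L - 1),
                final = NULL)
  fin <- conv3d_bwd_cpp(cache$final_in, net$final$w, dz,
                        dim(cache$final_in), 1L, 1L)
  grads$final <- list(w = fin$dw, b = as.numeric(fin$db))
  dh <- fin$dx
  for (l in seq_len(L - 1)) {
    cc <- cache$dec[[l]]
    b2 <- block_bwd(net$dec[[l]]$b2, cc$c2, dh, spec)
    b1 <- block_bwd(net$dec[[l]]$b1, cc$c1, b2$dx, spec)
    grads$dec[[l]] <- list(b1 = b1$grad, b2 = b2$grad)
    dcat <- b1$dx
    dup <- dcat[, , , seq_len(cc$up_ch), drop = FALSE]
    dskip <- dcat[, , , cc$up_ch + seq_len(dim(dcat)[4] - cc$up_ch), drop = FALSE]
    ddeep <- upsample2_bwd_cpp(dup, dim(dup))
    cache$dskip[[l]] <- dskip
    dh <- ddeep
  }
  # dh now flows into the bottleneck encoder level; walk the encoder back up
  for (l in rev(seq_len(L))) {
    if (l < L) {
      dpooled <- dh
      dh <- maxpool3d_bwd_cpp(dpooled, cache$pool[[l]]$argmax,
                              cache$pool[[l]]$indim)
      dh <- dh + cache$dskip[[l]]
    }
    ec <- cache$enc[[l]]
    b2 <- block_bwd(net$enc[[l]]$b2, ec$c2, dh, spec)
    b1 <- block_bwd(net$enc[[l]]$b1, ec$c1, b2$dx, spec)
    grads$enc[[l]] <- list(b1 = b1$grad, b2 = b2$grad)
    dh <- b1$dx
  }
  grads
}
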