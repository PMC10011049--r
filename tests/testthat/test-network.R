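test_that("forward pass preserves shape and outputs strict probabilities", {
  net <- build_network(tiny_spec(), seed = 3)
  for (shape in list(c(8, 8, 8), c(8, 12, 16), c(16, 8, 12))) {
    x <- array(rnorm(prod(shape)), shape)
    p <- network_forward(net, x)
    expect_equal(dim(p), shape)
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(network_forward(net, array(0, c(7, 8, 8))), "axis 1")
})

test_that("construction is deterministic under a seed", {
  x <- array(rnorm(8^3), c(8, 8, 8))
  a <- build_network(tiny_spec(), seed = 11)
  b <- build_network(tiny_spec(), seed = 11)
  expect_identical(network_forward(a, x), network_forward(b, x))
  c <- build_network(tiny_spec(), seed = 12)
  expect_false(identical(network_forward(a, x), network_forward(c, x)))
})

test_that("first convolution block yields base_filters channels (16 by default)", {
  spec <- network_spec()
  net <- build_network(spec, seed = 1)
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  blk <- chpseg:::block_fwd(net$enc[[1]]$b1, x, spec)
  expect_equal(dim(blk$out)[4], 16L)
})

test_that("parameter counts behave as the architecture dictates", {
  net <- build_network(tiny_spec(), seed = 1)
  n <- count_parameters(net)
  expect_gt(n, 0)
  # the parameter-free upsampling decoder is strictly smaller than the same
  # spec with learned up-convolutions
  expect_lt(n, chpseg:::count_parameters_upconv(net))
  # doubling base_filters increases the count
  big <- build_network(network_spec(levels = 2, base_filters = 8, groups = 2), seed = 1)
  expect_gt(count_parameters(big), n)
  # the count does not depend on input shape
  invisible(network_forward(net, array(0, c(8, 8, 8))))
  expect_identical(count_parameters(net), n)
})

test_that("analytic gradients match finite differences", {
  set.seed(21)
  net <- build_network(tiny_spec(), seed = 5)
  x <- array(rnorm(8^3), c(8, 8, 8))
  y <- array(0, c(8, 8, 8)); y[3:5, 2:4, 6:8] <- 1
  bp <- chpseg:::backprop_pair(net, x, y)
  f <- function(n) chpseg:::combined_loss_grad(network_forward(n, x), y)$loss$total
  eps <- 1e-6
  probes <- list(list("enc", 1L, "b1", "w", 5L), list("enc", 2L, "b2", "gamma", 1L),
                 list("dec", 1L, "b1", "w", 11L), list("enc", 1L, "b2", "beta", 3L),
                 list("final", "w", 2L), list("dec", 1L, "b2", "b", 2L))
  for (probe in probes) {
    path <- probe[-length(probe)]; k <- probe[[length(probe)]]
    pluck <- function(lst) { for (pp in path) lst <- lst[[pp]]; lst }
    poke <- function(lst, p) {
      if (length(p) == 1) { lst[[p[[1]]]][k] <- lst[[p[[1]]]][k] + eps; lst }
      else { lst[[p[[1]]]] <- poke(lst[[p[[1]]]], p[-1]); lst }
    }
    num <- (f(poke(net, path)) - f(net)) / eps
    expect_equal(pluck(bp$grads)[k], num, tolerance = 1e-3)
  }
})
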