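# Backbone architecture contracts: shapes, normalization, determinism,
# the multi-scale convolution module, and backprop correctness.

test_that("forward emits S+1 normalized full-resolution maps", {
  net <- tiny_net()
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  pr <- forward(net, img)
  expect_named(pr$maps, c("p0", "p1", "p2", "p3", "p4"))
  for (m in pr$maps) {
    expect_equal(dim(m), c(2, 64, 64))
    expect_true(all(m >= 0 & m <= 1))
    expect_true(max(abs(apply(m, c(2, 3), sum) - 1)) < 1e-5)
  }
  # without the MSC module there is no fused fine map
  pr2 <- forward(tiny_net(use_msc = FALSE), img)
  expect_named(pr2$maps, c("p1", "p2", "p3", "p4"))
})

test_that("evaluation mode is deterministic; train-mode dropout is not", {
  net <- tiny_net(dropout_rate = 0.3)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  a <- forward(net, img)
  b <- forward(net, img)
  expect_lt(max(abs(a$maps$p0 - b$maps$p0)), 1e-7)
  # distinct dropout streams give distinct train-mode outputs
  ta <- forward(net, img, train_mode = TRUE, seed = 1)
  tb <- forward(net, img, train_mode = TRUE, seed = 2)
  expect_gt(max(abs(ta$maps$p4 - tb$maps$p4)), 0)
  # same stream reproduces exactly
  tc <- forward(net, img, train_mode = TRUE, seed = 1)
  expect_identical(ta$maps$p4, tc$maps$p4)
})

test_that("indivisible input sizes are rejected with the divisor named", {
  net <- tiny_net()
  img <- array(runif(60 * 60 * 3), dim = c(60, 60, 3))
  expect_error(forward(net, img), "16")
})

test_that("msc module preserves spatial size and channel bookkeeping", {
  set.seed(31)
  x <- array(rnorm(32 * 32 * 6), dim = c(32, 32, 6))
  mod <- msc_module(in_width = 6, out_width = 8, kernels = c(1, 2, 3, 5))
  y <- msc_forward(x, mod)
  expect_equal(dim(y), c(32, 32, 8))
  # concatenation width before the fusing convolution = 4 branches x 6
  expect_equal(ncol(mod$w), 4 * 6 * 9)
  # window 1 pooling is the identity: the module reduces to a 3x3 convolution
  mod1 <- msc_module(in_width = 6, out_width = 8, kernels = 1)
  y1 <- msc_forward(x, mod1)
  direct <- dcseg:::cpp_conv2d_3x3(x, mod1$w, mod1$b)
  expect_equal(y1, direct, tolerance = 1e-12)
  # input smaller than the largest window is rejected
  small <- array(rnorm(4 * 4 * 6), dim = c(4, 4, 6))
  expect_error(msc_forward(small, mod), "kernel")
})

test_that("fine head recomposed from primitives matches the engine's p0", {
  net <- tiny_net()
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  pr <- forward(net, img, want_features = TRUE)
  p0 <- fine_head(pr$features, net)
  expect_equal(dim(p0), c(2, 64, 64))
  expect_equal(p0, pr$maps$p0, tolerance = 1e-8)
  expect_true(max(abs(apply(p0, c(2, 3), sum) - 1)) < 1e-5)
})

test_that("parameter count scales quadratically with width", {
  n1 <- n_parameters(tiny_net(base_width = 8))
  n2 <- n_parameters(tiny_net(base_width = 16))
  expect_gt(n2 / n1, 3)
  expect_lt(n2 / n1, 5)
})

test_that("engine gradients match central finite differences", {
  net <- tiny_net(base_width = 4, kernels = c(1, 2, 3))
  h <- 16; w <- 16; n <- 3; nl <- 2
  set.seed(33)
  x <- array(runif(h * w * 3 * n), dim = c(h, w, 3, n))
  y <- array(sample(0:1, h * w * nl, replace = TRUE), dim = c(h, w, nl))
  ecfg <- dcseg:::engine_cfg(net, h, w, n, n_labeled = nl, lambda = 0,
                             train_mode = TRUE, want_grads = TRUE)
  res <- dcseg:::cpp_net_run(net$params, x, as.integer(y), ecfg, "double")
  loss_at <- function(params) {
    dcseg:::cpp_net_run(params, x, as.integer(y), ecfg, "double")$l_sup
  }
  eps <- 1e-5
  for (nm in names(res$grads)) {
    for (i in sample(length(net$params[[nm]]), min(2, length(net$params[[nm]])))) {
      pp <- net$params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- loss_at(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- loss_at(pp)
      fd <- (lp - lm) / (2 * eps)
      expect_equal(res$grads[[nm]][i], fd, tolerance = 5e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip the network with its config", {
  net <- tiny_net()
  dir <- tempfile()
  path <- save_checkpoint(net, dir, epoch = 3)
  expect_match(basename(path), "net_epoch003_seed7.rds")
  back <- load_checkpoint(path)
  expect_equal(back$params, net$params)
  expect_equal(back$config, net$config)
})
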