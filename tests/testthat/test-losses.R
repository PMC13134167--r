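# Loss terms: closed-form values, reductions, and loop-oracle equivalence.

test_that("warm-up schedule matches its closed form and is monotone", {
  sched <- schedule_config(total_iters = 1000, k = 0.1)
  expect_identical(lambda_schedule(1000, sched), 0.1)
  expect_equal(lambda_schedule(0, sched), 0.1 * exp(-5))
  expect_equal(lambda_schedule(500, sched), 0.1 * exp(-1.25))
  ts <- seq(0, 1000, length.out = 101)
  expect_true(all(diff(lambda_schedule(ts, sched)) >= 0))
  # beyond T the ramp stays clamped at its ceiling
  expect_identical(lambda_schedule(2000, sched), 0.1)
  expect_error(lambda_schedule(-1, sched))
})

test_that("average prediction is the level mean and stays normalized", {
  set.seed(11)
  maps <- rand_level_maps(3, 2, 4, 4)
  pavg <- average_prediction(maps)
  expect_equal(pavg, (maps[[1]] + maps[[2]] + maps[[3]]) / 3)
  expect_equal(apply(pavg, c(2, 3), sum),
               matrix(1, 4, 4), tolerance = 1e-9)
  # identical levels average to themselves
  expect_equal(average_prediction(list(maps[[1]], maps[[1]])), maps[[1]])
  # two opposite one-hot pixels average to (0.5, 0.5)
  a <- array(c(1, 0), dim = c(2, 1, 1))
  b <- array(c(0, 1), dim = c(2, 1, 1))
  expect_equal(as.vector(average_prediction(list(a, b))), c(0.5, 0.5))
})

test_that("hierarchical consistency is zero at agreement and level-symmetric", {
  set.seed(12)
  maps <- rand_level_maps(4, 3, 6, 6)
  expect_identical(hierarchical_consistency(rep(maps[1], 4)), 0)
  v <- hierarchical_consistency(maps)
  expect_gt(v, 0)
  expect_equal(hierarchical_consistency(rev(maps)), v)
})

test_that("uncertainty map is the per-pixel KL with exponential weights", {
  set.seed(13)
  maps <- rand_level_maps(2, 2, 4, 4)
  um_same <- uncertainty_map(list(maps[[1]], maps[[1]]))
  expect_equal(um_same$d[[1]], matrix(0, 4, 4), tolerance = 1e-12)
  expect_equal(um_same$w[[1]], matrix(1, 4, 4), tolerance = 1e-12)
  um <- uncertainty_map(maps)
  for (s in 1:2) {
    expect_true(all(um$d[[s]] >= 0))          # Gibbs' inequality
    expect_true(all(um$w[[s]] > 0 & um$w[[s]] <= 1))
    expect_equal(um$w[[s]], exp(-um$d[[s]]))
  }
  # hand-computed KL at a single pixel
  ps <- array(c(0.9, 0.1), dim = c(2, 1, 1))
  pa <- array(c(0.5, 0.5), dim = c(2, 1, 1))
  d <- uncertainty_map(list(ps, ps), p_avg = pa)$d[[1]][1, 1]
  expect_equal(d, 0.9 * log(1.8) + 0.1 * log(0.2), tolerance = 1e-10)
  expect_equal(d, 0.3681, tolerance = 1e-4)
})

test_that("rectified consistency reduces to plain consistency at unit weights", {
  set.seed(14)
  for (rep in 1:10) {
    s <- sample(2:4, 1)
    maps <- rand_level_maps(s, sample(2:3, 1), 5, 5)
    ones <- lapply(seq_len(s), function(i) matrix(0, 5, 5))
    umap1 <- list(d = ones, w = lapply(ones, function(m) m + 1))
    expect_equal(rectified_consistency(maps, umap = umap1),
                 hierarchical_consistency(maps), tolerance = 1e-12)
  }
})

test_that("down-weighting a disagreeing pixel lowers its contribution", {
  set.seed(15)
  maps <- rand_level_maps(2, 2, 4, 4)
  um <- uncertainty_map(maps)
  v0 <- rectified_consistency(maps, umap = um)
  # raise the uncertainty of the most discrepant pixel of level 1
  pavg <- average_prediction(maps)
  m <- apply((maps[[1]] - pavg)^2, c(2, 3), sum)
  idx <- which(m == max(m), arr.ind = TRUE)[1, ]
  um$d[[1]][idx[1], idx[2]] <- um$d[[1]][idx[1], idx[2]] + 3
  um$w[[1]] <- exp(-um$d[[1]])
  expect_lt(rectified_consistency(maps, umap = um), v0)
})

test_that("coarse-fine consistency: zero at equality, symmetric, worked pixel", {
  set.seed(16)
  p0 <- rand_prob_map(2, 3, 3)
  expect_identical(cfgc_loss(p0, p0), 0)
  p1 <- rand_prob_map(2, 3, 3)
  expect_equal(cfgc_loss(p0, p1), cfgc_loss(p1, p0))
  # one differing pixel (1,0) vs (0,1) in a 2x2 map: channel-summed squared
  # difference 2 at that pixel, averaged over 4 pixels
  a <- array(0, dim = c(2, 2, 2)); a[1, , ] <- 1
  b <- a; b[, 1, 1] <- c(0, 1)
  expect_equal(cfgc_loss(a, b), 2 / 4)
  expect_error(cfgc_loss(p0, rand_prob_map(2, 4, 4)), "shape")
})

test_that("supervised loss: perfect prediction, uniform closed form, linearity", {
  mask <- matrix(sample(0:1, 16, replace = TRUE), 4, 4)
  onehot <- one_hot(mask, 2)
  maps <- rep(list(onehot), 5)
  expect_lt(supervised_loss(maps, mask), 1e-6)
  # uniform prediction over K = 2: CE = ln 2 per level; with S + 1 = 5
  # levels and unit alpha the CE contribution is 5 * 0.5 * ln 2
  unif <- array(0.5, dim = c(2, 4, 4))
  umaps <- rep(list(unif), 5)
  got <- supervised_loss(umaps, mask)
  dice_part <- oracle_sup(umaps, mask) - 5 * 0.5 * log(2)
  expect_equal(got - dice_part, 5 * 0.5 * log(2), tolerance = 1e-9)
  # doubling alpha doubles the loss
  set.seed(17)
  rmaps <- rand_level_maps(3, 2, 4, 4)
  expect_equal(supervised_loss(rmaps, mask, alpha = 2),
               2 * supervised_loss(rmaps, mask), tolerance = 1e-12)
  expect_error(supervised_loss(rmaps, mask + 5L), "classes")
})

test_that("vectorized losses match the per-pixel loop oracles", {
  set.seed(18)
  for (rep in 1:12) {
    s <- sample(2:4, 1); k <- sample(2:3, 1)
    maps <- rand_level_maps(s, k, 8, 8)
    expect_equal(hierarchical_consistency(maps), oracle_hc(maps),
                 tolerance = 1e-6)
    expect_equal(rectified_consistency(maps), oracle_urc(maps),
                 tolerance = 1e-6)
    expect_equal(cfgc_loss(maps[[1]], maps[[2]]),
                 oracle_cfgc(maps[[1]], maps[[2]]), tolerance = 1e-6)
    mask <- matrix(sample(0:(k - 1), 64, replace = TRUE), 8, 8)
    expect_equal(supervised_loss(maps, mask), oracle_sup(maps, mask),
                 tolerance = 1e-6)
  }
})

test_that("total loss satisfies the bundle identities", {
  sched <- schedule_config(total_iters = 100, k = 0.1, beta = 0.5)
  b <- total_loss(1.5, 0.2, 0.4, t = 100, schedule = sched)
  expect_equal(b$l_unsup, 0.5 * 0.2 + 0.5 * 0.4, tolerance = 1e-12)
  expect_equal(b$l_total, b$l_sup + b$lam * b$l_unsup, tolerance = 1e-12)
  expect_identical(b$lam, 0.1)
  # beta = 0.5 with equal components collapses to either
  b2 <- total_loss(0, 0.3, 0.3, t = 50, schedule = sched)
  expect_equal(b2$l_unsup, 0.3)
  # beta = 1 keeps the rectified term only (HC-only ablation)
  sched1 <- schedule_config(total_iters = 100, k = 0.1, beta = 1)
  b3 <- total_loss(0, 0.3, 0.9, t = 50, schedule = sched1)
  expect_equal(b3$l_unsup, 0.3)
  # early training: lambda(0) = k * exp(-5)
  b4 <- total_loss(1, 1, 1, t = 0, schedule = sched)
  expect_equal(b4$l_total, 1 + 0.1 * exp(-5), tolerance = 1e-12)
})
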