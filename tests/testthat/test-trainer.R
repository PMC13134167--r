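# Two-stream batching, training-step semantics, and the fit loop.

make_ds <- function(n = 30, frac = 0.2, h = 32) {
  spec <- patch_spec(height = h, width = h, seed = 60,
                     blob_radius_range = c(4, 8))
  make_ssl_split(generate_patches(spec, n), frac, seed = 3)
}

test_that("two-stream batches respect the 4:1 unlabeled:labeled ratio", {
  ds <- make_ds(50, 0.2)
  cfg <- train_config(seed = 1)
  batches <- make_batches(ds, cfg)
  expect_length(batches[[1]]$labeled, 4)
  expect_length(batches[[1]]$unlabeled, 16)
  cfg5 <- train_config(batch_size = 5L, seed = 1)
  b5 <- make_batches(ds, cfg5)
  expect_length(b5[[1]]$labeled, 1)
  expect_length(b5[[1]]$unlabeled, 4)
  expect_error(train_config(batch_size = 7L))
})

test_that("the smaller pool cycles evenly over an epoch", {
  ds <- make_ds(50, 0.2)   # 10 labeled, 40 unlabeled
  cfg <- train_config(seed = 2)
  batches <- make_batches(ds, cfg)
  lab <- unlist(lapply(batches, `[[`, "labeled"))
  counts <- table(factor(lab, levels = seq_len(ds$n_l)))
  expected <- length(batches) * 4 / ds$n_l
  expect_true(all(counts %in% c(floor(expected), ceiling(expected))))
  # unlabeled pool is fully covered
  expect_setequal(unlist(lapply(batches, `[[`, "unlabeled")), seq_len(ds$n_u))
})

test_that("supervised-only control draws labeled-only batches", {
  ds <- make_ds(30, 0.5)
  cfg <- train_config(seed = 1, use_hc = FALSE, use_cfgc = FALSE,
                      use_msc = FALSE)
  batches <- make_batches(ds, cfg)
  expect_length(batches[[1]]$labeled, 20)
  expect_length(batches[[1]]$unlabeled, 0)
  empty <- structure(list(labeled_items = list(), unlabeled_items = list(),
                          n_l = 0, n_u = 0), class = "patch_dataset")
  expect_error(make_batches(empty, cfg), "empty labeled pool")
})

test_that("train step bundle satisfies the loss identities", {
  ds <- make_ds(30, 0.2)
  cfg <- train_config(seed = 4, base_width = 4L, growth = 1L)
  b <- make_batches(ds, cfg)[[1]]
  stp <- train_step(tiny_net(base_width = 4), ds, b, NULL, t = 5,
                    total_iters = 100, cfg = cfg, precision = "double")
  bu <- stp$bundle
  sched <- schedule_config(100, k = cfg$k, beta = cfg$beta)
  expect_equal(bu$lam, lambda_schedule(5, sched))
  expect_equal(bu$l_unsup, cfg$beta * bu$l_urc + (1 - cfg$beta) * bu$l_cr,
               tolerance = 1e-9)
  expect_equal(bu$l_total, bu$l_sup + bu$lam * bu$l_unsup, tolerance = 1e-9)
  expect_true(all(c(bu$l_sup, bu$l_hc, bu$l_urc, bu$l_cr) >= 0))
})

test_that("engine loss components agree with the R loss functions", {
  ds <- make_ds(30, 0.2)
  cfg <- train_config(seed = 4, base_width = 4L, growth = 1L,
                      dropout_rate = 0)
  b <- make_batches(ds, cfg)[[1]]
  stp <- train_step(tiny_net(base_width = 4, dropout_rate = 0), ds, b, NULL,
                    t = 5, total_iters = 100, cfg = cfg,
                    want_preds = TRUE, precision = "double")
  nl <- stp$n_labeled
  nu <- dim(stp$preds$p1)[4] - nl
  per_image <- function(fn) {
    mean(vapply(nl + seq_len(nu), function(n) {
      fn(lapply(1:4, function(s) stp$preds[[paste0("p", s)]][, , , n]))
    }, numeric(1)))
  }
  expect_equal(stp$bundle$l_hc, per_image(hierarchical_consistency),
               tolerance = 1e-9)
  expect_equal(stp$bundle$l_urc, per_image(rectified_consistency),
               tolerance = 1e-9)
  l_cr <- mean(vapply(nl + seq_len(nu), function(n) {
    cfgc_loss(stp$preds$p0[, , , n], stp$preds$p1[, , , n])
  }, numeric(1)))
  expect_equal(stp$bundle$l_cr, l_cr, tolerance = 1e-9)
})

test_that("ablation flags all off reduce the step to the supervised loss", {
  ds <- make_ds(30, 0.5)
  cfg <- train_config(seed = 5, base_width = 4L, growth = 1L,
                      use_hc = FALSE, use_cfgc = FALSE, use_msc = FALSE)
  b <- make_batches(ds, cfg)[[1]]
  stp <- train_step(tiny_net(base_width = 4, use_msc = FALSE), ds, b, NULL,
                    t = 1, total_iters = 10, cfg = cfg, precision = "double")
  expect_equal(stp$bundle$l_urc, 0)
  expect_equal(stp$bundle$l_cr, 0)
  expect_equal(stp$bundle$l_total, stp$bundle$l_sup, tolerance = 1e-12)
})

test_that("fit writes a consistent history and is seed-reproducible", {
  ds <- make_ds(40, 0.25)
  cfg <- train_config(seed = 8, base_width = 4L, growth = 1L)
  test_items <- generate_patches(
    patch_spec(height = 32, width = 32, seed = 777,
               blob_radius_range = c(4, 8)), 4)
  hist_file <- tempfile(fileext = ".csv")
  r1 <- fit(ds, cfg, iters = 6, test_items = test_items,
            history_file = hist_file)
  expect_equal(nrow(r1$history), 6)
  expect_named(r1$history, c("iter", "epoch", "l_sup", "l_hc", "l_urc",
                             "l_cr", "l_unsup", "l_total", "lambda"))
  # lambda column reproduces the schedule exactly
  sched <- schedule_config(6, k = cfg$k)
  expect_equal(r1$history$lambda, lambda_schedule(1:6, sched))
  # bundle identities hold at every logged step
  expect_equal(r1$history$l_unsup,
               cfg$beta * r1$history$l_urc + (1 - cfg$beta) * r1$history$l_cr,
               tolerance = 1e-6)
  expect_equal(r1$history$l_total,
               r1$history$l_sup + r1$history$lambda * r1$history$l_unsup,
               tolerance = 1e-6)
  expect_true(file.exists(hist_file))
  expect_true(all(c("dsc", "iou") %in% colnames(r1$metrics)))
  # identical seed reproduces the history bit for bit
  r2 <- fit(ds, cfg, iters = 6)
  expect_identical(r1$history, r2$history)
  # a different seed changes the trajectory
  r3 <- fit(ds, train_config(seed = 9, base_width = 4L, growth = 1L),
            iters = 6)
  expect_false(identical(r1$history$l_total, r3$history$l_total))
})

test_that("predict_mask returns a valid label map", {
  ds <- make_ds(20, 0.5)
  net <- tiny_net(base_width = 4)
  m <- predict_mask(net, ds$labeled_items[[1]]$image)
  expect_equal(dim(m), c(32, 32))
  expect_true(all(m %in% 0:1))
})

test_that("training configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("batch_size: 10", "unlabeled_per_labeled: 4",
               "learning_rate: 0.02", "seed: 12", "use_cfgc: false"), path)
  cfg <- train_config_from_yaml(path)
  expect_equal(cfg$batch_size, 10L)
  expect_equal(cfg$learning_rate, 0.02)
  expect_false(cfg$use_cfgc)
  expect_true(cfg$use_hc)
})
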