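# Seeded semi-supervised training loop: two-stream batches (4 unlabeled per
# labeled item by default), SGD with momentum and weight decay, the Gaussian
# warm-up of the unsupervised weight, and a supervised-only control arm.

#' Training configuration
#'
#' Defaults follow the reference setting: SGD momentum 0.9, weight decay
#' 1e-4, batch size 20 with a 4:1 unlabeled:labeled ratio, warm-up ceiling
#' `k = 0.1`, consistency mix `beta = 0.5`, per-level supervision weights
#' all 1. The learning rate is constant (no decay).
#'
#' @param epochs number of passes over the unlabeled pool (ignored when
#'   `fit()` is driven by an explicit iteration count).
#' @param batch_size total items per batch; must be divisible by
#'   `1 + unlabeled_per_labeled`.
#' @param unlabeled_per_labeled unlabeled:labeled ratio within a batch.
#' @param learning_rate SGD step size.
#' @param momentum,weight_decay SGD hyperparameters.
#' @param k,beta,alpha schedule parameters, see [schedule_config()].
#' @param seed run seed; data order, weight initialization and dropout
#'   streams are derived from it at fixed offsets.
#' @param use_hc,use_cfgc,use_msc ablation flags: uncertainty-rectified
#'   hierarchical consistency, coarse-fine consistency, multi-scale module.
#'   All off gives the plain deeply-supervised control.
#' @param head_levels number of prediction levels `S`.
#' @param consistency_on_labeled extend the consistency losses to the whole
#'   batch instead of the unlabeled part only.
#' @param detach_p0 gradient-block the fine prediction in the coarse-fine
#'   term (pseudo-label reading); `FALSE` gives the symmetric variant.
#' @param augment_flips random horizontal/vertical flips (off by default;
#'   the method's perturbation is architectural).
#' @param base_width,growth,dropout_rate,msc_kernels backbone settings
#'   forwarded to [network_config()].
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 10L, batch_size = 20L,
                         unlabeled_per_labeled = 4L, learning_rate = 0.01,
                         momentum = 0.9, weight_decay = 1e-4,
                         k = 0.1, beta = 0.5, alpha = 1.0, seed = 1L,
                         use_hc = TRUE, use_cfgc = TRUE, use_msc = TRUE,
                         head_levels = 4L, consistency_on_labeled = FALSE,
                         detach_p0 = TRUE, augment_flips = FALSE,
                         base_width = 16L, growth = 2L, dropout_rate = 0.3,
                         msc_kernels = c(1L, 2L, 3L, 5L)) {
  stopifnot(batch_size %% (1L + unlabeled_per_labeled) == 0,
            learning_rate > 0, momentum >= 0, weight_decay >= 0)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         unlabeled_per_labeled = as.integer(unlabeled_per_labeled),
         learning_rate = learning_rate, momentum = momentum,
         weight_decay = weight_decay, k = k, beta = beta, alpha = alpha,
         seed = as.integer(seed), use_hc = isTRUE(use_hc),
         use_cfgc = isTRUE(use_cfgc), use_msc = isTRUE(use_msc),
         head_levels = as.integer(head_levels),
         consistency_on_labeled = isTRUE(consistency_on_labeled),
         detach_p0 = isTRUE(detach_p0),
         augment_flips = isTRUE(augment_flips),
         base_width = as.integer(base_width), growth = as.integer(growth),
         dropout_rate = dropout_rate,
         msc_kernels = as.integer(msc_kernels)),
    class = "train_config")
}

#' Read a training configuration from a YAML file
#'
#' The file mirrors [train_config()] field for field; absent fields keep
#' their defaults.
#'
#' @param path YAML file.
#' @return a `train_config`.
#' @export
train_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(train_config, vals)
}

# TRUE when the run is the supervised-only control (no consistency terms)
is_supervised_only <- function(cfg) {
  !cfg$use_hc && !cfg$use_cfgc
}

#' Two-stream batch index stream for one epoch
#'
#' Semi-supervised batches carry `batch_size / (1 + r)` labeled and
#' `batch_size * r / (1 + r)` unlabeled items (`r` = unlabeled:labeled
#' ratio). Both pools are reshuffled each epoch from the run seed; the
#' smaller pool cycles. The supervised-only control draws full batches from
#' the labeled pool alone.
#'
#' @param ds a `patch_dataset`.
#' @param cfg a `train_config`.
#' @param epoch 1-based epoch number (drives the reshuffle).
#' @return list of batches, each `list(labeled = idx, unlabeled = idx)`.
#' @export
make_batches <- function(ds, cfg, epoch = 1L) {
  if (ds$n_l == 0) stop("empty labeled pool")
  n_lab_per <- cfg$batch_size %/% (1L + cfg$unlabeled_per_labeled)
  n_unl_per <- cfg$batch_size - n_lab_per
  withr::with_seed(cfg$seed + 7919L * as.integer(epoch), {
    if (is_supervised_only(cfg) || ds$n_u == 0) {
      ord <- sample.int(ds$n_l)
      n_batches <- ceiling(ds$n_l / cfg$batch_size)
      lab <- rep_len(ord, n_batches * cfg$batch_size)
      return(lapply(seq_len(n_batches), function(b) {
        list(labeled = lab[(b - 1L) * cfg$batch_size + seq_len(cfg$batch_size)],
             unlabeled = integer(0))
      }))
    }
    ord_u <- sample.int(ds$n_u)
    ord_l <- sample.int(ds$n_l)
    n_batches <- ceiling(ds$n_u / n_unl_per)
    unl <- rep_len(ord_u, n_batches * n_unl_per)
    lab <- rep_len(ord_l, n_batches * n_lab_per)
    lapply(seq_len(n_batches), function(b) {
      list(labeled = lab[(b - 1L) * n_lab_per + seq_len(n_lab_per)],
           unlabeled = unl[(b - 1L) * n_unl_per + seq_len(n_unl_per)])
    })
  })
}

flip_image <- function(a, fh, fv) {
  if (fh) a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  if (fv) a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  a
}

# assemble (H, W, 3, N) image batch and (H, W, Nl) mask batch
assemble_batch <- function(ds, batch, cfg, t) {
  lab <- ds$labeled_items[batch$labeled]
  unl <- ds$unlabeled_items[batch$unlabeled]
  items <- c(lapply(lab, `[[`, "image"), lapply(unl, `[[`, "image"))
  masks <- lapply(lab, `[[`, "mask")
  if (cfg$augment_flips) {
    flips <- withr::with_seed(cfg$seed + 15485863L + t, {
      matrix(runif(2 * length(items)) < 0.5, ncol = 2)
    })
    for (i in seq_along(items)) {
      items[[i]] <- flip_image(items[[i]], flips[i, 1], flips[i, 2])
      if (i <= length(masks)) {
        m <- array(masks[[i]], c(dim(masks[[i]]), 1L))
        m <- flip_image(m, flips[i, 1], flips[i, 2])
        masks[[i]] <- array(m, dim(m)[1:2])
      }
    }
  }
  x <- simplify2array(items)
  y <- array(as.integer(unlist(masks)),
             dim = c(dim(x)[1], dim(x)[2], length(masks)))
  list(x = x, y = y, n_labeled = length(lab))
}

new_opt_state <- function(params) {
  lapply(params, function(p) array(0, dim = if (is.matrix(p)) dim(p) else
    length(p)))
}

sgd_update <- function(params, velocity, grads, cfg) {
  for (nm in names(grads)) {
    g <- grads[[nm]] + cfg$weight_decay * params[[nm]]
    v <- cfg$momentum * velocity[[nm]] + g
    velocity[[nm]] <- v
    params[[nm]] <- params[[nm]] - cfg$learning_rate * v
  }
  list(params = params, velocity = velocity)
}

#' One semi-supervised training step
#'
#' Runs a forward pass on the assembled two-stream batch, computes the
#' supervised loss on the labeled part and the consistency losses on the
#' unlabeled part, applies one SGD update with momentum and weight decay,
#' and returns the loss bundle for logging. Aborts with a diagnostic when
#' any loss term becomes non-finite.
#'
#' @param net a `seg_network`.
#' @param ds the training `patch_dataset`.
#' @param batch one element of [make_batches()].
#' @param state optimizer state (`NULL` to initialize).
#' @param t current iteration (1-based).
#' @param total_iters ramp horizon `T`.
#' @param cfg a `train_config`.
#' @param want_preds also return the per-level probability maps of the
#'   batch (used by consistency cross-checks).
#' @param precision `"float"` (training default) or `"double"`.
#' @return list with updated `net`, `state`, the `bundle`, and optionally
#'   `preds` / `n_labeled`.
#' @export
train_step <- function(net, ds, batch, state, t, total_iters, cfg,
                       want_preds = FALSE, precision = "float") {
  if (is.null(state)) state <- new_opt_state(net$params)
  dat <- assemble_batch(ds, batch, cfg, t)
  d <- dim(dat$x)
  sched <- schedule_config(total_iters, k = cfg$k, beta = cfg$beta,
                           alpha = cfg$alpha)
  lam <- lambda_schedule(t, sched)
  ecfg <- engine_cfg(net, d[1], d[2], d[4], n_labeled = dat$n_labeled,
                     lambda = lam, beta = cfg$beta,
                     alpha = rep_len(cfg$alpha, cfg$head_levels + 1),
                     use_hc = cfg$use_hc, use_cfgc = cfg$use_cfgc,
                     cons_all = cfg$consistency_on_labeled,
                     detach_p0 = cfg$detach_p0, train_mode = TRUE,
                     seed = cfg$seed + 104729 + t,
                     want_preds = want_preds, want_grads = TRUE)
  res <- cpp_net_run(net$params, dat$x, dat$y, ecfg, precision)
  terms <- c(l_sup = res$l_sup, l_urc = res$l_urc, l_cr = res$l_cr)
  if (any(!is.finite(terms))) {
    stop("non-finite loss at iteration ", t, ": ",
         paste(names(terms), signif(terms, 4), sep = "=", collapse = ", "))
  }
  bundle <- total_loss(res$l_sup, res$l_urc, res$l_cr, t, sched,
                       l_hc = res$l_hc)
  upd <- sgd_update(net$params, state, res$grads, cfg)
  net$params <- upd$params
  out <- list(net = net, state = upd$velocity, bundle = bundle)
  if (want_preds) {
    out$preds <- res$preds
    out$n_labeled <- dat$n_labeled
  }
  out
}

#' Predict a label mask for one image
#'
#' Uses the fused fine prediction `p_0` when the MSC module is active,
#' otherwise the full-resolution level `p_S`; returns the per-pixel argmax.
#'
#' @param net a `seg_network`.
#' @param image `H x W x 3` array.
#' @return `(H, W)` integer mask of 0-based classes.
#' @export
predict_mask <- function(net, image) {
  pr <- forward(net, image)
  p <- if (net$config$use_msc) pr$maps$p0 else
    pr$maps[[length(pr$maps)]]
  m <- apply(p, c(2, 3), which.max) - 1L
  storage.mode(m) <- "integer"
  m
}

#' Mean held-out metrics of a model over labeled items
#'
#' @param net a `seg_network`.
#' @param items list of `list(image, mask)` items.
#' @return named numeric of macro metrics averaged over items.
#' @export
evaluate_model <- function(net, items) {
  k <- net$config$n_classes
  mats <- vapply(items, function(it) {
    evaluate_segmentation(predict_mask(net, it$image), it$mask, k)$macro
  }, numeric(5))
  rowMeans(mats)
}

#' Fit the dual-consistency model
#'
#' Trains for `iters` optimizer steps (or `cfg$epochs` passes over the
#' unlabeled pool when `iters` is `NULL`). All randomness is derived from
#' `cfg$seed`. Writes a per-iteration history (and per-epoch held-out
#' metrics when `test_items` is given), optionally as CSV, and optional
#' per-epoch checkpoints from which a run can be resumed.
#'
#' @param ds training `patch_dataset`.
#' @param cfg a `train_config`.
#' @param net optional pre-initialized network (e.g. from a checkpoint);
#'   built from `cfg` when `NULL`.
#' @param iters explicit total iteration count `T`; overrides epochs.
#' @param test_items optional held-out labeled items evaluated per epoch.
#' @param history_file optional CSV path for the history.
#' @param checkpoint_dir optional directory for per-epoch checkpoints.
#' @param start_iter first iteration number (resume support).
#' @param n_classes number of classes (needed when `ds` lacks masks info).
#' @return list with `net`, `history` (data.frame: iter, epoch, l_sup,
#'   l_hc, l_urc, l_cr, l_unsup, l_total, lambda), and `metrics`
#'   (per-epoch held-out macro metrics, when evaluated).
#' @export
fit <- function(ds, cfg, net = NULL, iters = NULL, test_items = NULL,
                history_file = NULL, checkpoint_dir = NULL,
                start_iter = 1L, n_classes = NULL) {
  stopifnot(inherits(ds, "patch_dataset"), inherits(cfg, "train_config"))
  if (is.null(n_classes)) {
    n_classes <- max(vapply(ds$labeled_items, function(it) max(it$mask),
                            integer(1))) + 1L
    n_classes <- max(n_classes, 2L)
  }
  if (is.null(net)) {
    ncfg <- network_config(
      n_classes = n_classes, base_width = cfg$base_width,
      growth = cfg$growth, dropout_rate = cfg$dropout_rate,
      head_levels = cfg$head_levels, msc_kernels = cfg$msc_kernels,
      use_msc = cfg$use_msc)
    net <- init_network(ncfg, seed = cfg$seed)
  }
  batches_per_epoch <- length(make_batches(ds, cfg, epoch = 1L))
  total <- if (is.null(iters)) cfg$epochs * batches_per_epoch else iters
  state <- NULL
  hist <- vector("list", total - start_iter + 1L)
  metrics <- list()
  t <- start_iter
  epoch <- (start_iter - 1L) %/% batches_per_epoch + 1L
  while (t <= total) {
    batches <- make_batches(ds, cfg, epoch = epoch)
    for (b in batches) {
      if (t > total) break
      stp <- train_step(net, ds, b, state, t, total, cfg)
      net <- stp$net; state <- stp$state
      bu <- stp$bundle
      hist[[t - start_iter + 1L]] <- data.frame(
        iter = t, epoch = epoch, l_sup = bu$l_sup, l_hc = bu$l_hc,
        l_urc = bu$l_urc, l_cr = bu$l_cr, l_unsup = bu$l_unsup,
        l_total = bu$l_total, lambda = bu$lam)
      t <- t + 1L
    }
    if (!is.null(test_items)) {
      metrics[[length(metrics) + 1L]] <-
        c(epoch = epoch, evaluate_model(net, test_items))
    }
    if (!is.null(checkpoint_dir)) save_checkpoint(net, checkpoint_dir, epoch)
    epoch <- epoch + 1L
  }
  history <- do.call(rbind, hist)
  if (!is.null(history_file)) write.csv(history, history_file,
                                        row.names = FALSE)
  out <- list(net = net, history = history)
  if (length(metrics)) out$metrics <- do.call(rbind, metrics)
  out
}
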