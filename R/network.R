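# Encoder-decoder backbone with per-stage prediction heads and the
# multi-scale convolution (MSC) module.  The compute engine lives in
# src/engine.cpp; this file owns configuration, weight initialization and
# the user-facing forward pass.

#' Network architecture configuration
#'
#' A U-Net style backbone: `encoder_depth` convolution + max-pool stages, a
#' bottleneck, and a mirrored decoder. Each of the `head_levels` deepest
#' decoder stages carries a prediction head (dropout, 1x1 convolution to
#' `n_classes`, bilinear upsampling to input size, channel softmax),
#' yielding the multi-level predictions `p_1` (deepest stage, coarse) to
#' `p_S` (shallowest, full resolution). When `use_msc` is on, the three
#' shallowest decoder feature maps are fused (1x1 convolution), passed
#' through parallel poolings at the `msc_kernels` window sizes, re-upsampled,
#' concatenated and fused by a 3x3 convolution, and a final 1x1 convolution
#' + softmax emits the fine-grained prediction `p_0`.
#'
#' @param n_classes number of segmentation classes `K`.
#' @param in_channels input image channels (3 for RGB).
#' @param base_width channel count of the first encoder block.
#' @param encoder_depth number of encoder stages (input size must be
#'   divisible by `2^encoder_depth`).
#' @param growth per-stage channel multiplier (2 for the classic U-Net
#'   doubling; 1 gives a constant-width tiny backbone).
#' @param dropout_rate dropout probability in the prediction heads.
#' @param head_levels number of multi-level heads `S` (at most
#'   `encoder_depth`).
#' @param msc_kernels pooling window sizes of the MSC branches.
#' @param use_msc whether to build the MSC module and the fine head.
#' @param msc_pool `"avg"` (default) or `"max"` pooling in the MSC branches.
#' @param upsample `"bilinear"` (default) or `"nearest"` everywhere.
#' @return a `network_config` object.
#' @export
network_config <- function(n_classes, in_channels = 3L, base_width = 16L,
                           encoder_depth = 4L, growth = 2L,
                           dropout_rate = 0.3, head_levels = 4L,
                           msc_kernels = c(1L, 2L, 3L, 5L), use_msc = TRUE,
                           msc_pool = c("avg", "max"),
                           upsample = c("bilinear", "nearest")) {
  stopifnot(n_classes >= 2, base_width >= 1, encoder_depth >= 1,
            head_levels >= 1, head_levels <= encoder_depth,
            dropout_rate >= 0, dropout_rate < 1,
            length(msc_kernels) >= 1, all(msc_kernels >= 1))
  structure(
    list(n_classes = as.integer(n_classes),
         in_channels = as.integer(in_channels),
         base_width = as.integer(base_width),
         encoder_depth = as.integer(encoder_depth),
         growth = as.integer(growth),
         dropout_rate = dropout_rate,
         head_levels = as.integer(head_levels),
         msc_kernels = as.integer(msc_kernels),
         use_msc = isTRUE(use_msc),
         msc_pool = match.arg(msc_pool),
         upsample = match.arg(upsample)),
    class = "network_config")
}

# encoder channel widths per stage, capped to keep deep stages tractable
stage_widths <- function(config) {
  pmin(config$base_width * config$growth^(seq_len(config$encoder_depth) - 1L),
       512L)
}

he_matrix <- function(n_out, fan_in) {
  matrix(rnorm(n_out * fan_in, sd = sqrt(2 / fan_in)), n_out, fan_in)
}

#' Initialize a segmentation network
#'
#' He-normal weight initialization driven by a single seed; identical
#' config + seed gives identical weights.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return a `seg_network` holding `config`, `params` and the seed.
#' @export
init_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  d <- config$encoder_depth
  widths <- stage_widths(config)
  bott_w <- min(widths[d] * config$growth, 512L)
  k <- config$n_classes
  params <- withr::with_seed(as.integer(seed), {
    p <- list()
    cin <- config$in_channels
    for (s in seq_len(d)) {
      p[[paste0("enc_w", s - 1)]] <- he_matrix(widths[s], cin * 9)
      p[[paste0("enc_b", s - 1)]] <- numeric(widths[s])
      cin <- widths[s]
    }
    p$bott_w <- he_matrix(bott_w, widths[d] * 9)
    p$bott_b <- numeric(bott_w)
    for (j in seq_len(d)) {        # decoder stage j-1 (0 = shallowest)
      cprev <- if (j == d) bott_w else widths[j + 1]
      p[[paste0("dec_w", j - 1)]] <- he_matrix(widths[j], (cprev + widths[j]) * 9)
      p[[paste0("dec_b", j - 1)]] <- numeric(widths[j])
    }
    for (s in seq_len(config$head_levels)) {   # p_s reads stage d - s
      cj <- widths[d - s + 1]
      p[[paste0("head_w", s)]] <- he_matrix(k, cj)
      p[[paste0("head_b", s)]] <- numeric(k)
    }
    if (config$use_msc) {
      n_fuse <- min(3L, d)
      fuse_in <- sum(widths[seq_len(n_fuse)])
      fuse_out <- max(4L, config$base_width %/% 2L)
      p$fuse_w <- he_matrix(fuse_out, fuse_in)
      p$fuse_b <- numeric(fuse_out)
      p$msc_w <- he_matrix(config$base_width,
                           fuse_out * length(config$msc_kernels) * 9)
      p$msc_b <- numeric(config$base_width)
      p$fine_w <- he_matrix(k, config$base_width)
      p$fine_b <- numeric(k)
    }
    p
  })
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "seg_network")
}

#' Number of trainable parameters
#' @param net a `seg_network`.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

#' @export
print.seg_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "seg_network: depth %d, base width %d, %d classes, S = %d heads%s, %s parameters\n",
    cfg$encoder_depth, cfg$base_width, cfg$n_classes, cfg$head_levels,
    if (cfg$use_msc) " + MSC fine head" else "",
    format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# assemble the engine config list shared by forward() and train_step()
engine_cfg <- function(net, h, w, n, n_labeled = 0L, lambda = 0,
                       beta = 0.5, alpha = NULL, use_hc = FALSE,
                       use_cfgc = FALSE, cons_all = FALSE, detach_p0 = TRUE,
                       train_mode = FALSE, seed = 0, want_preds = TRUE,
                       want_features = FALSE, want_grads = FALSE) {
  cfg <- net$config
  s <- cfg$head_levels
  if (is.null(alpha)) alpha <- rep(1, s + 1)
  list(H = as.integer(h), W = as.integer(w), N = as.integer(n),
       K = cfg$n_classes, n_labeled = as.integer(n_labeled),
       pool_type = if (cfg$msc_pool == "avg") 0L else 1L,
       upsample = if (cfg$upsample == "bilinear") 0L else 1L,
       use_msc = cfg$use_msc, use_hc = use_hc, use_cfgc = use_cfgc,
       cons_all = cons_all, detach_p0 = detach_p0, train_mode = train_mode,
       dropout = cfg$dropout_rate, lambda = lambda, beta = beta,
       alpha = rep_len(alpha, s + 1), kernels = cfg$msc_kernels,
       seed = as.double(seed), want_preds = want_preds,
       want_features = want_features, want_grads = want_grads)
}

as_image_batch <- function(images) {
  if (is.list(images)) {
    images <- simplify2array(images)
  }
  if (length(dim(images)) == 3) dim(images) <- c(dim(images), 1L)
  images
}

#' Forward pass of the segmentation network
#'
#' Produces the ordered multi-level probability maps, all upsampled to the
#' input resolution and channel-normalized: `p_0` (fused fine prediction,
#' present when the MSC module is active) followed by `p_1` (coarsest) to
#' `p_S`. In evaluation mode dropout is inactive and the output is
#' deterministic for fixed weights.
#'
#' @param net a `seg_network`.
#' @param images `H x W x 3` array, list of such arrays, or
#'   `H x W x 3 x N` batch, values in `[0, 1]`; `H` and `W` must be
#'   divisible by `2^encoder_depth`.
#' @param train_mode enable head dropout (used by the trainer).
#' @param seed dropout stream seed (train mode only).
#' @param want_features also return the decoder feature pyramid.
#' @return a `multilevel_prediction`: list with `maps` (named list
#'   `p0`/`p1`/... of `K x H x W (x N)` arrays), and optionally `features`.
#' @export
forward <- function(net, images, train_mode = FALSE, seed = 0L,
                    want_features = FALSE) {
  stopifnot(inherits(net, "seg_network"))
  x <- as_image_batch(images)
  d <- dim(x)
  div <- 2^net$config$encoder_depth
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop("input size ", d[1], "x", d[2],
         " is not divisible by 2^encoder_depth = ", div)
  }
  cfg <- engine_cfg(net, d[1], d[2], d[4], train_mode = train_mode,
                    seed = seed, want_features = want_features)
  res <- cpp_net_run(net$params, x, NULL, cfg, "double")
  maps <- res$preds
  if (d[4] == 1L) maps <- lapply(maps, function(m) {
    dm <- dim(m); array(m, dm[1:3])
  })
  out <- list(maps = maps, n_classes = net$config$n_classes,
              has_fine = net$config$use_msc)
  if (want_features) {
    out$features <- res$decoder_features
    out$fused <- res$fused
  }
  structure(out, class = "multilevel_prediction")
}

#' @export
print.multilevel_prediction <- function(x, ...) {
  cat("multilevel_prediction:", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

#' Multi-scale convolution module weights
#'
#' @param in_width input channel count of the fused feature map.
#' @param out_width output channel count.
#' @param kernels pooling window sizes of the branches.
#' @param seed initialization seed.
#' @return an `msc_module` holding the 3x3 fusion convolution weights.
#' @export
msc_module <- function(in_width, out_width, kernels = c(1L, 2L, 3L, 5L),
                       seed = 1L) {
  stopifnot(length(kernels) >= 1, all(kernels >= 1))
  w <- withr::with_seed(as.integer(seed),
                        he_matrix(out_width, in_width * length(kernels) * 9))
  structure(list(w = w, b = numeric(out_width), kernels = as.integer(kernels),
                 in_width = as.integer(in_width)),
            class = "msc_module")
}

#' Multi-scale convolution forward pass
#'
#' Pools the input at each branch's window size (stride = window), upsamples
#' every branch back to the input resolution, concatenates the branches
#' along channels and applies a 3x3 convolution. Output spatial size equals
#' input spatial size. With `kernels = 1` the module reduces to a plain 3x3
#' convolution of the input.
#'
#' @param x `H x W x C` feature array.
#' @param module an [msc_module()].
#' @param pool `"avg"` or `"max"`.
#' @return `H x W x out_width` feature array.
#' @export
msc_forward <- function(x, module, pool = "avg") {
  stopifnot(inherits(module, "msc_module"))
  d <- dim(x)
  if (min(d[1], d[2]) < max(module$kernels)) {
    stop("msc_forward: input ", d[1], "x", d[2],
         " is smaller than the largest pooling kernel ", max(module$kernels))
  }
  branches <- lapply(module$kernels, function(k) {
    pooled <- cpp_pool2d(x, as.integer(k), pool)
    cpp_resize2d(pooled, d[1], d[2], "bilinear")
  })
  concat <- array(unlist(branches), dim = c(d[1], d[2],
                                            d[3] * length(branches)))
  cpp_conv2d_3x3(concat, module$w, module$b)
}

#' Fine-grained prediction head from a decoder feature pyramid
#'
#' Upsamples the deeper decoder features to the shallowest stage's
#' resolution, concatenates them with the shallowest features, applies the
#' network's 1x1 fusion, MSC module and final 1x1 convolution + softmax,
#' yielding the fine-grained probability map `p_0` at full input
#' resolution. This is the same computation the engine performs inside
#' [forward()], composed here from the exported primitives so that the two
#' routes can be cross-checked.
#'
#' @param features list of decoder feature arrays (`C x h x w x 1`),
#'   shallowest first, as returned by `forward(..., want_features = TRUE)`.
#' @param net the `seg_network` owning the fusion weights (requires
#'   `use_msc`).
#' @return `K x H x W` probability array.
#' @export
fine_head <- function(features, net) {
  stopifnot(inherits(net, "seg_network"), net$config$use_msc)
  to_hwc <- function(f) {            # (C, h, w, 1) -> (h, w, C)
    d <- dim(f)
    aperm(array(f, d[1:3]), c(2, 3, 1))
  }
  n_fuse <- min(3L, net$config$encoder_depth)
  f0 <- to_hwc(features[[1]])
  h <- dim(f0)[1]; w <- dim(f0)[2]
  parts <- list(f0)
  for (j in seq_len(n_fuse - 1L)) {
    parts[[j + 1L]] <- cpp_resize2d(to_hwc(features[[j + 1L]]), h, w,
                                    net$config$upsample)
  }
  concat <- array(unlist(parts), dim = c(h, w, sum(vapply(parts, function(p)
    dim(p)[3], integer(1)))))
  fused <- cpp_conv2d_1x1(concat, net$params$fuse_w, net$params$fuse_b)
  fused[fused < 0] <- 0
  mod <- structure(list(w = net$params$msc_w, b = net$params$msc_b,
                        kernels = net$config$msc_kernels,
                        in_width = dim(fused)[3]),
                   class = "msc_module")
  msc <- msc_forward(fused, mod, pool = net$config$msc_pool)
  msc[msc < 0] <- 0
  z <- cpp_conv2d_1x1(msc, net$params$fine_w, net$params$fine_b)
  p <- cpp_softmax_channels(z)
  aperm(p, c(3, 1, 2))               # (K, H, W)
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the full config; files are named by epoch and seed
#' when `epoch` is given.
#'
#' @param net a `seg_network`.
#' @param path destination file, or a directory when `epoch` is given.
#' @param epoch optional epoch number used in the file name.
#' @return the written path.
#' @export
save_checkpoint <- function(net, path, epoch = NULL) {
  if (!is.null(epoch)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(path, sprintf("net_epoch%03d_seed%d.rds", epoch, net$seed))
  }
  saveRDS(net, path)
  path
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "seg_network"))
  net
}
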