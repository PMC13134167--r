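# Packaged synthetic semi-supervised benchmark: the full dual-consistency
# method against a supervised-only control and an HC-only arm (hierarchical
# consistency alone, the URPC-style configuration), on one fixed synthetic
# dataset across several run seeds.

#' Scaled-down semi-supervised benchmark on synthetic patches
#'
#' Trains three arms on one fixed synthetic dataset of histology-like
#' patches (64 x 64, 2 classes) with a small labeled fraction, and reports
#' the mean held-out Dice of each arm over the run seeds:
#'
#' * `supervised`: deeply-supervised U-Net on the labeled pool only
#'   (consistency and MSC off);
#' * `hc_only`: adds the uncertainty-rectified hierarchical consistency on
#'   unlabeled data (`beta = 1`, no MSC / coarse-fine term);
#' * `full`: the complete dual-consistency method (hierarchical + coarse-
#'   fine consistency with the multi-scale convolution module).
#'
#' The expectation mirrored from larger-scale experiments is directional:
#' the full method's mean Dice should not fall below the supervised
#' control's, and should not fall below the HC-only arm's.
#'
#' @param seeds run seeds (network initialization, batch order, dropout).
#' @param iters optimizer iterations per run.
#' @param n_train,n_test synthetic training/held-out pool sizes.
#' @param labeled_fraction fraction of training patches keeping masks.
#' @param base_width backbone width (constant across stages here:
#'   `growth = 1`, the tiny-backbone setting).
#' @param learning_rate SGD step size for all arms.
#' @param data_seed seed of the synthetic dataset (fixed across arms and
#'   run seeds so every run sees identical data).
#' @param arms subset of `c("supervised", "hc_only", "full")` to run.
#' @param verbose print one line per finished run.
#' @return data.frame with columns `arm`, `seed`, `dsc`, `iou`.
#' @export
ssl_benchmark <- function(seeds = 1:5, iters = 300L, n_train = 200L,
                          n_test = 50L, labeled_fraction = 0.2,
                          base_width = 16L, learning_rate = 0.01,
                          data_seed = 41L,
                          arms = c("supervised", "hc_only", "full"),
                          verbose = TRUE) {
  spec <- patch_spec(height = 64, width = 64, n_classes = 2, seed = data_seed)
  train <- generate_patches(spec, n_train)
  test_spec <- patch_spec(height = 64, width = 64, n_classes = 2,
                          seed = data_seed + 100003L)
  test <- generate_patches(test_spec, n_test)
  ds <- make_ssl_split(train, labeled_fraction, seed = data_seed)

  arm_cfg <- function(arm, seed) {
    switch(arm,
      supervised = train_config(seed = seed, base_width = base_width,
                                growth = 1L, learning_rate = learning_rate,
                                use_hc = FALSE, use_cfgc = FALSE,
                                use_msc = FALSE),
      hc_only = train_config(seed = seed, base_width = base_width,
                             growth = 1L, learning_rate = learning_rate,
                             use_hc = TRUE, use_cfgc = FALSE,
                             use_msc = FALSE, beta = 1),
      full = train_config(seed = seed, base_width = base_width,
                          growth = 1L, learning_rate = learning_rate))
  }

  rows <- list()
  for (arm in arms) {
    for (seed in seeds) {
      res <- fit(ds, arm_cfg(arm, seed), iters = iters, n_classes = 2L)
      m <- evaluate_model(res$net, test)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, seed = seed, dsc = m[["dsc"]], iou = m[["iou"]])
      if (verbose) {
        message(sprintf("%s seed %d: DSC %.4f IoU %.4f",
                        arm, seed, m[["dsc"]], m[["iou"]]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Mean per-arm summary of an [ssl_benchmark()] result
#' @param bench data.frame from [ssl_benchmark()].
#' @return data.frame with one row per arm (mean dsc/iou over seeds).
#' @export
summarize_benchmark <- function(bench) {
  agg <- aggregate(cbind(dsc, iou) ~ arm, data = bench, FUN = mean)
  agg[order(match(agg$arm, c("supervised", "hc_only", "full"))), ]
}
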