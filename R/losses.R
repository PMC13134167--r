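# Loss terms and schedules of the dual-consistency objective.
#
# All probability maps are arrays of dim (K, H, W): class channel first.
# Masks are (H, W) integer arrays with 0-based class indices.  The L2
# consistency norms are computed as per-pixel squared differences summed
# over channels and averaged over pixels (and, where applicable, levels).

LOG_CLAMP <- 1e-8
DICE_SMOOTH <- 1e-5

#' Schedule and weighting configuration for the unsupervised objective
#'
#' @param total_iters total number of training iterations `T` of the ramp.
#' @param k ceiling of the Gaussian warm-up; the unsupervised weight reaches
#'   `k` at the final iteration. Default 0.1.
#' @param beta mixing weight between the uncertainty-rectified hierarchical
#'   consistency and the coarse-fine consistency in the unsupervised loss.
#'   Default 0.5; `beta = 1` disables the coarse-fine term.
#' @param alpha per-level supervision weights (recycled as needed); all 1 by
#'   default so every decoder level receives equal supervision.
#' @return a `schedule_config` object.
#' @export
schedule_config <- function(total_iters, k = 0.1, beta = 0.5, alpha = 1.0) {
  stopifnot(k > 0, total_iters >= 1, beta >= 0, beta <= 1, all(alpha >= 0))
  structure(
    list(k = k, total_iters = as.integer(total_iters),
         beta = beta, alpha = alpha),
    class = "schedule_config")
}

#' Gaussian warm-up weight for the unsupervised loss
#'
#' Evaluates `lambda(t) = k * exp(-5 * (1 - t/T)^2)`, the time-dependent
#' ramp that scales the unsupervised loss from `k * exp(-5)` at the start of
#' training up to `k` at the final iteration. Iterations beyond `T` are
#' clamped to `T` (the ramp stays at its ceiling).
#'
#' @param t current iteration (vectorized); must be non-negative.
#' @param schedule a [schedule_config()].
#' @return numeric vector of ramp values.
#' @export
lambda_schedule <- function(t, schedule) {
  stopifnot(inherits(schedule, "schedule_config"), all(t >= 0))
  t <- pmin(t, schedule$total_iters)
  schedule$k * exp(-5 * (1 - t / schedule$total_iters)^2)
}

# extract the list of level maps p_1..p_S (excluding the fused fine map p_0)
consistency_levels <- function(preds) {
  maps <- if (inherits(preds, "multilevel_prediction")) preds$maps else preds
  nm <- names(maps)
  if (!is.null(nm) && "p0" %in% nm) maps <- maps[nm != "p0"]
  maps
}

all_levels <- function(preds) {
  if (inherits(preds, "multilevel_prediction")) preds$maps else preds
}

# mean over pixels of the channel-summed squared difference
pixel_msd <- function(a, b) {
  sum((a - b)^2) / prod(dim(a)[-1])
}

#' Across-level average prediction
#'
#' Elementwise mean of the level predictions `p_1..p_S`; the fused fine map
#' `p_0` is excluded by construction.
#'
#' @param preds a `multilevel_prediction` or list of `(K, H, W)` maps.
#' @return a `(K, H, W)` probability array.
#' @export
average_prediction <- function(preds) {
  maps <- consistency_levels(preds)
  stopifnot(length(maps) >= 2)
  Reduce(`+`, maps) / length(maps)
}

#' Hierarchical consistency loss
#'
#' Mean over levels of the pixel-averaged, channel-summed squared difference
#' between each level prediction and the across-level average. Zero exactly
#' when all levels agree.
#'
#' @inheritParams average_prediction
#' @return scalar loss.
#' @export
hierarchical_consistency <- function(preds) {
  maps <- consistency_levels(preds)
  stopifnot(length(maps) >= 2)
  pavg <- Reduce(`+`, maps) / length(maps)
  mean(vapply(maps, pixel_msd, numeric(1), b = pavg))
}

#' Per-pixel uncertainty from inter-level disagreement
#'
#' For each level `s` and pixel `i`, the KL divergence
#' `D = sum_c p_s(c) log(p_s(c) / p_avg(c))` over class channels (both
#' arguments clamped below at 1e-8 inside the logarithm) and the derived
#' weight `w = exp(-D)`. Agreeing pixels get weight 1; disagreeing pixels
#' are down-weighted.
#'
#' @inheritParams average_prediction
#' @param p_avg optional precomputed average prediction.
#' @return list with elements `d` and `w`, each a list of `(H, W)` arrays,
#'   one per level.
#' @export
uncertainty_map <- function(preds, p_avg = NULL) {
  maps <- consistency_levels(preds)
  if (is.null(p_avg)) p_avg <- average_prediction(maps)
  lq <- log(pmax(p_avg, LOG_CLAMP))
  d <- lapply(maps, function(p) {
    colSums(p * (log(pmax(p, LOG_CLAMP)) - lq), dims = 1)
  })
  list(d = d, w = lapply(d, function(x) exp(-x)))
}

#' Uncertainty-rectified hierarchical consistency loss
#'
#' Per level, the weighted average over pixels of the channel-summed squared
#' difference to the average prediction, with weights `w = exp(-KL)`;
#' normalized by the total weight, then averaged over levels. With all
#' weights equal to 1 this reduces exactly to [hierarchical_consistency()].
#'
#' @inheritParams uncertainty_map
#' @param umap optional precomputed [uncertainty_map()].
#' @return scalar loss.
#' @export
rectified_consistency <- function(preds, p_avg = NULL, umap = NULL) {
  maps <- consistency_levels(preds)
  stopifnot(length(maps) >= 2)
  if (is.null(p_avg)) p_avg <- average_prediction(maps)
  if (is.null(umap)) umap <- uncertainty_map(maps, p_avg)
  terms <- vapply(seq_along(maps), function(s) {
    m <- colSums((maps[[s]] - p_avg)^2, dims = 1)
    w <- umap$w[[s]]
    sw <- sum(w)
    if (sw <= 0) stop("all-zero uncertainty weights")
    sum(w * m) / sw
  }, numeric(1))
  mean(terms)
}

#' Coarse-fine grained consistency loss
#'
#' Pixel-averaged, channel-summed squared difference between the fused
#' fine-grained prediction `p_0` and the coarse-grained prediction `p_1`.
#' During training `p_0` acts as the (gradient-blocked) pseudo-label target;
#' the value itself is symmetric in its arguments.
#'
#' @param p0,p1 `(K, H, W)` probability arrays of identical shape.
#' @return scalar loss.
#' @export
cfgc_loss <- function(p0, p1) {
  if (!identical(dim(p0), dim(p1))) {
    stop("cfgc_loss: shape mismatch between p0 (", paste(dim(p0), collapse = "x"),
         ") and p1 (", paste(dim(p1), collapse = "x"), ")")
  }
  pixel_msd(p0, p1)
}

one_hot <- function(mask, n_classes) {
  h <- dim(mask)[1]; w <- dim(mask)[2]
  y <- array(0, dim = c(n_classes, h, w))
  idx <- cbind(as.vector(mask) + 1L,
               rep(seq_len(h), times = w), rep(seq_len(w), each = h))
  y[idx] <- 1
  y
}

# 0.5 * cross-entropy + 0.5 * Dice between one probability map and a mask
dice_ce_loss <- function(p, mask) {
  k <- dim(p)[1]
  y <- one_hot(mask, k)
  npix <- prod(dim(mask))
  ce <- -sum(y * log(pmax(p, LOG_CLAMP))) / npix
  dice <- mean(vapply(seq_len(k), function(c) {
    num <- 2 * sum(p[c, , ] * y[c, , ]) + DICE_SMOOTH
    den <- sum(p[c, , ]) + sum(y[c, , ]) + DICE_SMOOTH
    1 - num / den
  }, numeric(1)))
  0.5 * ce + 0.5 * dice
}

#' Deeply-supervised segmentation loss
#'
#' Sum over prediction levels of `alpha_s * (0.5 * CE + 0.5 * Dice)` between
#' each probability map and the ground-truth mask. All levels present in
#' `preds` participate, including the fused fine map when the multi-scale
#' module is active.
#'
#' @param preds a `multilevel_prediction` or list of `(K, H, W)` maps.
#' @param mask `(H, W)` integer mask with 0-based classes below `K`.
#' @param alpha per-level weights, recycled to the number of levels; all 1
#'   by default.
#' @return scalar loss.
#' @export
supervised_loss <- function(preds, mask, alpha = NULL) {
  maps <- all_levels(preds)
  k <- dim(maps[[1]])[1]
  if (any(mask < 0) || any(mask >= k)) {
    stop("mask contains classes outside [0, ", k, ")")
  }
  if (is.null(alpha)) alpha <- rep(1, length(maps))
  alpha <- rep_len(alpha, length(maps))
  sum(alpha * vapply(maps, dice_ce_loss, numeric(1), mask = mask))
}

#' Assemble the total training objective
#'
#' Combines the supervised loss with the ramped unsupervised loss:
#' `L_unsup = beta * L_urc + (1 - beta) * L_cr` and
#' `L_total = L_sup + lambda(t) * L_unsup`.
#'
#' @param l_sup,l_urc,l_cr scalar loss components (all non-negative).
#' @param t current iteration.
#' @param schedule a [schedule_config()].
#' @param l_hc optional plain hierarchical-consistency value for logging.
#' @return a `loss_bundle` with fields `l_sup`, `l_hc`, `l_urc`, `l_cr`,
#'   `l_unsup`, `l_total`, `lam`.
#' @export
total_loss <- function(l_sup, l_urc, l_cr, t, schedule, l_hc = NA_real_) {
  stopifnot(l_sup >= 0, l_urc >= 0, l_cr >= 0)
  lam <- lambda_schedule(t, schedule)
  l_unsup <- schedule$beta * l_urc + (1 - schedule$beta) * l_cr
  structure(
    list(l_sup = l_sup, l_hc = l_hc, l_urc = l_urc, l_cr = l_cr,
         l_unsup = l_unsup, l_total = l_sup + lam * l_unsup, lam = lam),
    class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf(
    "loss bundle: total %.5f = sup %.5f + lambda %.5g * unsup %.5f (urc %.5f, cr %.5f)\n",
    x$l_total, x$l_sup, x$lam, x$l_unsup, x$l_urc, x$l_cr))
  invisible(x)
}
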