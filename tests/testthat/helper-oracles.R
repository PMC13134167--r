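# Independent brute-force oracles for the loss terms and metrics, written
# as explicit per-level / per-pixel / per-channel loops.  They share no code
# with the package implementations they check.

# random channel-normalized probability map, dim (K, H, W)
rand_prob_map <- function(k, h, w) {
  z <- array(exp(rnorm(k * h * w)), dim = c(k, h, w))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    z[, i, j] <- z[, i, j] / sum(z[, i, j])
  }
  z
}

rand_level_maps <- function(s, k, h, w) {
  lapply(seq_len(s), function(i) rand_prob_map(k, h, w))
}

oracle_avg <- function(maps) {
  out <- maps[[1]] * 0
  for (m in maps) out <- out + m
  out / length(maps)
}

# Eq. 3 oracle: mean over levels of pixel-mean channel-summed squared diff
oracle_hc <- function(maps) {
  pavg <- oracle_avg(maps)
  k <- dim(pavg)[1]; h <- dim(pavg)[2]; w <- dim(pavg)[3]
  total <- 0
  for (m in maps) {
    acc <- 0
    for (i in seq_len(h)) for (j in seq_len(w)) {
      d2 <- 0
      for (c in seq_len(k)) d2 <- d2 + (m[c, i, j] - pavg[c, i, j])^2
      acc <- acc + d2
    }
    total <- total + acc / (h * w)
  }
  total / length(maps)
}

# Eqs. 4-6 oracle: per-pixel KL weight, weighted pixel average, level mean
oracle_urc <- function(maps) {
  pavg <- oracle_avg(maps)
  k <- dim(pavg)[1]; h <- dim(pavg)[2]; w <- dim(pavg)[3]
  eps <- 1e-8
  total <- 0
  for (m in maps) {
    num <- 0; den <- 0
    for (i in seq_len(h)) for (j in seq_len(w)) {
      d2 <- 0; dkl <- 0
      for (c in seq_len(k)) {
        d2 <- d2 + (m[c, i, j] - pavg[c, i, j])^2
        dkl <- dkl + m[c, i, j] *
          (log(max(m[c, i, j], eps)) - log(max(pavg[c, i, j], eps)))
      }
      wgt <- exp(-dkl)
      num <- num + wgt * d2
      den <- den + wgt
    }
    total <- total + num / den
  }
  total / length(maps)
}

# Eq. 7 oracle
oracle_cfgc <- function(p0, p1) {
  k <- dim(p0)[1]; h <- dim(p0)[2]; w <- dim(p0)[3]
  acc <- 0
  for (i in seq_len(h)) for (j in seq_len(w))
    for (c in seq_len(k)) acc <- acc + (p0[c, i, j] - p1[c, i, j])^2
  acc / (h * w)
}

# Eq. 1 oracle: sum over levels of alpha * (0.5 CE + 0.5 Dice)
oracle_sup <- function(maps, mask, alpha = rep(1, length(maps))) {
  k <- dim(maps[[1]])[1]; h <- dim(mask)[1]; w <- dim(mask)[2]
  eps_log <- 1e-8; eps_dice <- 1e-5
  total <- 0
  for (s in seq_along(maps)) {
    m <- maps[[s]]
    ce <- 0
    for (i in seq_len(h)) for (j in seq_len(w))
      ce <- ce - log(max(m[mask[i, j] + 1, i, j], eps_log))
    ce <- ce / (h * w)
    dice <- 0
    for (c in seq_len(k)) {
      sp <- 0; sy <- 0; spy <- 0
      for (i in seq_len(h)) for (j in seq_len(w)) {
        yv <- as.numeric(mask[i, j] + 1 == c)
        sp <- sp + m[c, i, j]; sy <- sy + yv; spy <- spy + m[c, i, j] * yv
      }
      dice <- dice + 1 - (2 * spy + eps_dice) / (sp + sy + eps_dice)
    }
    dice <- dice / k
    total <- total + alpha[s] * (0.5 * ce + 0.5 * dice)
  }
  total
}

# per-pixel confusion tally
oracle_confusion <- function(pred, gt, n_classes) {
  out <- data.frame(class = 0:(n_classes - 1), tp = 0, fp = 0, fn = 0, tn = 0)
  for (c in 0:(n_classes - 1)) {
    for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
      p <- pred[i, j] == c; g <- gt[i, j] == c
      r <- c + 1
      if (p && g) out$tp[r] <- out$tp[r] + 1
      else if (p && !g) out$fp[r] <- out$fp[r] + 1
      else if (!p && g) out$fn[r] <- out$fn[r] + 1
      else out$tn[r] <- out$tn[r] + 1
    }
  }
  out
}

# small network used across architecture tests
tiny_net <- function(n_classes = 2, base_width = 4, use_msc = TRUE,
                     dropout_rate = 0, seed = 7, kernels = c(1, 2, 3),
                     growth = 1) {
  init_network(
    network_config(n_classes = n_classes, base_width = base_width,
                   growth = growth, dropout_rate = dropout_rate,
                   msc_kernels = kernels, use_msc = use_msc),
    seed = seed)
}
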