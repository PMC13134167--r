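# Seeded generator of histology-like image patches, labeled/unlabeled splits
# and synthetic whole-slide mosaics.  All randomness flows through one
# explicit seed per call; identical spec + seed gives bit-identical output.

# H&E-like mean colors in [0,1]: background (eosin-pink tissue), then the
# foreground classes: tumor (hematoxylin purple), stroma, lymphocyte
# infiltration, necrosis.
default_palette <- function(n_classes) {
  pal <- rbind(
    c(0.91, 0.79, 0.86),  # 0: background tissue
    c(0.45, 0.30, 0.60),  # 1: tumor
    c(0.86, 0.63, 0.74),  # 2: stroma
    c(0.33, 0.29, 0.56),  # 3: lymphocyte infiltration
    c(0.75, 0.69, 0.58))  # 4: necrosis
  if (n_classes > nrow(pal)) {
    extra <- matrix(runif(3 * (n_classes - nrow(pal))), ncol = 3)
    pal <- rbind(pal, extra)
  }
  pal[seq_len(n_classes), , drop = FALSE]
}

#' Specification of a synthetic histology-like patch
#'
#' Describes the random model from which [generate_patch()] draws: a
#' textured background (class 0) plus a number of irregular blobs --
#' ellipses perturbed by low-frequency radial noise -- with per-class mean
#' colors and Gaussian texture noise. In five-class mode blobs are assigned
#' cyclically to the foreground classes 1..4.
#'
#' @param height,width patch size in pixels (at least 16).
#' @param n_classes number of classes including background (2 or 5 typical).
#' @param blob_count_range integer interval for the number of blobs.
#' @param blob_radius_range pixel interval for the blob base radius.
#' @param texture_noise_sd standard deviation of per-pixel Gaussian noise,
#'   in intensity units on `[0, 1]`.
#' @param class_palette optional `n_classes x 3` matrix of mean RGB values
#'   in `[0, 1]`; a built-in H&E-like palette is used when `NULL`.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return a `patch_spec` object.
#' @export
patch_spec <- function(height = 64, width = 64, n_classes = 2,
                       blob_count_range = c(1, 3),
                       blob_radius_range = c(8, 16),
                       texture_noise_sd = 0.1,
                       class_palette = NULL, seed = 1L) {
  stopifnot(height >= 16, width >= 16, n_classes >= 2,
            length(blob_count_range) == 2, length(blob_radius_range) == 2,
            blob_count_range[1] >= 0,
            blob_count_range[1] <= blob_count_range[2],
            texture_noise_sd >= 0)
  if (any(blob_radius_range < 0) ||
      (blob_count_range[2] > 0 && blob_radius_range[2] <= 0)) {
    stop("blob_radius_range must be positive")
  }
  if (2 * max(blob_radius_range) > min(height, width)) {
    stop("degenerate spec: blob_radius_range exceeds the patch size (",
         "2 * ", max(blob_radius_range), " > ", min(height, width), ")")
  }
  if (is.null(class_palette)) {
    class_palette <- withr::with_seed(seed, default_palette(n_classes))
  }
  stopifnot(nrow(class_palette) == n_classes, ncol(class_palette) == 3)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_classes = as.integer(n_classes),
         blob_count_range = as.integer(blob_count_range),
         blob_radius_range = blob_radius_range,
         texture_noise_sd = texture_noise_sd,
         class_palette = class_palette, seed = as.integer(seed)),
    class = "patch_spec")
}

# paint one irregular blob (perturbed ellipse) of class `cls` into `mask`
paint_blob <- function(mask, cy, cx, r0, cls) {
  h <- nrow(mask); w <- ncol(mask)
  aspect <- runif(1, 0.72, 1.35)
  rot <- runif(1, 0, 2 * pi)
  amp <- runif(3, 0, 0.13)          # harmonics 2..4 of the radial perturbation
  phase <- runif(3, 0, 2 * pi)
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  u <- dx * cos(rot) + dy * sin(rot)
  v <- (-dx * sin(rot) + dy * cos(rot)) / aspect
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rlim <- r0 * (1 + amp[1] * cos(2 * theta + phase[1]) +
                  amp[2] * cos(3 * theta + phase[2]) +
                  amp[3] * cos(4 * theta + phase[3]))
  mask[rho <= rlim] <- cls
  mask
}

generate_canvas <- function(h, w, spec, radius_range, blob_count) {
  mask <- matrix(0L, h, w)
  k <- spec$n_classes
  if (blob_count > 0) {
    for (b in seq_len(blob_count)) {
      cls <- if (k == 2) 1L else ((b - 1L) %% (k - 1L)) + 1L
      r0 <- runif(1, radius_range[1], radius_range[2])
      m <- min(r0, (min(h, w) - 1) / 2)
      cy <- runif(1, 1 + m, h - m)
      cx <- runif(1, 1 + m, w - m)
      mask <- paint_blob(mask, cy, cx, r0, cls)
    }
  }
  # image: palette lookup + low-frequency mottle + per-pixel noise
  pal <- spec$class_palette
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- matrix(pal[mask + 1L, ch], h, w)
  period <- runif(2, 18, 40)
  ph <- runif(2, 0, 2 * pi)
  mottle <- 0.025 * outer(sin(2 * pi * seq_len(h) / period[1] + ph[1]),
                          sin(2 * pi * seq_len(w) / period[2] + ph[2]))
  img <- img + array(rep(mottle, 3), dim = c(h, w, 3))
  if (spec$texture_noise_sd > 0) {
    img <- img + array(rnorm(h * w * 3, sd = spec$texture_noise_sd),
                       dim = c(h, w, 3))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, mask = mask)
}

#' Generate one synthetic histology-like patch
#'
#' @param spec a [patch_spec()].
#' @param seed optional seed overriding `spec$seed` (used when drawing many
#'   patches from one spec).
#' @return list with `image` (`H x W x 3` array in `[0, 1]`) and `mask`
#'   (`H x W` integer array of 0-based classes).
#' @export
generate_patch <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "patch_spec"))
  withr::with_seed(as.integer(seed), {
    rng <- spec$blob_count_range
    n_blobs <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    generate_canvas(spec$height, spec$width, spec,
                    spec$blob_radius_range, n_blobs)
  })
}

#' Generate a reproducible collection of patches
#'
#' Patch `i` is drawn with seed `spec$seed + i - 1`, so the collection is a
#' pure function of the spec.
#'
#' @inheritParams generate_patch
#' @param n number of patches.
#' @return list of `generate_patch()` results.
#' @export
generate_patches <- function(spec, n) {
  lapply(seq_len(n), function(i) generate_patch(spec, seed = spec$seed + i - 1L))
}

#' Split patches into labeled and unlabeled pools
#'
#' Exactly `round(labeled_fraction * N)` patches keep their masks; the rest
#' have masks withheld. The partition is a function of `seed` only.
#'
#' @param patches list of `list(image, mask)` items.
#' @param labeled_fraction proportion in `(0, 1]`.
#' @param seed integer seed for the partition.
#' @return a `patch_dataset` with fields `labeled_items`, `unlabeled_items`,
#'   `n_l`, `n_u`; the chosen labeled indices are kept in the
#'   `labeled_idx` attribute.
#' @export
make_ssl_split <- function(patches, labeled_fraction, seed = 1L) {
  if (length(patches) == 0) stop("empty patch list")
  stopifnot(labeled_fraction > 0, labeled_fraction <= 1)
  n <- length(patches)
  n_l <- round(labeled_fraction * n)
  idx <- sort(withr::with_seed(as.integer(seed), sample.int(n, n_l)))
  labeled <- patches[idx]
  unlabeled <- lapply(patches[setdiff(seq_len(n), idx)],
                      function(it) list(image = it$image))
  structure(
    list(labeled_items = labeled, unlabeled_items = unlabeled,
         n_l = n_l, n_u = n - n_l),
    labeled_idx = idx,
    class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("patch_dataset: %d labeled + %d unlabeled items\n", x$n_l, x$n_u))
  invisible(x)
}

#' Generate a synthetic whole-slide mosaic
#'
#' A `rows x cols` grid of tiles of the spec's patch size, painted with
#' several large blobs whose radii are drawn from 0.35-0.8 of the tile size
#' so that they span tile boundaries; the first blob is centered on an
#' interior tile corner to guarantee a multi-tile region. Used to exercise
#' tiling, stitching and contour export.
#'
#' @param spec a [patch_spec()] (its height/width define the tile size).
#' @param grid integer vector `c(rows, cols)`, at least `c(2, 2)`.
#' @param magnification_factor ratio of slide resolution to working
#'   resolution (e.g. 4 for a 40x slide processed at 10x).
#' @return a `synthetic_wsi` with fields `image`, `mask`,
#'   `magnification_factor`.
#' @export
generate_wsi <- function(spec, grid = c(4, 4), magnification_factor = 4) {
  stopifnot(inherits(spec, "patch_spec"), length(grid) == 2, all(grid >= 2),
            magnification_factor >= 1)
  h <- spec$height * grid[1]
  w <- spec$width * grid[2]
  tile_min <- min(spec$height, spec$width)
  radius_range <- c(0.35, 0.8) * tile_min
  n_blobs <- max(3L, prod(grid) %/% 3L)
  out <- withr::with_seed(spec$seed, {
    res <- generate_canvas(h, w, spec, radius_range, 0L)
    mask <- res$mask
    # first blob pinned to an interior tile corner: guaranteed multi-tile
    mask <- paint_blob(mask, spec$height + 0.5, spec$width + 0.5,
                       runif(1, radius_range[1], radius_range[2]), 1L)
    for (b in seq_len(n_blobs - 1L)) {
      cls <- if (spec$n_classes == 2) 1L else (b %% (spec$n_classes - 1L)) + 1L
      r0 <- runif(1, radius_range[1], radius_range[2])
      mask <- paint_blob(mask, runif(1, r0, h - r0), runif(1, r0, w - r0),
                         r0, cls)
    }
    img <- res$image
    pal <- spec$class_palette
    for (ch in 1:3) {
      base <- matrix(pal[mask + 1L, ch], h, w)
      delta <- base - matrix(pal[1L, ch], h, w)
      img[, , ch] <- pmin(pmax(img[, , ch] + delta, 0), 1)
    }
    list(image = img, mask = mask)
  })
  structure(
    list(image = out$image, mask = out$mask,
         magnification_factor = magnification_factor),
    class = "synthetic_wsi")
}

#' Write a patch dataset to disk
#'
#' Images go to `images/` as 8-bit RGB PNG, masks to `masks/` as
#' single-channel PNG with pixel value = class index. A plain-text manifest
#' (one `path<TAB>labeled-flag` line per item) records the split.
#'
#' @param ds a `patch_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_patch_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "patch_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  for (i in seq_along(ds$labeled_items)) {
    it <- ds$labeled_items[[i]]
    rel <- sprintf("images/labeled_%04d.png", i)
    png::writePNG(it$image, file.path(dir, rel))
    png::writePNG(it$mask / 255, sprintf("%s/masks/labeled_%04d.png", dir, i))
    manifest <- c(manifest, paste(rel, 1, sep = "\t"))
  }
  for (i in seq_along(ds$unlabeled_items)) {
    rel <- sprintf("images/unlabeled_%04d.png", i)
    png::writePNG(ds$unlabeled_items[[i]]$image, file.path(dir, rel))
    manifest <- c(manifest, paste(rel, 0, sep = "\t"))
  }
  path <- file.path(dir, "manifest.txt")
  writeLines(manifest, path)
  invisible(path)
}

#' Read a patch dataset written by [write_patch_dataset()]
#'
#' @param dir dataset directory containing `manifest.txt`.
#' @return a `patch_dataset`.
#' @export
read_patch_dataset <- function(dir) {
  lines <- readLines(file.path(dir, "manifest.txt"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  labeled <- list(); unlabeled <- list()
  for (p in parts) {
    img <- png::readPNG(file.path(dir, p[1]))
    if (p[2] == "1") {
      mpath <- sub("images/", "masks/", p[1], fixed = TRUE)
      mask <- round(png::readPNG(file.path(dir, mpath)) * 255)
      storage.mode(mask) <- "integer"
      labeled[[length(labeled) + 1L]] <- list(image = img, mask = mask)
    } else {
      unlabeled[[length(unlabeled) + 1L]] <- list(image = img)
    }
  }
  structure(list(labeled_items = labeled, unlabeled_items = unlabeled,
                 n_l = length(labeled), n_u = length(unlabeled)),
            class = "patch_dataset")
}

#' Write a synthetic whole-slide mosaic as TIFF
#'
#' @param wsi a `synthetic_wsi`.
#' @param path output TIFF path.
#' @export
write_wsi <- function(wsi, path) {
  tiff::writeTIFF(wsi$image, path)
  invisible(path)
}
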