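# Slide-level tooling: tiling with background filtering and tumor-fraction
# labeling, stitching of per-tile predictions, connected-component contour
# extraction with fixed-interval vertex sampling, and polygon rasterization.

#' Tiling geometry
#'
#' 0-based, half-open tiles `[y, y + patch) x [x, x + patch)`. Tiles must
#' lie fully inside the image unless padding is enabled.
#'
#' @param patch_size tile side in pixels.
#' @param stride step between tile origins; at most `patch_size`.
#' @return a `tile_grid`.
#' @export
tile_grid <- function(patch_size = 512L, stride = 256L) {
  stopifnot(patch_size >= 1, stride >= 1, stride <= patch_size)
  structure(list(patch_size = as.integer(patch_size),
                 stride = as.integer(stride)),
            class = "tile_grid")
}

#' Cut a slide into patches
#'
#' Raster-order tiles at the grid's stride with recorded 0-based offsets.
#' By default only fully-inside tile positions are used (edge remainders
#' are skipped); with `pad = TRUE` edge tiles are zero-padded to the patch
#' size instead.
#'
#' @param wsi a `synthetic_wsi`, or a list with `image` (`H x W x 3`) and
#'   optional `mask`.
#' @param grid a [tile_grid()].
#' @param pad include zero-padded edge tiles.
#' @return list of `list(image, mask, y, x)` tiles.
#' @export
tile_wsi <- function(wsi, grid = tile_grid(), pad = FALSE) {
  img <- wsi$image
  msk <- wsi$mask
  h <- dim(img)[1]; w <- dim(img)[2]
  p <- grid$patch_size; s <- grid$stride
  if (h < p || w < p) stop("image smaller than patch_size")
  ys <- seq(0L, h - p, by = s)
  xs <- seq(0L, w - p, by = s)
  if (pad) {
    if (max(ys) + p < h) ys <- c(ys, max(ys) + s)
    if (max(xs) + p < w) xs <- c(xs, max(xs) + s)
  }
  tiles <- list()
  for (y in ys) for (x in xs) {
    ii <- (y + 1L):min(y + p, h)
    jj <- (x + 1L):min(x + p, w)
    im <- array(0, dim = c(p, p, dim(img)[3]))
    im[seq_along(ii), seq_along(jj), ] <- img[ii, jj, , drop = FALSE]
    mk <- NULL
    if (!is.null(msk)) {
      mk <- matrix(0L, p, p)
      mk[seq_along(ii), seq_along(jj)] <- msk[ii, jj]
    }
    tiles[[length(tiles) + 1L]] <- list(image = im, mask = mk,
                                        y = as.integer(y), x = as.integer(x))
  }
  tiles
}

#' Background filter for tissue patches
#'
#' A pixel counts as background when its minimum RGB channel exceeds the
#' whiteness threshold (near-white, the standard slide-background
#' heuristic). The patch is kept iff the background fraction does not
#' exceed `background_fraction_threshold`; patches with more than that
#' fraction of background are excluded.
#'
#' @param tile_image `H x W x 3` array in `[0, 1]`.
#' @param background_fraction_threshold exclusion threshold (default 0.5).
#' @param white_threshold per-channel whiteness cutoff (default 0.85).
#' @return `TRUE` to keep the patch.
#' @export
filter_patch <- function(tile_image, background_fraction_threshold = 0.5,
                         white_threshold = 0.85) {
  mn <- pmin(tile_image[, , 1], tile_image[, , 2], tile_image[, , 3])
  mean(mn > white_threshold) <= background_fraction_threshold
}

#' Tumor-fraction patch label
#'
#' A patch is labeled `"tumor"` iff the fraction of tumor pixels strictly
#' exceeds the threshold; a fraction exactly at the threshold is
#' `"non-tumor"`.
#'
#' @param tile_mask integer mask.
#' @param tumor_fraction_threshold default 0.25.
#' @param tumor_classes class indices counted as tumor.
#' @return `"tumor"` or `"non-tumor"`.
#' @export
label_patch <- function(tile_mask, tumor_fraction_threshold = 0.25,
                        tumor_classes = 1L) {
  frac <- mean(tile_mask %in% tumor_classes)
  if (frac > tumor_fraction_threshold) "tumor" else "non-tumor"
}

#' Stitch per-tile predictions into a slide-level label map
#'
#' Tiles may carry probability maps (`K x p x p`, element `prob`) or hard
#' label maps (`p x p`, element `label` or `mask`; converted to one-hot).
#' Where tiles overlap (stride < patch), probabilities are averaged before
#' the argmax (`method = "average"`); `method = "last"` gives
#' last-write-wins. Canvas area covered by no tile is filled as background
#' with a warning.
#'
#' @param tiles list of `list(prob | label, y, x)`.
#' @param canvas_size integer `c(H, W)`.
#' @param n_classes number of classes (inferred from probability tiles).
#' @param method overlap resolution.
#' @return list with `label` (`H x W` integer map), `prob`
#'   (`K x H x W` averaged probabilities) and `covered` (logical matrix).
#' @export
stitch <- function(tiles, canvas_size, n_classes = NULL,
                   method = c("average", "last")) {
  method <- match.arg(method)
  stopifnot(length(tiles) >= 1)
  get_prob <- function(tl) {
    if (!is.null(tl$prob)) return(tl$prob)
    lab <- if (!is.null(tl$label)) tl$label else tl$mask
    if (is.null(n_classes)) n_classes <<- max(lab) + 1L
    one_hot(lab, max(n_classes, max(lab) + 1L))
  }
  p0 <- get_prob(tiles[[1]])
  k <- dim(p0)[1]
  h <- canvas_size[1]; w <- canvas_size[2]
  acc <- array(0, dim = c(k, h, w))
  cnt <- matrix(0L, h, w)
  for (tl in tiles) {
    pr <- get_prob(tl)
    ph <- dim(pr)[2]; pw <- dim(pr)[3]
    ii <- (tl$y + 1L):min(tl$y + ph, h)
    jj <- (tl$x + 1L):min(tl$x + pw, w)
    if (tl$y + ph > h || tl$x + pw > w) {
      pr <- pr[, seq_along(ii), seq_along(jj), drop = FALSE]
    }
    if (method == "average") {
      acc[, ii, jj] <- acc[, ii, jj] + pr
      cnt[ii, jj] <- cnt[ii, jj] + 1L
    } else {
      acc[, ii, jj] <- pr
      cnt[ii, jj] <- 1L
    }
  }
  if (any(cnt == 0)) {
    warning("stitch: ", sum(cnt == 0),
            " uncovered pixels filled as background")
    acc[1, , ][cnt == 0] <- 1
    cnt[cnt == 0] <- 1L
  }
  for (c in seq_len(k)) acc[c, , ] <- acc[c, , ] / cnt
  lab <- apply(acc, c(2, 3), which.max) - 1L
  storage.mode(lab) <- "integer"
  list(label = lab, prob = acc, covered = cnt > 0)
}

# 8-connected component labeling by vectorized frontier flood fill
label_components_8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  todo <- mask > 0
  offsets <- expand.grid(di = -1:1, dj = -1:1)
  offsets <- offsets[!(offsets$di == 0 & offsets$dj == 0), ]
  cur <- 0L
  seeds <- which(todo)
  for (s in seeds) {
    if (!todo[s]) next
    cur <- cur + 1L
    frontier <- s
    while (length(frontier)) {
      lab[frontier] <- cur
      todo[frontier] <- FALSE
      i <- ((frontier - 1L) %% h) + 1L
      j <- ((frontier - 1L) %/% h) + 1L
      nbrs <- integer(0)
      for (r in seq_len(nrow(offsets))) {
        ni <- i + offsets$di[r]; nj <- j + offsets$dj[r]
        ok <- ni >= 1 & ni <= h & nj >= 1 & nj <= w
        if (any(ok)) nbrs <- c(nbrs, ni[ok] + (nj[ok] - 1L) * h)
      }
      nbrs <- unique(nbrs)
      frontier <- nbrs[todo[nbrs]]
    }
  }
  lab
}

# Moore-neighbor boundary tracing (8-connectivity, Jacob's stopping
# criterion: terminate on re-entering the start pixel from the starting
# backtrack).  Returns the ordered chain of boundary pixels as an n x 2
# matrix of (row, col), 1-based.
trace_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- function(i, j) i >= 1 && i <= h && j >= 1 && j <= w && mask[i, j]
  start_lin <- which(mask)[1]
  si <- ((start_lin - 1L) %% h) + 1L
  sj <- ((start_lin - 1L) %/% h) + 1L
  # clockwise neighbor ring starting at W; the start pixel is the first
  # foreground pixel in scan order, so its west neighbor is background
  ring <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                 ncol = 2, byrow = TRUE)
  npix <- sum(mask)
  chain <- matrix(0L, 4L * npix + 8L, 2)
  chain[1, ] <- c(si, sj)
  n <- 1L
  pi <- si; pj <- sj
  bi <- si; bj <- sj - 1L
  b0i <- bi; b0j <- bj
  repeat {
    d_idx <- which(ring[, 1] == bi - pi & ring[, 2] == bj - pj)
    found <- FALSE
    ni <- 0L; nj <- 0L
    for (t in 1:8) {
      idx <- ((d_idx + t - 1L) %% 8L) + 1L
      ni <- pi + ring[idx, 1]; nj <- pj + ring[idx, 2]
      if (fg(ni, nj)) { found <- TRUE; break }
      bi <- ni; bj <- nj       # last background neighbor examined
    }
    if (!found) break          # isolated pixel
    pi <- ni; pj <- nj
    if (pi == si && pj == sj && bi == b0i && bj == b0j) break
    n <- n + 1L
    chain[n, ] <- c(pi, pj)
    if (n >= 4L * npix) break  # safety bound for degenerate shapes
  }
  chain[seq_len(n), , drop = FALSE]
}

#' Polygon annotation document
#'
#' @param polygons list of polygons, each `list(name, group, coords)` with
#'   `coords` an `n x 3` matrix of columns `order`, `x`, `y` (0-based
#'   vertex order, slide coordinates).
#' @param magnification_factor scalar scaling already applied to the
#'   coordinates.
#' @return an `annotation_document`.
#' @export
annotation_document <- function(polygons = list(), magnification_factor = 1) {
  for (p in polygons) {
    stopifnot(nrow(p$coords) >= 3, all(p$coords[, "order"] ==
                                         seq_len(nrow(p$coords)) - 1L))
  }
  structure(list(polygons = polygons,
                 magnification_factor = magnification_factor),
            class = "annotation_document")
}

#' @export
print.annotation_document <- function(x, ...) {
  cat(sprintf("annotation_document: %d polygon(s), magnification factor %g\n",
              length(x$polygons), x$magnification_factor))
  invisible(x)
}

#' Extract sampled contours from a label map
#'
#' Traces the boundary of every 8-connected foreground component
#' (Moore-neighbor tracing), keeps every `sample_interval`-th boundary
#' pixel along the traced chain (the first vertex is always kept), scales
#' the 0-based pixel coordinates by the magnification factor and collects
#' the polygons into an [annotation_document()]. Components whose sampled
#' chain has fewer than 3 vertices are dropped.
#'
#' @param label_map `H x W` integer map; foreground is `value > 0`, or
#'   `value == class` when `class` is given.
#' @param sample_interval boundary sampling interval in pixels (default 15).
#' @param magnification_factor coordinate scaling to slide space.
#' @param class optional single class to contour.
#' @param group annotation group name in the document.
#' @return an `annotation_document`.
#' @export
extract_contours <- function(label_map, sample_interval = 15L,
                             magnification_factor = 1,
                             class = NULL, group = "tumor") {
  fg <- if (is.null(class)) label_map > 0 else label_map == class
  comps <- label_components_8(fg)
  polys <- list()
  for (cid in seq_len(max(comps, 0L))) {
    comp <- comps == cid
    if (sum(comp) < 3) next
    chain <- trace_boundary(comp)
    keep <- seq(1L, nrow(chain), by = sample_interval)
    if (length(keep) < 3) next
    pts <- chain[keep, , drop = FALSE]
    coords <- cbind(order = seq_along(keep) - 1L,
                    x = (pts[, 2] - 1) * magnification_factor,
                    y = (pts[, 1] - 1) * magnification_factor)
    polys[[length(polys) + 1L]] <- list(
      name = sprintf("Annotation %d", length(polys)),
      group = group, coords = coords)
  }
  annotation_document(polys, magnification_factor)
}

#' Rasterize a polygon into a binary mask
#'
#' Even-odd scanline fill over 0-based integer pixel centers; used to check
#' contour fidelity against the source mask.
#'
#' @param xs,ys polygon vertex coordinates (0-based pixel space).
#' @param h,w output mask size.
#' @return `H x W` logical matrix.
#' @export
rasterize_polygon <- function(xs, ys, h, w) {
  n <- length(xs)
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  out <- matrix(FALSE, h, w)
  centers <- 0:(w - 1)
  for (row in seq_len(h)) {
    y0 <- row - 1
    crosses <- (ys <= y0 & y2 > y0) | (y2 <= y0 & ys > y0)
    if (!any(crosses)) next
    xi <- xs[crosses] + (y0 - ys[crosses]) *
      (x2[crosses] - xs[crosses]) / (y2[crosses] - ys[crosses])
    xi <- sort(xi)
    for (q in seq(1, length(xi) - 1, by = 2)) {
      sel <- centers >= xi[q] & centers < xi[q + 1]
      out[row, sel] <- TRUE
    }
  }
  out
}

#' Full slide annotation pipeline
#'
#' Tiles a slide, predicts every tile with the model, stitches the
#' probability maps, extracts sampled contours and returns the annotation
#' document in slide coordinates.
#'
#' @param net a trained `seg_network`.
#' @param wsi a `synthetic_wsi` (or list with `image` and
#'   `magnification_factor`).
#' @param grid a [tile_grid()] whose patch size is divisible by
#'   `2^encoder_depth`.
#' @param sample_interval contour sampling interval.
#' @return an `annotation_document`.
#' @export
annotate_wsi <- function(net, wsi, grid = tile_grid(),
                         sample_interval = 15L) {
  tiles <- tile_wsi(wsi, grid)
  k <- net$config$n_classes
  pred_tiles <- lapply(tiles, function(tl) {
    pr <- forward(net, tl$image)
    p <- if (net$config$use_msc) pr$maps$p0 else pr$maps[[length(pr$maps)]]
    list(prob = p, y = tl$y, x = tl$x)
  })
  st <- stitch(pred_tiles, dim(wsi$image)[1:2], n_classes = k)
  extract_contours(st$label, sample_interval,
                   magnification_factor = wsi$magnification_factor)
}
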