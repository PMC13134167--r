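# Slide tooling: tiling, filtering/labeling rules, stitching, contour
# extraction, and ASAP XML round-trips.

flat_image <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

test_that("tiling geometry: counts, offsets, content reconstruction", {
  spec <- patch_spec(height = 256, width = 256, seed = 70,
                     blob_radius_range = c(20, 60))
  wsi <- generate_wsi(spec, grid = c(4, 4))   # 1024 x 1024
  g <- tile_grid(512, 256)
  tiles <- tile_wsi(wsi, g)
  expect_length(tiles, 9)                      # (floor(512/256)+1)^2
  # single fully-inside position at stride 256 on a 512 canvas
  small <- list(image = wsi$image[1:512, 1:512, ], mask = wsi$mask[1:512, 1:512])
  expect_length(tile_wsi(small, g), 1)
  # offsets reconstruct the tile content exactly
  t5 <- tiles[[5]]
  expect_identical(t5$image,
                   wsi$image[t5$y + 1:512, t5$x + 1:512, , drop = FALSE])
  expect_identical(t5$mask, wsi$mask[t5$y + 1:512, t5$x + 1:512])
  expect_error(tile_grid(256, 512))            # stride > patch
})

test_that("background filter keeps tissue and drops white patches", {
  white <- flat_image(20, 20, c(0.97, 0.96, 0.98))
  tissue <- flat_image(20, 20, c(0.85, 0.6, 0.75))
  expect_false(filter_patch(white))
  expect_true(filter_patch(tissue))
  # exactly 60% white excluded, 40% white kept
  mixed60 <- tissue; mixed60[1:12, , ] <- 0.95
  mixed40 <- tissue; mixed40[1:8, , ] <- 0.95
  expect_false(filter_patch(mixed60))
  expect_true(filter_patch(mixed40))
})

test_that("tumor labeling uses a strict 25% threshold", {
  m <- matrix(0L, 100, 100)
  m[seq_len(2600)] <- 1L
  expect_equal(label_patch(m), "tumor")          # 26%
  m25 <- matrix(0L, 100, 100); m25[seq_len(2500)] <- 1L
  expect_equal(label_patch(m25), "non-tumor")    # exactly 25%
  expect_equal(label_patch(matrix(0L, 10, 10)), "non-tumor")
})

test_that("stitching: identity, overlap averaging, inverse of tiling", {
  # single tile covering the canvas
  lab <- matrix(sample(0:1, 64 * 64, replace = TRUE), 64, 64)
  st <- stitch(list(list(label = lab, y = 0L, x = 0L)), c(64, 64),
               n_classes = 2)
  expect_identical(st$label, lab)
  # identical half-overlapping tiles change nothing
  p <- one_hot(lab, 2)
  st2 <- stitch(list(list(prob = p, y = 0L, x = 0L),
                     list(prob = p, y = 0L, x = 0L)), c(64, 64))
  expect_identical(st2$label, lab)
  # conflicting foreground probabilities average before the argmax
  pa <- array(c(0.2, 0.8), dim = c(2, 1, 1))
  pb <- array(c(0.6, 0.4), dim = c(2, 1, 1))
  st3 <- stitch(list(list(prob = pa, y = 0L, x = 0L),
                     list(prob = pb, y = 0L, x = 0L)), c(1, 1))
  expect_equal(st3$prob[2, 1, 1], 0.6)
  expect_equal(st3$label[1, 1], 1L)
  # last-write-wins mode
  st4 <- stitch(list(list(prob = pa, y = 0L, x = 0L),
                     list(prob = pb, y = 0L, x = 0L)), c(1, 1),
                method = "last")
  expect_equal(st4$label[1, 1], 0L)
  # uncovered canvas area becomes background with a warning
  expect_warning(
    st5 <- stitch(list(list(label = lab, y = 0L, x = 0L)), c(64, 100),
                  n_classes = 2), "uncovered")
  expect_true(all(st5$label[, 65:100] == 0L))
  # stitch . tile is the identity at stride = patch
  spec <- patch_spec(height = 64, width = 64, seed = 71,
                     blob_radius_range = c(10, 25))
  wsi <- generate_wsi(spec, grid = c(4, 4))
  tiles <- tile_wsi(wsi, tile_grid(64, 64))
  ltiles <- lapply(tiles, function(t) list(label = t$mask, y = t$y, x = t$x))
  st6 <- stitch(ltiles, dim(wsi$mask), n_classes = 2)
  expect_identical(st6$label, wsi$mask)
})

test_that("boundary tracing of a filled square yields the known chain", {
  m <- matrix(FALSE, 80, 80)
  m[11:70, 11:70] <- TRUE                       # 60 x 60 square
  chain <- dcseg:::trace_boundary(m)
  expect_equal(nrow(chain), 4 * 60 - 4)         # 236 boundary pixels
  doc <- extract_contours(matrix(as.integer(m), 80, 80),
                          sample_interval = 15)
  expect_length(doc$polygons, 1)
  expect_equal(nrow(doc$polygons[[1]]$coords), ceiling(236 / 15)) # 16
})

test_that("contours scale by the magnification factor exactly", {
  m <- matrix(0L, 40, 40); m[10:30, 10:30] <- 1L
  d1 <- extract_contours(m, sample_interval = 5, magnification_factor = 1)
  d4 <- extract_contours(m, sample_interval = 5, magnification_factor = 4)
  expect_equal(d4$polygons[[1]]$coords[, c("x", "y")],
               d1$polygons[[1]]$coords[, c("x", "y")] * 4)
})

test_that("tiny components are dropped from the annotation", {
  m <- matrix(0L, 20, 20)
  m[3, 4:5] <- 1L                               # 2-pixel component
  doc <- extract_contours(m, sample_interval = 15)
  expect_length(doc$polygons, 0)
})

test_that("contour fidelity: rasterized polygon matches a round blob", {
  spec <- patch_spec(height = 128, width = 128, seed = 73,
                     blob_count_range = c(1, 1),
                     blob_radius_range = c(30, 40))
  p <- generate_patch(spec)
  doc <- extract_contours(p$mask, sample_interval = 15)
  expect_length(doc$polygons, 1)
  co <- doc$polygons[[1]]$coords
  ras <- rasterize_polygon(co[, "x"], co[, "y"], 128, 128)
  inter <- sum(ras & p$mask > 0)
  union <- sum(ras | p$mask > 0)
  expect_gte(inter / union, 0.9)
})

test_that("ASAP XML round-trips documents losslessly", {
  tri <- list(name = "Annotation 0", group = "tumor",
              coords = cbind(order = 0:2, x = c(1.5, 20, 7.25),
                             y = c(2, 8.125, 30)))
  doc <- annotation_document(list(tri), magnification_factor = 4)
  path <- tempfile(fileext = ".xml")
  write_asap_xml(doc, path)
  back <- read_asap_xml(path, magnification_factor = 4)
  expect_length(back$polygons, 1)
  expect_equal(back$polygons[[1]]$coords, tri$coords)
  expect_equal(back$polygons[[1]]$name, "Annotation 0")
  expect_equal(back$polygons[[1]]$group, "tumor")
  # schema elements are the ASAP dialect
  xml <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(xml), "ASAP_Annotations")
  ann <- xml2::xml_find_first(xml, ".//Annotation")
  expect_equal(xml2::xml_attr(ann, "Type"), "Polygon")
  expect_equal(length(xml2::xml_find_all(xml, ".//Coordinate")), 3)
  expect_equal(length(xml2::xml_find_all(xml, ".//AnnotationGroups/Group")), 1)
  # empty document still writes a valid file
  path2 <- tempfile(fileext = ".xml")
  write_asap_xml(annotation_document(), path2)
  expect_length(read_asap_xml(path2)$polygons, 0)
  # malformed input fails loudly
  bad <- tempfile(fileext = ".xml")
  writeLines("<ASAP_Annotations><Annotations>", bad)
  expect_error(read_asap_xml(bad))
  notasap <- tempfile(fileext = ".xml")
  writeLines("<Other/>", notasap)
  expect_error(read_asap_xml(notasap), "root element")
})

test_that("polygon vertex validation rejects malformed documents", {
  two <- list(name = "a", group = "g",
              coords = cbind(order = 0:1, x = c(1, 2), y = c(1, 2)))
  expect_error(annotation_document(list(two)))
  misordered <- list(name = "a", group = "g",
                     coords = cbind(order = c(0, 2, 1), x = 1:3, y = 1:3))
  expect_error(annotation_document(list(misordered)))
})
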