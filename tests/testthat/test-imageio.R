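test_that("calibrated TIFF read/write round-trips and validates inputs", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  img <- calibrated_image(matrix(0, 100, 100), 0.5)
  write_calibrated_image(img, tmp)
  back <- read_calibrated_image(tmp, 0.5)
  expect_equal(dim(back$pixels), c(100L, 100L))
  expect_true(all(back$pixels == 0))
  expect_equal(back$scale_um_per_px, 0.5)

  expect_error(read_calibrated_image(tmp, -1), "positive")
  expect_error(read_calibrated_image(file.path(tempdir(), "nope.tif"), 0.5))

  # 16-bit content round trip
  px <- matrix(sample(0:65535, 40 * 30, replace = TRUE), 40, 30)
  write_calibrated_image(calibrated_image(px, 1.3), tmp, bits = 16L)
  expect_identical(read_calibrated_image(tmp, 1.3)$pixels, px + 0)

  # masks: 0/255 storage, lossless
  m <- binary_mask(matrix(runif(50 * 70) > 0.5, 50, 70), 0.5)
  write_mask(m, tmp)
  expect_identical(read_mask(tmp, 0.5)$pixels, m$pixels)
})

test_that("non-grayscale and corrupt TIFFs are rejected", {
  tmp <- withr::local_tempfile(fileext = ".tif")
  writeBin(as.raw(1:64), tmp)
  expect_error(read_calibrated_image(tmp, 0.5), "TIFF")
  # craft an RGB TIFF header by patching SamplesPerPixel
  img <- calibrated_image(matrix(1, 4, 4), 1)
  write_calibrated_image(img, tmp, bits = 8L)
  raw <- readBin(tmp, "raw", file.size(tmp))
  # entry 7 (tag 277) value offset: 8 header + 16 data + pad? locate tag 277
  for (i in seq(1, length(raw) - 12)) {
    if (raw[i] == as.raw(0x15) && raw[i + 1] == as.raw(0x01)) {
      raw[i + 8] <- as.raw(3)
      break
    }
  }
  writeBin(raw, tmp)
  expect_error(read_mask(tmp, 1), "multi-channel")
})

test_that("point CSV and GeoJSON outlines round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  ps <- point_set(cbind(c(1.5, 2.25, 2.25), c(10, 20, 20)), "obs1",
                  area_um2 = c(12, 9, 9))
  write_points_csv(ps, tmp)
  back <- read_points_csv(tmp, "obs1")
  expect_equal(back$points, ps$points)
  expect_equal(back$area_um2, ps$area_um2)
  expect_equal(n_duplicate_points(back), 1L)

  gj <- withr::local_tempfile(fileext = ".geojson")
  outl <- region_outline(list(list(
    outer = cbind(c(0, 100, 100, 0), c(0, 0, 80, 80)),
    holes = list(cbind(c(20, 40, 40, 20), c(20, 20, 40, 40))))),
    label = "cortex+OSOM")
  write_outline_geojson(outl, gj)
  back <- read_outline_geojson(gj)
  expect_equal(back$label, "cortex+OSOM")
  expect_equal(outline_area_um2(back), 100 * 80 - 20 * 20)
})

test_that("file-name metadata follows the six-field convention", {
  md <- parse_section_metadata("WT_GFP_M_0001_IRI14_Kim1.tif")
  expect_equal(md$stain, "Kim1")
  expect_equal(md$condition, "IRI14")
  expect_equal(md$source_id, "WT_GFP_M_0001_IRI14_Kim1")
  md2 <- parse_section_metadata("some-other-layout.tif")
  expect_equal(md2$source_id, "some-other-layout")
  expect_null(md2$stain)
})

test_that("rasterize_outline follows the pixel-center convention", {
  template <- calibrated_image(matrix(0, 100, 100), 0.5)
  sq <- region_outline(cbind(c(0, 50, 50, 0), c(0, 0, 50, 50)))
  m <- rasterize_outline(sq, template)
  expect_equal(sum(m$pixels), 100L * 100L)
  expect_true(all(m$pixels[1:100, 1:100]))

  far <- region_outline(cbind(c(500, 600, 600, 500), c(500, 500, 600, 600)))
  expect_error(rasterize_outline(far, template), "empty-region")
})

test_that("rasterized area with holes matches brute-force point-in-polygon", {
  template <- calibrated_image(matrix(0, 120, 120), 1)
  outer <- cbind(c(10, 110, 110, 10), c(10, 10, 110, 110))
  hole <- cbind(c(40, 70, 70, 40), c(40, 40, 70, 70))
  outl <- region_outline(list(list(outer = outer, holes = list(hole))))
  m <- rasterize_outline(outl, template)

  brute <- 0L
  for (r in 1:120) for (c in 1:120) {
    x <- (c - 0.5); y <- (r - 0.5)
    if (oracle_point_in_polygon(x, y, outer) &&
        !oracle_point_in_polygon(x, y, hole)) brute <- brute + 1L
  }
  expect_equal(sum(m$pixels), brute)
  # shoelace agreement within one pixel row per edge (8 edges)
  shoe <- shoelace <- (100 * 100 - 30 * 30)
  expect_lt(abs(sum(m$pixels) - shoe), 8 * 120)
})

test_that("raster/vector area agreement tightens with resolution", {
  sq <- region_outline(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
  template <- calibrated_image(matrix(0, 1000, 1000), 1)
  m <- rasterize_outline(sq, template)
  expect_lt(abs(sum(m$pixels) * 1 - outline_area_um2(sq)) /
              outline_area_um2(sq), 0.02)
})

test_that("montage tiles row-major with blank trailing cells", {
  masks <- lapply(1:5, function(i)
    binary_mask(matrix(i %% 2 == 0, 64, 64), 1))
  m4 <- make_montage(masks[1:4], columns = 2L, tile_px = 32L)
  expect_equal(dim(m4$pixels), c(2 * 32, 2 * 32))
  m5 <- make_montage(masks, columns = 2L, tile_px = 32L)
  expect_equal(dim(m5$pixels), c(3 * 32, 2 * 32))
  # last cell blank
  expect_true(all(m5$pixels[65:96, 33:64] == 0))
  m1 <- make_montage(masks[2], columns = 1L, tile_px = 32L)
  expect_equal(dim(m1$pixels), c(32, 32))
  expect_true(all(m1$pixels == 180))
  expect_error(make_montage(list()), ">= 1")
})
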