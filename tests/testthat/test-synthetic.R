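small_spec <- function(...) {
  scene_spec(width_mm = 1, height_mm = 0.8, scale_um_per_px = 2, ...)
}

test_that("scenes are bitwise reproducible from the seed", {
  a <- generate_scene(small_spec(seed = 3L))
  b <- generate_scene(small_spec(seed = 3L))
  expect_identical(a$images$memA$pixels, b$images$memA$pixels)
  expect_identical(a$truth$masks$nucA$pixels, b$truth$masks$nucA$pixels)
  expect_identical(a$truth$points$nucA$points, b$truth$points$nucA$points)
  c <- generate_scene(small_spec(seed = 4L))
  expect_false(identical(a$images$memA$pixels, c$images$memA$pixels))
})

test_that("object counts follow the Poisson expectation", {
  # nucleus density 100/mm^2 over a region of known area
  spec <- scene_spec(width_mm = 2.6, height_mm = 2.2, scale_um_per_px = 2,
                     seed = 9L)
  scene <- generate_scene(spec)
  area_mm2 <- sum(scene$truth$region$pixels) * (2 / 1000)^2
  expected <- 100 * area_mm2
  got <- nrow(scene$truth$points$nucA$points)
  expect_lt(abs(got - expected), 3 * sqrt(expected))
})

test_that("ground truth is internally consistent", {
  scene <- generate_scene(small_spec(seed = 5L))
  pts <- scene$truth$points$nucA$points
  mask <- scene$truth$masks$nucA
  s <- mask$scale_um_per_px
  inside <- 0L
  for (i in seq_len(nrow(pts))) {
    r <- floor(pts[i, 2] / s) + 1L; c <- floor(pts[i, 1] / s) + 1L
    if (r >= 1 && r <= nrow(mask$pixels) && c >= 1 && c <= ncol(mask$pixels) &&
        mask$pixels[r, c]) inside <- inside + 1L
  }
  # centers in the region have their own blob under them (only nuclei whose
  # disk was clipped off by the section boundary may miss)
  expect_gte(inside / nrow(pts), 0.95)
  # membrane truth: rims are hollow (fill_holes adds area)
  mem <- scene$truth$masks$memA
  expect_gt(sum(fill_holes(mem)$pixels), sum(mem$pixels))
})

test_that("infeasible correlation targets raise a spec error", {
  ch <- default_channels()
  ch$memA$density_per_mm2 <- 0.5 # almost no objects: huge attenuation
  expect_error(generate_scene(small_spec(channels = ch, rho = 0.9, seed = 1L)),
               "spec error")
})

test_that("degrade preserves identity, mean intensity and raises on upsampling", {
  scene <- generate_scene(small_spec(seed = 6L))
  img <- scene$images$nucA
  expect_identical(degrade(img, img$scale_um_per_px), img)
  deg <- degrade(img, 5.2)
  expect_equal(deg$scale_um_per_px, 5.2, tolerance = 0.02)
  expect_equal(mean(deg$pixels), mean(img$pixels), tolerance = 0.01)
  expect_error(degrade(deg, 2), "finer")
})

test_that("degrading to 1.3 um/px keeps detections and area fraction stable", {
  # the resolution-robustness fixture: 0.5 -> 1.3 um/px
  spec <- scene_spec(width_mm = 1.2, height_mm = 1, scale_um_per_px = 0.5,
                     seed = 8L)
  scene <- generate_scene(spec)
  region <- scene$truth$region

  # nuclear channel: threshold the degraded image and count detections
  img0 <- scene$images$nucA
  img1 <- degrade(img0, 1.3)
  thr0 <- auto_threshold(img0, "otsu")$mask
  thr1 <- auto_threshold(img1, "otsu")$mask
  n0 <- nrow(detect_nuclei(thr0, 9)$points)
  n1 <- nrow(detect_nuclei(thr1, 9)$points)
  expect_lt(abs(n1 - n0) / n0, 0.05)

  # membrane channel: area fraction from the segmentation carried to the
  # coarser grid (segmentation quality at low resolution is the external
  # segmenter's concern; the measurement chain must stay stable)
  deg_mask <- function(m, target) {
    img <- calibrated_image(matrix(as.numeric(m$pixels), nrow(m$pixels)),
                            m$scale_um_per_px)
    d <- degrade(img, target)
    binary_mask(d$pixels > 0.5, d$scale_um_per_px)
  }
  m0 <- scene$truth$masks$memA
  af0 <- area_fraction(m0, region)
  af1 <- area_fraction(deg_mask(m0, 1.3), deg_mask(region, 1.3))
  expect_lt(abs(af1 - af0) / af0, 0.02)

  # and the nuclear counts from the degraded mask representation
  nm0 <- nrow(detect_nuclei(scene$truth$masks$nucA, 9)$points)
  nm1 <- nrow(detect_nuclei(deg_mask(scene$truth$masks$nucA, 1.3), 9)$points)
  expect_lt(abs(nm1 - nm0) / nm0, 0.05)
})

test_that("otsu on a high-contrast scene recovers the true mask at Dice >= 0.9", {
  scene <- generate_scene(small_spec(seed = 10L))
  for (ch in c("memA", "nucA")) {
    pre <- rolling_ball_subtract(scene$images[[ch]], 50)
    got <- auto_threshold(pre$image, "otsu")$mask
    pm <- pixel_metrics(scene$truth$masks[[ch]], got)
    expect_gte(pm$dice, 0.9)
  }
})
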