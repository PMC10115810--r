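test_that("density heatmap reproduces constant fields and kernel counts", {
  region <- binary_mask(matrix(TRUE, 60, 60), 10)
  all_on <- binary_mask(matrix(TRUE, 60, 60), 10)
  hm <- density_heatmap(all_on, region, radius_um = 100)
  # full-kernel denominator: exactly 1 wherever the kernel fits (valid);
  # frame-edge pixels are flagged invalid, not renormalized
  expect_true(all(abs(hm$values[hm$valid] - 1) < 1e-9))
  expect_true(any(hm$valid))
  expect_false(all(hm$valid))

  none <- binary_mask(matrix(FALSE, 60, 60), 10)
  hm0 <- density_heatmap(none, region, radius_um = 100)
  expect_true(all(abs(hm0$values) < 1e-9))

  single <- binary_mask(matrix(FALSE, 60, 60), 10)
  single$pixels[30, 30] <- TRUE
  hm1 <- density_heatmap(single, region, radius_um = 100)
  # brute-force discrete kernel count for radius 10 px
  cnt <- sum(outer((-10:10)^2, (-10:10)^2, "+") <= 10^2)
  expect_equal(hm1$kernel_px, cnt)
  expect_equal(hm1$values[30, 30], 1 / cnt, tolerance = 1e-9)

  expect_error(density_heatmap(all_on, region, radius_um = 5), "one pixel")
})

test_that("heatmap mass is conserved away from boundaries", {
  set.seed(51)
  px <- matrix(FALSE, 200, 200)
  px[31:170, 31:170] <- runif(140 * 140) < 0.2 # margin wider than the kernel
  mask <- binary_mask(px, 1)
  region <- binary_mask(matrix(TRUE, 200, 200), 1)
  hm <- density_heatmap(mask, region, radius_um = 10)
  # every true pixel's kernel lies inside the frame: exact conservation
  expect_equal(sum(hm$values, na.rm = TRUE), sum(mask$pixels),
               tolerance = 1e-6)
  # interior values are exact local fractions: spot-check against brute force
  for (k in 1:5) {
    r <- sample(30:170, 1); c <- sample(30:170, 1)
    patch <- mask$pixels[(r - 10):(r + 10), (c - 10):(c + 10)]
    ker <- outer((-10:10)^2, (-10:10)^2, "+") <= 100
    expect_equal(hm$values[r, c], mean(patch[ker]) * sum(ker) / hm$kernel_px,
                 tolerance = 1e-9)
  }
})

test_that("circle tiling satisfies packing, containment and the square oracle", {
  r <- 200
  sq <- square_outline(10 * r)
  tiles <- tile_region(sq, r)
  n <- nrow(tiles$centers_um)
  expect_equal(n, oracle_hex_count_square(10 * r, r))
  # pairwise non-overlap
  d <- as.matrix(dist(tiles$centers_um))
  diag(d) <- Inf
  expect_gte(min(d), 2 * r - 1e-9)
  # containment
  expect_true(all(tiles$centers_um >= r - 1e-9 &
                  tiles$centers_um <= 10 * r - r + 1e-9))

  # packing fraction approaches pi/(2*sqrt(3)) on a large square
  big <- square_outline(40 * r)
  bt <- tile_region(big, r)
  frac <- nrow(bt$centers_um) * pi * r^2 / (40 * r)^2
  expect_lt(frac, pi / (2 * sqrt(3)))
  expect_gt(frac, pi / (2 * sqrt(3)) * 0.9)
})

test_that("a disk of radius 1.5r holds exactly the one concentric circle", {
  r <- 100
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  disk <- region_outline(cbind(500 + 1.5 * r * cos(th),
                               500 + 1.5 * r * sin(th)))
  tiles <- tile_region(disk, r, anchor = c(500, 500))
  expect_equal(nrow(tiles$centers_um), 1L)
  expect_equal(unname(tiles$centers_um[1, ]), c(500, 500), tolerance = 1e-6)
  tiny <- region_outline(cbind(c(0, 50, 50, 0), c(0, 0, 50, 50)))
  expect_warning(t0 <- tile_region(tiny, r), "no circle")
  expect_equal(nrow(t0$centers_um), 0L)
})

test_that("tile densities follow mask fractions and point arithmetic", {
  r <- 200
  sq <- square_outline(6 * r)
  tiles <- tile_region(sq, r)
  n <- nrow(tiles$centers_um)
  expect_gt(n, 0)
  all_on <- binary_mask(matrix(TRUE, 240, 240), 5) # 1200x1200 um
  # restrict tiles to those inside the raster frame
  keep <- tiles$centers_um[, 1] <= 1200 - r & tiles$centers_um[, 2] <= 1200 - r
  tiles$centers_um <- tiles$centers_um[keep, , drop = FALSE]
  pts <- point_set(tiles$centers_um[1, , drop = FALSE]) # one point in tile 1
  tab <- tile_densities(tiles, all_on, pts)
  expect_true(all(abs(tab$density_a - 1) < 1e-9))
  expect_equal(tab$density_b[1], 1 / (pi * r^2 / 1e6), tolerance = 1e-9)
  expect_true(all(tab$density_b[-1] == 0))

  empty_tiles <- tiles
  empty_tiles$centers_um <- tiles$centers_um[0, , drop = FALSE]
  expect_equal(nrow(tile_densities(empty_tiles, all_on, pts)), 0L)
})

test_that("pearson correlation handles exact and null relationships", {
  x <- c(0.1, 0.4, 0.2, 0.8, 0.5)
  tab <- data.frame(density_a = x, density_b = 2 * x + 1)
  expect_equal(pearson_correlation(tab)$r, 1)
  tab2 <- data.frame(density_a = x, density_b = -x)
  expect_equal(pearson_correlation(tab2)$r, -1)
  set.seed(52)
  null <- data.frame(density_a = runif(10000), density_b = runif(10000))
  expect_lt(abs(pearson_correlation(null)$r), 0.05)
  expect_error(pearson_correlation(data.frame(density_a = rep(1, 5),
                                              density_b = x)),
               "degenerate-correlation")
  expect_error(pearson_correlation(data.frame(density_a = x[1:2],
                                              density_b = x[1:2])),
               "at least 3")
})
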