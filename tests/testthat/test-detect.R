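test_that("fill_holes fills interior background only", {
  # annulus -> filled disk
  ring <- fixture_disk_mask(40, 40, rbind(c(20, 20)), 12)
  inner <- fixture_disk_mask(40, 40, rbind(c(20, 20)), 6)
  ann <- binary_mask(ring$pixels & !inner$pixels, 1)
  filled <- fill_holes(ann)
  expect_identical(filled$pixels, ring$pixels)
  # solid disk unchanged (idempotence)
  expect_identical(fill_holes(ring)$pixels, ring$pixels)
  # corridor touching the border is not filled
  m <- matrix(TRUE, 20, 20)
  m[8:12, 1:10] <- FALSE
  bm <- binary_mask(m, 1)
  expect_identical(fill_holes(bm)$pixels, m)
})

test_that("watershed splits touching convex blobs and leaves singles alone", {
  two <- fixture_disk_mask(60, 60, rbind(c(30, 22), c(30, 38)), c(10, 10))
  expect_equal(max(watershed_split(two)), 2L)

  one <- fixture_disk_mask(40, 40, rbind(c(20, 20)), 10)
  lab <- watershed_split(one)
  expect_equal(max(lab), 1L)
  expect_equal(sum(lab > 0), sum(one$pixels)) # nothing eroded

  chain <- fixture_disk_mask(40, 100,
                             rbind(c(20, 20), c(20, 38), c(20, 56)),
                             c(10, 10, 10))
  expect_equal(max(watershed_split(chain)), 3L)
})

test_that("particle area filtering is inclusive at the minimum", {
  # 6x6 px at 0.5 um/px = 9 um^2 exactly: kept, centroid at the center
  lab <- matrix(0L, 20, 20)
  lab[5:10, 5:10] <- 1L
  ps <- particles_to_points(lab, 0.5, min_area_um2 = 9)
  expect_equal(nrow(ps$points), 1L)
  expect_equal(ps$area_um2, 9)
  # 0-based rows 4..9, centroid row0 6.5 -> (6.5 + 0.5) * 0.5 = 3.5 um
  expect_equal(unname(ps$points[1, ]), c(3.5, 3.5))

  # 35 px at 0.5 um/px = 8.75 um^2: removed
  lab2 <- matrix(0L, 20, 20)
  lab2[5:9, 5:11] <- 1L # 35 px
  expect_equal(nrow(particles_to_points(lab2, 0.5, 9)$points), 0L)

  expect_equal(nrow(particles_to_points(matrix(0L, 5, 5), 0.5, 9)$points), 0L)
})

test_that("detect_nuclei recovers non-touching disks with sub-pixel centroids", {
  pos <- as.matrix(expand.grid(r = seq(15, 285, by = 30),
                               c = seq(15, 285, by = 30)))
  mask <- fixture_disk_mask(300, 300, pos, rep(4, 100), scale = 1)
  pts <- detect_nuclei(mask, min_area_um2 = 9)
  expect_equal(nrow(pts$points), 100L)
  # true center (row0, col0) = pos - 1; physical = (pos - 0.5)
  want <- cbind((pos[, 2] - 0.5), (pos[, 1] - 0.5))
  got <- pts$points[order(pts$points[, 2], pts$points[, 1]), ]
  want <- want[order(want[, 2], want[, 1]), ]
  expect_lt(max(abs(got - want)), 1)
})

test_that("touching disk pairs are split into two detections each", {
  centers <- list()
  for (k in 0:19) {
    r0 <- 20 + (k %/% 5) * 40
    c0 <- 20 + (k %% 5) * 40
    centers[[length(centers) + 1L]] <- c(r0, c0)
    centers[[length(centers) + 1L]] <- c(r0, c0 + 9)
  }
  cen <- do.call(rbind, centers)
  mask <- fixture_disk_mask(180, 220, cen, rep(5, nrow(cen)), scale = 1)
  pts <- detect_nuclei(mask, min_area_um2 = 9)
  expect_equal(nrow(pts$points), 40L)
})

test_that("empty masks yield empty point sets", {
  empty <- binary_mask(matrix(FALSE, 30, 30), 0.5)
  expect_equal(nrow(detect_nuclei(empty)$points), 0L)
})

test_that("count recovery holds on random fields with moderate overlap", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 60
    rc <- cbind(runif(n, 10, 290), runif(n, 10, 290))
    # enforce pairwise distance >= 7 so overlap stays moderate (r = 5)
    keep <- rep(TRUE, n)
    for (i in 2:n) {
      d <- sqrt((rc[1:(i - 1), 1] - rc[i, 1])^2 +
                (rc[1:(i - 1), 2] - rc[i, 2])^2)
      if (any(d[keep[1:(i - 1)]] < 7)) keep[i] <- FALSE
    }
    rc <- rc[keep, , drop = FALSE]
    mask <- fixture_disk_mask(300, 300, rc, rep(5, nrow(rc)), scale = 1)
    pts <- detect_nuclei(mask, min_area_um2 = 9)
    expect_lte(abs(nrow(pts$points) - nrow(rc)) / nrow(rc), 0.05)
  }
})
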