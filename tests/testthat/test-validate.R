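test_that("pixel metrics match hand-computed confusion counts", {
  m <- function(v) binary_mask(matrix(v, 2, 4), 1)
  ref <- m(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  comp <- m(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  pm <- pixel_metrics(ref, comp)
  expect_equal(pm$confusion, list(tp = 2L, fp = 2L, fn = 2L, tn = 2L))
  expect_equal(pm$dice, 4 / 8)
  expect_equal(pm$sensitivity, 0.5)
  expect_equal(pm$specificity, 0.5)

  same <- pixel_metrics(ref, ref)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$specificity, 1)
  expect_equal(same$dice, 1)

  none <- pixel_metrics(ref, m(rep(FALSE, 8)))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$dice, 0)

  # 0/0 degenerate cases flagged, not zeroed
  allneg <- m(rep(FALSE, 8))
  deg <- pixel_metrics(allneg, allneg)
  expect_true(is.na(deg$sensitivity))
  expect_true(is.na(deg$dice))
  expect_setequal(deg$undefined, c("sensitivity", "dice"))
  allpos <- m(rep(TRUE, 8))
  deg2 <- pixel_metrics(allpos, allpos)
  expect_true(is.na(deg2$specificity))

  expect_error(pixel_metrics(ref, binary_mask(matrix(TRUE, 3, 3), 1)),
               "mismatch")
})

test_that("dice equals 2 IoU / (1 + IoU) on random mask pairs", {
  set.seed(21)
  for (k in 1:20) {
    a <- binary_mask(matrix(runif(400) < runif(1, 0.2, 0.8), 20, 20), 1)
    b <- binary_mask(matrix(runif(400) < runif(1, 0.2, 0.8), 20, 20), 1)
    iou <- intersection_over_union(a, b)
    pm <- pixel_metrics(a, b)
    expect_equal(pm$dice, 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})

test_that("point matching is globally nearest-first with one match each", {
  p <- function(...) point_set(matrix(c(...), ncol = 2, byrow = TRUE))
  m <- match_points(p(0, 0), p(0, 3), radius_um = 5)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$distance_um, 3)

  m2 <- match_points(p(0, 0), p(0, 6), radius_um = 5)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_reference, 1L)

  # closest pair wins even when a later reference point is left stranded
  m3 <- match_points(p(0, 0, 0, 5), p(0, 2), radius_um = 5)
  expect_equal(m3$pairs$reference, 1L)
  expect_equal(m3$pairs$distance_um, 2)
  expect_equal(m3$unmatched_reference, 2L)
})

test_that("greedy matching cardinality equals maximum bipartite matching", {
  set.seed(22)
  for (k in 1:40) {
    nr <- sample(0:12, 1); nc <- sample(0:12, 1)
    ref <- matrix(runif(2 * nr, 0, 30), ncol = 2)
    comp <- matrix(runif(2 * nc, 0, 30), ncol = 2)
    m <- match_points(point_set(ref), point_set(comp), radius_um = 5)
    expect_equal(nrow(m$pairs), oracle_max_matching(ref, comp, 5))
  }
})

test_that("detection dice handles perfect, partial and degenerate sets", {
  p <- function(...) point_set(matrix(c(...), ncol = 2, byrow = TRUE))
  empty <- point_set(matrix(numeric(0), ncol = 2))
  m <- match_points(p(0, 0, 10, 10), p(0, 1), radius_um = 5)
  expect_equal(detection_dice(m), 2 / 3)
  perfect <- match_points(p(0, 0, 10, 10), p(0, 0, 10, 10), 5)
  expect_equal(detection_dice(perfect), 1)
  none <- match_points(p(0, 0), p(20, 20), 5)
  expect_equal(detection_dice(none), 0)
  expect_true(is.na(detection_dice(match_points(empty, empty, 5))))
  # symmetry
  a <- p(0, 0, 3, 3, 9, 9); b <- p(1, 1, 8, 8)
  expect_equal(detection_dice(match_points(a, b, 5)),
               detection_dice(match_points(b, a, 5)))
})

test_that("ROI sampling is seeded, returns one retained ROI per section", {
  sections <- lapply(1:10, function(i) list(
    image = calibrated_image(matrix(0, 300, 300), 1),
    outline = square_outline(300), section_id = paste0("S", i)))
  a <- sample_validation_rois(sections, c(60, 60), 5L, seed = 42L)
  b <- sample_validation_rois(sections, c(60, 60), 5L, seed = 42L)
  expect_identical(a, b)
  expect_equal(length(a), 50L)
  expect_equal(sum(vapply(a, `[[`, TRUE, "retained")), 10L)
  retained_per_sec <- table(vapply(a[vapply(a, `[[`, TRUE, "retained")],
                                   `[[`, "", "section_id"))
  expect_true(all(retained_per_sec == 1))
  # every candidate box lies inside its image
  for (s in a) {
    expect_true(all(s$roi$origin_px >= 0))
    expect_true(all(s$roi$origin_px + s$roi$size_px <= c(300, 300)))
  }
  small <- list(list(image = calibrated_image(matrix(0, 50, 50), 1),
                     outline = square_outline(50)))
  expect_error(sample_validation_rois(small, c(100, 100), 5L, 1L),
               "sampling error")
})

test_that("inclusion rules follow the stated bounds", {
  m <- function(frac) binary_mask(matrix(seq_len(100) <= frac * 100, 10, 10), 1)
  expect_false(apply_inclusion_rules(m(0.05), "membrane")$included)
  expect_match(apply_inclusion_rules(m(0.05), "membrane")$reason, "below 0.1")
  expect_true(apply_inclusion_rules(m(0.5), "membrane")$included)
  expect_true(apply_inclusion_rules(m(0.1), "membrane")$included)  # inclusive
  expect_true(apply_inclusion_rules(m(0.9), "membrane")$included)  # inclusive
  expect_false(apply_inclusion_rules(m(0.95), "membrane")$included)

  p <- function(n) point_set(matrix(runif(2 * n), ncol = 2))
  expect_false(apply_inclusion_rules(p(4), "nuclear")$included)
  expect_true(apply_inclusion_rules(p(5), "nuclear")$included)

  expect_error(apply_inclusion_rules(p(5), "membrane"), "binary_mask")
})

test_that("observer report emits ROI rows plus median/IQR summaries", {
  set.seed(23)
  ref <- lapply(1:3, function(i)
    binary_mask(matrix(runif(100) < 0.4, 10, 10), 1))
  comparators <- list(self = ref,
                      noisy = lapply(ref, function(m) {
                        px <- xor(m$pixels, matrix(runif(100) < 0.1, 10, 10))
                        binary_mask(px, 1)
                      }))
  rep <- observer_report(ref, comparators, "membrane")
  expect_equal(sum(rep$row_type == "roi"), 6L)
  expect_equal(sum(rep$row_type == "median"), 2L)
  expect_equal(sum(rep$row_type == "iqr"), 2L)
  self_med <- rep[rep$comparator == "self" & rep$row_type == "median", ]
  expect_equal(self_med$dice, 1)
  self_iqr <- rep[rep$comparator == "self" & rep$row_type == "iqr", ]
  expect_equal(self_iqr$dice, 0)
  expect_error(observer_report(ref, list(bad = ref[1:2]), "membrane"),
               "cover")
})

test_that("matched distance total is bounded below by the min-cost optimum", {
  set.seed(24)
  for (k in 1:12) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    ref <- matrix(runif(2 * nr, 0, 25), ncol = 2)
    comp <- matrix(runif(2 * nc, 0, 25), ncol = 2)
    m <- match_points(point_set(ref), point_set(comp), radius_um = 5)
    opt <- oracle_min_cost_max_matching(ref, comp, 5)
    expect_equal(nrow(m$pairs), opt$card)
    expect_gte(sum(m$pairs$distance_um) + 1e-9, opt$cost)
  }
})
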