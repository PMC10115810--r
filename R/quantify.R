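#' Positive area fraction of a mask within a region
#' @param mask a [binary_mask()].
#' @param region a [binary_mask()] of the analysed compartment, same shape.
#' @return fraction in `[0, 1]`.
#' @export
area_fraction <- function(mask, region) {
  stopifnot(inherits(mask, "binary_mask"), inherits(region, "binary_mask"))
  check_same_frame(mask, region)
  n <- sum(region$pixels)
  if (n == 0) stop("empty region", call. = FALSE)
  sum(mask$pixels & region$pixels) / n
}

#' Detections per square millimetre within a region
#'
#' Counts the points falling inside the region (boundary points count as
#' inside) and divides by the region area in mm^2.
#'
#' @param points a [point_set()] in micrometres.
#' @param region a [region_outline()] or [binary_mask()].
#' @param scale_um_per_px required when `region` is a mask without one.
#' @return density in detections per mm^2.
#' @export
density_per_mm2 <- function(points, region, scale_um_per_px = NULL) {
  stopifnot(inherits(points, "point_set"))
  pts <- points$points
  if (inherits(region, "region_outline")) {
    area_mm2 <- outline_area_um2(region) / 1e6
    if (area_mm2 <= 0) stop("zero-area region", call. = FALSE)
    n <- if (nrow(pts)) sum(vapply(seq_len(nrow(pts)), function(i)
      point_in_outline(pts[i, 1], pts[i, 2], region), TRUE)) else 0L
  } else if (inherits(region, "binary_mask")) {
    s <- scale_um_per_px %||% region$scale_um_per_px
    area_mm2 <- sum(region$pixels) * s^2 / 1e6
    if (area_mm2 <= 0) stop("zero-area region", call. = FALSE)
    n <- 0L
    if (nrow(pts)) {
      rr <- pmin(pmax(floor(pts[, 2] / s) + 1, 1), nrow(region$pixels))
      cc <- pmin(pmax(floor(pts[, 1] / s) + 1, 1), ncol(region$pixels))
      n <- sum(region$pixels[cbind(rr, cc)])
    }
  } else stop("`region` must be a region_outline or binary_mask",
              call. = FALSE)
  n / area_mm2
}

#' Intersection over union of two masks within a region
#'
#' Co-localization measure `|A & B & R| / |(A | B) & R|`. An empty union is
#' undefined and returned as `NA` (flagged), never 0.
#'
#' @param mask_a,mask_b [binary_mask()] objects, same shape.
#' @param region optional [binary_mask()] restriction (default: whole frame).
#' @return IoU in `[0, 1]`, or `NA` when the union is empty.
#' @export
intersection_over_union <- function(mask_a, mask_b, region = NULL) {
  stopifnot(inherits(mask_a, "binary_mask"), inherits(mask_b, "binary_mask"))
  check_same_frame(mask_a, mask_b)
  a <- mask_a$pixels; b <- mask_b$pixels
  if (!is.null(region)) {
    check_same_frame(mask_a, region)
    a <- a & region$pixels; b <- b & region$pixels
  }
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Count stained structures (connected components) in a region
#'
#' Enumerates 8-connected components of the mask restricted to the region,
#' discarding components below `min_area_um2`. This is the operational
#' definition of "positive tubules" for membrane/structure stains, where each
#' stained tubule cross-section forms one component; the default 80 um^2
#' cutoff suppresses debris at typical tubule cross-section sizes.
#'
#' @param mask a [binary_mask()].
#' @param region a [binary_mask()] restriction, same shape.
#' @param min_area_um2 inclusive minimum component area (default 80).
#' @return list with `count` and `per_mm2` (count / region area).
#' @export
count_structures <- function(mask, region, min_area_um2 = 80) {
  stopifnot(inherits(mask, "binary_mask"), inherits(region, "binary_mask"))
  check_same_frame(mask, region)
  s <- mask$scale_um_per_px
  area_mm2 <- sum(region$pixels) * s^2 / 1e6
  if (area_mm2 <= 0) stop("empty region", call. = FALSE)
  lab <- cpp_label(mask$pixels & region$pixels, 8L)
  np <- max(lab)
  count <- 0L
  if (np > 0) {
    st <- cpp_label_stats(lab, np)
    count <- sum(st[, 2] * s^2 >= min_area_um2)
  }
  list(count = count, per_mm2 = count / area_mm2, region_area_mm2 = area_mm2)
}

#' Whole-section summary for one channel
#'
#' Bundles the per-section metrics exported for downstream statistics:
#' region area, positive area fraction and, when points are supplied,
#' detections per mm^2.
#'
#' @param mask a [binary_mask()] segmentation of the channel.
#' @param region a [binary_mask()] of the analysed compartment.
#' @param points optional [point_set()] of detections.
#' @param section_id,channel_label,region_label free-text identifiers.
#' @return one-row data.frame.
#' @export
section_summary <- function(mask, region, points = NULL, section_id = "",
                            channel_label = "", region_label = "") {
  af <- area_fraction(mask, region)
  s <- mask$scale_um_per_px
  area_mm2 <- sum(region$pixels) * s^2 / 1e6
  dpm <- if (is.null(points)) NA_real_ else density_per_mm2(points, region)
  data.frame(section_id = section_id, channel_label = channel_label,
             region_label = region_label, region_area_mm2 = area_mm2,
             area_fraction = af, detections_per_mm2 = dpm)
}
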