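#' Fill holes in a binary mask
#'
#' Every background component not connected to the image border becomes
#' foreground; foreground pixels are unchanged. Background connectivity is 4
#' and foreground connectivity 8 (the usual dual raster convention).
#'
#' @param mask a [binary_mask()].
#' @return A [binary_mask()].
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  bg <- !mask$pixels
  lab <- cpp_label(bg, 4L)
  nr <- nrow(lab); nc <- ncol(lab)
  border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border <- border[border > 0]
  holes <- bg & !(lab %in% border)
  dim(holes) <- dim(bg)
  binary_mask(mask$pixels | holes, mask$scale_um_per_px,
              source_label = mask$source_label)
}

#' Separate touching particles by distance-transform watershed
#'
#' The classic binary watershed: the Euclidean distance transform of the
#' foreground is flooded from its regional maxima so that touching convex
#' blobs are split by one-pixel background lines. Small or ragged maxima
#' over-segment, so seeds are suppressed before flooding: maxima with
#' distance value below `min_peak_dist_px` are discarded and maxima closer
#' than `merge_dist_px` (single linkage on plateau centroids) are merged
#' into one seed.
#'
#' @param mask a hole-filled [binary_mask()].
#' @param merge_dist_px merge maxima closer than this (default 4).
#' @param min_peak_dist_px discard maxima with EDT value below this
#'   (default 2).
#' @return Integer label matrix; 0 = background/watershed line, labels are
#'   connected particles.
#' @export
watershed_split <- function(mask, merge_dist_px = 4, min_peak_dist_px = 2) {
  stopifnot(inherits(mask, "binary_mask"))
  fg <- mask$pixels
  if (!any(fg)) return(matrix(0L, nrow(fg), ncol(fg)))
  d <- sqrt(cpp_edt_sq(fg))
  if (!any(!fg)) d[] <- 1 # all-foreground frame: single basin
  peaks <- cpp_regional_maxima(d, fg)
  np <- max(peaks)
  if (np == 0L) return(cpp_label(fg, 8L))
  st <- cpp_label_stats(peaks, np)
  cr <- st[, 3] / st[, 2]; cc <- st[, 4] / st[, 2]
  pv <- d[match(seq_len(np), peaks)] # plateau EDT value (first pixel)
  keep <- pv >= min_peak_dist_px
  if (!any(keep)) {
    # nothing survives suppression: no splitting
    return(cpp_label(fg, 8L))
  }
  idx <- which(keep)
  # single-linkage merge of nearby seeds
  grp <- seq_along(idx)
  if (length(idx) > 1L) {
    dm <- as.matrix(stats::dist(cbind(cr[idx], cc[idx])))
    for (a in seq_along(idx)) for (b in seq_len(a - 1L)) {
      if (dm[a, b] < merge_dist_px && grp[a] != grp[b]) {
        grp[grp == grp[a]] <- grp[b]
      }
    }
  }
  grp <- match(grp, unique(grp))
  markers <- matrix(0L, nrow(fg), ncol(fg))
  for (k in seq_along(idx)) markers[peaks == idx[k]] <- grp[k]
  lab <- cpp_watershed(d, markers, fg)
  lab[lab < 0] <- 0L
  # isolated blobs whose maxima were all suppressed are unreachable from any
  # seed; rescue them as their own particles so nothing silently vanishes.
  # Watershed-line pixels (adjacent to a labelled particle) are NOT rescued.
  orphan <- fg & lab == 0L
  if (any(orphan)) {
    se <- expand.grid(dr = -1:1, dc = -1:1)
    near <- cpp_gray_dilate(matrix(as.numeric(lab > 0L), nrow(lab)),
                            se$dr, se$dc, rep(0, 9)) > 0
    extra <- cpp_label(orphan, 8L)
    nmax <- max(lab)
    for (l in seq_len(max(extra))) {
      sel <- extra == l
      if (!any(near[sel])) lab[sel] <- nmax + l
    }
  }
  lab
}

#' Convert labelled particles to centroid points with an area cutoff
#'
#' Emits the area centroid (in micrometres, pixel-center convention) of every
#' labelled particle whose area is at least `min_area_um2`. The bound is
#' inclusive: a particle of exactly the minimum area is retained. The default
#' of 9 um^2 rejects sub-nuclear debris at typical magnifications.
#'
#' @param labels integer label matrix (from [watershed_split()]).
#' @param scale_um_per_px micrometres per pixel.
#' @param min_area_um2 inclusive minimum particle area (default 9).
#' @return A [point_set()] with `area_um2` per point.
#' @export
particles_to_points <- function(labels, scale_um_per_px, min_area_um2 = 9) {
  stopifnot(is.matrix(labels), scale_um_per_px > 0, min_area_um2 >= 0)
  np <- max(labels, 0L)
  if (np == 0L)
    return(point_set(matrix(numeric(0), ncol = 2),
                     source_label = "detect_nuclei"))
  st <- cpp_label_stats(labels, np)
  area <- st[, 2] * scale_um_per_px^2
  keep <- st[, 2] > 0 & area >= min_area_um2
  x <- (st[keep, 4] / st[keep, 2] + 0.5) * scale_um_per_px
  y <- (st[keep, 3] / st[keep, 2] + 0.5) * scale_um_per_px
  point_set(cbind(x, y), source_label = "detect_nuclei",
            area_um2 = area[keep])
}

#' Detect nucleus centroids in a nuclear-stain segmentation mask
#'
#' The standard detection chain for nuclear stains: fill holes, split
#' touching nuclei with the distance-transform watershed, then keep
#' particles of at least `min_area_um2` and return their centroids.
#'
#' @param mask a [binary_mask()] of the nuclear stain.
#' @param min_area_um2 inclusive minimum particle area in um^2 (default 9).
#' @param merge_dist_px,min_peak_dist_px watershed seed suppression, see
#'   [watershed_split()].
#' @return A [point_set()] of nucleus centroids (x_um, y_um) with areas.
#' @export
detect_nuclei <- function(mask, min_area_um2 = 9, merge_dist_px = 4,
                          min_peak_dist_px = 2) {
  stopifnot(inherits(mask, "binary_mask"))
  filled <- fill_holes(mask)
  lab <- watershed_split(filled, merge_dist_px, min_peak_dist_px)
  ps <- particles_to_points(lab, mask$scale_um_per_px, min_area_um2)
  ps$source_label <- if (nzchar(mask$source_label))
    paste0("detect:", mask$source_label) else "detect_nuclei"
  ps
}
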