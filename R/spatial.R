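# 2-D circular convolution via FFT, result cropped to "same" size with the
# kernel centered. Used for large circular mean kernels (a 200 um radius at
# 0.5 um/px is an 800-px-wide kernel, far beyond direct convolution).
conv2_same_fft <- function(img, kern) {
  nr <- nrow(img) + nrow(kern) - 1L
  nc <- ncol(img) + ncol(kern) - 1L
  pa <- matrix(0, nr, nc); pb <- matrix(0, nr, nc)
  pa[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  pb[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  full <- Re(fft(fft(pa) * fft(pb), inverse = TRUE)) / (nr * nc)
  r0 <- (nrow(kern) - 1L) %/% 2L
  c0 <- (ncol(kern) - 1L) %/% 2L
  full[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))]
}

# Discrete disk kernel: 1 where the pixel center is within radius_px of the
# kernel center pixel.
disk_kernel <- function(radius_px) {
  r <- floor(radius_px)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  k <- matrix(as.numeric(g$dr^2 + g$dc^2 <= radius_px^2), nrow = 2 * r + 1)
  k
}

#' Local staining-density heatmap (circular mean filter)
#'
#' Replaces every pixel by the mean of the binary mask over a discrete
#' circular neighbourhood (a pixel belongs to the kernel iff its center lies
#' within the radius), i.e. the local positive area fraction at the kernel
#' scale. Pixels outside the region are masked to `NA`. The denominator is
#' always the full kernel; pixels whose kernel crosses the region boundary
#' are flagged `FALSE` in the companion `valid` raster instead of being
#' renormalized, so that boundary values are visibly partial rather than
#' silently extrapolated.
#'
#' @param mask a [binary_mask()] of the stain.
#' @param region a [binary_mask()] of the analysed compartment, same shape.
#' @param radius_um kernel radius in micrometres (default 200).
#' @return list of class `density_heatmap`: `values` (matrix in `[0,1]`,
#'   `NA` outside region), `valid` (logical matrix), `kernel_radius_um`,
#'   `kernel_px` (pixel count of the discrete kernel), `scale_um_per_px`.
#' @export
density_heatmap <- function(mask, region, radius_um = 200) {
  stopifnot(inherits(mask, "binary_mask"), inherits(region, "binary_mask"))
  check_same_frame(mask, region)
  s <- mask$scale_um_per_px
  rpx <- radius_um / s
  if (rpx < 1) stop("kernel radius below one pixel", call. = FALSE)
  k <- disk_kernel(rpx)
  nk <- sum(k)
  m <- matrix(as.numeric(mask$pixels), nrow(mask$pixels))
  v <- conv2_same_fft(m, k) / nk
  v <- pmin(pmax(v, 0), 1)
  cover <- conv2_same_fft(matrix(as.numeric(region$pixels),
                                 nrow(region$pixels)), k) / nk
  valid <- cover > 1 - 1e-9
  v[!region$pixels] <- NA_real_
  structure(list(values = v, valid = valid & region$pixels,
                 kernel_radius_um = radius_um, kernel_px = nk,
                 scale_um_per_px = s),
            class = "density_heatmap")
}

#' Tile a region with close-packed non-overlapping circles
#'
#' Lays a hexagonal lattice of circle centers (pitch `2r` within a row, rows
#' `sqrt(3)*r` apart, alternate rows offset by `r`) over the region
#' bounding box and keeps every candidate whose full disk lies inside the
#' region polygons (strict containment: the center is inside and at least
#' `r` from every boundary edge, holes included). Partially contained
#' circles are rejected because they would bias density denominators.
#'
#' @param region a [region_outline()].
#' @param radius_um circle radius in micrometres (default 200).
#' @param anchor `"bbox"` (lattice anchored at the bounding-box origin,
#'   default) or a numeric `(x, y)` in um through which a lattice point
#'   passes.
#' @return list of class `circle_tile_set`: `centers_um` (n x 2 matrix),
#'   `radius_um`, `region_label`. Zero rows (with a warning) when no circle
#'   fits.
#' @export
tile_region <- function(region, radius_um = 200, anchor = "bbox") {
  stopifnot(inherits(region, "region_outline"), radius_um > 0)
  r <- radius_um
  bb <- sapply(region$polygons, function(p) c(range(p$outer[, 1]),
                                              range(p$outer[, 2])))
  x0 <- min(bb[1, ]); x1 <- max(bb[2, ])
  y0 <- min(bb[3, ]); y1 <- max(bb[4, ])
  ax <- x0 + r; ay <- y0 + r
  if (is.numeric(anchor) && length(anchor) == 2) { ax <- anchor[1]; ay <- anchor[2] }
  dy <- r * sqrt(3)
  jr <- seq(floor((y0 - ay) / dy), ceiling((y1 - ay) / dy))
  centers <- NULL
  for (j in jr) {
    y <- ay + j * dy
    if (y < y0 - r || y > y1 + r) next
    off <- if (j %% 2 == 0) 0 else r
    ir <- seq(floor((x0 - ax - off) / (2 * r)), ceiling((x1 - ax - off) / (2 * r)))
    xs <- ax + off + ir * 2 * r
    xs <- xs[xs >= x0 - r & xs <= x1 + r]
    for (x in xs) {
      if (disk_in_outline(x, y, r, region)) centers <- rbind(centers, c(x, y))
    }
  }
  if (is.null(centers)) {
    warning("no circle of the requested radius fits in the region")
    centers <- matrix(numeric(0), ncol = 2)
  }
  colnames(centers) <- c("x_um", "y_um")
  structure(list(centers_um = centers, radius_um = radius_um,
                 region_label = region$label),
            class = "circle_tile_set")
}

# Strict full-disk containment: center inside the outline and at least r
# away from every ring edge (outer boundaries and holes alike).
disk_in_outline <- function(x, y, r, outline) {
  if (!point_in_outline(x, y, outline)) return(FALSE)
  for (p in outline$polygons) {
    rings <- c(list(p$outer), p$holes)
    for (ring in rings) {
      if (min_dist_to_ring(x, y, ring) < r - 1e-9) return(FALSE)
    }
  }
  TRUE
}

# Minimum distance from a point to the edges of a closed ring (vectorized
# point-segment distance).
min_dist_to_ring <- function(x, y, ring) {
  ring <- close_ring(ring)
  ax <- ring[-nrow(ring), 1]; ay <- ring[-nrow(ring), 2]
  bx <- ring[-1, 1]; by <- ring[-1, 2]
  ex <- bx - ax; ey <- by - ay
  len2 <- ex^2 + ey^2
  t <- pmin(pmax(((x - ax) * ex + (y - ay) * ey) / pmax(len2, 1e-300), 0), 1)
  px <- ax + t * ex; py <- ay + t * ey
  sqrt(min((x - px)^2 + (y - py)^2))
}

#' Per-tile paired stain densities
#'
#' For every circle tile, measures the density of two channels over the disk
#' (pixels whose centers lie within the radius): area fraction for mask
#' channels, detections per mm^2 for point channels. One row per tile.
#'
#' @param tiles a `circle_tile_set` from [tile_region()].
#' @param channel_a,channel_b [binary_mask()] or [point_set()] objects in
#'   the same section frame.
#' @param scale_um_per_px required when neither channel is a mask.
#' @return data.frame of class `density_table`: tile, x_um, y_um,
#'   density_a, density_b.
#' @export
tile_densities <- function(tiles, channel_a, channel_b,
                           scale_um_per_px = NULL) {
  stopifnot(inherits(tiles, "circle_tile_set"))
  if (inherits(channel_a, "binary_mask") && inherits(channel_b, "binary_mask"))
    check_same_frame(channel_a, channel_b)
  n <- nrow(tiles$centers_um)
  da <- numeric(n); db <- numeric(n)
  for (i in seq_len(n)) {
    da[i] <- tile_density_one(tiles$centers_um[i, ], tiles$radius_um,
                              channel_a, scale_um_per_px)
    db[i] <- tile_density_one(tiles$centers_um[i, ], tiles$radius_um,
                              channel_b, scale_um_per_px)
  }
  out <- data.frame(tile = seq_len(n),
                    x_um = tiles$centers_um[, 1],
                    y_um = tiles$centers_um[, 2],
                    density_a = da, density_b = db)
  class(out) <- c("density_table", "data.frame")
  out
}

tile_density_one <- function(center, radius_um, channel, scale) {
  x <- center[1]; y <- center[2]
  if (inherits(channel, "binary_mask")) {
    s <- channel$scale_um_per_px
    px <- channel$pixels
    c0 <- max(1L, floor((x - radius_um) / s)); c1 <- min(ncol(px), ceiling((x + radius_um) / s) + 1L)
    r0 <- max(1L, floor((y - radius_um) / s)); r1 <- min(nrow(px), ceiling((y + radius_um) / s) + 1L)
    if (c0 > c1 || r0 > r1) return(NA_real_)
    cols <- c0:c1; rows <- r0:r1
    xs <- (cols - 0.5) * s; ys <- (rows - 0.5) * s
    inside <- outer((ys - y)^2, (xs - x)^2, "+") <= radius_um^2
    tot <- sum(inside)
    if (tot == 0) return(NA_real_)
    sum(px[rows, cols][inside]) / tot
  } else if (inherits(channel, "point_set")) {
    pts <- channel$points
    cnt <- if (nrow(pts)) sum((pts[, 1] - x)^2 + (pts[, 2] - y)^2 <= radius_um^2)
           else 0L
    cnt / (pi * radius_um^2 / 1e6)
  } else stop("channel must be a binary_mask or point_set", call. = FALSE)
}

#' Pearson correlation of paired densities
#'
#' Sample Pearson correlation of the two density columns with the two-sided
#' p-value from the t transform, the readout for within-section spatial
#' correlation of two stains over circle tiles (and equally for
#' between-section summary pairs).
#'
#' @param table a `density_table` (columns density_a, density_b), or a
#'   numeric vector `x` with `y` supplied.
#' @param y optional second vector when `table` is a vector.
#' @return list with `r`, `n`, `p_value`.
#' @export
pearson_correlation <- function(table, y = NULL) {
  if (is.data.frame(table)) {
    x <- table$density_a; yy <- table$density_b
  } else {
    x <- table; yy <- y
  }
  keep <- is.finite(x) & is.finite(yy)
  x <- x[keep]; yy <- yy[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired densities", call. = FALSE)
  if (sd(x) == 0 || sd(yy) == 0)
    stop("degenerate-correlation error: constant density column",
         call. = FALSE)
  r <- cor(x, yy)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(r = r, n = n, p_value = p)
}
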