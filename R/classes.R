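#' @useDynLib histoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif median quantile cor pt sd fft
#' @importFrom utils read.csv write.csv head
NULL

#' Calibrated grayscale image
#'
#' The universal input: a 2-D raster of non-negative intensities plus an
#' isotropic spatial calibration in micrometres per pixel.
#'
#' Coordinate convention used throughout the package: pixel indices are
#' 0-based `(row, col)` internally; physical coordinates are pixel centers,
#' `x_um = (col0 + 0.5) * scale`, `y_um = (row0 + 0.5) * scale`, with x along
#' columns and y along rows. All physical quantities are in micrometres.
#'
#' @param pixels numeric matrix of intensities (>= 1 row and column).
#' @param scale_um_per_px positive scalar, micrometres per pixel.
#' @param channel_label free-text stain/channel label.
#' @param source_id free-text section identifier.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, scale_um_per_px,
                             channel_label = "", source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      !is.finite(scale_um_per_px) || scale_um_per_px <= 0)
    stop("`scale_um_per_px` must be a positive scalar", call. = FALSE)
  structure(
    list(pixels = pixels, scale_um_per_px = as.numeric(scale_um_per_px),
         channel_label = as.character(channel_label),
         source_id = as.character(source_id)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px @ %.4g um/px", nrow(x$pixels),
              ncol(x$pixels), x$scale_um_per_px))
  if (nzchar(x$channel_label)) cat("  channel:", x$channel_label)
  if (nzchar(x$source_id)) cat("  source:", x$source_id)
  cat(sprintf("\n  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' @param pixels logical matrix; `TRUE` marks segmented-positive pixels.
#' @param scale_um_per_px positive scalar, micrometres per pixel.
#' @param source_label provenance (segmenter name or observer ID).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, scale_um_per_px, source_label = "") {
  if (is.numeric(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix", call. = FALSE)
  if (anyNA(pixels)) stop("mask contains NA pixels", call. = FALSE)
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      scale_um_per_px <= 0)
    stop("`scale_um_per_px` must be a positive scalar", call. = FALSE)
  structure(
    list(pixels = pixels, scale_um_per_px = as.numeric(scale_um_per_px),
         source_label = as.character(source_label)),
    class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px @ %.4g um/px, %.2f%% positive",
              nrow(x$pixels), ncol(x$pixels), x$scale_um_per_px,
              100 * mean(x$pixels)))
  if (nzchar(x$source_label)) cat("  source:", x$source_label)
  cat("\n")
  invisible(x)
}

#' Region outline (polygons in micrometres)
#'
#' Delimits the analysed tissue compartment, e.g. cortex + outer stripe of
#' the outer medulla. Each polygon is a list with `outer` (n x 2 matrix of
#' x,y vertices in um) and optional `holes` (list of such matrices).
#'
#' @param polygons list of polygons as described above. A single n x 2
#'   matrix is promoted to one hole-free polygon.
#' @param label free-text compartment label.
#' @return An object of class `region_outline`.
#' @export
region_outline <- function(polygons, label = "") {
  if (is.matrix(polygons)) polygons <- list(list(outer = polygons))
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(outer = p)
    stopifnot(is.matrix(p$outer), ncol(p$outer) == 2)
    if (is.null(p$holes)) p$holes <- list()
    if (anyNA(p$outer) || !all(is.finite(p$outer)))
      stop("outline vertices must be finite", call. = FALSE)
    p
  })
  if (length(polygons) == 0L) stop("outline needs >= 1 polygon", call. = FALSE)
  a <- outline_area_um2_internal(polygons)
  if (a <= 0) stop("outline has non-positive total area", call. = FALSE)
  structure(list(polygons = polygons, label = as.character(label)),
            class = "region_outline")
}

# Shoelace area of one ring (um^2), absolute value.
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

outline_area_um2_internal <- function(polygons) {
  sum(vapply(polygons, function(p) {
    shoelace_area(p$outer) - sum(vapply(p$holes, shoelace_area, 0))
  }, 0))
}

#' Total outline area in square micrometres (shoelace, holes subtracted)
#' @param outline a [region_outline()].
#' @return scalar area in um^2.
#' @export
outline_area_um2 <- function(outline) {
  stopifnot(inherits(outline, "region_outline"))
  outline_area_um2_internal(outline$polygons)
}

#' @export
print.region_outline <- function(x, ...) {
  cat(sprintf("<region_outline> '%s': %d polygon(s), area %.3g mm^2\n",
              x$label, length(x$polygons), outline_area_um2(x) / 1e6))
  invisible(x)
}

#' Point set (centroids in micrometres)
#'
#' Detection or annotation centroids with a provenance label.
#'
#' @param points n x 2 numeric matrix (columns x_um, y_um) or data frame.
#' @param source_label provenance (observer or algorithm).
#' @param area_um2 optional per-point particle areas.
#' @return An object of class `point_set`.
#' @export
point_set <- function(points, source_label = "", area_um2 = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  if (length(points) == 0L) points <- matrix(numeric(0), ncol = 2)
  if (!is.matrix(points) || ncol(points) != 2)
    stop("`points` must be an n x 2 matrix of (x_um, y_um)", call. = FALSE)
  if (nrow(points) && !all(is.finite(points)))
    stop("point coordinates must be finite", call. = FALSE)
  colnames(points) <- c("x_um", "y_um")
  structure(list(points = points, source_label = as.character(source_label),
                 area_um2 = area_um2),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d point(s)", nrow(x$points)))
  if (nzchar(x$source_label)) cat("  source:", x$source_label)
  dup <- n_duplicate_points(x)
  if (dup > 0) cat(sprintf("  [QC: %d duplicated]", dup))
  cat("\n")
  invisible(x)
}

#' QC check: number of duplicated coordinates in a point set
#' @param ps a [point_set()].
#' @return integer count of duplicated rows.
#' @export
n_duplicate_points <- function(ps) {
  stopifnot(inherits(ps, "point_set"))
  sum(duplicated(ps$points))
}

#' Rectangular ROI in pixel coordinates
#'
#' @param origin_px integer `(row, col)` of the top-left corner, 0-based.
#' @param size_px integer `(height, width)`, both positive.
#' @param parent_dim optional `(nrow, ncol)` of the parent image; when given,
#'   the box must lie fully inside it.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(origin_px, size_px, parent_dim = NULL) {
  origin_px <- as.integer(origin_px); size_px <- as.integer(size_px)
  stopifnot(length(origin_px) == 2, length(size_px) == 2)
  if (any(size_px < 1L)) stop("ROI size must be positive", call. = FALSE)
  if (any(origin_px < 0L)) stop("ROI origin must be >= 0", call. = FALSE)
  if (!is.null(parent_dim)) {
    if (origin_px[1] + size_px[1] > parent_dim[1] ||
        origin_px[2] + size_px[2] > parent_dim[2])
      stop("ROI does not fit inside its parent image", call. = FALSE)
  }
  structure(list(origin_px = origin_px, size_px = size_px), class = "roi_box")
}

#' Extract a rectangular ROI from an image or mask
#'
#' Crops the raster to an [roi_box()] (training-annotation ROIs are
#' typically 200-1000 px square; validation ROIs 400 or 200 px square).
#'
#' @param image a [calibrated_image()] or [binary_mask()].
#' @param box an [roi_box()] lying fully inside the image.
#' @return An object of the same class as `image`.
#' @export
extract_roi <- function(image, box) {
  stopifnot(inherits(box, "roi_box"))
  roi_box(box$origin_px, box$size_px, parent_dim = dim(image$pixels))
  out <- image
  out$pixels <- crop_to_roi(image$pixels, box)
  out
}

# Crop a pixel matrix to an roi_box.
crop_to_roi <- function(pixels, box) {
  r0 <- box$origin_px[1]; c0 <- box$origin_px[2]
  pixels[(r0 + 1L):(r0 + box$size_px[1]),
         (c0 + 1L):(c0 + box$size_px[2]), drop = FALSE]
}

# Assert two rasters share a shape (and scale when both carry one).
check_same_frame <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("rasters have mismatched shapes", call. = FALSE)
  invisible(TRUE)
}
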