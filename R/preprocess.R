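# Ball structuring-element offsets for grayscale morphology: all integer
# offsets within radius, with spherical height sqrt(R^2 - d^2).
ball_element <- function(radius_px) {
  r <- as.integer(radius_px)
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- d$dr^2 + d$dc^2
  keep <- d2 <= radius_px^2
  list(dr = as.integer(d$dr[keep]), dc = as.integer(d$dc[keep]),
       h = sqrt(radius_px^2 - d2[keep]))
}

# Grayscale opening with a ball element (exact, direct).
gray_open_ball <- function(pixels, radius_px) {
  se <- ball_element(radius_px)
  er <- cpp_gray_erode(pixels, se$dr, se$dc, se$h)
  cpp_gray_dilate(er, se$dr, se$dc, se$h)
}

#' Rolling-ball background subtraction
#'
#' Estimates slowly varying background by rolling a ball of the given radius
#' under the intensity surface (grayscale opening with a spherical,
#' non-flat structuring element, the classic Sternberg construction) and
#' subtracts it. Structures smaller than the ball survive; any plateau wider
#' than the ball is treated as background. Intended for dark-background
#' fluorescence images; there is no light-background mode.
#'
#' For radii above 16 px the image is first shrunk by block minimum, a
#' proportionally smaller ball is rolled, and the background is re-expanded
#' by bilinear interpolation (the standard large-radius strategy); the
#' background is always clipped to be <= the input so that
#' `input = result + background` holds exactly with `result >= 0`.
#'
#' @param image a [calibrated_image()].
#' @param radius_px ball radius in pixels (default 50, the whole-section
#'   standard for slide-scanner output at 0.5 um/px).
#' @return list with `image` (background-subtracted [calibrated_image()])
#'   and `background` (list: `background` raster, `ball_radius_px`).
#' @export
rolling_ball_subtract <- function(image, radius_px = 50L) {
  stopifnot(inherits(image, "calibrated_image"))
  radius_px <- as.numeric(radius_px)
  if (length(radius_px) != 1L || !is.finite(radius_px) || radius_px < 1)
    stop("`radius_px` must be >= 1", call. = FALSE)
  px <- image$pixels
  if (radius_px > nrow(px) && radius_px > ncol(px))
    stop("ball radius exceeds both image dimensions", call. = FALSE)
  if (radius_px <= 16) {
    bg <- gray_open_ball(px, radius_px)
  } else {
    s <- ceiling(radius_px / 16)
    small <- cpp_block_reduce(px, as.integer(s), 1L) # block min
    bg_small <- gray_open_ball(small, radius_px / s)
    bg <- cpp_bilinear_resize(bg_small, nrow(px), ncol(px))
  }
  bg <- pmin(bg, px)
  res <- px - bg
  list(
    image = calibrated_image(res, image$scale_um_per_px,
                             channel_label = image$channel_label,
                             source_id = image$source_id),
    background = list(background = bg, ball_radius_px = radius_px))
}

#' Down-sample an image by block mean
#'
#' @param image a [calibrated_image()].
#' @param factor integer reduction factor (>= 1); the spatial calibration is
#'   multiplied by `factor`. Trailing partial blocks are averaged over the
#'   available pixels.
#' @return A [calibrated_image()].
#' @export
downsample <- function(image, factor) {
  stopifnot(inherits(image, "calibrated_image"))
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  if (factor > nrow(image$pixels) || factor > ncol(image$pixels))
    stop("`factor` exceeds the image size", call. = FALSE)
  if (factor == 1L) return(image)
  calibrated_image(cpp_block_reduce(image$pixels, factor, 0L),
                   image$scale_um_per_px * factor,
                   channel_label = image$channel_label,
                   source_id = image$source_id)
}
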