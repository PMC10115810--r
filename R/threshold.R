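THRESHOLD_METHODS <- c("default_isodata", "otsu", "triangle", "mean", "li")

# 256-bin histogram over [min, max] of the supplied intensities, 8-bit
# semantics: 16-bit input is binned, not truncated. Returns counts plus the
# affine bin mapping.
hist256 <- function(values) {
  lo <- min(values); hi <- max(values)
  if (hi <= lo) stop("degenerate-histogram error: constant image",
                     call. = FALSE)
  idx <- pmin(255L, as.integer(floor((values - lo) / (hi - lo) * 256)))
  # numeric, not integer: moment sums like sum(i * counts) overflow 32-bit
  # integers on whole-section images
  counts <- as.numeric(tabulate(idx + 1L, nbins = 256L))
  list(counts = counts, lo = lo, hi = hi)
}

# Intensity at the upper edge of bin `idx` (0-based): pixels strictly above
# this value are exactly the pixels binned above `idx`.
bin_upper_edge <- function(h, idx) h$lo + (idx + 1) * (h$hi - h$lo) / 256

# ---- threshold index selectors (0-based bin index 0..255) ----------------

# IsoData variant of the reference tool ("Default"): iterative intermeans on
# the histogram with the extreme bins zeroed (so saturated/erased areas do
# not drag the split point).
thr_default_isodata <- function(counts) {
  d <- counts
  d[1] <- 0L; d[256] <- 0L
  nz <- which(d > 0)
  if (length(nz) == 0L) return(127L)
  mn <- nz[1] - 1L; mx <- nz[length(nz)] - 1L
  if (mn >= mx) return(127L)
  i <- 0:255
  moving <- mn
  repeat {
    below <- i >= mn & i <= moving
    above <- i > moving & i <= mx
    sum1 <- sum(i[below] * d[i[below] + 1L]); sum2 <- sum(d[i[below] + 1L])
    sum3 <- sum(i[above] * d[i[above] + 1L]); sum4 <- sum(d[i[above] + 1L])
    result <- (if (sum2 > 0) sum1 / sum2 else 0) / 2 +
              (if (sum4 > 0) sum3 / sum4 else 0) / 2
    moving <- moving + 1L
    if (!((moving + 1) <= result && moving < mx - 1L)) break
  }
  as.integer(round(result))
}

# Otsu: maximize between-class variance; smallest index on ties.
thr_otsu <- function(counts) {
  i <- 0:255
  n <- sum(counts)
  w0 <- cumsum(counts)              # pixels in bins 0..t
  s0 <- cumsum(i * counts)
  total <- s0[256]
  best <- -Inf; best_t <- 0L
  for (t in 0:254) {
    n0 <- w0[t + 1L]; n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- s0[t + 1L] / n0
    mu1 <- (total - s0[t + 1L]) / n1
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  if (!is.finite(best)) stop("degenerate-histogram error", call. = FALSE)
  as.integer(best_t)
}

# Triangle (Zack): line from the histogram peak to the far tail end; the
# threshold is the bin furthest below that line. The shorter side is flipped
# so the long tail is always walked.
thr_triangle <- function(counts) {
  d <- as.numeric(counts)
  n <- length(d)
  nz <- which(d > 0)
  mn <- nz[1] - 1L
  if (mn > 0L) mn <- mn - 1L
  mn2 <- nz[length(nz)] - 1L
  if (mn2 < n - 1L) mn2 <- mn2 + 1L
  mx <- which.max(d) - 1L
  inverted <- FALSE
  if ((mx - mn) < (mn2 - mx)) {
    inverted <- TRUE
    d <- rev(d)
    mn <- n - 1L - mn2
    mx <- n - 1L - mx
  }
  if (mn == mx) return(as.integer(if (inverted) n - 1L - mn else mn))
  nx <- d[mx + 1L]; ny <- mn - mx
  dd <- sqrt(nx^2 + ny^2)
  nx <- nx / dd; ny <- ny / dd
  dconst <- nx * mn + ny * d[mn + 1L]
  split <- mn; split_dist <- 0
  for (i in (mn + 1L):mx) {
    nd <- nx * i + ny * d[i + 1L] - dconst
    if (nd > split_dist) { split <- i; split_dist <- nd }
  }
  split <- split - 1L
  as.integer(if (inverted) n - 1L - split else split)
}

# Mean of the histogram (floor of the mean bin index).
thr_mean <- function(counts) {
  i <- 0:255
  as.integer(floor(sum(i * counts) / sum(counts)))
}

# Li minimum cross-entropy: exact discrete minimizer of the cross-entropy
# criterion over all 255 splits, by cumulative sums; smallest index on ties.
# (The classic Li-Tam fixed-point iteration can settle in a shallow
# neighbouring basin on noisy histograms; the discrete argmin is the
# criterion's definition and is just as cheap at 256 bins.)
thr_li <- function(counts) {
  i <- 0:255
  sb <- cumsum(i * counts)          # weighted mass of bins 0..t
  nb <- cumsum(counts)
  stot <- sb[256]; ntot <- nb[256]
  so <- stot - sb; no <- ntot - nb
  term <- function(s, n) ifelse(s > 0 & n > 0, -s * log(s / n), 0)
  crit <- term(sb, nb) + term(so, no)
  as.integer(which.min(crit[1:255]) - 1L)
}

# Cross-entropy criterion eta(t) minimized by the Li threshold.
li_criterion <- function(counts, t) {
  i <- 0:255
  low <- i <= t
  sb <- sum(i[low] * counts[low]); so <- sum(i[!low] * counts[!low])
  nb <- sum(counts[low]); no <- sum(counts[!low])
  term <- function(s, n) if (s > 0 && n > 0) -s * log(s / n) else 0
  term(sb, nb) + term(so, no)
}

select_threshold_index <- function(counts, method) {
  switch(method,
    default_isodata = thr_default_isodata(counts),
    otsu = thr_otsu(counts),
    triangle = thr_triangle(counts),
    mean = thr_mean(counts),
    li = thr_li(counts),
    stop("unknown threshold method: ", method, call. = FALSE))
}

#' Histogram auto-thresholding
#'
#' Computes a global threshold from the 256-bin histogram of the image (or of
#' the pixels inside `restrict`) by one of the classic algorithms, and
#' returns the mask of pixels strictly above the threshold. The histogram
#' spans `[min, max]` of the considered pixels in 256 equal-width bins
#' (8-bit semantics; 16-bit input is binned, not truncated).
#'
#' Methods: `default_isodata` (iterative intermeans with clipped extreme
#' bins, the "default" of the reference tool), `otsu` (maximum between-class
#' variance), `triangle` (Zack geometric), `mean` (histogram mean), `li`
#' (minimum cross-entropy, exact discrete minimizer).
#'
#' @param image a [calibrated_image()].
#' @param method one of `"default_isodata"`, `"otsu"`, `"triangle"`,
#'   `"mean"`, `"li"`.
#' @param restrict optional [binary_mask()] restricting the histogram.
#' @param mode recorded analysis mode, `"whole_section"` or `"per_roi"`.
#' @return list with `result` (threshold, method, mode, bin_index) and
#'   `mask` (a [binary_mask()] over the full image frame).
#' @export
auto_threshold <- function(image, method = "default_isodata", restrict = NULL,
                           mode = "whole_section") {
  stopifnot(inherits(image, "calibrated_image"))
  method <- match.arg(method, THRESHOLD_METHODS)
  vals <- if (is.null(restrict)) as.vector(image$pixels)
          else {
            check_same_frame(image, restrict)
            image$pixels[restrict$pixels]
          }
  if (length(vals) < 2L || min(vals) >= max(vals))
    stop("degenerate-histogram error: need >= 2 distinct intensities",
         call. = FALSE)
  h <- hist256(vals)
  idx <- select_threshold_index(h$counts, method)
  thr <- bin_upper_edge(h, idx)
  list(
    result = list(threshold = thr, bin_index = idx, method = method,
                  mode = mode),
    mask = binary_mask(image$pixels > thr, image$scale_um_per_px,
                       source_label = paste0("threshold:", method)))
}

#' Per-ROI auto-thresholding
#'
#' Applies [auto_threshold()] independently to each rectangular ROI crop;
#' per-ROI thresholds may differ (the second analysis mode of the reference
#' workflow). A constant-intensity ROI is flagged degenerate with an empty
#' mask rather than aborting the batch.
#'
#' @param image a [calibrated_image()].
#' @param rois list of [roi_box()] lying inside the image.
#' @param method threshold method name.
#' @return list of per-ROI records: `roi`, `result` (NULL when degenerate),
#'   `mask` ([binary_mask()] of the crop), `degenerate` flag.
#' @export
threshold_per_roi <- function(image, rois, method = "default_isodata") {
  stopifnot(inherits(image, "calibrated_image"))
  lapply(rois, function(box) {
    stopifnot(inherits(box, "roi_box"))
    roi_box(box$origin_px, box$size_px, parent_dim = dim(image$pixels))
    crop <- calibrated_image(crop_to_roi(image$pixels, box),
                             image$scale_um_per_px)
    out <- tryCatch(auto_threshold(crop, method, mode = "per_roi"),
                    error = function(e) NULL)
    if (is.null(out)) {
      list(roi = box, result = NULL,
           mask = binary_mask(matrix(FALSE, box$size_px[1], box$size_px[2]),
                              image$scale_um_per_px,
                              source_label = paste0("threshold:", method)),
           degenerate = TRUE)
    } else {
      list(roi = box, result = out$result, mask = out$mask,
           degenerate = FALSE)
    }
  })
}
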