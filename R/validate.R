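# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library calls never perturb user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample validation ROIs from sections
#'
#' For each section, places `candidates_per_section` rectangular ROIs
#' uniformly at random with their centers inside the region outline (and the
#' box fully inside the image), then retains exactly one per section by a
#' second seeded draw — mirroring a validation design where several ROIs are
#' extracted but one is randomly included, so that ROI choice cannot be
#' steered by segmentation quality. Deterministic given `seed`.
#'
#' @param sections list of lists with `image` ([calibrated_image()]),
#'   `outline` ([region_outline()]) and optional `section_id`.
#' @param roi_size_px integer `(height, width)`, e.g. c(400, 400) for
#'   membrane stains or c(200, 200) for nuclear stains.
#' @param candidates_per_section candidate ROIs per section (default 5).
#' @param seed integer seed.
#' @return list of ROI samples: `roi` ([roi_box()]), `section_id`,
#'   `retained` flag (exactly one TRUE per section), `included` (inclusion
#'   status, set later by [apply_inclusion_rules()]), `exclusion_reason`.
#' @export
sample_validation_rois <- function(sections, roi_size_px = c(400L, 400L),
                                   candidates_per_section = 5L, seed = 0L) {
  roi_size_px <- as.integer(roi_size_px)
  with_seed(seed, {
    out <- list()
    for (si in seq_along(sections)) {
      sec <- sections[[si]]
      img <- sec$image; outl <- sec$outline
      sid <- sec$section_id %||% img$source_id %||% as.character(si)
      nr <- nrow(img$pixels); nc <- ncol(img$pixels)
      s <- img$scale_um_per_px
      if (roi_size_px[1] > nr || roi_size_px[2] > nc)
        stop("sampling error: ROI larger than section ", sid, call. = FALSE)
      bb <- sapply(outl$polygons, function(p) c(range(p$outer[, 1]),
                                                range(p$outer[, 2])))
      xr <- c(min(bb[1, ]), max(bb[2, ])); yr <- c(min(bb[3, ]), max(bb[4, ]))
      cands <- list()
      tries <- 0L
      while (length(cands) < candidates_per_section) {
        tries <- tries + 1L
        if (tries > 2000L * candidates_per_section)
          stop("sampling error: region too small for the requested ROI",
               call. = FALSE)
        x <- runif(1, xr[1], xr[2]); y <- runif(1, yr[1], yr[2])
        if (!point_in_outline(x, y, outl)) next
        r0 <- as.integer(round(y / s - roi_size_px[1] / 2))
        c0 <- as.integer(round(x / s - roi_size_px[2] / 2))
        if (r0 < 0L || c0 < 0L || r0 + roi_size_px[1] > nr ||
            c0 + roi_size_px[2] > nc) next
        cands[[length(cands) + 1L]] <- roi_box(c(r0, c0), roi_size_px)
      }
      pick <- sample.int(length(cands), 1L)
      for (k in seq_along(cands)) {
        out[[length(out) + 1L]] <- list(
          roi = cands[[k]], section_id = sid, retained = (k == pick),
          included = NA, exclusion_reason = NULL)
      }
    }
    out
  })
}

point_in_outline <- function(x, y, outline) {
  for (p in outline$polygons) {
    if (sp::point.in.polygon(x, y, p$outer[, 1], p$outer[, 2]) > 0) {
      in_hole <- FALSE
      for (h in p$holes) {
        if (sp::point.in.polygon(x, y, h[, 1], h[, 2]) == 1) in_hole <- TRUE
      }
      if (!in_hole) return(TRUE)
    }
  }
  FALSE
}

#' Apply validation inclusion rules to a reference ROI payload
#'
#' Validation metrics are unstable when an ROI is nearly empty or nearly
#' saturated, so membrane-stain ROIs are included only when the reference
#' positive area fraction lies in `[0.1, 0.9]` (bounds inclusive) and
#' nuclear-stain ROIs only when the reference observer marked at least five
#' nuclei.
#'
#' @param roi_payload a [binary_mask()] (membrane) or [point_set()] (nuclear)
#'   of the *reference* annotation for the ROI.
#' @param stain_class `"membrane"` or `"nuclear"`.
#' @return list with `included` (logical) and `reason` (NULL when included).
#' @export
apply_inclusion_rules <- function(roi_payload, stain_class) {
  stain_class <- match.arg(stain_class, c("membrane", "nuclear"))
  if (stain_class == "membrane") {
    if (!inherits(roi_payload, "binary_mask"))
      stop("membrane inclusion needs a binary_mask payload", call. = FALSE)
    f <- mean(roi_payload$pixels)
    if (f < 0.1) return(list(included = FALSE,
                             reason = "area fraction below 0.1"))
    if (f > 0.9) return(list(included = FALSE,
                             reason = "area fraction above 0.9"))
    list(included = TRUE, reason = NULL)
  } else {
    if (!inherits(roi_payload, "point_set"))
      stop("nuclear inclusion needs a point_set payload", call. = FALSE)
    n <- nrow(roi_payload$points)
    if (n < 5L) return(list(included = FALSE,
                            reason = "fewer than 5 reference nuclei"))
    list(included = TRUE, reason = NULL)
  }
}

#' Pixel confusion counts between two masks
#' @param reference,comparator [binary_mask()] objects of identical shape.
#' @return list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
pixel_confusion <- function(reference, comparator) {
  stopifnot(inherits(reference, "binary_mask"),
            inherits(comparator, "binary_mask"))
  check_same_frame(reference, comparator)
  r <- reference$pixels; c <- comparator$pixels
  list(tp = sum(r & c), fp = sum(!r & c), fn = sum(r & !c), tn = sum(!r & !c))
}

#' Pixel-level segmentation metrics (sensitivity, specificity, Dice)
#'
#' Dice is computed as `2 * TP / ((TP + FP) + (TP + FN))` for the comparator
#' relative to the reference (equivalent to the F1 score for binary masks).
#' Any 0/0 ratio is reported as `NA` and listed in `undefined` rather than
#' silently coerced to 0, so degenerate ROIs cannot bias summaries.
#'
#' @param reference,comparator [binary_mask()] objects of identical shape.
#' @return list with `sensitivity`, `specificity`, `dice`, the `confusion`
#'   counts and an `undefined` character vector.
#' @export
pixel_metrics <- function(reference, comparator) {
  cf <- pixel_confusion(reference, comparator)
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  sens <- ratio(cf$tp, cf$tp + cf$fn, "sensitivity")
  spec <- ratio(cf$tn, cf$tn + cf$fp, "specificity")
  dice <- ratio(2 * cf$tp, (cf$tp + cf$fp) + (cf$tp + cf$fn), "dice")
  list(sensitivity = sens, specificity = spec, dice = dice,
       confusion = cf, undefined = undef)
}

#' One-to-one point matching within a radius
#'
#' Matches reference and comparator points one-to-one within `radius_um`:
#' first greedily, globally nearest pair first (the smallest-distance
#' unmatched pair is fixed repeatedly, ties broken by lower reference then
#' comparator index), then repaired by augmenting paths so the matching has
#' maximum cardinality over the radius-constrained bipartite graph. On
#' realistic detection data (point spacing well above the jitter between
#' observers) the greedy stage is already maximal and the repair is a no-op;
#' on adversarial configurations the repair recovers matches a pure greedy
#' pass would forfeit. The result is order-invariant and deterministic.
#'
#' @param reference,comparator [point_set()] objects (coordinates in um).
#' @param radius_um maximum center-to-center match distance (default 5).
#' @return list of class `match_result`: `pairs` (data.frame of
#'   reference/comparator indices and distance), `unmatched_reference`,
#'   `unmatched_comparator`, `radius_um`.
#' @export
match_points <- function(reference, comparator, radius_um = 5) {
  stopifnot(inherits(reference, "point_set"), inherits(comparator, "point_set"))
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("`radius_um` must be positive", call. = FALSE)
  rp <- reference$points; cp <- comparator$points
  nr <- nrow(rp); nc <- nrow(cp)
  match_r <- integer(nr) # ref -> comp, 0 = unmatched
  match_c <- integer(nc)
  d <- NULL
  if (nr > 0 && nc > 0) {
    dx <- outer(rp[, 1], cp[, 1], "-"); dy <- outer(rp[, 2], cp[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d <= radius_um, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (match_r[i] == 0L && match_c[j] == 0L) {
          match_r[i] <- j; match_c[j] <- i
        }
      }
      # augmenting-path repair to maximum cardinality; comparator
      # candidates visited nearest-first for determinism
      adj <- lapply(seq_len(nr), function(i) {
        js <- which(d[i, ] <= radius_um)
        js[order(d[i, js], js)]
      })
      augment <- function(i, st) {
        for (j in adj[[i]]) {
          if (!st$seen[j]) {
            st$seen[j] <- TRUE
            owner <- match_c[j]
            if (owner == 0L || augment(owner, st)) {
              match_r[i] <<- j; match_c[j] <<- i
              return(TRUE)
            }
          }
        }
        FALSE
      }
      for (i in which(match_r == 0L)) {
        if (length(adj[[i]])) {
          st <- new.env(parent = emptyenv())
          st$seen <- logical(nc)
          augment(i, st)
        }
      }
    }
  }
  mi <- which(match_r > 0L)
  pairs <- data.frame(reference = mi, comparator = match_r[mi],
                      distance_um = if (length(mi)) d[cbind(mi, match_r[mi])]
                                    else numeric(0))
  structure(list(
    pairs = pairs,
    unmatched_reference = which(match_r == 0L),
    unmatched_comparator = which(match_c == 0L),
    n_reference = nr, n_comparator = nc, radius_um = radius_um),
    class = "match_result")
}

#' Detection Dice score from a match result
#'
#' `2 * |pairs| / (n_reference + n_comparator)`; when both sets are empty the
#' score is undefined and returned as `NA` (flagged), never 0.
#'
#' @param match a `match_result` from [match_points()].
#' @return Dice score in `[0, 1]`, or `NA` for the 0/0 case.
#' @export
detection_dice <- function(match) {
  stopifnot(inherits(match, "match_result"))
  den <- match$n_reference + match$n_comparator
  if (den == 0) return(NA_real_)
  2 * nrow(match$pairs) / den
}

#' Observer-comparison report
#'
#' Computes the per-ROI validation metric of each comparator against the
#' reference annotation and appends per-comparator summary rows (median and
#' interquartile range, the standard reporting for observer panels). For
#' membrane stains the metric set is pixel sensitivity/specificity/Dice; for
#' nuclear stains it is the detection Dice at `radius_um`.
#'
#' @param reference list of per-ROI reference payloads ([binary_mask()] or
#'   [point_set()] per `stain_class`).
#' @param comparators named list; each element is a list of per-ROI payloads
#'   parallel to `reference`.
#' @param stain_class `"membrane"` or `"nuclear"`.
#' @param radius_um matching radius for nuclear stains (default 5).
#' @return data.frame with columns comparator, roi, metric columns and a
#'   `row_type` of `"roi"`, `"median"` or `"iqr"`.
#' @export
observer_report <- function(reference, comparators, stain_class,
                            radius_um = 5) {
  stain_class <- match.arg(stain_class, c("membrane", "nuclear"))
  if (is.null(names(comparators)) || any(!nzchar(names(comparators))))
    stop("`comparators` must be a named list", call. = FALSE)
  n_roi <- length(reference)
  rows <- list()
  for (nm in names(comparators)) {
    comp <- comparators[[nm]]
    if (length(comp) != n_roi)
      stop("comparator '", nm, "' does not cover the reference ROI list",
           call. = FALSE)
    for (i in seq_len(n_roi)) {
      if (stain_class == "membrane") {
        pm <- pixel_metrics(reference[[i]], comp[[i]])
        rows[[length(rows) + 1L]] <- data.frame(
          comparator = nm, roi = i, row_type = "roi",
          sensitivity = pm$sensitivity, specificity = pm$specificity,
          dice = pm$dice)
      } else {
        dd <- detection_dice(match_points(reference[[i]], comp[[i]],
                                          radius_um))
        rows[[length(rows) + 1L]] <- data.frame(
          comparator = nm, roi = i, row_type = "roi",
          sensitivity = NA_real_, specificity = NA_real_, dice = dd)
      }
    }
  }
  df <- do.call(rbind, rows)
  summaries <- list()
  for (nm in names(comparators)) {
    sub <- df[df$comparator == nm, ]
    med <- vapply(sub[c("sensitivity", "specificity", "dice")],
                  function(v) median(v, na.rm = TRUE), 0)
    iqr <- vapply(sub[c("sensitivity", "specificity", "dice")], function(v) {
      q <- quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
      q[2] - q[1]
    }, 0)
    summaries[[length(summaries) + 1L]] <- data.frame(
      comparator = nm, roi = NA_integer_, row_type = "median",
      sensitivity = med[1], specificity = med[2], dice = med[3])
    summaries[[length(summaries) + 1L]] <- data.frame(
      comparator = nm, roi = NA_integer_, row_type = "iqr",
      sensitivity = iqr[1], specificity = iqr[2], dice = iqr[3])
  }
  rbind(df, do.call(rbind, summaries))
}
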