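DEFAULT_FEATURE_SCALES <- c(0.7, 1.0, 1.6, 3.5, 5.0)

# Gaussian and Gaussian-derivative 1-D kernels (truncated at 3 sigma).
gauss_deriv_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  d1 <- -x / sigma^2 * g
  d2 <- (x^2 - sigma^2) / sigma^4 * g
  list(g = g, d1 = d1, d2 = d2)
}

#' Per-pixel filter-bank features for pixel classification
#'
#' The classic interactive-learning filter bank: Gaussian-smoothed
#' intensity, Laplacian of Gaussian, Gaussian gradient magnitude and the two
#' structure-tensor eigenvalues, each at scales sigma in
#' `{0.7, 1.0, 1.6, 3.5, 5.0}` px by default, plus the raw intensity.
#'
#' @param pixels numeric matrix of intensities.
#' @param scales numeric vector of filter scales in pixels.
#' @return 3-D array `[nrow, ncol, n_features]` with named feature slices.
#' @export
pixel_features <- function(pixels, scales = DEFAULT_FEATURE_SCALES) {
  stopifnot(is.matrix(pixels), length(scales) >= 1)
  feats <- list(raw = pixels)
  for (s in scales) {
    k <- gauss_deriv_kernels(s)
    sm <- cpp_conv1d(cpp_conv1d(pixels, k$g, 1L), k$g, 2L)
    gx <- cpp_conv1d(cpp_conv1d(pixels, k$g, 1L), k$d1, 2L)
    gy <- cpp_conv1d(cpp_conv1d(pixels, k$d1, 1L), k$g, 2L)
    lap <- cpp_conv1d(cpp_conv1d(pixels, k$d2, 1L), k$g, 2L) +
           cpp_conv1d(cpp_conv1d(pixels, k$g, 1L), k$d2, 2L)
    # structure tensor: gradient products smoothed at the same scale
    jxx <- cpp_conv1d(cpp_conv1d(gx * gx, k$g, 1L), k$g, 2L)
    jxy <- cpp_conv1d(cpp_conv1d(gx * gy, k$g, 1L), k$g, 2L)
    jyy <- cpp_conv1d(cpp_conv1d(gy * gy, k$g, 1L), k$g, 2L)
    tr <- (jxx + jyy) / 2
    disc <- sqrt(pmax(((jxx - jyy) / 2)^2 + jxy^2, 0))
    tag <- sprintf("s%.1f", s)
    feats[[paste0("gauss_", tag)]] <- sm
    feats[[paste0("log_", tag)]] <- lap
    feats[[paste0("gradmag_", tag)]] <- sqrt(gx^2 + gy^2)
    feats[[paste0("st_eig1_", tag)]] <- tr + disc
    feats[[paste0("st_eig2_", tag)]] <- tr - disc
  }
  arr <- array(unlist(feats, use.names = FALSE),
               dim = c(nrow(pixels), ncol(pixels), length(feats)))
  dimnames(arr) <- list(NULL, NULL, names(feats))
  arr
}

# ---- native random forest (bagged CART, Gini, random feature subsets) ----

rf_build_tree <- function(X, y, mtry, max_depth, min_node) {
  # nodes stored in a growing list; children indices filled after recursion
  nodes <- list()
  grow <- function(idx, depth) {
    n1 <- sum(y[idx] == 1L); n0 <- length(idx) - n1
    node <- list(leaf = TRUE, pred = if (n1 >= n0) 1L else 2L,
                 feature = NA_integer_, cut = NA_real_,
                 left = NA_integer_, right = NA_integer_)
    me <- length(nodes) + 1L
    nodes[[me]] <<- node
    if (depth >= max_depth || length(idx) < min_node || n1 == 0L || n0 == 0L)
      return(me)
    feats <- sample.int(ncol(X), min(mtry, ncol(X)))
    best <- list(gain = 0)
    py <- y[idx] == 1L
    gini_parent <- 2 * mean(py) * (1 - mean(py))
    for (f in feats) {
      v <- X[idx, f]
      cuts <- unique(quantile(v, probs = seq(0.05, 0.95, length.out = 15),
                              names = FALSE, type = 7))
      for (cut in cuts) {
        l <- v <= cut
        nl <- sum(l); nr <- length(idx) - nl
        if (nl == 0L || nr == 0L) next
        pl <- mean(py[l]); pr <- mean(py[!l])
        gini <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) /
          length(idx)
        gain <- gini_parent - gini
        if (gain > best$gain + 1e-12) best <- list(gain = gain, f = f, cut = cut)
      }
    }
    if (best$gain <= 0) return(me)
    v <- X[idx, best$f]
    li <- idx[v <= best$cut]; ri <- idx[v > best$cut]
    lnode <- grow(li, depth + 1L)
    rnode <- grow(ri, depth + 1L)
    nodes[[me]] <<- list(leaf = FALSE, pred = NA_integer_,
                         feature = best$f, cut = best$cut,
                         left = lnode, right = rnode)
    me
  }
  grow(seq_len(nrow(X)), 0L)
  # flatten to a matrix for fast vectorized prediction
  t(vapply(nodes, function(nd) c(as.integer(nd$leaf), nd$pred %||% NA_integer_,
                                 nd$feature, nd$cut, nd$left, nd$right),
           numeric(6)))
}

rf_predict_tree <- function(tree, X) {
  n <- nrow(X)
  node <- rep(1L, n)
  out <- integer(n)
  active <- seq_len(n)
  while (length(active)) {
    nd <- node[active]
    leaf <- tree[nd, 1] == 1
    if (any(leaf)) {
      out[active[leaf]] <- as.integer(tree[nd[leaf], 2])
      active <- active[!leaf]
      if (!length(active)) break
      nd <- node[active]
    }
    f <- as.integer(tree[nd, 3]); cut <- tree[nd, 4]
    goleft <- X[cbind(active, f)] <= cut
    node[active] <- as.integer(ifelse(goleft, tree[nd, 5], tree[nd, 6]))
  }
  out
}

#' Train a random-forest pixel classifier
#'
#' Trains bagged CART trees (Gini impurity, random feature subsets) on
#' filter-bank features of annotated pixels, in the mould of the default
#' interactive pixel classifier of segmentation tools: label images mark
#' pixels positive (1), negative (2) or unlabeled (0), and the model
#' predicts one class per pixel.
#'
#' @param images list of [calibrated_image()] training images.
#' @param annotations list of integer label matrices (same shapes;
#'   0 = unlabeled, 1 = positive, 2 = negative).
#' @param n_trees number of trees (default 100).
#' @param scales filter-bank scales in px (default
#'   `{0.7, 1.0, 1.6, 3.5, 5.0}`).
#' @param max_samples_per_class cap on training pixels drawn per class
#'   (default 4000).
#' @param seed RNG seed for bagging and feature subsets (default 0; fixed
#'   seed gives an identical model and identical masks).
#' @param max_depth,min_node tree growth limits.
#' @return list of class `pixel_classifier` with `trees`, `feature_spec`,
#'   `classes`, `seed`.
#' @export
train_pixel_classifier <- function(images, annotations, n_trees = 100L,
                                   scales = DEFAULT_FEATURE_SCALES,
                                   max_samples_per_class = 4000L,
                                   seed = 0L, max_depth = 12L, min_node = 5L) {
  stopifnot(length(images) == length(annotations), length(images) >= 1)
  Xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]; ann <- annotations[[i]]
    stopifnot(inherits(img, "calibrated_image"),
              identical(dim(img$pixels), dim(ann)))
    lab <- which(ann != 0L)
    if (!length(lab)) next
    fb <- pixel_features(img$pixels, scales)
    fm <- matrix(fb, nrow = prod(dim(fb)[1:2]))
    Xs[[length(Xs) + 1L]] <- fm[lab, , drop = FALSE]
    ys[[length(ys) + 1L]] <- as.integer(ann[lab])
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  if (is.null(X) || length(unique(y)) < 2L)
    stop("training error: annotations must contain both classes",
         call. = FALSE)
  with_seed(seed, {
    keep <- unlist(lapply(c(1L, 2L), function(cl) {
      w <- which(y == cl)
      if (length(w) > max_samples_per_class)
        sample(w, max_samples_per_class) else w
    }))
    X <- X[keep, , drop = FALSE]; y <- y[keep]
    mtry <- max(1L, floor(sqrt(ncol(X))))
    trees <- lapply(seq_len(n_trees), function(t) {
      boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
      rf_build_tree(X[boot, , drop = FALSE], y[boot], mtry, max_depth,
                    min_node)
    })
    structure(list(trees = trees,
                   feature_spec = list(scales = scales,
                                       names = dimnames(pixel_features(
                                         matrix(0, 8, 8), scales))[[3]]),
                   classes = c(positive = 1L, negative = 2L),
                   n_trees = as.integer(n_trees), seed = as.integer(seed)),
              class = "pixel_classifier")
  })
}

#' Predict a segmentation mask with a trained pixel classifier
#'
#' Majority vote over the forest; the positive class maps to `TRUE`.
#' Prediction is deterministic given a fixed model.
#'
#' @param model a `pixel_classifier` from [train_pixel_classifier()].
#' @param image a [calibrated_image()].
#' @return A [binary_mask()].
#' @export
predict_pixel_classifier <- function(model, image) {
  if (!inherits(model, "pixel_classifier") || is.null(model$trees) ||
      length(model$trees) == 0L)
    stop("state error: model is not a trained pixel_classifier",
         call. = FALSE)
  stopifnot(inherits(image, "calibrated_image"))
  fb <- pixel_features(image$pixels, model$feature_spec$scales)
  fm <- matrix(fb, nrow = prod(dim(fb)[1:2]))
  votes_pos <- integer(nrow(fm))
  for (tr in model$trees) {
    votes_pos <- votes_pos + (rf_predict_tree(tr, fm) == 1L)
  }
  mask <- matrix(votes_pos >= length(model$trees) / 2,
                 nrow(image$pixels), ncol(image$pixels))
  binary_mask(mask, image$scale_um_per_px, source_label = "pixel_classifier")
}

#' Save / load a pixel classifier
#'
#' The model is a plain list of numeric tree matrices, serialized with R's
#' native format; it round-trips bit-identically.
#'
#' @param model a `pixel_classifier`.
#' @param path file path.
#' @return `path` / the model.
#' @export
save_pixel_classifier <- function(model, path) {
  stopifnot(inherits(model, "pixel_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pixel_classifier"))
    stop("not a pixel_classifier file", call. = FALSE)
  model
}
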