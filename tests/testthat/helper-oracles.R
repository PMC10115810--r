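# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with R/: plain loops and naive formulas.

# Brute-force grayscale opening with a ball element: for every pixel, an
# explicit min then max over all offsets within the radius, offsets outside
# the image ignored.
oracle_gray_open_ball <- function(img, radius) {
  r <- as.integer(radius)
  offs <- list()
  for (dr in -r:r) for (dc in -r:r) {
    d2 <- dr^2 + dc^2
    if (d2 <= radius^2) offs[[length(offs) + 1L]] <-
        c(dr, dc, sqrt(radius^2 - d2))
  }
  nr <- nrow(img); nc <- ncol(img)
  er <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    best <- Inf
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        best <- min(best, img[ii, jj] - o[3])
    }
    er[i, j] <- best
  }
  di <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    best <- -Inf
    for (o in offs) {
      ii <- i - o[1]; jj <- j - o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        best <- max(best, er[ii, jj] + o[3])
    }
    di[i, j] <- best
  }
  di
}

# ---- brute-force threshold selectors on a 256-bin histogram ---------------

oracle_thr_otsu <- function(h) {
  best <- -Inf; best_t <- 0L
  for (t in 0:254) {
    lo <- 0:t; hi <- (t + 1):255
    n0 <- sum(h[lo + 1]); n1 <- sum(h[hi + 1])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(lo * h[lo + 1]) / n0
    mu1 <- sum(hi * h[hi + 1]) / n1
    v <- n0 * n1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}

oracle_thr_mean <- function(h) floor(sum((0:255) * h) / sum(h))

# Scan form of the clipped-histogram iterative-intermeans "default": smallest
# m with intermean(m) < m + 2 (or the upper cap), threshold = round of that
# intermean.
oracle_thr_default <- function(h) {
  d <- h; d[1] <- 0; d[256] <- 0
  nz <- which(d > 0) - 1L
  if (length(nz) == 0L) return(127L)
  mn <- min(nz); mx <- max(nz)
  if (mn >= mx) return(127L)
  f <- function(m) {
    lo <- mn:m; hi <- if (m < mx) (m + 1):mx else integer(0)
    a <- if (sum(d[lo + 1]) > 0) sum(lo * d[lo + 1]) / sum(d[lo + 1]) else 0
    b <- if (length(hi) && sum(d[hi + 1]) > 0)
      sum(hi * d[hi + 1]) / sum(d[hi + 1]) else 0
    (a + b) / 2
  }
  m <- mn
  repeat {
    r <- f(m)
    if (r < m + 2 || m >= mx - 2L) return(as.integer(round(r)))
    m <- m + 1L
  }
}

# Triangle by direct signed perpendicular point-line distance over all bins
# between the adjusted tail end and the peak, using the pinned convention:
# the reference line passes through (min, h[min]) and rises by the peak
# height over the min->peak run; the threshold is one bin below the
# furthest-below-line bin, after unflipping.
oracle_thr_triangle <- function(h) {
  d <- as.numeric(h); n <- length(d)
  nz <- which(d > 0) - 1L
  mn <- min(nz); if (mn > 0) mn <- mn - 1L
  mn2 <- max(nz); if (mn2 < n - 1L) mn2 <- mn2 + 1L
  peak <- which.max(d) - 1L
  inverted <- (peak - mn) < (mn2 - peak)
  if (inverted) {
    d <- rev(d)
    mn <- n - 1L - mn2
    peak <- n - 1L - peak
  }
  if (mn == peak) {
    split <- mn
  } else {
    a <- c(mn, d[mn + 1])
    b <- c(peak, a[2] + d[peak + 1]) # rises by the peak height
    v <- b - a
    best <- -Inf; split <- mn
    for (i in (mn + 1L):peak) {
      below <- (v[2] * (i - a[1]) - v[1] * (d[i + 1] - a[2])) / sqrt(sum(v^2))
      if (below > best) { best <- below; split <- i }
    }
    split <- split - 1L
  }
  as.integer(if (inverted) n - 1L - split else split)
}

# Li: exhaustive scan minimizing the cross-entropy criterion.
oracle_thr_li <- function(h) {
  i <- 0:255
  crit <- rep(Inf, 255)
  for (t in 0:254) {
    lo <- i <= t
    sb <- sum(i[lo] * h[lo]); so <- sum(i[!lo] * h[!lo])
    nb <- sum(h[lo]); no <- sum(h[!lo])
    val <- 0
    if (sb > 0 && nb > 0) val <- val - sb * log(sb / nb)
    if (so > 0 && no > 0) val <- val - so * log(so / no)
    crit[t + 1] <- val
  }
  which.min(crit) - 1L
}

oracle_threshold <- function(h, method) {
  switch(method,
    default_isodata = oracle_thr_default(h),
    otsu = oracle_thr_otsu(h),
    triangle = oracle_thr_triangle(h),
    mean = oracle_thr_mean(h),
    li = oracle_thr_li(h))
}

# Realistic random histogram: two-component Gaussian mixture plus noise.
random_bimodal_hist <- function() {
  mu1 <- runif(1, 20, 90); mu2 <- runif(1, 130, 235)
  s1 <- runif(1, 5, 25); s2 <- runif(1, 5, 30)
  w <- runif(1, 0.3, 0.95)
  n <- 20000
  v <- c(rnorm(round(n * w), mu1, s1), rnorm(round(n * (1 - w)), mu2, s2))
  v <- pmin(pmax(round(v), 0), 255)
  tabulate(v + 1L, nbins = 256L)
}

# ---- point-in-polygon by even-odd ray casting -----------------------------
oracle_point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in 1:n) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# ---- maximum bipartite matching (Kuhn augmenting paths) -------------------
oracle_max_matching <- function(ref, comp, radius) {
  nr <- nrow(ref); nc <- nrow(comp)
  if (nr == 0 || nc == 0) return(0L)
  adj <- vector("list", nr)
  for (i in 1:nr) {
    d <- sqrt((comp[, 1] - ref[i, 1])^2 + (comp[, 2] - ref[i, 2])^2)
    adj[[i]] <- which(d <= radius)
  }
  aug <- function(i, seen_env) {
    for (j in adj[[i]]) {
      if (!seen_env$seen[j]) {
        seen_env$seen[j] <- TRUE
        if (seen_env$match_c[j] == 0L || aug(seen_env$match_c[j], seen_env)) {
          seen_env$match_c[j] <- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  env <- new.env()
  env$match_c <- rep(0L, nc)
  total <- 0L
  for (i in 1:nr) {
    env$seen <- rep(FALSE, nc)
    if (aug(i, env)) total <- total + 1L
  }
  total
}

# ---- independent hexagonal lattice enumeration for a square region --------
# Square [0, S] x [0, S]; lattice anchored at (r, r); count centers whose
# disk fits entirely inside (center at least r from each side).
oracle_hex_count_square <- function(S, r) {
  dy <- r * sqrt(3)
  count <- 0L
  j <- 0L
  repeat {
    y <- r + j * dy
    if (y > S - r + 1e-9) break
    off <- if (j %% 2 == 0) 0 else r
    x <- r + off
    while (x <= S - r + 1e-9) {
      count <- count + 1L
      x <- x + 2 * r
    }
    j <- j + 1L
  }
  count
}

# ---- fixture builders -----------------------------------------------------
# Disk mask built by vectorized grid arithmetic (not the package renderer).
fixture_disk_mask <- function(nr, nc, centers_rc, radii_px, scale = 1) {
  m <- matrix(FALSE, nr, nc)
  rows <- matrix(1:nr, nr, nc); cols <- matrix(1:nc, nr, nc, byrow = TRUE)
  for (k in seq_len(nrow(centers_rc))) {
    m <- m | ((rows - centers_rc[k, 1])^2 + (cols - centers_rc[k, 2])^2 <=
                radii_px[k]^2)
  }
  binary_mask(m, scale)
}

square_outline <- function(S, label = "square") {
  region_outline(cbind(c(0, S, S, 0), c(0, 0, S, S)), label = label)
}

# Minimum-total-distance matching of maximum cardinality, exact bitmask DP
# over comparator subsets (use only for <= ~10 points per side).
oracle_min_cost_max_matching <- function(ref, comp, radius) {
  nr <- nrow(ref); nc <- nrow(comp)
  if (nr == 0 || nc == 0) return(list(card = 0L, cost = 0))
  d <- sqrt(outer(ref[, 1], comp[, 1], "-")^2 +
            outer(ref[, 2], comp[, 2], "-")^2)
  d[d > radius] <- NA
  # state: best (card, cost) per used-comparator bitmask after each ref point
  best_card <- rep(-1L, 2^nc); best_cost <- rep(Inf, 2^nc)
  best_card[1] <- 0L; best_cost[1] <- 0
  for (i in seq_len(nr)) {
    nb_card <- best_card; nb_cost <- best_cost
    for (mask in which(best_card >= 0L) - 1L) {
      for (j in seq_len(nc)) {
        if (is.na(d[i, j]) || bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L)
          next
        nm <- bitwOr(mask, bitwShiftL(1L, j - 1L)) + 1L
        cand_card <- best_card[mask + 1L] + 1L
        cand_cost <- best_cost[mask + 1L] + d[i, j]
        if (cand_card > nb_card[nm] ||
            (cand_card == nb_card[nm] && cand_cost < nb_cost[nm])) {
          nb_card[nm] <- cand_card; nb_cost[nm] <- cand_cost
        }
      }
    }
    best_card <- nb_card; best_cost <- nb_cost
  }
  top <- max(best_card)
  list(card = top, cost = min(best_cost[best_card == top]))
}
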