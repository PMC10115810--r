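#' Specification of a synthetic kidney-section scene
#'
#' Describes a calibrated synthetic section: a section-shaped region (ellipse
#' with a hilum-like notch), tubule cross-sections rendered as membrane rims,
#' nuclei as filled disks, per-channel stain intensity models, additive
#' smooth background (to exercise rolling-ball subtraction), Gaussian noise,
#' and a latent Gaussian random field that modulates object placement so two
#' channels can share spatial structure with a controllable tile-level
#' correlation.
#'
#' Defaults mirror the acquisition the toolkit targets: 0.5 um/px slide
#' scans, 200 um analysis radius, stained-tubule densities of order
#' 100/mm^2 (injury markers are patchy, far below the anatomical tubule
#' packing), nuclear radii 3-5 um, tubule cross-section radii 15-25 um.
#'
#' @param width_mm,height_mm section bounding extent (default 2.5 x 2).
#' @param scale_um_per_px calibration (default 0.5).
#' @param channels named list of channel specs; each a list with `pattern`
#'   (`"membrane"`, `"nuclear"` or `"structure"`), `density_per_mm2`,
#'   `radius_um_range`, `fg_mean`, `fg_sd`, `bg_mean`, `bg_sd`, and for
#'   membrane channels `rim_um` (rim thickness, default 3).
#' @param overlap_fraction fraction of nuclei placed as touching pairs
#'   (default 0).
#' @param correlation_length_um latent-field correlation length (default 300).
#' @param rho target tile-level density correlation between the first two
#'   channels (default 0).
#' @param modulation_sd log-scale strength of the latent modulation
#'   (default 0.8); the local intensity multiplier is
#'   `exp(g * Z - g^2 / 2)` with `Z` a standard Gaussian field.
#' @param tile_radius_um tile radius at which `rho` is calibrated
#'   (default 200, the spatial-analysis standard).
#' @param noise_sd additive Gaussian read-noise SD (default 8).
#' @param background_amp,background_length_um smooth additive background
#'   amplitude and correlation length (defaults 30 and 800).
#' @param seed integer; fixes the entire scene.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(width_mm = 2.5, height_mm = 2,
                       scale_um_per_px = 0.5,
                       channels = default_channels(),
                       overlap_fraction = 0,
                       correlation_length_um = 300,
                       rho = 0,
                       modulation_sd = 0.8,
                       tile_radius_um = 200,
                       noise_sd = 8,
                       background_amp = 30,
                       background_length_um = 800,
                       seed = 0L) {
  stopifnot(width_mm > 0, height_mm > 0, scale_um_per_px > 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            rho >= -1, rho <= 1, modulation_sd >= 0, noise_sd >= 0)
  for (ch in channels) {
    stopifnot(ch$pattern %in% c("membrane", "nuclear", "structure"),
              ch$density_per_mm2 >= 0, all(ch$radius_um_range > 0))
  }
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 scale_um_per_px = scale_um_per_px, channels = channels,
                 overlap_fraction = overlap_fraction,
                 correlation_length_um = correlation_length_um, rho = rho,
                 modulation_sd = modulation_sd,
                 tile_radius_um = tile_radius_um, noise_sd = noise_sd,
                 background_amp = background_amp,
                 background_length_um = background_length_um,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @export
default_channels <- function() {
  list(
    memA = list(pattern = "membrane", density_per_mm2 = 100,
                radius_um_range = c(15, 25), rim_um = 3,
                fg_mean = 180, fg_sd = 15, bg_mean = 15, bg_sd = 5),
    nucA = list(pattern = "nuclear", density_per_mm2 = 100,
                radius_um_range = c(3, 5),
                fg_mean = 200, fg_sd = 15, bg_mean = 15, bg_sd = 5))
}

# Ellipse-with-notch section outline polygon (um), centered in the extent.
section_outline_polygon <- function(width_um, height_um, n = 256) {
  cx <- width_um / 2; cy <- height_um / 2
  a <- 0.475 * width_um; b <- 0.45 * height_um
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  scale <- rep(1, n)
  # hilum-like concave notch around angle pi
  w <- pmax(0, cos((th - pi) / 0.45 * pi / 2))
  scale <- 1 - 0.35 * ifelse(abs(th - pi) < 0.45, w, 0)
  x <- cx + a * scale * cos(th)
  y <- cy + b * scale * sin(th)
  region_outline(cbind(x, y), label = "cortex+OSOM")
}

# Standard Gaussian random field on an nr x nc grid by spectral smoothing of
# white noise with a periodic Gaussian kernel; corr(d) ~ exp(-d^2/(2 L^2))
# for smoothing sigma = L / sqrt(2). Standardized to mean 0, sd 1.
gaussian_random_field <- function(nr, nc, length_px) {
  sigma <- max(length_px / sqrt(2), 1e-6)
  w <- matrix(rnorm(nr * nc), nr, nc)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kr <- exp(-dr^2 / (2 * sigma^2)); kc <- exp(-dc^2 / (2 * sigma^2))
  kmat <- outer(kr, kc)
  f <- Re(fft(fft(w) * fft(kmat), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / sd(f)
}

# Pairwise field correlations over a disk of radius R for Gaussian
# correlation exp(-d^2/(2 L^2)); deterministic grid quadrature. Returns the
# vector of pair correlations (including self pairs), the substrate for
# exact lognormal tile-moment calculations.
pair_corr_in_disk <- function(R, L) {
  h <- R / 6
  g <- expand.grid(x = seq(-R, R, by = h), y = seq(-R, R, by = h))
  g <- g[g$x^2 + g$y^2 <= R^2, ]
  d2 <- outer(g$x, g$x, "-")^2 + outer(g$y, g$y, "-")^2
  as.vector(exp(-d2 / (2 * L^2)))
}

# Per-object mask area moments (um^2) for a channel's object geometry.
object_area_moments <- function(ch) {
  rr <- seq(ch$radius_um_range[1], ch$radius_um_range[2], length.out = 101)
  a <- if (ch$pattern == "membrane") {
    rim <- ch$rim_um %||% 3
    pi * (rr^2 - pmax(rr - rim, 0)^2)
  } else pi * rr^2
  list(m1 = mean(a), m2 = mean(a^2))
}

# Compound-Poisson moments of one channel's tile density, scaled so both
# are relative to (mu * E[a])^2: `V` is the tile-averaged lognormal signal
# variance, `noise` the Poisson sampling term. The tile-level correlation a
# field correlation rho_f induces between two such channels is
#   C(rho_f) / sqrt((V_a + noise_a) * (V_b + noise_b)),
# with C(rho_f) = mean over point pairs of exp(g^2 rho_f rho(d)) - 1.
channel_tile_moments <- function(ch, spec, pair_corr) {
  At <- pi * spec$tile_radius_um^2            # um^2
  mu <- ch$density_per_mm2 * At / 1e6         # expected objects per tile
  if (mu <= 0) return(NULL)
  mo <- object_area_moments(ch)
  g2 <- spec$modulation_sd^2
  V <- mean(exp(g2 * pair_corr) - 1)
  noise <- mo$m2 / (mu * mo$m1^2)
  list(V = V, noise = noise)
}

# Solve the Gaussian-field cross-correlation needed so that the *measured*
# tile densities of the first two channels correlate at rho (exact lognormal
# pair-moment model, solved by root finding; monotone in rho_f).
solve_field_correlation <- function(spec) {
  if (length(spec$channels) < 2 || spec$rho == 0) return(0)
  pc <- pair_corr_in_disk(spec$tile_radius_um, spec$correlation_length_um)
  m1 <- channel_tile_moments(spec$channels[[1]], spec, pc)
  m2 <- channel_tile_moments(spec$channels[[2]], spec, pc)
  if (is.null(m1) || is.null(m2))
    stop("spec error: channels carry no latent signal, rho != 0 infeasible",
         call. = FALSE)
  g2 <- spec$modulation_sd^2
  target_cov <- spec$rho * sqrt((m1$V + m1$noise) * (m2$V + m2$noise))
  cross <- function(rho_f) mean(exp(g2 * rho_f * pc) - 1)
  if (target_cov > cross(1) + 1e-12 || target_cov < cross(-1) - 1e-12)
    stop("spec error: target correlation infeasible for these field ",
         "parameters (attenuation too strong)", call. = FALSE)
  stats::uniroot(function(r) cross(r) - target_cov, c(-1, 1),
                 tol = 1e-10)$root
}

#' Generate a synthetic calibrated section with full ground truth
#'
#' Draws the section region, simulates per-channel object centers from an
#' inhomogeneous Poisson process whose intensity is modulated by a
#' log-Gaussian latent field (channels 1 and 2 share field structure scaled
#' so their tile-level densities correlate at approximately `spec$rho`),
#' renders membrane rims / nuclear disks, and composes intensity images with
#' per-class Gaussian intensities, a smooth additive background and read
#' noise. Fully reproducible from `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @param render_images render intensity images (default TRUE). `FALSE`
#'   produces ground truth only (masks, points, fields), roughly halving the
#'   cost for analyses that never look at intensities; the RNG stream then
#'   differs from the rendered run, so each mode is seeded-reproducible
#'   within itself.
#' @return list with `images` (named [calibrated_image()] list; empty when
#'   `render_images = FALSE`), `truth` (named `masks`, `points` for nuclear
#'   channels, `fields`, `outline`, `region`), and `spec`.
#' @export
generate_scene <- function(spec, render_images = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  s <- spec$scale_um_per_px
  W <- spec$width_mm * 1000; H <- spec$height_mm * 1000
  nc <- as.integer(round(W / s)); nr <- as.integer(round(H / s))
  outline <- section_outline_polygon(W, H)
  template <- calibrated_image(matrix(0, nr, nc), s)
  region <- rasterize_outline(outline, template)
  rho_f <- solve_field_correlation(spec)
  g <- spec$modulation_sd
  L_px <- spec$correlation_length_um / s
  with_seed(spec$seed, {
    z_shared <- gaussian_random_field(nr, nc, L_px)
    bg_field <- if (render_images)
      gaussian_random_field(nr, nc, spec$background_length_um / s) else NULL
    images <- list(); masks <- list(); points <- list(); fields <- list()
    for (ci in seq_along(spec$channels)) {
      ch <- spec$channels[[ci]]
      nm <- names(spec$channels)[ci]
      z_own <- gaussian_random_field(nr, nc, L_px)
      w <- if (ci <= 2) abs(rho_f) else 0
      sgn <- if (ci == 2 && rho_f < 0) -1 else 1
      z <- sgn * sqrt(w) * z_shared + sqrt(1 - w) * z_own
      mult <- exp(g * z - g^2 / 2)
      lam <- ch$density_per_mm2 / 1e6 * s^2 * mult
      lam[!region$pixels] <- 0
      cnt <- rpois(length(lam), lam)
      idx <- which(cnt > 0)
      idx <- rep(idx, cnt[idx])
      n_obj <- length(idx)
      if (n_obj > 0) {
        row0 <- (idx - 1) %% nr; col0 <- (idx - 1) %/% nr
        x <- (col0 + runif(n_obj)) * s
        y <- (row0 + runif(n_obj)) * s
        rad <- runif(n_obj, ch$radius_um_range[1], ch$radius_um_range[2])
      } else {
        x <- y <- rad <- numeric(0)
      }
      if (ch$pattern == "nuclear" && spec$overlap_fraction > 0 && n_obj > 0) {
        k <- round(spec$overlap_fraction * n_obj)
        if (k > 0) {
          pick <- sample.int(n_obj, k)
          ang <- runif(k, 0, 2 * pi)
          # touching pairs: the twin sits at 1.8 r, so the two disks fuse
          # into one blob but keep distinct distance-transform maxima;
          # heavier overlap (< 1.5 r) shifts split-half centroids by > 2 um
          # and is outside what "touching" nuclei in sections look like
          d <- 1.8 * rad[pick]
          x <- c(x, x[pick] + d * cos(ang))
          y <- c(y, y[pick] + d * sin(ang))
          rad <- c(rad, rad[pick])
        }
      }
      inner <- if (ch$pattern == "membrane")
        pmax(rad - (ch$rim_um %||% 3), 0) else rep(0, length(rad))
      mask_px <- cpp_draw_disks(nr, nc, y / s - 0.5, x / s - 0.5,
                                rad / s, inner / s)
      mask_px <- mask_px & region$pixels
      dim(mask_px) <- c(nr, nc)
      masks[[nm]] <- binary_mask(mask_px, s, source_label = paste0("truth:", nm))
      if (ch$pattern == "nuclear")
        points[[nm]] <- point_set(cbind(x, y),
                                  source_label = paste0("truth:", nm))
      fields[[nm]] <- mult
      if (render_images) {
        px <- matrix(rnorm(nr * nc, ch$bg_mean, ch$bg_sd), nr, nc)
        px[mask_px] <- rnorm(sum(mask_px), ch$fg_mean, ch$fg_sd)
        px[!region$pixels] <- px[!region$pixels] * 0.2
        px <- px + spec$background_amp / (1 + exp(-bg_field)) +
          rnorm(nr * nc, 0, spec$noise_sd)
        px <- pmax(px, 0)
        images[[nm]] <- calibrated_image(px, s, channel_label = nm,
                                         source_id = sprintf("synthetic_seed%d",
                                                             spec$seed))
      }
    }
    list(images = images,
         truth = list(masks = masks, points = points, fields = fields,
                      outline = outline, region = region,
                      field_correlation = rho_f),
         spec = spec)
  })
}

#' Degrade an image to a coarser acquisition scale
#'
#' Emulates re-imaging at a lower-resolution microscope (e.g. 0.5 to
#' 1.3 um/px): Gaussian anti-alias blur matched to the scale ratio, then
#' bilinear resampling onto the coarser grid. Used to test robustness of
#' downstream metrics to acquisition resolution.
#'
#' @param image a [calibrated_image()].
#' @param target_scale_um_per_px target calibration, >= the native scale.
#' @return A [calibrated_image()] at (approximately) the requested scale;
#'   the exact scale is adjusted so the pixel grid is integral.
#' @export
degrade <- function(image, target_scale_um_per_px) {
  stopifnot(inherits(image, "calibrated_image"))
  native <- image$scale_um_per_px
  if (target_scale_um_per_px < native * (1 - 1e-9))
    stop("target scale finer than native resolution", call. = FALSE)
  ratio <- target_scale_um_per_px / native
  if (abs(ratio - 1) < 1e-9) return(image)
  sig <- 0.5 * sqrt(ratio^2 - 1)
  k <- gauss_kernel(sig)
  px <- cpp_conv1d(cpp_conv1d(image$pixels, k, 1L), k, 2L)
  onr <- max(1L, as.integer(round(nrow(px) / ratio)))
  onc <- max(1L, as.integer(round(ncol(px) / ratio)))
  out <- cpp_bilinear_resize(px, onr, onc)
  calibrated_image(out, native * nrow(px) / onr,
                   channel_label = image$channel_label,
                   source_id = image$source_id)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}
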