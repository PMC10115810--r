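#' Read a calibrated single-channel TIFF
#'
#' Reads an uncompressed grayscale TIFF (8/16-bit unsigned or 32-bit float)
#' and attaches the caller-supplied spatial calibration. Calibration is not
#' parsed from TIFF tags: section metadata travels in file names in the
#' acquisition convention this pipeline targets, so the scale is an explicit
#' argument (slide scanners in the motivating studies produced 0.5 um/px,
#' standard epifluorescence 1.3 um/px).
#'
#' @param path TIFF file path.
#' @param scale_um_per_px positive scalar, micrometres per pixel.
#' @param channel_label optional channel label; defaults to the stain field
#'   of the file-name metadata when parseable.
#' @return A [calibrated_image()].
#' @export
read_calibrated_image <- function(path, scale_um_per_px, channel_label = NULL) {
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      !is.finite(scale_um_per_px) || scale_um_per_px <= 0)
    stop("`scale_um_per_px` must be a positive scalar", call. = FALSE)
  px <- read_tiff_raw(path)
  meta <- parse_section_metadata(basename(path))
  if (is.null(channel_label)) channel_label <- meta$stain %||% ""
  calibrated_image(px, scale_um_per_px, channel_label = channel_label,
                   source_id = meta$source_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a calibrated image as TIFF
#' @param image a [calibrated_image()].
#' @param path output path.
#' @param bits 8, 16 (unsigned) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(image, path, bits = 16L) {
  stopifnot(inherits(image, "calibrated_image"))
  write_tiff_raw(image$pixels, path, bits = as.integer(bits))
  invisible(path)
}

#' Read a binary mask TIFF (any non-zero pixel is positive)
#' @param path TIFF file path.
#' @param scale_um_per_px positive scalar, micrometres per pixel.
#' @param source_label provenance label.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, scale_um_per_px, source_label = "") {
  px <- read_tiff_raw(path)
  binary_mask(px != 0, scale_um_per_px, source_label = source_label)
}

#' Write a binary mask as an 8-bit TIFF (positive pixels stored as 255)
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_tiff_raw(matrix(ifelse(mask$pixels, 255, 0), nrow = nrow(mask$pixels)),
                 path, bits = 8L)
  invisible(path)
}

#' Read a point set from CSV (columns x_um, y_um and optional area_um2)
#' @param path CSV path.
#' @param source_label provenance label.
#' @return A [point_set()].
#' @export
read_points_csv <- function(path, source_label = "") {
  df <- read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("point CSV needs columns x_um, y_um", call. = FALSE)
  point_set(cbind(df$x_um, df$y_um), source_label = source_label,
            area_um2 = df$area_um2)
}

#' Write a point set to CSV with header x_um,y_um (plus area_um2 if present)
#' @param ps a [point_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(ps, path) {
  stopifnot(inherits(ps, "point_set"))
  df <- as.data.frame(ps$points)
  if (!is.null(ps$area_um2)) df$area_um2 <- ps$area_um2
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a region outline from GeoJSON (coordinates in micrometres)
#'
#' Accepts a FeatureCollection, Feature or bare geometry holding Polygon or
#' MultiPolygon coordinates (QuPath-style export). The first ring of each
#' polygon is the outer boundary; further rings are holes.
#'
#' @param path GeoJSON file path.
#' @param label compartment label; defaults to a `name`/`classification`
#'   property when present.
#' @return A [region_outline()].
#' @export
read_outline_geojson <- function(path, label = NULL) {
  g <- jsonlite::read_json(path)
  feats <- switch(g$type %||% "",
    FeatureCollection = g$features,
    Feature = list(g),
    list(list(geometry = g)))
  polys <- list()
  lab <- label
  for (f in feats) {
    geom <- f$geometry %||% f
    if (is.null(lab)) lab <- f$properties$name %||% f$properties$classification$name
    coords <- geom$coordinates
    rings_sets <- if (identical(geom$type, "Polygon")) list(coords)
                  else if (identical(geom$type, "MultiPolygon")) coords
                  else next
    for (rings in rings_sets) {
      ring_mat <- function(r) do.call(rbind, lapply(r, function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      outer <- ring_mat(rings[[1]])
      holes <- lapply(rings[-1], ring_mat)
      polys[[length(polys) + 1L]] <- list(outer = outer, holes = holes)
    }
  }
  if (length(polys) == 0L)
    stop("no Polygon/MultiPolygon geometry in ", path, call. = FALSE)
  region_outline(polys, label = lab %||% "")
}

#' Write a region outline to GeoJSON (coordinates in micrometres)
#' @param outline a [region_outline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outline_geojson <- function(outline, path) {
  stopifnot(inherits(outline, "region_outline"))
  ring_list <- function(m) {
    m <- close_ring(m)
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  coords <- lapply(outline$polygons, function(p)
    c(list(ring_list(p$outer)), lapply(p$holes, ring_list)))
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(name = outline$label),
    geometry = list(type = "MultiPolygon", coordinates = coords))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(m) {
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ]) else m
}

#' Parse the six-field underscore file-name convention
#'
#' Section images in the targeted acquisition workflow carry metadata in the
#' file name as `genotype_reporter_sex_tag_condition_stain.tif`. Unknown
#' layouts pass through with `source_id` set to the file stem and no fields.
#'
#' @param filename file name or path.
#' @return list with `source_id` and, when the name has six fields,
#'   `genotype`, `reporter`, `sex`, `tag`, `condition`, `stain`.
#' @export
parse_section_metadata <- function(filename) {
  stem <- sub("\\.[^.]*$", "", basename(filename))
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  out <- list(source_id = stem)
  if (length(parts) == 6L) {
    out <- c(out, stats::setNames(as.list(parts),
      c("genotype", "reporter", "sex", "tag", "condition", "stain")))
  }
  out
}

#' Rasterize a region outline onto an image grid
#'
#' A pixel is positive iff its center (pixel-center convention: 0-based
#' `(row, col)`, `x = (col + 0.5) * scale`) lies inside an outline polygon
#' and outside its holes.
#'
#' @param outline a [region_outline()].
#' @param template a [calibrated_image()] (or [binary_mask()]) supplying the
#'   grid and scale.
#' @return A [binary_mask()] of the template's shape.
#' @export
rasterize_outline <- function(outline, template) {
  stopifnot(inherits(outline, "region_outline"))
  px <- template$pixels
  s <- template$scale_um_per_px
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(FALSE, nr, nc)
  for (p in outline$polygons) {
    bb <- apply(p$outer, 2, range)
    c0 <- max(1L, floor(bb[1, 1] / s) + 1L)
    c1 <- min(nc, ceiling(bb[2, 1] / s))
    r0 <- max(1L, floor(bb[1, 2] / s) + 1L)
    r1 <- min(nr, ceiling(bb[2, 2] / s))
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    xs <- (cols - 0.5) * s; ys <- (rows - 0.5) * s
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
    inside <- sp::point.in.polygon(gx, gy, p$outer[, 1], p$outer[, 2]) > 0
    for (h in p$holes) {
      inside <- inside &
        sp::point.in.polygon(gx, gy, h[, 1], h[, 2]) == 0
    }
    sub <- matrix(inside, nrow = length(rows), ncol = length(cols))
    out[rows, cols] <- out[rows, cols] | sub
  }
  if (!any(out))
    stop("empty-region error: outline does not overlap the image",
         call. = FALSE)
  binary_mask(out, s, source_label = outline$label)
}

#' Assemble a QC montage of mask previews with outline overlay
#'
#' Tiles down-sampled previews of segmentation masks in row-major order with
#' the section outlines burned in at full intensity, for human review of a
#' batch before quantification. Purely a QC visual; no measurement reads it.
#'
#' @param masks non-empty list of [binary_mask()].
#' @param outlines list of [region_outline()] matched to `masks` (recycled if
#'   length 1; may be empty for no overlay).
#' @param columns number of montage columns.
#' @param tile_px maximum tile edge in pixels (default 256).
#' @return A [calibrated_image()] holding the montage (intensities 0..255).
#' @export
make_montage <- function(masks, outlines = list(), columns = 2L,
                         tile_px = 256L) {
  if (length(masks) == 0L) stop("montage needs >= 1 mask", call. = FALSE)
  columns <- as.integer(columns)
  stopifnot(columns >= 1L)
  if (length(outlines) == 1L) outlines <- rep(outlines, length(masks))
  tiles <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    f <- max(1L, ceiling(max(dim(m$pixels)) / tile_px))
    prev <- cpp_block_reduce(matrix(as.numeric(m$pixels), nrow = nrow(m$pixels)),
                             f, 0L) * 180
    if (i <= length(outlines) && !is.null(outlines[[i]])) {
      prev <- burn_outline(prev, outlines[[i]], m$scale_um_per_px * f)
    }
    list(px = prev, scale = m$scale_um_per_px * f)
  })
  th <- max(vapply(tiles, function(t) nrow(t$px), 0L))
  tw <- max(vapply(tiles, function(t) ncol(t$px), 0L))
  rows <- ceiling(length(tiles) / columns)
  out <- matrix(0, rows * th, columns * tw)
  for (i in seq_along(tiles)) {
    r <- (i - 1L) %/% columns; c <- (i - 1L) %% columns
    t <- tiles[[i]]
    out[r * th + seq_len(nrow(t$px)), c * tw + seq_len(ncol(t$px))] <- t$px
  }
  calibrated_image(out, tiles[[1]]$scale, channel_label = "montage")
}

# Burn polygon edges into a preview raster at the preview's scale.
burn_outline <- function(px, outline, scale) {
  nr <- nrow(px); nc <- ncol(px)
  rings <- unlist(lapply(outline$polygons, function(p) c(list(p$outer), p$holes)),
                  recursive = FALSE)
  for (ring in rings) {
    ring <- close_ring(ring)
    for (i in seq_len(nrow(ring) - 1L)) {
      a <- ring[i, ]; b <- ring[i + 1L, ]
      n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / scale))
      t <- seq(0, 1, length.out = n)
      cc <- round((a[1] + t * (b[1] - a[1])) / scale + 0.5)
      rr <- round((a[2] + t * (b[2] - a[2])) / scale + 0.5)
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      px[cbind(rr[ok], cc[ok])] <- 255
    }
  }
  px
}
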