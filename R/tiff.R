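# Minimal baseline TIFF codec: uncompressed, single-channel (grayscale),
# strip-organized, 8/16-bit unsigned or 32-bit float, either byte order on
# read, little-endian on write. No imaging package in the dependency stack
# provides TIFF, so the subset the pipeline needs is implemented here.
# Anything outside that subset (RGB, palette, compression, tiles) is rejected
# with a format error rather than misread.

TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

read_tiff_raw <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  endian <- if (raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)) "little"
            else if (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d)) "big"
            else stop("not a TIFF file: ", path, call. = FALSE)
  rd_int <- function(off, size, n = 1L) {
    # size-4 reads are signed (readBin limitation); TIFF offsets/counts in
    # the supported subset stay far below 2^31 so the sign bit is never set
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4L, endian = endian)
  }
  magic <- rd_int(2L, 2L)
  if (magic != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  ifd_off <- rd_int(4L, 4L)
  n_entries <- rd_int(ifd_off, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e_off <- ifd_off + 2L + (i - 1L) * 12L
    tag <- rd_int(e_off, 2L)
    type <- rd_int(e_off + 2L, 2L)
    count <- rd_int(e_off + 4L, 4L)
    tsz <- if (type >= 1L && type <= 12L) TIFF_TYPE_SIZE[type] else 1L
    total <- tsz * count
    val_off <- if (total <= 4L) e_off + 8L else rd_int(e_off + 8L, 4L)
    vals <- if (type == 3L) rd_int(val_off, 2L, count)
            else if (type == 4L) rd_int(val_off, 4L, count)
            else if (type == 1L) as.integer(raw[(val_off + 1L):(val_off + count)])
            else NULL
    tags[[as.character(tag)]] <- vals
  }
  get1 <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v[1]
  }
  width <- get1(256L); height <- get1(257L)
  if (is.null(width) || is.null(height) || width < 1L || height < 1L)
    stop("TIFF format error: zero-sized or missing dimensions", call. = FALSE)
  spp <- get1(277L, 1L)
  photometric <- get1(262L, 1L)
  if (spp != 1L || photometric > 1L)
    stop("TIFF format error: multi-channel images are not supported; ",
         "supply single-channel grayscale", call. = FALSE)
  if (get1(259L, 1L) != 1L)
    stop("TIFF format error: compressed TIFF not supported", call. = FALSE)
  bits <- get1(258L, 1L)
  fmt <- get1(339L, 1L) # 1 = unsigned int, 3 = IEEE float
  if (!(bits %in% c(8L, 16L, 32L)) || !(fmt %in% c(1L, 3L)) ||
      (fmt == 3L && bits != 32L) || (fmt == 1L && bits == 32L))
    stop("TIFF format error: unsupported bit depth / sample format",
         call. = FALSE)
  offs <- tags[["273"]]; counts <- tags[["279"]]
  if (is.null(offs)) stop("TIFF format error: missing strip offsets", call. = FALSE)
  if (is.null(counts)) counts <- rep(width * height * bits / 8L / length(offs),
                                     length(offs))
  bsz <- bits %/% 8L
  vals <- numeric(0)
  for (i in seq_along(offs)) {
    n <- counts[i] %/% bsz
    chunk <- raw[(offs[i] + 1L):(offs[i] + counts[i])]
    v <- if (fmt == 3L) readBin(chunk, "double", n = n, size = 4L, endian = endian)
         else if (bits == 8L) as.numeric(chunk)
         else readBin(chunk, "integer", n = n, size = 2L, signed = FALSE,
                      endian = endian)
    vals <- c(vals, v)
  }
  if (length(vals) < width * height)
    stop("TIFF format error: truncated pixel data", call. = FALSE)
  # TIFF is row-major; R matrices are column-major
  matrix(vals[seq_len(width * height)], nrow = height, ncol = width,
         byrow = TRUE)
}

write_tiff_raw <- function(pixels, path, bits = 16L) {
  stopifnot(is.matrix(pixels), bits %in% c(8L, 16L, 32L))
  h <- nrow(pixels); w <- ncol(pixels)
  fmt <- if (bits == 32L) 3L else 1L
  if (fmt == 1L) {
    maxv <- 2^bits - 1
    pixels <- round(pmin(pmax(pixels, 0), maxv))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  data_off <- 8L
  nbytes <- w * h * (bits %/% 8L)
  ifd_off <- data_off + nbytes
  if (ifd_off %% 2L == 1L) ifd_off <- ifd_off + 1L
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  v <- as.vector(t(pixels)) # row-major
  if (bits == 8L) {
    writeBin(as.raw(v), con)
  } else if (bits == 16L) {
    writeBin(writeBin(as.integer(v), raw(), size = 2, endian = "little"), con)
  } else {
    writeBin(writeBin(as.numeric(v), raw(), size = 4, endian = "little"), con)
  }
  if ((data_off + nbytes) %% 2L == 1L) writeBin(as.raw(0L), con)
  entries <- list(
    c(256L, 4L, 1L, w),
    c(257L, 4L, 1L, h),
    c(258L, 3L, 1L, bits),
    c(259L, 3L, 1L, 1L),      # no compression
    c(262L, 3L, 1L, 1L),      # BlackIsZero
    c(273L, 4L, 1L, data_off),
    c(277L, 3L, 1L, 1L),      # one sample per pixel
    c(278L, 4L, 1L, h),       # single strip
    c(279L, 4L, 1L, nbytes),
    c(339L, 3L, 1L, fmt))
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(as.integer(e[1]), con, size = 2, endian = "little")
    writeBin(as.integer(e[2]), con, size = 2, endian = "little")
    writeBin(as.integer(e[3]), con, size = 4, endian = "little")
    if (e[2] == 3L) {
      writeBin(as.integer(e[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(e[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}
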