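# Minimal baseline TIFF codec.
#
# Nothing in the installed R stack reads TIFF, so the package carries its own
# reader/writer restricted to the subset microscopy exports actually use
# here: uncompressed, 8- or 16-bit, either one grayscale plane per page
# (multi-page) or a single interleaved RGB page, chunky planar layout.
# The writer always emits little-endian multi-page grayscale with the pixel
# size stored in XResolution/YResolution (ResolutionUnit = cm); the reader
# accepts both byte orders.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

.read_uint <- function(raw, offset, size, endian, n = 1L) {
  # offset is 0-based within `raw`
  bytes <- raw[(offset + 1L):(offset + n * size)]
  if (size == 4L) {
    # readBin cannot read unsigned 32-bit; offsets in supported files < 2^31
    v <- readBin(bytes, what = "integer", n = n, size = 4L,
                 signed = TRUE, endian = endian)
    if (any(v < 0)) stop("TIFF value exceeds 2^31; unsupported")
  } else {
    v <- readBin(bytes, what = "integer", n = n, size = size,
                 signed = FALSE, endian = endian)
  }
  v
}

.tiff_entry_values <- function(raw, entry_off, endian) {
  tag   <- .read_uint(raw, entry_off, 2L, endian)
  type  <- .read_uint(raw, entry_off + 2L, 2L, endian)
  count <- .read_uint(raw, entry_off + 4L, 4L, endian)
  tsz   <- .tiff_type_size[as.character(type)]
  if (is.na(tsz)) return(list(tag = tag, values = NULL))
  nbytes <- tsz * count
  voff <- if (nbytes <= 4L) entry_off + 8L else .read_uint(raw, entry_off + 8L, 4L, endian)
  if (type == 5L) { # RATIONAL: pairs of uint32
    nums <- .read_uint(raw, voff, 4L, endian, n = 2L * count)
    values <- nums[seq(1L, by = 2L, length.out = count)] /
      nums[seq(2L, by = 2L, length.out = count)]
  } else {
    values <- .read_uint(raw, voff, tsz, endian, n = count)
  }
  list(tag = tag, values = values)
}

#' Read an uncompressed TIFF file
#'
#' Parses the restricted TIFF subset used by this package: uncompressed
#' pages, 8 or 16 bits per sample, grayscale pages or one interleaved RGB
#' page. Returns raw integer planes (no intensity normalization).
#'
#' @param path path to a `.tif`/`.tiff` file.
#' @return a list with `planes` (list of integer matrices, one per channel),
#'   `bits` (bits per sample) and `pixel_size_um` (`NA` when the file
#'   carries no resolution tags).
#' @keywords internal
read_tiff_raw <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (.read_uint(raw, 2L, 2L, endian) != 42L) stop("not a TIFF file: ", path)

  planes <- list()
  bits <- NULL
  pixel_size_um <- NA_real_
  ifd_off <- .read_uint(raw, 4L, 4L, endian)
  while (ifd_off != 0L) {
    n_entries <- .read_uint(raw, ifd_off, 2L, endian)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e <- .tiff_entry_values(raw, ifd_off + 2L + (k - 1L) * 12L, endian)
      tags[[as.character(e$tag)]] <- e$values
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    width  <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    bps <- g(258, 1L); spp <- g(277, 1L)
    if (length(unique(bps)) != 1L) stop("mixed bits-per-sample unsupported")
    bps <- bps[1L]
    if (!bps %in% c(8L, 16L)) stop("only 8- and 16-bit TIFF supported, got ", bps)
    if (!is.null(bits) && bits != bps) stop("pages with mixed bit depth unsupported")
    bits <- bps
    if (g(259, 1L) != 1L) stop("compressed TIFF unsupported (compression tag ",
                               g(259), ")")
    if (g(284, 1L) != 1L) stop("planar (non-chunky) TIFF unsupported")
    strip_off <- g(273); strip_cnt <- g(279)
    if (is.null(strip_off)) stop("TIFF page missing strip offsets")
    if (is.null(strip_cnt)) {
      strip_cnt <- width * height * spp * (bps / 8L)
    }
    data <- unlist(lapply(seq_along(strip_off), function(i) {
      raw[(strip_off[i] + 1L):(strip_off[i] + strip_cnt[i])]
    }))
    vals <- readBin(data, what = "integer", n = width * height * spp,
                    size = bps / 8L, signed = FALSE, endian = endian)
    if (bps == 16L && any(vals < 0)) vals <- vals + 65536L * (vals < 0)
    # resolution: pixels per unit -> micrometres per pixel
    xres <- g(282); runit <- g(296, 2L)
    if (!is.null(xres) && xres > 0 && runit %in% c(2L, 3L)) {
      unit_um <- if (runit == 3L) 10000 else 25400
      pixel_size_um <- unit_um / xres
    }
    if (spp == 1L) {
      planes[[length(planes) + 1L]] <-
        matrix(as.integer(vals), nrow = height, ncol = width, byrow = TRUE)
    } else {
      for (s in seq_len(spp)) {
        planes[[length(planes) + 1L]] <-
          matrix(as.integer(vals[seq(s, by = spp, length.out = width * height)]),
                 nrow = height, ncol = width, byrow = TRUE)
      }
    }
    ifd_off <- .read_uint(raw, ifd_off + 2L + n_entries * 12L, 4L, endian)
  }
  if (length(planes) == 0L) stop("TIFF file contains no pages: ", path)
  list(planes = planes, bits = bits, pixel_size_um = pixel_size_um)
}

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

.ifd_entry <- function(tag, type, count, value) {
  val <- if (type == 3L) c(.u16(value), as.raw(c(0, 0))) else .u32(value)
  c(.u16(tag), .u16(type), .u32(count), val)
}

#' Write integer planes as a multi-page grayscale TIFF
#'
#' Little-endian, uncompressed, one strip per page. The physical pixel size
#' is stored in the XResolution/YResolution tags with ResolutionUnit = cm,
#' which `read_tiff_raw()` converts back to micrometres.
#'
#' @param planes list of integer matrices (all the same shape) holding raw
#'   intensities in `[0, 2^bits - 1]`.
#' @param path output path.
#' @param bits 8 or 16.
#' @param pixel_size_um physical pixel edge in micrometres.
#' @keywords internal
write_tiff_raw <- function(planes, path, bits = 16L, pixel_size_um = NA_real_) {
  stopifnot(bits %in% c(8L, 16L), length(planes) >= 1L)
  dims <- dim(planes[[1L]])
  for (p in planes) {
    if (!identical(dim(p), dims)) stop("all planes must share dimensions")
    if (min(p) < 0L || max(p) > 2^bits - 1) {
      stop("plane values outside [0, ", 2^bits - 1, "]")
    }
  }
  h <- dims[1L]; w <- dims[2L]
  bytes_pp <- bits / 8L
  strip_bytes <- h * w * bytes_pp
  n_pages <- length(planes)

  # layout: 8-byte header | page strips | shared resolution rationals | IFDs
  data_off <- 8L
  res_off <- data_off + n_pages * strip_bytes
  ifd0_off <- res_off + 16L
  ifd_size <- 2L + 12L * 12L + 4L # 12 entries

  # resolution as a rational: pixels per cm = 1e4 / pixel_size_um
  if (is.na(pixel_size_um)) {
    res_num <- 1L; res_den <- 1L; res_unit <- 1L # unit "none": no pixel size
  } else {
    res_num <- 100000000L
    res_den <- as.integer(round(pixel_size_um * 1e4))
    res_unit <- 3L
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(.u16(42L), .u32(ifd0_off)), con)
  for (p in planes) {
    vals <- as.integer(t(p)) # row-major strips
    if (bits == 16L) {
      writeBin(writeBin(vals, raw(), size = 2L, endian = "little"), con)
    } else {
      writeBin(as.raw(vals), con)
    }
  }
  writeBin(c(.u32(res_num), .u32(res_den), .u32(res_num), .u32(res_den)), con)
  for (i in seq_len(n_pages)) {
    strip_off <- data_off + (i - 1L) * strip_bytes
    next_ifd <- if (i < n_pages) ifd0_off + i * ifd_size else 0L
    entries <- c(
      .ifd_entry(256L, 3L, 1L, w),           # ImageWidth
      .ifd_entry(257L, 3L, 1L, h),           # ImageLength
      .ifd_entry(258L, 3L, 1L, bits),        # BitsPerSample
      .ifd_entry(259L, 3L, 1L, 1L),          # Compression = none
      .ifd_entry(262L, 3L, 1L, 1L),          # Photometric = BlackIsZero
      .ifd_entry(273L, 4L, 1L, strip_off),   # StripOffsets
      .ifd_entry(277L, 3L, 1L, 1L),          # SamplesPerPixel
      .ifd_entry(278L, 3L, 1L, h),           # RowsPerStrip
      .ifd_entry(279L, 4L, 1L, strip_bytes), # StripByteCounts
      .ifd_entry(282L, 5L, 1L, res_off),     # XResolution
      .ifd_entry(283L, 5L, 1L, res_off + 8L),# YResolution
      .ifd_entry(296L, 3L, 1L, res_unit)     # ResolutionUnit
    )
    writeBin(c(.u16(12L), entries, .u32(next_ifd)), con)
  }
  invisible(path)
}
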