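# Image and table input: the entry point every downstream stage consumes.

#' Construct a multichannel fluorescence image
#'
#' The common currency of the imaging stages: three intensity planes (red =
#' BG4/G-quadruplex, green = hnRNP H, blue = DAPI) on one pixel grid, with
#' the physical pixel size attached. Intensities must already lie in
#' \eqn{[0, 1]}; use [normalize_plane()] for raw integer data.
#'
#' @param red,green,blue numeric matrices of identical dimensions with
#'   values in `[0, 1]`.
#' @param pixel_size_um physical edge length of one pixel, micrometres (> 0).
#' @param source_id opaque label carried through to results.
#' @return an object of class `multichannel_image`.
#' @export
multichannel_image <- function(red, green, blue, pixel_size_um,
                               source_id = "image") {
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue))) {
    stop("all three planes must share identical dimensions")
  }
  for (nm in c("red", "green", "blue")) {
    p <- get(nm)
    if (!is.numeric(p) || anyNA(p)) stop(nm, " plane must be numeric without NA")
    if (min(p) < 0 || max(p) > 1) {
      stop(nm, " plane has intensities outside [0, 1]; normalize first")
    }
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(
    list(red = red, green = green, blue = blue,
         pixel_size_um = pixel_size_um, source_id = as.character(source_id)),
    class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  cat(sprintf("<multichannel_image '%s': %d x %d px, %.4g um/px>\n",
              x$source_id, nrow(x$red), ncol(x$red), x$pixel_size_um))
  invisible(x)
}

#' Normalize a raw integer plane to [0, 1]
#'
#' Integer data are divided by the full-scale value of their bit depth
#' (255 or 65535), never by the observed maximum: the downstream absolute
#' intensity threshold (0.1 by default) presumes one fixed scale across all
#' images. Already-normalized float planes pass through unchanged, so the
#' operation is idempotent.
#'
#' @param plane numeric or integer matrix.
#' @param bits bit depth of the acquisition (8 or 16). Ignored for float
#'   input already inside `[0, 1]`.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
normalize_plane <- function(plane, bits = 16L) {
  if (is.double(plane) && min(plane) >= 0 && max(plane) <= 1) return(plane)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  full <- 2^bits - 1
  if (min(plane) < 0 || max(plane) > full) {
    stop("raw intensities outside [0, ", full, "] for ", bits, "-bit data")
  }
  plane / full
}

#' Default channel map
#'
#' Maps stored plane order to semantic channels. The order is never inferred
#' from the file; the default follows the staining convention red = BG4
#' (FLAG), green = hnRNP H, blue = DAPI with planes stored in that order.
#'
#' @param red,green,blue 1-based plane (or RGB sample) index of each channel.
#' @return named integer vector usable as `channel_map`.
#' @export
channel_map <- function(red = 1L, green = 2L, blue = 3L) {
  m <- c(red = as.integer(red), green = as.integer(green),
         blue = as.integer(blue))
  if (anyNA(m) || length(unique(m)) != 3L || any(m < 1L)) {
    stop("channel_map must assign three distinct positive plane indices")
  }
  m
}

#' Load a multichannel TIFF image
#'
#' Reads a TIFF with at least three grayscale pages, or one interleaved RGB
#' page, normalizes each plane by its bit depth, and assigns channels
#' through `channel_map`. The pixel size is taken from the TIFF resolution
#' tags when present, otherwise from `pixel_size_um`.
#'
#' @param path TIFF file path.
#' @param map channel assignment from [channel_map()].
#' @param pixel_size_um fallback pixel size when the file has no resolution
#'   metadata (e.g. from a config file).
#' @param source_id label for the image; defaults to the file name.
#' @return a [multichannel_image()].
#' @export
load_image <- function(path, map = channel_map(), pixel_size_um = NULL,
                       source_id = basename(path)) {
  tif <- read_tiff_raw(path)
  for (ch in c("red", "green", "blue")) {
    if (map[[ch]] > length(tif$planes)) {
      stop("missing channel '", ch, "': file has ", length(tif$planes),
           " plane(s), channel map wants plane ", map[[ch]])
    }
  }
  ps <- tif$pixel_size_um
  if (is.na(ps)) {
    if (is.null(pixel_size_um)) {
      stop("no pixel size in TIFF metadata; supply pixel_size_um ",
           "(config key 'pixel_size_um')")
    }
    ps <- pixel_size_um
  }
  multichannel_image(
    red = normalize_plane(tif$planes[[map[["red"]]]], tif$bits),
    green = normalize_plane(tif$planes[[map[["green"]]]], tif$bits),
    blue = normalize_plane(tif$planes[[map[["blue"]]]], tif$bits),
    pixel_size_um = ps, source_id = source_id)
}

#' Write a multichannel image as a 16-bit TIFF
#'
#' Inverse of [load_image()]: planes are scaled to the 16-bit grid and
#' written as three grayscale pages (red, green, blue) with the pixel size
#' in the resolution tags. Images produced by the synthetic generator are
#' already quantized to this grid, so a write/load round trip is
#' bit-identical.
#'
#' @param image a [multichannel_image()].
#' @param path output path.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  q <- function(p) matrix(as.integer(round(p * 65535)), nrow(p), ncol(p))
  write_tiff_raw(list(q(image$red), q(image$green), q(image$blue)),
                 path, bits = 16L, pixel_size_um = image$pixel_size_um)
  invisible(path)
}

# ---- tabular input -------------------------------------------------------

.table_schemas <- list(
  bands = list(
    cols = c(sample = "character", group = "character", gene = "character",
             replicate = "integer", incl_intensity = "numeric",
             excl_intensity = "numeric"),
    key = c("sample", "gene", "replicate")),
  fractions = list(
    cols = c(sample = "character", group = "character",
             replicate = "integer", soluble = "numeric",
             sarkosyl_soluble = "numeric", sarkosyl_insoluble = "numeric"),
    key = c("sample", "replicate")),
  binding = list(
    cols = c(series = "character", protein_conc_nM = "numeric",
             bound_intensity = "numeric", free_intensity = "numeric"),
    key = NULL),
  cells = list(
    cols = c(image_id = "character", cell_count = "integer"),
    key = "image_id"),
  metadata = list(
    cols = c(sample = "character", group = "character",
             disease_duration_months = "numeric"),
    key = "sample"),
  design = list(
    cols = c(image_id = "character", experiment_id = "character",
             line_id = "character", group = "character",
             condition = "character"),
    key = "image_id")
)

#' Read and validate a CSV table against a declared schema
#'
#' Supported schemas: `bands` (splicing band pairs), `fractions`
#' (three-fraction westerns), `binding` (gel-shift series), `cells`
#' (per-image cell counts), `metadata` (sample group and disease duration)
#' and `design` (image-to-line assignment). Extra columns are kept; missing
#' schema columns, non-coercible values (reported with their CSV line
#' number) and duplicated key rows are fatal.
#'
#' @param path CSV file path.
#' @param schema one of the schema names above.
#' @return a `data.frame` with the schema's column types enforced.
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(.table_schemas)) {
    stop("unknown schema '", schema, "'; available: ",
         paste(names(.table_schemas), collapse = ", "))
  }
  sc <- .table_schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  missing <- setdiff(names(sc$cols), names(df))
  if (length(missing) > 0L) {
    stop("schema '", schema, "': missing column(s) ",
         paste(missing, collapse = ", "), " in ", path)
  }
  for (col in names(sc$cols)) {
    type <- sc$cols[[col]]
    if (type == "character") next
    suppressWarnings(v <- as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(is.na(df[[col]]) | df[[col]] == "" |
                                df[[col]] == "NA"))
    if (length(bad) > 0L) {
      stop("schema '", schema, "', column '", col, "': non-numeric value ",
           "at CSV line ", paste(bad + 1L, collapse = ", "))
    }
    df[[col]] <- if (type == "integer") as.integer(round(v)) else v
  }
  if (!is.null(sc$key)) {
    keys <- do.call(paste, c(df[sc$key], sep = "\r"))
    if (anyDuplicated(keys)) {
      dup <- df[duplicated(keys), sc$key, drop = FALSE][1L, ]
      stop("schema '", schema, "': duplicate key row (",
           paste(sprintf("%s=%s", names(dup), unlist(dup)), collapse = ", "),
           ")")
    }
  }
  df
}

#' Read a plain-text key/value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values that parse
#' as numbers are returned numeric. Recognized keys include the thresholds
#' of [threshold_config()], `pixel_size_um`, `channel_red`/`channel_green`/
#' `channel_blue` plane indices, and `seed`.
#'
#' @param path config file path.
#' @return named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
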