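# The BG4-Count foci quantification algorithm: threshold the red
# (G-quadruplex) channel, discard red staining that does not overlap DAPI,
# measure connected objects, and estimate the foci count as total stained
# area divided by the trimmed mean area of a single object.

#' Quantification thresholds and options
#'
#' All tunables of the imaging stages in one validated object. The red and
#' blue thresholds default to 0.1 on the normalized `[0, 1]` scale -- the
#' single absolute threshold applied to every image. `trim_fraction` is the
#' proportion of the object-area distribution removed from each tail before
#' averaging (10%). `min_nucleus_area_um2` separates nuclei from specks in
#' the DAPI channel; `min_coloc_area_um2` suppresses single-pixel
#' red/green intersections; `cytoplasm_threshold` is the low DAPI level
#' that still marks DAPI-positive cytoplasm; `large_focus_min_um` is the
#' minimum focus dimension used for motor-neuron-style large-focus counts.
#'
#' @param red_threshold,blue_threshold intensities in `[0, 1]`.
#' @param min_nucleus_area_um2 minimum nucleus area, square micrometres.
#' @param trim_fraction proportion trimmed from each tail, in `[0, 0.5)`.
#' @param connectivity pixel connectivity, 4 or 8.
#' @param min_coloc_area_um2 minimum colocalization event area.
#' @param cytoplasm_threshold DAPI intensity marking cytoplasm.
#' @param large_focus_min_um large-focus size cutoff, micrometres.
#' @param feret use the maximum pixel-to-pixel (Feret) diameter instead of
#'   the bounding-box side for the size cutoff.
#' @return an object of class `threshold_config`.
#' @export
threshold_config <- function(red_threshold = 0.1, blue_threshold = 0.1,
                             min_nucleus_area_um2 = 20, trim_fraction = 0.10,
                             connectivity = 8L, min_coloc_area_um2 = 0.25,
                             cytoplasm_threshold = 0.02,
                             large_focus_min_um = 0.5, feret = FALSE) {
  for (thr in c(red_threshold, blue_threshold, cytoplasm_threshold)) {
    if (!is.numeric(thr) || thr < 0 || thr > 1) {
      stop("intensity thresholds must lie in [0, 1]")
    }
  }
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must lie in [0, 0.5)")
  }
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(red_threshold = red_threshold,
                 blue_threshold = blue_threshold,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 trim_fraction = trim_fraction,
                 connectivity = as.integer(connectivity),
                 min_coloc_area_um2 = min_coloc_area_um2,
                 cytoplasm_threshold = cytoplasm_threshold,
                 large_focus_min_um = large_focus_min_um,
                 feret = isTRUE(feret)),
            class = "threshold_config")
}

#' Threshold an intensity plane
#'
#' Boundary-inclusive: a pixel is stained iff its intensity is `>=` the
#' threshold, so results are bit-reproducible at exact threshold values.
#'
#' @param plane numeric matrix with values in `[0, 1]`.
#' @param threshold intensity in `[0, 1]`.
#' @return logical matrix (the stained mask).
#' @export
threshold_channel <- function(plane, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]")
  }
  plane >= threshold
}

#' Remove red objects that do not overlap blue staining
#'
#' Gating is object-level: a connected red object is kept in full if at
#' least one of its pixels coincides with a stained blue pixel, and removed
#' in full otherwise. This mirrors discarding whole stains outside
#' DAPI-positive regions rather than clipping them pixelwise, which would
#' distort total-area semantics.
#'
#' @param red_mask,blue_mask logical matrices of identical shape.
#' @param connectivity 4 or 8.
#' @return the gated red mask.
#' @export
gate_by_blue <- function(red_mask, blue_mask, connectivity = 8L) {
  if (!identical(dim(red_mask), dim(blue_mask))) {
    stop("red and blue masks must share dimensions")
  }
  lab <- .label_components(red_mask, as.integer(connectivity))
  n <- attr(lab, "n_objects")
  if (n == 0L) return(red_mask & FALSE)
  hit <- logical(n)
  touching <- lab[blue_mask & red_mask]
  hit[unique(touching)] <- TRUE
  out <- red_mask
  out[red_mask] <- hit[lab[red_mask]]
  out
}

.feret_diameter_px <- function(rows, cols) {
  # max pairwise distance between pixel centers; objects here are foci-sized
  if (length(rows) == 1L) return(0)
  if (length(rows) > 4000L) { # guard: fall back to bbox diagonal
    return(sqrt(diff(range(rows))^2 + diff(range(cols))^2))
  }
  max(stats::dist(cbind(rows, cols)))
}

#' Measure connected objects in a binary mask
#'
#' One row per connected component under the configured connectivity, with
#' exact pixel-count areas, physical areas, centroids (0-based row/column
#' pixel coordinates) and the longest bounding-box side in micrometres
#' (`max_dim_um`; the Feret diameter when `feret = TRUE`).
#'
#' @param mask logical matrix.
#' @param pixel_size_um micrometres per pixel edge.
#' @param connectivity 4 or 8.
#' @param feret measure `max_dim_um` as the Feret diameter.
#' @return a `data.frame` with columns `label`, `area_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`, `max_dim_um`.
#' @export
label_objects <- function(mask, pixel_size_um = 1, connectivity = 8L,
                          feret = FALSE) {
  lab <- .label_components(mask, as.integer(connectivity))
  n <- attr(lab, "n_objects")
  empty <- data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), max_dim_um = numeric())
  if (n == 0L) return(empty)
  idx <- which(mask, arr.ind = TRUE)
  l <- lab[mask]
  area <- tabulate(l, nbins = n)
  crow <- rowsum(as.numeric(idx[, 1L] - 1L), l)[, 1L] / area
  ccol <- rowsum(as.numeric(idx[, 2L] - 1L), l)[, 1L] / area
  rmin <- tapply(idx[, 1L], l, min); rmax <- tapply(idx[, 1L], l, max)
  cmin <- tapply(idx[, 2L], l, min); cmax <- tapply(idx[, 2L], l, max)
  if (isTRUE(feret)) {
    max_dim <- vapply(seq_len(n), function(k) {
      sel <- l == k
      .feret_diameter_px(idx[sel, 1L], idx[sel, 2L])
    }, numeric(1)) * pixel_size_um
  } else {
    max_dim <- pmax(rmax - rmin + 1L, cmax - cmin + 1L) * pixel_size_um
  }
  data.frame(label = seq_len(n), area_px = area,
             area_um2 = area * pixel_size_um^2,
             centroid_row = crow, centroid_col = ccol,
             max_dim_um = as.numeric(max_dim))
}

#' Trimmed mean of object areas
#'
#' Sorts the areas, removes `floor(trim_fraction * n)` values from each
#' tail, and averages the remainder; this is the estimated area of a single
#' stained object. With fewer than three objects the plain mean is
#' returned. An empty input returns `NA` ("no objects"); the caller then
#' reports a foci count of zero.
#'
#' @param areas numeric vector of positive object areas.
#' @param trim_fraction proportion trimmed per tail, `[0, 0.5)`.
#' @return the trimmed mean area (or `NA_real_` for empty input).
#' @export
trimmed_mean_area <- function(areas, trim_fraction = 0.10) {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must lie in [0, 0.5)")
  }
  n <- length(areas)
  if (n == 0L) return(NA_real_)
  if (n < 3L) return(mean(areas))
  k <- floor(trim_fraction * n)
  s <- sort(areas)
  mean(s[(k + 1L):(n - k)])
}

#' Count nuclei in the DAPI channel
#'
#' Number of connected blue objects at least `min_nucleus_area_um2` in
#' area. When a `cells.csv` count is available for the image, pass it to
#' [quantify_image()] instead; this estimator backs the case where cells
#' were not enumerated externally.
#'
#' @param blue_plane normalized DAPI plane.
#' @param pixel_size_um micrometres per pixel edge.
#' @param config a [threshold_config()].
#' @return integer nucleus count.
#' @export
count_cells <- function(blue_plane, pixel_size_um,
                        config = threshold_config()) {
  mask <- threshold_channel(blue_plane, config$blue_threshold)
  obj <- label_objects(mask, pixel_size_um, config$connectivity)
  sum(obj$area_um2 >= config$min_nucleus_area_um2)
}

#' Quantify BG4 foci in one image
#'
#' The full per-image pipeline: threshold the red channel, gate to blue
#' staining, measure objects, and report the total stained area
#' (`area_total_px`), the trimmed mean single-object area and the
#' trimmed-mean approximated foci count
#' `foci_count = area_total_px / trimmed_mean_area_px` (a real number;
#' equal to the exact object count whenever all objects have the same
#' area). Per-cell values are defined only when `n_cells > 0`.
#'
#' @param image a [multichannel_image()].
#' @param config a [threshold_config()].
#' @param n_cells externally supplied cell count (e.g. from `cells.csv`);
#'   when `NULL`, nuclei are counted with [count_cells()].
#' @return an object of class `foci_quant`: a list with `image_id`,
#'   `objects` (the [label_objects()] table), `n_objects`,
#'   `area_total_px`, `area_total_um2`, `trimmed_mean_area_px`,
#'   `foci_count`, `n_cells`, `foci_per_cell`, `area_per_cell_um2`.
#' @export
quantify_image <- function(image, config = threshold_config(),
                           n_cells = NULL) {
  stopifnot(inherits(image, "multichannel_image"))
  ps <- image$pixel_size_um
  red_mask <- threshold_channel(image$red, config$red_threshold)
  blue_mask <- threshold_channel(image$blue, config$blue_threshold)
  gated <- gate_by_blue(red_mask, blue_mask, config$connectivity)
  objects <- label_objects(gated, ps, config$connectivity, config$feret)
  area_total_px <- sum(objects$area_px)
  tma <- trimmed_mean_area(objects$area_px, config$trim_fraction)
  foci_count <- if (nrow(objects) == 0L) 0 else area_total_px / tma
  if (is.null(n_cells)) {
    n_cells <- count_cells(image$blue, ps, config)
  }
  if (n_cells == 0 && foci_count > 0) {
    warning("image '", image$source_id,
            "': foci present but no cells counted; per-cell values undefined")
  }
  per_cell_ok <- n_cells > 0
  structure(list(
    image_id = image$source_id,
    objects = objects,
    n_objects = nrow(objects),
    area_total_px = area_total_px,
    area_total_um2 = area_total_px * ps^2,
    trimmed_mean_area_px = tma,
    foci_count = foci_count,
    n_cells = as.integer(n_cells),
    foci_per_cell = if (per_cell_ok) foci_count / n_cells else NA_real_,
    area_per_cell_um2 = if (per_cell_ok) area_total_px * ps^2 / n_cells
                        else NA_real_),
    class = "foci_quant")
}

#' @export
print.foci_quant <- function(x, ...) {
  cat(sprintf(
    "<foci_quant '%s': %d objects, AreaTotal %d px, foci count %.2f, %d cells>\n",
    x$image_id, x$n_objects, x$area_total_px, x$foci_count, x$n_cells))
  invisible(x)
}

#' Convert a list of per-image quantifications to a table
#'
#' @param results list of `foci_quant` objects.
#' @return a `data.frame` with one row per image, columns matching the
#'   per-image CSV: `image_id`, `n_objects`, `area_total_px`,
#'   `area_total_um2`, `trimmed_mean_area_px`, `foci_count`, `n_cells`,
#'   `foci_per_cell`, `area_per_cell_um2`.
#' @export
foci_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(image_id = r$image_id, n_objects = r$n_objects,
               area_total_px = r$area_total_px,
               area_total_um2 = r$area_total_um2,
               trimmed_mean_area_px = r$trimmed_mean_area_px,
               foci_count = r$foci_count, n_cells = r$n_cells,
               foci_per_cell = r$foci_per_cell,
               area_per_cell_um2 = r$area_per_cell_um2)
  }))
}
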