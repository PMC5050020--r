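# Colocalization of hnRNP H (green) with G-quadruplex (red) staining:
# event detection as red/green mask intersections, nuclear vs
# DAPI-positive-cytoplasm classification, the large-focus size criterion,
# and per-cell-line incidence summaries.

#' Detect red/green colocalization events in one image
#'
#' Events are connected components of the intersection of the thresholded
#' red and green masks with area at least `min_coloc_area_um2` (the
#' discrete-event definition; no intensity-correlation metrics). Each event
#' is classified as nuclear or cytoplasmic by [classify_compartment()].
#'
#' @param image a [multichannel_image()].
#' @param config a [threshold_config()].
#' @return a `data.frame` of events: `image_id`, `area_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`, `max_dim_um`, `compartment`.
#' @export
detect_coloc_events <- function(image, config = threshold_config()) {
  stopifnot(inherits(image, "multichannel_image"))
  ps <- image$pixel_size_um
  inter <- threshold_channel(image$red, config$red_threshold) &
    threshold_channel(image$green, config$red_threshold)
  obj <- label_objects(inter, ps, config$connectivity, config$feret)
  obj <- obj[obj$area_um2 >= config$min_coloc_area_um2, , drop = FALSE]
  comp <- classify_compartment(obj$centroid_row, obj$centroid_col,
                               image$blue, ps, config)
  out <- data.frame(image_id = rep(image$source_id, nrow(obj)),
                    area_px = obj$area_px, area_um2 = obj$area_um2,
                    centroid_row = obj$centroid_row,
                    centroid_col = obj$centroid_col,
                    max_dim_um = obj$max_dim_um,
                    compartment = comp)
  rownames(out) <- NULL
  out
}

#' Classify event locations as nuclear or cytoplasmic
#'
#' Nuclei are blue objects at or above `blue_threshold` with area at least
#' `min_nucleus_area_um2`; DAPI-positive cytoplasm is any remaining pixel
#' at or above `cytoplasm_threshold` (faint DAPI signal outside nuclei
#' indicates cytoplasmic nucleic acids). Classification uses the event
#' centroid, which is robust to one-pixel boundary crossings; centroids in
#' neither region are `"unassigned"`.
#'
#' @param rows,cols event centroids, 0-based pixel coordinates.
#' @param blue_plane normalized DAPI plane.
#' @param pixel_size_um micrometres per pixel edge.
#' @param config a [threshold_config()].
#' @return character vector: `"nuclear"`, `"cytoplasmic"` or `"unassigned"`.
#' @export
classify_compartment <- function(rows, cols, blue_plane, pixel_size_um,
                                 config = threshold_config()) {
  if (length(rows) == 0L) return(character())
  nuc_mask <- threshold_channel(blue_plane, config$blue_threshold)
  nuc_obj <- label_objects(nuc_mask, pixel_size_um, config$connectivity)
  small <- nuc_obj$label[nuc_obj$area_um2 < config$min_nucleus_area_um2]
  if (length(small) > 0L) {
    lab <- .label_components(nuc_mask, config$connectivity)
    nuc_mask[nuc_mask][lab[nuc_mask] %in% small] <- FALSE
  }
  cyto_mask <- threshold_channel(blue_plane, config$cytoplasm_threshold) &
    !nuc_mask
  ri <- pmin(pmax(round(rows) + 1L, 1L), nrow(blue_plane))
  ci <- pmin(pmax(round(cols) + 1L, 1L), ncol(blue_plane))
  at <- cbind(ri, ci)
  ifelse(nuc_mask[at], "nuclear",
         ifelse(cyto_mask[at], "cytoplasmic", "unassigned"))
}

#' Filter objects by the large-focus size criterion
#'
#' Retains objects whose maximum dimension is at least `min_dim_um`
#' (default 0.5 micrometres, the lower limit for discernible puncta in
#' tissue sections). The dimension is the longer bounding-box side, or the
#' Feret diameter when the objects were measured with `feret = TRUE`.
#'
#' @param objects a [label_objects()] or event table carrying `max_dim_um`.
#' @param min_dim_um size cutoff in micrometres.
#' @return the retained subset of `objects`.
#' @export
filter_large_foci <- function(objects, min_dim_um = 0.5) {
  objects[objects$max_dim_um >= min_dim_um, , drop = FALSE]
}

#' Summarize colocalization incidence per cell line
#'
#' Aggregates per-image events over cell lines and reports, per compartment,
#' both incidence metrics in percent: `incidence_events` = events divided by
#' total cells, and `incidence_cells` = fraction of cells containing at
#' least one event. When events carry no per-cell assignment (column
#' `cell_id`), cells-with-event counts assume distinct cells per event,
#' capped at the event count per image -- exact in the sparse-event regime
#' these experiments live in.
#'
#' @param events a `data.frame` of events (from [detect_coloc_events()],
#'   possibly row-bound over images) with columns `image_id`,
#'   `compartment`, optionally `cell_id` and `max_dim_um`.
#' @param cells a `data.frame` with `image_id`, `cell_count`.
#' @param design a `data.frame` with `image_id`, `line_id` (e.g. from the
#'   `design` schema of [read_table()]).
#' @param config a [threshold_config()] (for the large-focus cutoff).
#' @return a `data.frame`, one row per line: cell totals, event counts and
#'   both incidences per compartment, and `n_large_foci`.
#' @export
summarize_coloc <- function(events, cells, design,
                            config = threshold_config()) {
  if (!all(cells$image_id %in% design$image_id)) {
    stop("every image must be assigned to a line in `design`")
  }
  line_of <- stats::setNames(design$line_id, design$image_id)
  cells$line_id <- line_of[cells$image_id]
  events$line_id <- line_of[events$image_id]
  lines <- sort(unique(design$line_id))
  out <- lapply(lines, function(ln) {
    n_cells <- sum(cells$cell_count[cells$line_id == ln])
    ev <- events[!is.na(events$line_id) & events$line_id == ln, , drop = FALSE]
    n_nuc <- sum(ev$compartment == "nuclear")
    n_cyt <- sum(ev$compartment == "cytoplasmic")
    cells_with <- function(comp) {
      sub <- ev[ev$compartment == comp, , drop = FALSE]
      if ("cell_id" %in% names(sub) && !anyNA(sub$cell_id)) {
        nrow(unique(sub[c("image_id", "cell_id")]))
      } else {
        # distinct-cell assumption, capped at each image's cell count
        tab <- table(sub$image_id)
        caps <- cells$cell_count[match(names(tab), cells$image_id)]
        sum(pmin(as.integer(tab), caps), na.rm = TRUE)
      }
    }
    if (n_cells == 0) {
      warning("line '", ln, "' has zero cells; incidences undefined")
    }
    pct <- function(x) if (n_cells > 0) 100 * x / n_cells else NA_real_
    n_large <- if ("max_dim_um" %in% names(ev)) {
      nrow(filter_large_foci(ev, config$large_focus_min_um))
    } else NA_integer_
    data.frame(line_id = ln, n_cells = n_cells,
               n_events_nuclear = n_nuc, n_events_cytoplasmic = n_cyt,
               incidence_events_nuclear = pct(n_nuc),
               incidence_events_cytoplasmic = pct(n_cyt),
               incidence_cells_nuclear = pct(min(cells_with("nuclear"),
                                                 n_cells)),
               incidence_cells_cytoplasmic = pct(min(cells_with("cytoplasmic"),
                                                     n_cells)),
               n_large_foci = n_large)
  })
  do.call(rbind, out)
}
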