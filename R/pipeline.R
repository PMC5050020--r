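# Dataset-level orchestration: quantify a directory of images, pool
# per-line values, normalize per experiment, and compare groups.

#' Quantify every TIFF in a directory
#'
#' Runs [quantify_image()] over all `.tif`/`.tiff` files, taking cell
#' counts from a `cells.csv` (the `cells` schema) when present -- the
#' `cells.csv` written by [generate_experiment()] carries the true planted
#' counts -- and counting nuclei otherwise.
#'
#' @param dir directory of multichannel TIFFs.
#' @param config a [threshold_config()].
#' @param cells optional `data.frame` (`image_id`, `cell_count`); defaults
#'   to `dir/cells.csv` when that file exists.
#' @param map a [channel_map()].
#' @param pixel_size_um fallback pixel size for files without resolution
#'   metadata.
#' @return the per-image table of [foci_results_table()].
#' @export
quantify_directory <- function(dir, config = threshold_config(),
                               cells = NULL, map = channel_map(),
                               pixel_size_um = NULL) {
  paths <- list.files(dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (length(paths) == 0L) stop("no TIFF images found in ", dir)
  if (is.null(cells) && file.exists(file.path(dir, "cells.csv"))) {
    cells <- read_table(file.path(dir, "cells.csv"), "cells")
  }
  results <- lapply(paths, function(p) {
    id <- basename(p)
    n_cells <- if (!is.null(cells) && id %in% cells$image_id) {
      cells$cell_count[match(id, cells$image_id)]
    } else NULL
    img <- load_image(p, map = map, pixel_size_um = pixel_size_um,
                      source_id = id)
    r <- quantify_image(img, config, n_cells = n_cells)
    r$objects <- NULL # per-object tables are large; keep summaries only
    r
  })
  foci_results_table(results)
}

#' Pool per-image quantifications into per-line experiment records
#'
#' For each experiment-by-line cell, pools all of that line's images
#' (total foci over total cells, and total stained area over total cells)
#' and emits the record format [normalize_to_control()] consumes.
#'
#' @param results per-image table from [quantify_directory()].
#' @param design `data.frame` with `image_id`, `experiment_id`, `line_id`,
#'   `group`, optionally `condition` (rows with `condition != "untreated"`
#'   are kept and flagged; filter before calling if needed).
#' @param metric `"foci_per_cell"` or `"area_per_cell_um2"`.
#' @return a `data.frame` with `experiment_id`, `line_id`, `group`,
#'   `value`, `n_cells`.
#' @export
experiment_records <- function(results, design,
                               metric = c("foci_per_cell",
                                          "area_per_cell_um2")) {
  metric <- match.arg(metric)
  m <- merge(results, design, by = "image_id")
  if (nrow(m) < nrow(results)) {
    stop("design is missing ", nrow(results) - nrow(m), " image(s)")
  }
  num <- if (metric == "foci_per_cell") m$foci_count else m$area_total_um2
  agg <- stats::aggregate(
    cbind(num = num, n_cells = m$n_cells),
    by = list(experiment_id = m$experiment_id, line_id = m$line_id,
              group = m$group),
    FUN = sum)
  data.frame(experiment_id = agg$experiment_id, line_id = agg$line_id,
             group = agg$group, value = agg$num / agg$n_cells,
             n_cells = agg$n_cells)
}

#' Full foci pipeline over a generated or acquired dataset
#'
#' Quantifies every image, pools per line, normalizes each experiment to
#' its average control cell, and compares case against control: the
#' analysis behind the reported patient:control fold changes.
#'
#' @param dir dataset directory with TIFFs, `cells.csv` and `design.csv`.
#' @param metric `"foci_per_cell"` or `"area_per_cell_um2"`.
#' @param config a [threshold_config()].
#' @param condition which condition rows of the design to analyze.
#' @param var_equal Student pooled-variance t-test (default) or Welch.
#' @return a list: `comparison` (a [compare_groups()] result), `records`
#'   (normalized per-line values), `results` (per-image table).
#' @export
run_foci_pipeline <- function(dir, metric = "foci_per_cell",
                              config = threshold_config(),
                              condition = "untreated", var_equal = TRUE) {
  design <- read_table(file.path(dir, "design.csv"), "design")
  design <- design[design$condition == condition, , drop = FALSE]
  results <- quantify_directory(dir, config)
  results <- results[results$image_id %in% design$image_id, , drop = FALSE]
  records <- normalize_to_control(experiment_records(results, design,
                                                     metric))
  list(comparison = compare_groups(records, var_equal = var_equal),
       records = records, results = results)
}

#' RNAse-treatment analysis over a generated rnase dataset
#'
#' Quantifies untreated and treated images, pools foci per cell per line
#' and condition, and reports the per-group percent reductions plus the
#' implied and measured untreated case:control ratios.
#'
#' @param dir dataset directory (e.g. from
#'   `generate_experiment("rnase")`).
#' @param config a [threshold_config()].
#' @return the [rnase_comparison()] list.
#' @export
run_rnase_pipeline <- function(dir, config = threshold_config()) {
  design <- read_table(file.path(dir, "design.csv"), "design")
  results <- quantify_directory(dir, config)
  recs <- function(cond) {
    d <- design[design$condition == cond, , drop = FALSE]
    r <- experiment_records(results[results$image_id %in% d$image_id, ],
                            d, "foci_per_cell")
    data.frame(line_id = r$line_id, group = r$group, value = r$value)
  }
  rnase_comparison(recs("untreated"), recs("treated"))
}
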