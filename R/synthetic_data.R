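# Synthetic ground-truth generator: multichannel images with planted
# nuclei and red/green foci, plus band/fraction/binding tables, under
# named presets calibrated to the effect sizes the imaging and
# densitometry experiments report. Everything is deterministic for a fixed
# seed; generators use a private RNG state so callers' streams are
# untouched.

.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# paint a filled disk, returning the updated plane and the pixel count
.add_disk <- function(plane, cy, cx, r_px, intensity) {
  i0 <- max(1L, floor(cy - r_px)); i1 <- min(nrow(plane), ceiling(cy + r_px))
  j0 <- max(1L, floor(cx - r_px)); j1 <- min(ncol(plane), ceiling(cx + r_px))
  if (i0 > i1 || j0 > j1) return(list(plane = plane, n_px = 0L))
  rr <- i0:i1; cc <- j0:j1
  m <- outer((rr - cy)^2, (cc - cx)^2, `+`) <= r_px^2
  sub <- plane[rr, cc, drop = FALSE]
  sub[m] <- pmax(sub[m], intensity)
  plane[rr, cc] <- sub
  list(plane = plane, n_px = sum(m))
}

# paint a filled rotated ellipse (axes a, b in px, angle theta)
.add_ellipse <- function(plane, cy, cx, a, b, theta, intensity) {
  r <- max(a, b)
  i0 <- max(1L, floor(cy - r)); i1 <- min(nrow(plane), ceiling(cy + r))
  j0 <- max(1L, floor(cx - r)); j1 <- min(ncol(plane), ceiling(cx + r))
  rr <- i0:i1; cc <- j0:j1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  m <- (u / a)^2 + (v / b)^2 <= 1
  sub <- plane[rr, cc, drop = FALSE]
  sub[m] <- pmax(sub[m], intensity)
  plane[rr, cc] <- sub
  list(plane = plane, n_px = sum(m))
}

#' Specification of one synthetic multichannel image
#'
#' Describes the planted scene: jittered-grid nuclei (filled ellipses in
#' blue, each surrounded by a dim DAPI-positive cytoplasm annulus), red
#' (G-quadruplex) foci planted inside nuclei at a Poisson per-cell rate
#' with lognormal radii, optional green (hnRNP H) foci, and red/green
#' colocalization pairs that may sit in the nucleus or the cytoplasm
#' annulus. Focus intensities are drawn strictly above the detection
#' threshold so that recovery failures reflect the algorithm, not the
#' rendering; the `dim` preset deliberately straddles the threshold.
#'
#' @param shape image dimensions (rows, cols); `NULL` sizes the image to
#'   fit `n_cells` on the grid.
#' @param pixel_size_um micrometres per pixel edge.
#' @param n_cells number of planted cells.
#' @param nucleus_radius_um,nucleus_intensity uniform ranges.
#' @param cyto_width_um,cyto_intensity cytoplasm annulus width and
#'   intensity range (dim: above `cytoplasm_threshold`, below
#'   `blue_threshold`).
#' @param foci_per_cell_mean Poisson rate of red foci per cell.
#' @param focus_radius_um,focus_radius_cv lognormal radius mean and CV.
#' @param focus_intensity uniform intensity range of foci.
#' @param green_foci_per_cell_mean Poisson rate of green-only foci.
#' @param green_focus_radius_um,green_focus_radius_cv green radius model.
#' @param coloc_fraction fraction of red foci paired with an identical
#'   green focus (a planted colocalization event).
#' @param coloc_cyto_fraction fraction of colocalization pairs placed in
#'   the cytoplasm annulus rather than the nucleus.
#' @param stray_red_foci expected count of red foci outside any cell
#'   (removed by blue gating; exercises the gate).
#' @param rna_removable_fraction probability that each red focus is
#'   deleted before rendering (simulated RNAse digestion of RNA foci).
#' @param background,noise_sd Gaussian background level and sd, clipped to
#'   `[0, 1]` and quantized to the 16-bit grid.
#' @param seed RNG seed for this image.
#' @param source_id image label.
#' @return a `sim_image_spec` list.
#' @export
sim_image_spec <- function(shape = NULL, pixel_size_um = 0.25, n_cells = 25,
                           nucleus_radius_um = c(4.2, 5.0),
                           nucleus_intensity = c(0.5, 0.9),
                           cyto_width_um = 2.5,
                           cyto_intensity = c(0.03, 0.06),
                           foci_per_cell_mean = 5,
                           focus_radius_um = 0.3, focus_radius_cv = 0.2,
                           focus_intensity = c(0.3, 0.9),
                           green_foci_per_cell_mean = 0,
                           green_focus_radius_um = 0.6,
                           green_focus_radius_cv = 0.2,
                           coloc_fraction = 0, coloc_cyto_fraction = 0.5,
                           stray_red_foci = 2,
                           rna_removable_fraction = 0,
                           background = 0.01, noise_sd = 0.015,
                           seed = 1L, source_id = "sim") {
  spec <- as.list(environment())
  stopifnot(pixel_size_um > 0, n_cells >= 0, foci_per_cell_mean >= 0,
            green_foci_per_cell_mean >= 0,
            coloc_fraction >= 0, coloc_fraction <= 1,
            rna_removable_fraction >= 0, rna_removable_fraction <= 1,
            noise_sd >= 0)
  class(spec) <- "sim_image_spec"
  spec
}

# sample a point inside (scale < 1) or on a ring of an ellipse, rotated
.ellipse_point <- function(cy, cx, a, b, theta, smin, smax) {
  t <- runif(1, 0, 2 * pi)
  s <- sqrt(runif(1, smin^2, smax^2))
  u <- s * a * cos(t); v <- s * b * sin(t)
  c(cy + cos(theta) * u - sin(theta) * v,
    cx + sin(theta) * u + cos(theta) * v)
}

#' Generate one synthetic multichannel image with ground truth
#'
#' Deterministic for a fixed spec (same spec and seed give bit-identical
#' images). Foci are placed with a minimum center separation so planted
#' objects are disjoint; when a focus cannot be placed within the attempt
#' budget it is skipped and the truth reflects only placed objects (a
#' warning is raised).
#'
#' @param spec a [sim_image_spec()].
#' @return a list with `image` (a [multichannel_image()]) and `truth`
#'   (`cells`: per-cell counts and areas; `foci`: one row per planted
#'   focus with `cell_id`, `channel`, `compartment`, position, radius and
#'   rendered `area_px`; `summary`: image-level aggregates).
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "sim_image_spec"))
  .with_seed(spec$seed, {
    ps <- spec$pixel_size_um
    r_nuc_max <- max(spec$nucleus_radius_um) / ps
    cyto_w <- spec$cyto_width_um / ps
    spacing <- ceiling(2 * (r_nuc_max + cyto_w)) + 10L
    gcols <- max(1L, ceiling(sqrt(spec$n_cells)))
    grows <- max(1L, ceiling(spec$n_cells / gcols))
    if (is.null(spec$shape)) {
      shape <- c(grows, gcols) * spacing
    } else {
      shape <- spec$shape
      if (spec$n_cells > 0 &&
          (shape[1L] < grows * spacing || shape[2L] < gcols * spacing)) {
        stop("image shape too small for ", spec$n_cells, " cells; need >= ",
             grows * spacing, " x ", gcols * spacing)
      }
    }
    blue <- matrix(0, shape[1L], shape[2L])
    red <- matrix(0, shape[1L], shape[2L])
    green <- matrix(0, shape[1L], shape[2L])

    n_skipped <- 0L
    foci <- list()
    cells <- list()
    cell_ids <- seq_len(spec$n_cells)
    for (k in cell_ids) {
      gi <- (k - 1L) %/% gcols; gj <- (k - 1L) %% gcols
      cy <- (gi + 0.5) * spacing + runif(1, -0.05, 0.05) * spacing
      cx <- (gj + 0.5) * spacing + runif(1, -0.05, 0.05) * spacing
      r <- runif(1, spec$nucleus_radius_um[1L],
                 spec$nucleus_radius_um[2L]) / ps
      a <- r * runif(1, 0.9, 1.1); b <- r * runif(1, 0.9, 1.1)
      theta <- runif(1, 0, pi)
      nuc_int <- runif(1, spec$nucleus_intensity[1L],
                       spec$nucleus_intensity[2L])
      cyt_int <- runif(1, spec$cyto_intensity[1L], spec$cyto_intensity[2L])
      res <- .add_ellipse(blue, cy, cx, a + cyto_w, b + cyto_w, theta,
                          cyt_int)
      blue <- res$plane
      res <- .add_ellipse(blue, cy, cx, a, b, theta, nuc_int)
      blue <- res$plane
      nucleus_area_px <- res$n_px

      placed <- matrix(numeric(0), ncol = 3L) # row, col, radius_px
      place_focus <- function(r_px, compartment) {
        # ring placement keeps the focus fully inside its compartment
        margin <- (r_px + 1.5) / min(a, b)
        bounds <- if (compartment == "nuclear") {
          c(0, max(0.05, 1 - margin))
        } else {
          lo <- 1 + (r_px + 1.5) / min(a, b)
          hi <- (min(a, b) + cyto_w - r_px - 1.5) / min(a, b)
          if (hi <= lo) return(NULL)
          c(lo, hi)
        }
        for (att in 1:60) {
          p <- .ellipse_point(cy, cx, a, b, theta, bounds[1L], bounds[2L])
          # 1.5 px clearance: adjacent pixels are <= sqrt(2) apart, so
          # planted disks can never touch under 8-connectivity
          if (nrow(placed) == 0L ||
              all((placed[, 1L] - p[1L])^2 + (placed[, 2L] - p[2L])^2 >=
                    (placed[, 3L] + r_px + 1.5)^2)) {
            return(p)
          }
        }
        NULL
      }
      draw_radius <- function(mean_um, cv) {
        sdlog <- sqrt(log(1 + cv^2))
        max(0.8, rlnorm(1, log(mean_um / ps) - sdlog^2 / 2, sdlog))
      }

      n_red <- rpois(1, spec$foci_per_cell_mean)
      if (spec$rna_removable_fraction > 0 && n_red > 0) {
        n_red <- rbinom(1, n_red, 1 - spec$rna_removable_fraction)
      }
      n_coloc <- if (spec$coloc_fraction > 0 && n_red > 0) {
        rbinom(1, n_red, spec$coloc_fraction)
      } else 0L
      cell_foci <- list()
      for (f in seq_len(n_red)) {
        is_coloc <- f <= n_coloc
        comp <- if (is_coloc && runif(1) < spec$coloc_cyto_fraction) {
          "cytoplasmic"
        } else "nuclear"
        r_px <- draw_radius(spec$focus_radius_um, spec$focus_radius_cv)
        p <- place_focus(r_px, comp)
        if (is.null(p)) { n_skipped <- n_skipped + 1L; next }
        int <- runif(1, spec$focus_intensity[1L], spec$focus_intensity[2L])
        res <- .add_disk(red, p[1L], p[2L], r_px, int)
        red <- res$plane
        if (is_coloc) {
          gint <- runif(1, spec$focus_intensity[1L],
                        spec$focus_intensity[2L])
          green <- .add_disk(green, p[1L], p[2L], r_px, gint)$plane
        }
        placed <- rbind(placed, c(p, r_px))
        cell_foci[[length(cell_foci) + 1L]] <- data.frame(
          cell_id = k, channel = if (is_coloc) "coloc" else "red",
          compartment = comp, row = p[1L] - 1, col = p[2L] - 1,
          radius_px = r_px, area_px = res$n_px)
      }
      n_green_only <- rpois(1, spec$green_foci_per_cell_mean)
      for (f in seq_len(n_green_only)) {
        r_px <- draw_radius(spec$green_focus_radius_um,
                            spec$green_focus_radius_cv)
        p <- place_focus(r_px, "nuclear")
        if (is.null(p)) { n_skipped <- n_skipped + 1L; next }
        gint <- runif(1, spec$focus_intensity[1L], spec$focus_intensity[2L])
        res <- .add_disk(green, p[1L], p[2L], r_px, gint)
        green <- res$plane
        placed <- rbind(placed, c(p, r_px))
        cell_foci[[length(cell_foci) + 1L]] <- data.frame(
          cell_id = k, channel = "green", compartment = "nuclear",
          row = p[1L] - 1, col = p[2L] - 1, radius_px = r_px,
          area_px = res$n_px)
      }
      cf <- if (length(cell_foci) > 0L) do.call(rbind, cell_foci) else NULL
      foci[[k]] <- cf
      count <- function(ch, comp = NULL) {
        if (is.null(cf)) return(0L)
        sel <- cf$channel %in% ch
        if (!is.null(comp)) sel <- sel & cf$compartment == comp
        sum(sel)
      }
      area_of <- function(ch, comp = NULL) {
        if (is.null(cf)) return(0L)
        sel <- cf$channel %in% ch
        if (!is.null(comp)) sel <- sel & cf$compartment == comp
        sum(cf$area_px[sel])
      }
      cells[[k]] <- data.frame(
        cell_id = k, center_row = cy - 1, center_col = cx - 1,
        nucleus_area_px = nucleus_area_px,
        n_red_nuclear = count(c("red", "coloc"), "nuclear"),
        red_area_nuclear_px = area_of(c("red", "coloc"), "nuclear"),
        n_red_cyto = count(c("red", "coloc"), "cytoplasmic"),
        n_green_only = count("green"),
        n_coloc_nuclear = count("coloc", "nuclear"),
        n_coloc_cyto = count("coloc", "cytoplasmic"))
    }

    # stray red foci on empty background (must not touch any blue staining)
    n_stray <- if (spec$stray_red_foci > 0) rpois(1, spec$stray_red_foci) else 0L
    stray_placed <- 0L
    for (s in seq_len(n_stray)) {
      for (att in 1:50) {
        p <- c(runif(1, 5, shape[1L] - 5), runif(1, 5, shape[2L] - 5))
        r_px <- max(0.8, spec$focus_radius_um / ps)
        i0 <- max(1L, floor(p[1L] - r_px - 2))
        i1 <- min(shape[1L], ceiling(p[1L] + r_px + 2))
        j0 <- max(1L, floor(p[2L] - r_px - 2))
        j1 <- min(shape[2L], ceiling(p[2L] + r_px + 2))
        if (all(blue[i0:i1, j0:j1] == 0)) {
          int <- runif(1, spec$focus_intensity[1L],
                       spec$focus_intensity[2L])
          red <- .add_disk(red, p[1L], p[2L], r_px, int)$plane
          stray_placed <- stray_placed + 1L
          break
        }
      }
    }
    if (n_skipped > 0L) {
      warning("generate_image('", spec$source_id, "'): ", n_skipped,
              " focus placement(s) failed; truth reflects placed objects")
    }

    finish <- function(p) {
      p <- p + spec$background +
        matrix(rnorm(length(p), 0, spec$noise_sd), nrow(p), ncol(p))
      p <- pmin(pmax(p, 0), 1)
      round(p * 65535) / 65535 # 16-bit grid: write/load round trip is exact
    }
    image <- multichannel_image(finish(red), finish(green), finish(blue),
                                pixel_size_um = ps,
                                source_id = spec$source_id)
    cells_df <- if (length(cells) > 0L) do.call(rbind, cells) else
      data.frame()
    foci_df <- do.call(rbind, foci[!vapply(foci, is.null, logical(1))])
    summary <- list(
      n_cells = spec$n_cells,
      n_red_nuclear = sum(cells_df$n_red_nuclear),
      red_area_nuclear_px = sum(cells_df$red_area_nuclear_px),
      n_red_cyto = sum(cells_df$n_red_cyto),
      n_green_only = sum(cells_df$n_green_only),
      n_coloc_nuclear = sum(cells_df$n_coloc_nuclear),
      n_coloc_cyto = sum(cells_df$n_coloc_cyto),
      n_stray_red = stray_placed,
      n_skipped = n_skipped)
    list(image = image, truth = list(cells = cells_df, foci = foci_df,
                                     summary = summary))
  })
}

# ---- experiment presets --------------------------------------------------

.sim_presets <- function() {
  list(
    fibroblast = list(
      n_experiments = 4L, case_pool = paste0("C9-", 1:7),
      control_pool = paste0("CTRL-", 1:5), case_per_exp = 4L,
      control_per_exp = 3L, cells_per_line = 100L,
      lambda_control = 5, fold_foci = 1.8, fold_area = 2.8,
      line_cv = 0.05, conditions = "untreated"),
    astrocyte = list(
      n_experiments = 3L, case_pool = "C9-AST", control_pool = "CTRL-AST",
      case_per_exp = 1L, control_per_exp = 1L, cells_per_line = 72L,
      lambda_control = 5, fold_foci = 2.0, fold_area = 2.3,
      # one line per group: a between-line multiplier would change the
      # planted ratio itself, so none is applied
      line_cv = 0, conditions = "untreated"),
    rnase = list(
      n_experiments = 1L, case_pool = "C9-AST", control_pool = "CTRL-AST",
      case_per_exp = 1L, control_per_exp = 1L, cells_per_line = 400L,
      lambda_control = 5, fold_foci = 2.7, fold_area = 2.7,
      line_cv = 0, conditions = c("untreated", "treated"),
      removable_control = 0.27, removable_case = 0.76),
    control_only = list(
      n_experiments = 2L, case_pool = paste0("X-", 1:3),
      control_pool = paste0("CTRL-", 1:3), case_per_exp = 3L,
      control_per_exp = 3L, cells_per_line = 60L,
      lambda_control = 5, fold_foci = 1.0, fold_area = 1.0,
      line_cv = 0.05, conditions = "untreated"),
    mn = list(
      n_experiments = 1L, case_pool = paste0("C9-MN", 1:2),
      control_pool = paste0("CTRL-MN", 1:2), case_per_exp = 2L,
      control_per_exp = 2L, cells_per_line = 18L,
      lambda_control = 5, fold_foci = 1.0, fold_area = 1.0,
      line_cv = 0, conditions = "untreated",
      green_rate_case = 46 / 36, green_rate_control = 3 / 19),
    dim = list(
      n_experiments = 1L, case_pool = "C9-DIM", control_pool = "CTRL-DIM",
      case_per_exp = 1L, control_per_exp = 1L, cells_per_line = 40L,
      lambda_control = 5, fold_foci = 1.8, fold_area = 1.8,
      line_cv = 0, conditions = "untreated",
      focus_intensity = c(0.05, 0.2))
  )
}

#' Names of the built-in experiment presets
#' @return character vector of preset names.
#' @export
sim_preset_names <- function() names(.sim_presets())

#' Generate a full synthetic staining experiment set
#'
#' Emits a directory of multichannel TIFFs plus `cells.csv` (true cell
#' counts), `design.csv` (image-to-experiment/line/group/condition
#' assignment) and per-image truth, under a named preset calibrated to the
#' reported effect sizes:
#' \describe{
#'   \item{fibroblast}{4 experiments, 7 patient and 5 control lines (4 + 3
#'     per experiment, giving 16 and 12 replicate values), planted
#'     foci-per-cell ratio 1.8 and stained-area ratio 2.8.}
#'   \item{astrocyte}{3 experiments, one line per group, ratios 2.0 (foci)
#'     and 2.3 (area).}
#'   \item{rnase}{untreated/treated pairs; untreated case:control ratio
#'     2.7 with removable fractions 0.76 (case) and 0.27 (control).}
#'   \item{control_only}{null preset, both groups identical (fold 1).}
#'   \item{mn}{large (> 0.5 um) green foci at motor-neuron rates 46/36
#'     (case) vs 3/19 (control) per cell.}
#'   \item{dim}{focus intensities straddling the 0.1 threshold (stress).}
#' }
#' Per-cell densities are scaled down from the hundreds of foci per cell
#' the RNAse experiment implies (unresolvable as discrete disks); the
#' planted *ratios* match the reported ones, which is what the pipeline
#' recovers.
#'
#' @param preset preset name (see [sim_preset_names()]).
#' @param out_dir output directory (created); defaults to a fresh tempdir.
#' @param seed master seed; per-image seeds are derived from it.
#' @param n_experiments,cells_per_line overrides of the preset defaults.
#' @return a list: `dir`, `design`, `cells` (both `data.frame`s, also
#'   written as CSV), `line_truth` (planted per-line per-cell foci and
#'   area), `image_truth`.
#' @export
generate_experiment <- function(preset, out_dir = NULL, seed = 1234L,
                                n_experiments = NULL,
                                cells_per_line = NULL) {
  presets <- .sim_presets()
  if (!preset %in% names(presets)) {
    stop("unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  p <- presets[[preset]]
  if (!is.null(n_experiments)) p$n_experiments <- n_experiments
  if (!is.null(cells_per_line)) p$cells_per_line <- cells_per_line
  if (is.null(out_dir)) {
    out_dir <- tempfile(paste0("quadfoci_", preset, "_"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  radius_scale <- sqrt(p$fold_area / max(p$fold_foci, 1e-9))
  lambda_case <- p$lambda_control * p$fold_foci

  .with_seed(seed, {
    # per-line multipliers: biological line-to-line variability
    all_lines <- c(p$case_pool, p$control_pool)
    line_mult <- stats::setNames(
      if (p$line_cv > 0) {
        sdlog <- sqrt(log(1 + p$line_cv^2))
        rlnorm(length(all_lines), -sdlog^2 / 2, sdlog)
      } else rep(1, length(all_lines)), all_lines)
  })

  design <- list(); cells_rows <- list(); line_truth <- list()
  image_truth <- list()
  img_i <- 0L
  for (ex in seq_len(p$n_experiments)) {
    exp_id <- sprintf("exp%02d", ex)
    pick <- function(pool, k, off) {
      if (length(pool) <= k) pool else
        pool[((off + seq_len(k) - 2L) %% length(pool)) + 1L]
    }
    lines_case <- pick(p$case_pool, p$case_per_exp, ex)
    lines_ctrl <- pick(p$control_pool, p$control_per_exp, ex)
    for (ln in c(lines_case, lines_ctrl)) {
      grp <- if (ln %in% p$case_pool) "case" else "control"
      lambda <- (if (grp == "case") lambda_case else p$lambda_control) *
        line_mult[[ln]]
      rscale <- if (grp == "case") radius_scale else 1
      for (cond in p$conditions) {
        img_i <- img_i + 1L
        image_id <- sprintf("%s_%s_%s_%s.tif", preset, exp_id, ln, cond)
        removable <- if (cond == "treated") {
          if (grp == "case") p$removable_case else p$removable_control
        } else 0
        spec <- sim_image_spec(
          n_cells = p$cells_per_line,
          foci_per_cell_mean = if (!is.null(p$green_rate_case)) 0 else lambda,
          focus_radius_um = 0.3 * rscale,
          focus_intensity = if (!is.null(p$focus_intensity))
            p$focus_intensity else c(0.3, 0.9),
          green_foci_per_cell_mean = if (!is.null(p$green_rate_case)) {
            if (grp == "case") p$green_rate_case else p$green_rate_control
          } else 0,
          green_focus_radius_um = 0.45,
          rna_removable_fraction = removable,
          seed = .derive_seed(seed, img_i),
          source_id = image_id)
        g <- generate_image(spec)
        write_image(g$image, file.path(out_dir, image_id))
        design[[img_i]] <- data.frame(
          image_id = image_id, experiment_id = exp_id, line_id = ln,
          group = grp, condition = cond)
        cells_rows[[img_i]] <- data.frame(image_id = image_id,
                                          cell_count = p$cells_per_line)
        s <- g$truth$summary
        image_truth[[img_i]] <- data.frame(
          image_id = image_id, experiment_id = exp_id, line_id = ln,
          group = grp, condition = cond, n_cells = s$n_cells,
          n_red_nuclear = s$n_red_nuclear,
          red_area_nuclear_px = s$red_area_nuclear_px,
          n_green_only = s$n_green_only,
          n_coloc_nuclear = s$n_coloc_nuclear,
          n_coloc_cyto = s$n_coloc_cyto)
      }
    }
  }
  design <- do.call(rbind, design)
  cells_df <- do.call(rbind, cells_rows)
  image_truth <- do.call(rbind, image_truth)
  image_truth$foci_per_cell_true <- image_truth$n_red_nuclear /
    image_truth$n_cells
  utils::write.csv(design, file.path(out_dir, "design.csv"),
                   row.names = FALSE)
  utils::write.csv(cells_df, file.path(out_dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(image_truth, file.path(out_dir, "truth_images.csv"),
                   row.names = FALSE)
  list(dir = out_dir, design = design, cells = cells_df,
       image_truth = image_truth, preset = preset,
       planted = list(fold_foci = p$fold_foci, fold_area = p$fold_area,
                      lambda_control = p$lambda_control,
                      removable = if (preset == "rnase") {
                        c(control = p$removable_control,
                          case = p$removable_case)
                      } else NULL))
}

.derive_seed <- function(seed, index) {
  (as.numeric(seed) * 2654435761 + index * 97561) %% (2^31 - 1)
}

# ---- tabular generators --------------------------------------------------

#' Default severity-coupled splicing gene panel
#'
#' Eighteen cassette-exon targets: fourteen whose inclusion tracks overall
#' hnRNP H loss (positive coupling; more exclusion in cases) and four
#' regulated in the opposite direction (WDR45, HNRPDL, RPL10, OS9; more
#' inclusion in cases, negative coupling).
#'
#' @return a `data.frame` with `gene`, `base_psi` (control mean),
#'   `delta_psi` (case shift) and `coupling` (slope coefficient on the
#'   severity axis).
#' @export
psi_gene_panel <- function() {
  pos <- c("ATXN2", "KIF1C", "PEX19", "ARRB2", "GABBR1", "PSMD4", "BAT3",
           "PPP1R12C", "PAN2", "RNH1", "DAZAP1", "RBM38", "PCBP2",
           "SIGMAR1")
  neg <- c("WDR45", "HNRPDL", "RPL10", "OS9")
  data.frame(
    gene = c(pos, neg),
    base_psi = c(seq(45, 80, length.out = length(pos)),
                 seq(30, 55, length.out = length(neg))),
    delta_psi = c(rep(-12, length(pos)), rep(12, length(neg))),
    coupling = c(rep(1, length(pos)), rep(-0.6, length(neg))))
}

#' Generate a synthetic RT-PCR bands table with known PSI truth
#'
#' Case patients carry a latent severity in `[0, 1]`; each gene's true
#' case PSI is `base + delta + coupling * spread * (severity - 1/2)`,
#' clamped to `[2, 98]`, so positively coupled genes fall with severity
#' and negatively coupled genes rise. Band intensities are
#' `(psi, 100 - psi)` scaled by a random lane factor with multiplicative
#' lognormal noise. Disease duration is generated anti-monotone in
#' severity (shorter duration for more severe missplicing) with Gaussian
#' jitter.
#'
#' @param genes a gene panel as from [psi_gene_panel()].
#' @param n_case,n_control patients per group.
#' @param n_replicates lanes per patient and gene (3-4 typical).
#' @param noise_sd multiplicative (lognormal sdlog) band noise.
#' @param severity_spread PSI points spanned by the severity axis.
#' @param duration_noise_sd jitter on the duration-severity link (on the
#'   unit severity scale).
#' @param seed RNG seed.
#' @return a list: `bands` (the `bands` schema), `metadata` (`sample`,
#'   `group`, `disease_duration_months`), `truth` (`psi` per
#'   sample-by-gene, patient severities, the gene panel).
#' @export
generate_psi_table <- function(genes = psi_gene_panel(), n_case = 7,
                               n_control = 7, n_replicates = 4,
                               noise_sd = 0.03, severity_spread = 25,
                               duration_noise_sd = 0.2, seed = 1L) {
  .with_seed(seed, {
    samples <- data.frame(
      sample = c(sprintf("C9-%02d", seq_len(n_case)),
                 sprintf("CTRL-%02d", seq_len(n_control))),
      group = rep(c("case", "control"), c(n_case, n_control)),
      severity = c(runif(n_case), rep(NA_real_, n_control)))
    true_psi <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      psi <- if (s$group == "case") {
        # higher severity = more hnRNP H loss: positively coupled exons
        # lose inclusion, negatively coupled exons gain it
        genes$base_psi + genes$delta_psi -
          genes$coupling * severity_spread * (s$severity - 0.5)
      } else {
        genes$base_psi
      }
      data.frame(sample = s$sample, group = s$group, gene = genes$gene,
                 psi_true = pmin(98, pmax(2, psi)))
    }))
    bands <- do.call(rbind, lapply(seq_len(nrow(true_psi)), function(i) {
      r <- true_psi[i, ]
      lane <- runif(n_replicates, 0.5, 1.5) * 100
      data.frame(sample = r$sample, group = r$group, gene = r$gene,
                 replicate = seq_len(n_replicates),
                 incl_intensity = r$psi_true * lane *
                   rlnorm(n_replicates, 0, noise_sd),
                 excl_intensity = (100 - r$psi_true) * lane *
                   rlnorm(n_replicates, 0, noise_sd))
    }))
    duration <- ifelse(
      is.na(samples$severity), NA_real_,
      pmax(6, 12 + 60 * ((1 - samples$severity) +
                           rnorm(nrow(samples), 0, duration_noise_sd))))
    metadata <- data.frame(sample = samples$sample, group = samples$group,
                           disease_duration_months = round(duration, 1))
    list(bands = bands, metadata = metadata,
         truth = list(psi = true_psi, patients = samples, genes = genes))
  })
}

#' Generate a synthetic three-fraction western table
#'
#' Per-sample true percent-insoluble values are drawn around the group
#' means (Gaussian between-sample spread, truncated to `[2, 98]`);
#' replicate measurements add within-sample noise; the three fraction
#' intensities are fabricated under a random per-lane loading factor so
#' that loading cancels in the percent-insoluble computation.
#'
#' @param mean_control,mean_case group mean percent insoluble.
#' @param between_sd,within_sd between-sample and replicate sds (percent
#'   points).
#' @param n_per_group samples per group.
#' @param n_replicates independent experiments per sample.
#' @param seed RNG seed.
#' @return a list: `fractions` (the `fractions` schema), `truth`
#'   (per-sample true percents and the group means).
#' @export
generate_fraction_table <- function(mean_control = 30.0, mean_case = 56.1,
                                    between_sd = 6, within_sd = 2,
                                    n_per_group = 7, n_replicates = 2,
                                    seed = 1L) {
  .with_seed(seed, {
    samples <- data.frame(
      sample = c(sprintf("C9-%02d", seq_len(n_per_group)),
                 sprintf("CTRL-%02d", seq_len(n_per_group))),
      group = rep(c("case", "control"), each = n_per_group))
    samples$true_pct <- pmin(98, pmax(2, rnorm(
      nrow(samples),
      ifelse(samples$group == "case", mean_case, mean_control),
      between_sd)))
    fractions <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      pct <- pmin(98, pmax(2, s$true_pct + rnorm(n_replicates, 0, within_sd)))
      loading <- runif(n_replicates, 0.6, 1.4) * 100
      split <- runif(n_replicates, 0.4, 0.8) # soluble share of the rest
      data.frame(sample = s$sample, group = s$group,
                 replicate = seq_len(n_replicates),
                 soluble = loading * (100 - pct) / 100 * split,
                 sarkosyl_soluble = loading * (100 - pct) / 100 * (1 - split),
                 sarkosyl_insoluble = loading * pct / 100)
    }))
    list(fractions = fractions,
         truth = list(samples = samples, mean_control = mean_control,
                      mean_case = mean_case))
  })
}

#' Generate synthetic gel-shift binding data
#'
#' One-site model `f = Bmax P / (Kd + P)` over a two-fold dilution series,
#' with additive Gaussian noise on the fraction bound (clipped to
#' `[0, 1]`). Presets: `"4R"` (Kd 75.5 nM, series to 640 nM) and
#' `"4R-7dG"` (Kd 13.5 nM, series to 160 nM).
#'
#' @param preset `"4R"`, `"4R-7dG"`, or `NULL` to use `kd_nM` directly.
#' @param kd_nM,bmax true parameters.
#' @param conc_nM concentration series; derived from the preset when
#'   omitted.
#' @param noise_sd sd of the additive noise on fraction bound.
#' @param n_replicates independent repeats.
#' @param seed RNG seed.
#' @return a list: `binding` (the `binding` schema), `points`
#'   (concentration and noisy fraction bound), `truth`.
#' @export
generate_binding_data <- function(preset = "4R", kd_nM = NULL, bmax = 0.95,
                                  conc_nM = NULL, noise_sd = 0.03,
                                  n_replicates = 3, seed = 1L) {
  if (!is.null(preset)) {
    kd_nM <- switch(preset, "4R" = 75.5, "4R-7dG" = 13.5,
                    stop("unknown binding preset '", preset,
                         "'; available: 4R, 4R-7dG"))
    if (is.null(conc_nM)) {
      top <- switch(preset, "4R" = 640, "4R-7dG" = 160)
      conc_nM <- c(0, top / 2^(8:0))
    }
  }
  if (is.null(kd_nM)) stop("supply a preset or kd_nM")
  if (is.null(conc_nM)) conc_nM <- c(0, 640 / 2^(8:0))
  series_id <- if (is.null(preset)) "custom" else preset
  .with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
      f_true <- bmax * conc_nM / (kd_nM + conc_nM)
      f <- pmin(1, pmax(0, f_true + rnorm(length(conc_nM), 0, noise_sd)))
      total <- runif(length(conc_nM), 0.7, 1.3) * 1000
      data.frame(series = series_id, replicate = rep,
                 protein_conc_nM = conc_nM,
                 bound_intensity = f * total,
                 free_intensity = (1 - f) * total)
    }))
    list(binding = pts,
         points = data.frame(protein_conc_nM = pts$protein_conc_nM,
                             fraction_bound = pts$bound_intensity /
                               (pts$bound_intensity + pts$free_intensity)),
         truth = list(kd_nM = kd_nM, bmax = bmax))
  })
}

#' Generate a synthetic co-IP table with beads-alone background
#'
#' @param ratio true case:control ratio of background-subtracted signal.
#' @param base control-group mean signal (arbitrary units).
#' @param cv lognormal coefficient of variation of replicate signals.
#' @param n_per_group samples per group.
#' @param n_replicates co-IP repeats.
#' @param background_level beads-alone signal as a fraction of `base`.
#' @param seed RNG seed.
#' @return a list: `ip`, `beads_only` (both with `sample`, `group`,
#'   `replicate`, `signal`), `truth`.
#' @export
generate_coip_table <- function(ratio = 2.7, base = 1.0, cv = 0.2,
                                n_per_group = 5, n_replicates = 3,
                                background_level = 0.15, seed = 1L) {
  .with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    samples <- data.frame(
      sample = c(sprintf("C9-%02d", seq_len(n_per_group)),
                 sprintf("CTRL-%02d", seq_len(n_per_group))),
      group = rep(c("case", "control"), each = n_per_group))
    ip <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
      s <- samples[i, ]
      true <- base * if (s$group == "case") ratio else 1
      bg <- base * background_level * rlnorm(n_replicates, -sdlog^2 / 2, sdlog)
      data.frame(sample = s$sample, group = s$group,
                 replicate = seq_len(n_replicates),
                 signal = true * rlnorm(n_replicates, -sdlog^2 / 2, sdlog) + bg,
                 bg = bg)
    }))
    beads <- data.frame(sample = ip$sample, group = ip$group,
                        replicate = ip$replicate, signal = ip$bg)
    ip$bg <- NULL
    list(ip = ip, beads_only = beads,
         truth = list(ratio = ratio, background_level = background_level))
  })
}
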