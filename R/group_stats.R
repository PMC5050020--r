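# Per-experiment normalization to the average control cell, fold-change
# computation, pooled unpaired t-tests, and the RNAse-treatment arithmetic.

#' Normalize per-line values to the average control cell per experiment
#'
#' Staining intensity varies between experiments, so each experiment is
#' analyzed separately: every line's per-cell value is divided by the
#' *average control cell* of that experiment -- the cell-count-weighted
#' mean of the control lines' per-cell values, i.e. the value obtained by
#' pooling all control cells. Control values then average to 1 (with
#' cell-count weights) by construction, and every value becomes a fold
#' change relative to control.
#'
#' @param records a `data.frame` with columns `experiment_id`, `line_id`,
#'   `group` (`"control"` or `"case"`), `value` (a per-cell metric such as
#'   foci per cell) and `n_cells`.
#' @return `records` with an added `norm_value` column.
#' @export
normalize_to_control <- function(records) {
  req <- c("experiment_id", "line_id", "group", "value", "n_cells")
  if (!all(req %in% names(records))) {
    stop("records need columns: ", paste(req, collapse = ", "))
  }
  out <- records
  out$norm_value <- NA_real_
  for (ex in unique(records$experiment_id)) {
    sel <- records$experiment_id == ex
    ctrl <- sel & records$group == "control"
    if (!any(ctrl)) stop("experiment '", ex, "' has no control lines")
    ctrl_mean <- stats::weighted.mean(records$value[ctrl],
                                      records$n_cells[ctrl])
    if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
      stop("experiment '", ex, "' has non-positive control mean")
    }
    out$norm_value[sel] <- records$value[sel] / ctrl_mean
  }
  out
}

#' Significance stars for a p-value
#'
#' Thresholds 0.05, 0.01, 0.001, 0.0001.
#'
#' @param p p-value(s).
#' @return character vector of `""` to `"****"`.
#' @export
p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) "" else if (x < 1e-4) "****" else if (x < 1e-3) "***"
    else if (x < 1e-2) "**" else if (x < 0.05) "*" else ""
  }, character(1))
}

#' Compare case and control groups of normalized replicate values
#'
#' Pools all case replicates into one group and all control replicates into
#' another and applies an unpaired two-sample t-test (Student
#' equal-variance form by default; Welch via `var_equal = FALSE`). The fold
#' change is the ratio of group means of the normalized values. Degenerate
#' zero-variance inputs are handled directly: identical groups give p = 1,
#' separated constant groups give p = 0.
#'
#' @param records a `data.frame` with `group` and `norm_value` columns
#'   (from [normalize_to_control()]), or any value column named by
#'   `value_col`.
#' @param value_col column holding the replicate values.
#' @param var_equal use the pooled-variance Student test (default).
#' @return an object of class `group_comparison`: `metric`,
#'   `n_case`, `n_control`, `mean_case`, `mean_control`, `fold_change`,
#'   `t_statistic`, `df`, `p_value`, `stars`.
#' @export
compare_groups <- function(records, value_col = "norm_value",
                           var_equal = TRUE) {
  x <- records[[value_col]][records$group == "case"]
  y <- records[[value_col]][records$group == "control"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    warning("fewer than 2 replicates in a group; comparison skipped")
    return(structure(list(metric = value_col, n_case = length(x),
                          n_control = length(y),
                          mean_case = mean(x), mean_control = mean(y),
                          fold_change = mean(x) / mean(y),
                          t_statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, stars = ""),
                     class = "group_comparison"))
  }
  degenerate <- function() {
    # zero (or numerically negligible) variance in both groups
    identical_groups <- isTRUE(all.equal(mean(x), mean(y)))
    list(statistic = if (identical_groups) 0 else
           Inf * sign(mean(x) - mean(y)),
         parameter = length(x) + length(y) - 2,
         p.value = if (identical_groups) 1 else 0)
  }
  eps <- 1e-10 * (abs(mean(x)) + abs(mean(y)) + 1)
  tt <- if (stats::sd(x) <= eps && stats::sd(y) <= eps) {
    degenerate()
  } else {
    tryCatch(stats::t.test(x, y, var.equal = var_equal),
             error = function(e) degenerate())
  }
  structure(list(metric = value_col, n_case = length(x),
                 n_control = length(y), mean_case = mean(x),
                 mean_control = mean(y), fold_change = mean(x) / mean(y),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value, stars = p_stars(tt$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison: fold change %.3f (n=%d case, %d control), t=%.3f, p=%.3g %s>\n",
    x$fold_change, x$n_case, x$n_control, x$t_statistic, x$p_value, x$stars))
  invisible(x)
}

#' RNAse-treatment comparison
#'
#' Percent reduction in foci per cell after RNAse treatment, per group, and
#' the implied untreated case:control ratio recoverable from treated counts
#' and reductions alone (useful when only post-treatment counts are
#' printed): `untreated = treated / (1 - reduction)`, so the implied ratio
#' is `[treated_case / (1 - red_case)] / [treated_control /
#' (1 - red_control)]`.
#'
#' @param untreated,treated `data.frame`s with `line_id`, `group`, `value`
#'   (foci per cell), matched on `line_id`.
#' @return a list with per-group `reduction_pct` (named `control`/`case`),
#'   `treated_means`, `untreated_means`, `untreated_ratio` (measured) and
#'   `implied_untreated_ratio` (reconstructed from treated + reductions).
#' @export
rnase_comparison <- function(untreated, treated) {
  if (!setequal(untreated$line_id, treated$line_id)) {
    stop("untreated and treated must cover the same lines")
  }
  gm <- function(df, grp) mean(df$value[df$group == grp])
  u <- c(control = gm(untreated, "control"), case = gm(untreated, "case"))
  t_ <- c(control = gm(treated, "control"), case = gm(treated, "case"))
  if (any(u == 0)) stop("untreated group mean of 0; reduction undefined")
  red <- 100 * (u - t_) / u
  list(reduction_pct = red, treated_means = t_, untreated_means = u,
       untreated_ratio = unname(u["case"] / u["control"]),
       implied_untreated_ratio = implied_untreated_ratio(
         t_["case"], t_["control"], red["case"], red["control"]))
}

#' Untreated ratio implied by treated counts and percent reductions
#'
#' @param treated_case,treated_control post-treatment foci per cell.
#' @param reduction_case_pct,reduction_control_pct percent reductions
#'   caused by treatment in each group.
#' @return the implied untreated case:control ratio.
#' @export
implied_untreated_ratio <- function(treated_case, treated_control,
                                    reduction_case_pct,
                                    reduction_control_pct) {
  unname((treated_case / (1 - reduction_case_pct / 100)) /
           (treated_control / (1 - reduction_control_pct / 100)))
}
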