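# Sarkosyl-fractionation percent-insoluble quantification, co-IP with
# beads-alone background subtraction, and one-site gel-shift binding fits.

#' Percent insoluble protein from three-fraction densitometry
#'
#' `100 * insoluble / (soluble + sarkosyl_soluble + sarkosyl_insoluble)`.
#' Invariant to common rescaling of the three fractions, so differences in
#' total loading between samples cancel. Zero totals are unquantifiable
#' (`NA`).
#'
#' @param soluble,sarkosyl_soluble,sarkosyl_insoluble nonnegative
#'   densitometry intensities (vectorized).
#' @return percent insoluble in `[0, 100]`.
#' @export
percent_insoluble <- function(soluble, sarkosyl_soluble,
                              sarkosyl_insoluble) {
  if (any(c(soluble, sarkosyl_soluble, sarkosyl_insoluble) < 0,
          na.rm = TRUE)) {
    stop("fraction intensities must be nonnegative")
  }
  total <- soluble + sarkosyl_soluble + sarkosyl_insoluble
  ifelse(total > 0, 100 * sarkosyl_insoluble / total, NA_real_)
}

#' Group summary of percent-insoluble values
#'
#' Computes percent insoluble per replicate, averages replicates within
#' samples, then compares case and control sample means with an unpaired
#' t-test and reports the case:control ratio of group means.
#'
#' @param fractions a `data.frame` in the `fractions` schema of
#'   [read_table()] (`sample`, `group`, `replicate`, the three fraction
#'   intensities).
#' @param var_equal Student pooled-variance test (default) or Welch.
#' @return a list: `per_sample` (`data.frame` of sample means),
#'   `mean_control`, `mean_case`, `ratio`, `t_statistic`, `p_value`,
#'   `stars`.
#' @export
fraction_group_summary <- function(fractions, var_equal = TRUE) {
  fractions$pct_insoluble <- percent_insoluble(
    fractions$soluble, fractions$sarkosyl_soluble,
    fractions$sarkosyl_insoluble)
  ok <- !is.na(fractions$pct_insoluble)
  per_sample <- stats::aggregate(pct_insoluble ~ sample + group,
                                 data = fractions[ok, ], FUN = mean)
  cmp <- compare_groups(data.frame(group = per_sample$group,
                                   v = per_sample$pct_insoluble),
                        value_col = "v", var_equal = var_equal)
  list(per_sample = per_sample, mean_control = cmp$mean_control,
       mean_case = cmp$mean_case,
       ratio = cmp$mean_case / cmp$mean_control,
       t_statistic = cmp$t_statistic, p_value = cmp$p_value,
       stars = cmp$stars)
}

#' Co-IP quantification with beads-alone background subtraction
#'
#' Subtracts each sample's no-antibody (beads-alone) signal from its
#' antibody signal, flooring at zero (negative differences are noise and
#' are logged); without a background table the raw signals are used.
#' Replicates are averaged per sample and the case:control ratio of group
#' means reported.
#'
#' @param ip a `data.frame` with `sample`, `group`, `replicate`, `signal`.
#' @param beads_only optional `data.frame` with `sample`, `replicate`,
#'   `signal`, matched on sample and replicate.
#' @return a list: `per_sample` (`data.frame` with `sample`, `group`,
#'   `value`), `mean_control`, `mean_case`, `ratio`, `p_value`.
#' @export
coip_quant <- function(ip, beads_only = NULL) {
  value <- ip$signal
  if (!is.null(beads_only)) {
    key <- function(d) paste(d$sample, d$replicate, sep = "\r")
    bg <- beads_only$signal[match(key(ip), key(beads_only))]
    if (anyNA(bg)) stop("beads-only background missing for some samples")
    value <- ip$signal - bg
    n_neg <- sum(value < 0)
    if (n_neg > 0L) {
      message(n_neg, " background-subtracted value(s) below 0 floored")
      value <- pmax(value, 0)
    }
  }
  d <- data.frame(sample = ip$sample, group = ip$group, value = value)
  per_sample <- stats::aggregate(value ~ sample + group, data = d,
                                 FUN = mean)
  cmp <- compare_groups(data.frame(group = per_sample$group,
                                   v = per_sample$value),
                        value_col = "v")
  list(per_sample = per_sample, mean_control = cmp$mean_control,
       mean_case = cmp$mean_case,
       ratio = cmp$mean_case / cmp$mean_control, p_value = cmp$p_value)
}

#' Fit a one-site binding curve to gel-shift data
#'
#' Nonlinear least squares for the one-site specific-binding model
#' `f(P) = Bmax * P / (Kd + P)`, valid when the probe concentration is far
#' below Kd (0.3 nM probe here). `Bmax` is left free rather than fixed at 1
#' to absorb incomplete shifting; no cooperativity (Hill) term is fitted.
#' Initialization: `Kd0` = concentration nearest half the maximum observed
#' fraction bound, `Bmax0` = maximum observed; on failure a fixed grid of
#' rescaled starts is tried before the fit is flagged unconverged.
#'
#' @param protein_conc_nM protein concentrations (nM); at least four
#'   distinct values including 0.
#' @param fraction_bound observed fraction bound in `[0, 1]`. Compute as
#'   `bound / (bound + free)`; when supershifted multimeric complexes are
#'   quantified separately, sum them into `bound` first.
#' @return an object of class `binding_fit`: `kd_nM`, `bmax`, `kd_se`,
#'   `bmax_se`, `rss`, `converged`, `n`.
#' @export
fit_binding_curve <- function(protein_conc_nM, fraction_bound) {
  if (length(protein_conc_nM) != length(fraction_bound)) {
    stop("concentration and fraction-bound vectors must match")
  }
  if (length(unique(protein_conc_nM)) < 4L || !any(protein_conc_nM == 0)) {
    stop("need >= 4 distinct concentrations including 0")
  }
  if (any(fraction_bound < 0 | fraction_bound > 1)) {
    stop("fraction_bound must lie in [0, 1]")
  }
  d <- data.frame(P = protein_conc_nM, f = fraction_bound)
  bmax0 <- max(d$f)
  half <- bmax0 / 2
  conc_means <- tapply(d$f, d$P, mean)
  concs <- as.numeric(names(conc_means))
  pos <- concs > 0
  kd0 <- concs[pos][which.min(abs(conc_means[pos] - half))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(concs[pos])
  starts <- rbind(c(kd0, bmax0),
                  c(kd0 * 0.5, bmax0), c(kd0 * 2, bmax0),
                  c(kd0 * 0.2, min(1, bmax0 * 1.2)),
                  c(kd0 * 5, min(1, bmax0 * 1.2)),
                  c(stats::median(concs[pos]), 0.9))
  fit <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nls(f ~ bmax * P / (kd + P), data = d,
                 start = list(kd = starts[i, 1L], bmax = starts[i, 2L]),
                 control = stats::nls.control(maxiter = 200,
                                              scaleOffset = 1,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(kd_nM = NA_real_, bmax = NA_real_,
                          kd_se = NA_real_, bmax_se = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          n = nrow(d)),
                     class = "binding_fit"))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(kd = NA_real_, bmax = NA_real_))
  structure(list(kd_nM = unname(est["kd"]), bmax = unname(est["bmax"]),
                 kd_se = unname(se["kd"]), bmax_se = unname(se["bmax"]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 n = nrow(d)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<binding_fit: Kd = %.1f +/- %.1f nM, Bmax = %.3f (n=%d)>\n",
                x$kd_nM, x$kd_se, x$bmax, x$n))
  } else {
    cat("<binding_fit: not converged>\n")
  }
  invisible(x)
}
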