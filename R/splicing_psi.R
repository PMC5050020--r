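# Percent-exon-inclusion (PSI/PEI) quantification from RT-PCR band pairs,
# per-exon group comparisons, and the per-gene severity regression of each
# gene's inclusion against the per-patient mean inclusion.

#' Percent exon inclusion from a band pair
#'
#' `psi = 100 * incl / (incl + excl)`, the proportion of exon-inclusion
#' product in a lane. Invariant to rescaling both bands by a common lane
#' factor. Lanes with both intensities zero are unquantifiable and return
#' `NA`. With radiolabelled dCTP the signal scales with the number of
#' labelled nucleotides per product, so an optional correction divides each
#' intensity by its product's labelled-C count before the ratio; off by
#' default because densitometry proportions are conventionally reported
#' raw.
#'
#' @param incl,excl nonnegative band intensities (vectorized).
#' @param incl_nt,excl_nt labelled-nucleotide counts of the two products;
#'   both must be given to enable the correction.
#' @return percent inclusion in `[0, 100]`.
#' @export
compute_psi <- function(incl, excl, incl_nt = NULL, excl_nt = NULL) {
  if (any(incl < 0, na.rm = TRUE) || any(excl < 0, na.rm = TRUE)) {
    stop("band intensities must be nonnegative")
  }
  if (!is.null(incl_nt) && !is.null(excl_nt)) {
    incl <- incl / incl_nt
    excl <- excl / excl_nt
  }
  total <- incl + excl
  out <- ifelse(total > 0, 100 * incl / total, NA_real_)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " lane(s) with zero total intensity excluded")
  }
  out
}

#' Per-patient mean PSI from a bands table
#'
#' Computes PSI per lane and averages replicates within each
#' sample-by-gene cell (typically 3-4 independent repeats per patient).
#' Rows flagged in an optional logical/0-1 `exclude` column (artifact
#' lanes) are dropped first.
#'
#' @param bands a `data.frame` in the `bands` schema of [read_table()]:
#'   `sample`, `group`, `gene`, `replicate`, `incl_intensity`,
#'   `excl_intensity`, optionally `exclude`.
#' @return a `data.frame` with `sample`, `group`, `gene`, `psi` (the
#'   replicate mean), `n_replicates`.
#' @export
psi_patient_means <- function(bands) {
  if ("exclude" %in% names(bands)) {
    bands <- bands[!(as.logical(bands$exclude) %in% TRUE), , drop = FALSE]
  }
  bands$psi <- compute_psi(bands$incl_intensity, bands$excl_intensity)
  bands <- bands[!is.na(bands$psi), , drop = FALSE]
  agg <- stats::aggregate(psi ~ sample + group + gene, data = bands,
                          FUN = mean)
  n <- stats::aggregate(psi ~ sample + group + gene, data = bands,
                        FUN = length)
  agg$n_replicates <- n$psi
  agg[order(agg$gene, agg$group, agg$sample), ]
}

#' Per-exon group comparison of patient mean PSI
#'
#' For each gene/exon, an unpaired t-test of per-patient mean PSI between
#' case and control groups, significance at p < 0.05. Exons detectable as
#' only one isoform (PSI pinned at 0 or 100 for every sample) are excluded,
#' as are exons with fewer than two patients in either group.
#'
#' @param psi_means output of [psi_patient_means()].
#' @param var_equal Student pooled-variance test (default) or Welch.
#' @return a `data.frame` per gene: group means, `delta_psi`
#'   (case - control), `t_statistic`, `p_value`, `significant`, `stars`.
#' @export
compare_exons <- function(psi_means, var_equal = TRUE) {
  out <- lapply(split(psi_means, psi_means$gene), function(d) {
    x <- d$psi[d$group == "case"]
    y <- d$psi[d$group == "control"]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    if (all(c(x, y) == 0) || all(c(x, y) == 100)) return(NULL) # single isoform
    cmp <- compare_groups(data.frame(group = d$group, v = d$psi),
                          value_col = "v", var_equal = var_equal)
    data.frame(gene = d$gene[1L], n_case = length(x), n_control = length(y),
               mean_case = mean(x), mean_control = mean(y),
               delta_psi = mean(x) - mean(y),
               t_statistic = cmp$t_statistic, p_value = cmp$p_value,
               significant = !is.na(cmp$p_value) & cmp$p_value < 0.05,
               stars = cmp$stars)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene severity regression against patient mean inclusion
#'
#' Orders case patients by their mean PSI over a significant gene set (low
#' mean inclusion = strongest splicing disruption = most severe), then
#' regresses each gene's PSI on that per-patient mean by ordinary least
#' squares. Genes tracking the overall disruption have positive slopes;
#' genes regulated in the opposite direction have negative slopes. When
#' every gene is complete, the equal-weight average of slopes is exactly 1
#' (each patient's x is the mean of the same genes).
#'
#' @param psi_means output of [psi_patient_means()]; only `group == "case"`
#'   rows are used.
#' @param genes gene set defining the severity axis; defaults to all genes
#'   present. Genes missing a value for any patient are dropped with a
#'   warning.
#' @return a list: `regressions` (`data.frame` with `gene`, `slope`,
#'   `intercept`, `r_squared`, `slope_sign`), `patients` (`data.frame`
#'   with `sample`, `mean_psi`, ascending), `genes_used`.
#' @export
severity_regression <- function(psi_means, genes = NULL) {
  d <- psi_means[psi_means$group == "case", , drop = FALSE]
  if (is.null(genes)) genes <- unique(d$gene)
  d <- d[d$gene %in% genes, , drop = FALSE]
  patients <- unique(d$sample)
  if (length(patients) < 3L) stop("severity regression needs >= 3 patients")
  wide <- stats::reshape(d[c("sample", "gene", "psi")], idvar = "sample",
                         timevar = "gene", direction = "wide")
  rownames(wide) <- wide$sample
  mat <- as.matrix(wide[, -1L, drop = FALSE])
  colnames(mat) <- sub("^psi\\.", "", colnames(mat))
  incomplete <- colnames(mat)[colSums(is.na(mat)) > 0L]
  if (length(incomplete) > 0L) {
    warning("dropping gene(s) with missing patient values: ",
            paste(incomplete, collapse = ", "))
    mat <- mat[, setdiff(colnames(mat), incomplete), drop = FALSE]
  }
  if (ncol(mat) == 0L) stop("no complete genes for severity regression")
  x <- rowMeans(mat)
  regs <- do.call(rbind, lapply(colnames(mat), function(g) {
    fit <- stats::lm(mat[, g] ~ x)
    data.frame(gene = g, slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]),
               r_squared = summary(fit)$r.squared,
               slope_sign = sign(unname(coef(fit)[2L])))
  }))
  ord <- order(x)
  list(regressions = regs,
       patients = data.frame(sample = rownames(mat)[ord],
                             mean_psi = unname(x[ord])),
       genes_used = colnames(mat))
}

#' Rank correlation of splicing severity with disease duration
#'
#' Spearman correlation (mid-ranks for ties) of per-patient mean PSI with
#' disease duration in months; patients without a duration are excluded.
#' A positive rho means shorter duration goes with lower inclusion, i.e.
#' greater splicing disruption in faster-progressing disease.
#'
#' @param patients `data.frame` with `sample`, `mean_psi` (e.g. from
#'   [severity_regression()]).
#' @param metadata `data.frame` with `sample`, `disease_duration_months`.
#' @return a list: `rho`, `p_value`, `n`.
#' @export
duration_correlation <- function(patients, metadata) {
  m <- merge(patients, metadata[c("sample", "disease_duration_months")],
             by = "sample")
  m <- m[!is.na(m$disease_duration_months), , drop = FALSE]
  if (nrow(m) < 3L) stop("duration correlation needs >= 3 patients")
  ct <- suppressWarnings(
    stats::cor.test(m$mean_psi, m$disease_duration_months,
                    method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
}
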