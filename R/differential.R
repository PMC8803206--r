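#' One-way ANOVA p-value for promoter activity
#'
#' Classic equal-variance one-way ANOVA (F test) across condition groups,
#' used for both absolute and relative promoter activity. With exactly two
#' groups the F statistic equals the square of the pooled two-sample t
#' statistic, so the p-value coincides with the two-sided equal-variance
#' t-test. NA values are dropped; any group left with fewer than two finite
#' values yields `NA`.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (same length as `values`).
#' @return the ANOVA p-value, or `NA`.
#' @export
promoter_anova <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  v <- values[ok]
  g <- factor(groups[ok])
  if (nlevels(g) < 2L || any(table(g) < 2L)) return(NA_real_)
  if (stats::var(v) == 0) return(1)  # no variance at all: F = 0
  p <- stats::oneway.test(v ~ g, var.equal = TRUE)$p.value
  if (is.nan(p)) NA_real_ else p
}

#' Per-gene differential expression between tumor and normal
#'
#' Counts are normalised with median-of-ratios size factors. The fold
#' change is `log2((mean normalized tumor + 1) / (mean normalized normal +
#' 1))`; the p-value comes from a two-sided paired t-test on
#' `log2(normalized + 1)` values, pairing tumor and normal samples by
#' `pair_id`. A gene is flagged as differentially expressed (DEG) when
#' `p < p_cut` and `|log2FC| > lfc_cut`.
#'
#' @param counts gene x sample count matrix (also used for transcript-level
#'   expression matrices; values need not be integers).
#' @param design design table with `sample_id`, `condition`, `pair_id`.
#' @param p_cut,lfc_cut DEG thresholds (defaults 0.05 and 1).
#' @param eps pseudocount in the fold-change ratio.
#' @return data frame `gene_id`, `log2_fc`, `p_value`, `is_deg`.
#' @export
gene_differential <- function(counts, design, p_cut = 0.05, lfc_cut = 1,
                              eps = 1) {
  counts <- as.matrix(counts)
  design <- as_design(design, require_pairs = TRUE)
  check_design_samples(design, colnames(counts))
  pr <- paired_samples(design)
  if (length(pr$tumor) < 2L) {
    warning("fewer than 2 tumor/normal pairs; p-values are NA", call. = FALSE)
  }
  sf <- tryCatch(estimate_size_factors(counts[, design$sample_id, drop = FALSE]),
                 warning = function(w) {
                   suppressWarnings(
                     estimate_size_factors(counts[, design$sample_id, drop = FALSE]))
                 })
  norm <- sweep(counts[, design$sample_id, drop = FALSE], 2L, sf, "/")
  colnames(norm) <- design$sample_id
  ln <- log2(norm + 1)

  mt <- rowMeans(norm[, pr$tumor, drop = FALSE])
  mn <- rowMeans(norm[, pr$normal, drop = FALSE])
  lfc <- log2((mt + eps) / (mn + eps))

  diffs <- ln[, pr$tumor, drop = FALSE] - ln[, pr$normal, drop = FALSE]
  all_zero <- rowSums(counts[, design$sample_id, drop = FALSE]) == 0
  pvals <- apply(diffs, 1L, function(d) {
    d <- d[is.finite(d)]
    if (length(d) < 2L) return(NA_real_)
    s <- stats::sd(d)
    if (s == 0) return(if (all(d == 0)) 1 else NA_real_)
    stats::t.test(d)$p.value
  })
  pvals[all_zero] <- NA_real_
  data.frame(
    gene_id = rownames(counts),
    log2_fc = unname(lfc),
    p_value = unname(pvals),
    is_deg = !is.na(pvals) & pvals < p_cut & abs(lfc) > lfc_cut,
    stringsAsFactors = FALSE
  )
}

#' Promoter activity fold change between group means
#'
#' `log2((mean_tumor + eps) / (mean_normal + eps))`, with means taken on
#' the absolute (log2) activity scale and a small pseudo-activity guarding
#' against zero means.
#'
#' @param absolute promoters x samples absolute activity matrix.
#' @param design design table.
#' @param eps pseudo-activity (default 0.001).
#' @return data frame `promoter_id`, `mean_abs_tumor`, `mean_abs_normal`,
#'   `log2_fc_abs`.
#' @export
promoter_fold_change <- function(absolute, design, eps = 0.001) {
  design <- as_design(design)
  check_design_samples(design, colnames(absolute))
  tum <- design$sample_id[design$condition == "tumor"]
  nor <- design$sample_id[design$condition == "normal"]
  mt <- rowMeans(absolute[, tum, drop = FALSE], na.rm = TRUE)
  mn <- rowMeans(absolute[, nor, drop = FALSE], na.rm = TRUE)
  data.frame(
    promoter_id = rownames(absolute),
    mean_abs_tumor = unname(mt),
    mean_abs_normal = unname(mn),
    log2_fc_abs = unname(log2((mt + eps) / (mn + eps))),
    stringsAsFactors = FALSE
  )
}

#' Per-promoter differential activity statistics
#'
#' Computes, for every promoter, the fold change of mean absolute activity
#' plus one-way ANOVA p-values on absolute (`p_abs`) and relative
#' (`p_rel`) activity between tumor and normal samples, then flags DRPs
#' via [call_drps()].
#'
#' @param activity an `activity_matrix` with absolute and relative slots.
#' @param design design table.
#' @param p_cut,fc_cut DRP thresholds (defaults 0.05 and linear 1.2).
#' @param eps pseudo-activity for the fold change.
#' @return data frame with one row per promoter: `promoter_id`, `gene_id`,
#'   `mean_abs_tumor`, `mean_abs_normal`, `log2_fc_abs`, `p_abs`, `p_rel`,
#'   `is_drp`, `direction`.
#' @export
promoter_differential <- function(activity, design, p_cut = 0.05,
                                  fc_cut = 1.2, eps = 0.001) {
  stopifnot(inherits(activity, "activity_matrix"))
  design <- as_design(design)
  check_design_samples(design, colnames(activity$absolute))
  cond <- design$condition[match(colnames(activity$absolute),
                                 design$sample_id)]
  fc <- promoter_fold_change(activity$absolute, design, eps = eps)
  p_abs <- apply(activity$absolute, 1L, promoter_anova, groups = cond)
  p_rel <- apply(activity$relative, 1L, promoter_anova, groups = cond)
  tab <- data.frame(
    fc,
    gene_id = activity$promoters$gene_id[
      match(fc$promoter_id, activity$promoters$promoter_id)],
    p_abs = unname(p_abs),
    p_rel = unname(p_rel),
    stringsAsFactors = FALSE
  )
  call_drps(tab, p_cut = p_cut, fc_cut = fc_cut)
}

#' Flag differentially regulated promoters (DRPs)
#'
#' A promoter is a DRP when its absolute-activity ANOVA p-value is below
#' `p_cut` and the linear fold change of its mean absolute activity
#' exceeds `fc_cut` (i.e. `|log2_fc_abs| > log2(fc_cut)`). The direction
#' is the sign of the fold change for DRPs, `"none"` otherwise.
#'
#' @param promoter_stats data frame with `log2_fc_abs` and `p_abs`
#'   (typically from [promoter_differential()]).
#' @param p_cut,fc_cut thresholds; `fc_cut` is a linear ratio.
#' @return the input with `is_drp` and `direction` columns; the numbers of
#'   DRPs and of genes carrying at least one DRP (DRPGs, requires a
#'   `gene_id` column) are attached as attributes `n_drp` / `n_drpg`.
#' @export
call_drps <- function(promoter_stats, p_cut = 0.05, fc_cut = 1.2) {
  stopifnot(all(c("log2_fc_abs", "p_abs") %in% names(promoter_stats)))
  lfc_cut <- log2(fc_cut)
  is_drp <- !is.na(promoter_stats$p_abs) & promoter_stats$p_abs < p_cut &
    abs(promoter_stats$log2_fc_abs) > lfc_cut
  direction <- ifelse(is_drp,
                      ifelse(promoter_stats$log2_fc_abs > 0, "up", "down"),
                      "none")
  promoter_stats$is_drp <- is_drp
  promoter_stats$direction <- direction
  attr(promoter_stats, "n_drp") <- sum(is_drp)
  if ("gene_id" %in% names(promoter_stats)) {
    attr(promoter_stats, "n_drpg") <-
      length(unique(promoter_stats$gene_id[is_drp]))
  }
  promoter_stats
}
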