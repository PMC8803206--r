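#' Identify alternative promoters (APs)
#'
#' An alternative promoter is a promoter whose activity shifts between
#' tumor and normal although its gene's overall expression does not. Four
#' criteria must hold simultaneously:
#' \enumerate{
#'   \item gene expression not differential: gene `p >= gene_p` and linear
#'     gene `|FC| < gene_fc`;
#'   \item minimum activity: mean absolute activity `> activity_min` in
#'     both the tumor and the normal group;
#'   \item both absolute and relative activity significantly changed:
#'     `p_abs < p_cut` and `p_rel < p_cut`;
#'   \item activity fold change: linear `|FC| > fc_cut` of mean absolute
#'     activity.
#' }
#' Promoters of genes with an undefined gene p-value are ineligible and
#' recorded in the attrition log.
#'
#' @param gene_diff output of [gene_differential()].
#' @param promoter_diff output of [promoter_differential()] (must carry
#'   `gene_id`).
#' @param gene_p,gene_fc,activity_min,p_cut,fc_cut thresholds; the two fold
#'   changes are linear ratios (defaults 0.05, 2, 0.25, 0.05, 1.2).
#' @return the promoter table with per-criterion pass flags
#'   (`pass_gene_expr`, `pass_min_activity`, `pass_significance`,
#'   `pass_fc`), `is_ap` and `direction`; a per-criterion attrition summary
#'   is attached as attribute `attrition`.
#' @export
identify_aps <- function(gene_diff, promoter_diff, gene_p = 0.05,
                         gene_fc = 2, activity_min = 0.25, p_cut = 0.05,
                         fc_cut = 1.2) {
  stopifnot(all(c("gene_id", "log2_fc_abs", "p_abs", "p_rel",
                  "mean_abs_tumor", "mean_abs_normal") %in%
                  names(promoter_diff)))
  gi <- match(promoter_diff$gene_id, gene_diff$gene_id)
  gp <- gene_diff$p_value[gi]
  gfc <- gene_diff$log2_fc[gi]
  eligible <- !is.na(gp)
  if (any(!eligible)) {
    message(sum(!eligible),
            " promoter(s) ineligible: gene p-value undefined")
  }
  tab <- promoter_diff
  tab$gene_p <- gp
  tab$gene_log2_fc <- gfc
  tab$pass_gene_expr <- eligible & gp >= gene_p & abs(gfc) < log2(gene_fc)
  tab$pass_min_activity <- tab$mean_abs_tumor > activity_min &
    tab$mean_abs_normal > activity_min
  tab$pass_significance <- !is.na(tab$p_abs) & !is.na(tab$p_rel) &
    tab$p_abs < p_cut & tab$p_rel < p_cut
  tab$pass_fc <- abs(tab$log2_fc_abs) > log2(fc_cut)
  tab$is_ap <- tab$pass_gene_expr & tab$pass_min_activity &
    tab$pass_significance & tab$pass_fc
  tab$is_ap[is.na(tab$is_ap)] <- FALSE
  tab$direction <- ifelse(tab$is_ap,
                          ifelse(tab$log2_fc_abs > 0, "up", "down"),
                          tab$direction %||% "none")
  attr(tab, "attrition") <- data.frame(
    criterion = c("gene_p_defined", "gene_not_differential", "min_activity",
                  "significance", "fold_change", "all"),
    n_pass = c(sum(eligible), sum(tab$pass_gene_expr, na.rm = TRUE),
               sum(tab$pass_min_activity, na.rm = TRUE),
               sum(tab$pass_significance, na.rm = TRUE),
               sum(tab$pass_fc, na.rm = TRUE), sum(tab$is_ap))
  )
  tab
}

#' Find switch-usage genes
#'
#' Genes concurrently carrying at least one upregulated and one
#' downregulated AP: when one promoter is suppressed another is activated,
#' the promoter-substitution pattern.
#'
#' @param ap_table output of [identify_aps()].
#' @return sorted character vector of gene ids.
#' @export
find_switch_genes <- function(ap_table) {
  aps <- ap_table[ap_table$is_ap, ]
  up <- unique(aps$gene_id[aps$direction == "up"])
  down <- unique(aps$gene_id[aps$direction == "down"])
  sort(intersect(up, down))
}

#' Classify APs by their association with transcript isoforms
#'
#' Relates each AP's activity change to the differential expression of the
#' transcript isoforms it drives. Single-isoform APs are classed
#' `single_significant` when the isoform changes significantly
#' (`p < p_cut`), else `single_fc_only` when its linear `|FC| > fc_cut`,
#' else `single_neutral`. Multi-isoform APs are classed
#' `multi_major_significant` when the most significant isoform (minimum p;
#' ties broken by larger `|FC|`, then lexicographic transcript id) has
#' `p < p_cut`, else `multi_major_fc` when the largest-`|FC|` isoform
#' exceeds `fc_cut`, else `multi_other`.
#'
#' @param ap_table output of [identify_aps()].
#' @param members promoter-to-transcript membership (`catalog$members`).
#' @param isoform_diff per-transcript differential table with `gene_id`
#'   (here the transcript id), `log2_fc`, `p_value` — typically
#'   [gene_differential()] run on a transcript expression matrix.
#' @param p_cut,fc_cut thresholds (defaults 0.05 and linear 1.2).
#' @return data frame `promoter_id`, `n_isoforms`, `isoform_class` for the
#'   APs in `ap_table` (class NA, with a warning, where isoform expression
#'   is missing).
#' @export
classify_isoform_association <- function(ap_table, members, isoform_diff,
                                         p_cut = 0.05, fc_cut = 1.2) {
  aps <- ap_table[ap_table$is_ap, ]
  lfc_cut <- log2(fc_cut)
  res <- lapply(aps$promoter_id, function(pid) {
    tx <- members$transcript_id[members$promoter_id == pid]
    st <- isoform_diff[match(tx, isoform_diff$gene_id), ]
    n <- length(tx)
    if (!n || anyNA(st$gene_id)) {
      warning("missing isoform expression for promoter ", pid, call. = FALSE)
      return(data.frame(promoter_id = pid, n_isoforms = n,
                        isoform_class = NA_character_))
    }
    if (n == 1L) {
      cls <- if (!is.na(st$p_value) && st$p_value < p_cut) {
        "single_significant"
      } else if (abs(st$log2_fc) > lfc_cut) {
        "single_fc_only"
      } else "single_neutral"
    } else {
      ord <- order(st$p_value, -abs(st$log2_fc), st$gene_id)
      top <- st[ord[1L], ]
      cls <- if (!is.na(top$p_value) && top$p_value < p_cut) {
        "multi_major_significant"
      } else if (max(abs(st$log2_fc), na.rm = TRUE) > lfc_cut) {
        "multi_major_fc"
      } else "multi_other"
    }
    data.frame(promoter_id = pid, n_isoforms = n, isoform_class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
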