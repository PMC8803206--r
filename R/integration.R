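#' Classify promoter-methylation correlations
#'
#' Each promoter's representative CpG link is classed `negative` when the
#' correlation is significant (`p < p_cut`) with `r < 0`, `positive` when
#' significant with `r > 0`, and `none` otherwise (including undefined
#' correlations).
#'
#' @param links output of [select_representative_cpg()].
#' @param p_cut significance threshold (default 0.05).
#' @return `links` with a `corr_class` column.
#' @export
classify_correlation <- function(links, p_cut = 0.05) {
  cls <- rep("none", nrow(links))
  sig <- !is.na(links$p) & links$p < p_cut & !is.na(links$r)
  cls[sig & links$r < 0] <- "negative"
  cls[sig & links$r > 0] <- "positive"
  links$corr_class <- cls
  links
}

#' Call methylation-regulated APs (mrAPs)
#'
#' mrAPs are the APs whose activity is significantly negatively correlated
#' with their representative CpG's methylation.
#'
#' @param ap_table output of [identify_aps()].
#' @param links classified links (from [classify_correlation()]).
#' @return character vector of mrAP promoter ids.
#' @export
call_mraps <- function(ap_table, links) {
  if (!"corr_class" %in% names(links)) links <- classify_correlation(links)
  neg <- links$promoter_id[links$corr_class == "negative"]
  sort(intersect(ap_table$promoter_id[ap_table$is_ap], neg))
}

#' Assemble the promoter-methylation integration table
#'
#' One row per promoter carrying the differential statistics, set
#' memberships (DRP / AP / mrAP), the representative CpG's delta beta and
#' correlation class, and the significant-methylation-change flag
#' (`|delta beta| > delta_cut`).
#'
#' @param ap_table output of [identify_aps()] (carries the DRP flags).
#' @param links classified links.
#' @param dbeta per-probe methylation differences from [delta_beta()].
#' @param delta_cut methylation-change threshold (default 0.1; the
#'   stricter mode uses 0.2).
#' @return data frame with `promoter_id`, `gene_id`, `norm_fc` (log2
#'   activity fold change), `is_drp`, `is_ap`, `is_mrap`, `probe_id`,
#'   `delta_meth`, `passes_meth_change`, `corr_class`.
#' @export
build_integration_table <- function(ap_table, links, dbeta,
                                    delta_cut = 0.1) {
  if (!"corr_class" %in% names(links)) links <- classify_correlation(links)
  mraps <- call_mraps(ap_table, links)
  li <- match(ap_table$promoter_id, links$promoter_id)
  probe <- links$probe_id[li]
  dm <- dbeta$delta_beta[match(probe, dbeta$probe_id)]
  data.frame(
    promoter_id = ap_table$promoter_id,
    gene_id = ap_table$gene_id,
    norm_fc = ap_table$log2_fc_abs,
    is_drp = ap_table$is_drp,
    is_ap = ap_table$is_ap,
    is_mrap = ap_table$promoter_id %in% mraps,
    probe_id = probe,
    delta_meth = dm,
    passes_meth_change = !is.na(dm) & abs(dm) > delta_cut,
    corr_class = ifelse(is.na(li), NA_character_, links$corr_class[li]),
    stringsAsFactors = FALSE
  )
}

#' Group-level correlation of methylation change and activity change
#'
#' Pearson correlation between the representative CpG delta beta and the
#' promoter activity fold change, restricted to one promoter set (DRP, AP
#' or mrAP) and to promoters with a significant methylation change
#' (`|delta beta| > delta_cut`). NA with fewer than 3 qualifying
#' promoters.
#'
#' @param integration output of [build_integration_table()].
#' @param set one of `"DRP"`, `"AP"`, `"mrAP"`.
#' @param delta_cut methylation-change filter (default 0.1).
#' @return list `r`, `p`, `n` (number of qualifying promoters).
#' @export
group_correlation_test <- function(integration, set = c("DRP", "AP", "mrAP"),
                                   delta_cut = 0.1) {
  set <- match.arg(set)
  memb <- switch(set, DRP = integration$is_drp, AP = integration$is_ap,
                 mrAP = integration$is_mrap)
  keep <- memb & !is.na(integration$delta_meth) &
    abs(integration$delta_meth) > delta_cut & is.finite(integration$norm_fc)
  if (sum(keep) < 3L) return(list(r = NA_real_, p = NA_real_, n = sum(keep)))
  pearson_test(integration$delta_meth[keep], integration$norm_fc[keep])
}

#' Confirm promoter activity changes in a validation cohort
#'
#' A reference fold change is confirmed when, in at least one
#' tumor/normal pair of the validation cohort, the promoter's
#' linear-scale activity ratio exceeds `fc_cut` in the same direction.
#' Linear activity is `2^absolute - 1` (the normalised count scale);
#' `eps` guards ratios against zero activity. Promoters absent from the
#' validation matrix are `untestable`.
#'
#' @param reference data frame with `promoter_id` and `log2_fc_abs` (the
#'   discovery-cohort fold changes).
#' @param validation_absolute promoters x samples absolute activity matrix
#'   of the validation cohort.
#' @param design validation design table with complete pairs.
#' @param fc_cut linear ratio threshold (default 1.2).
#' @param eps pseudo-activity on the linear scale (default 0.001).
#' @return data frame `promoter_id`, `status` in
#'   `confirmed`/`not_confirmed`/`untestable`, `n_pairs_confirming`.
#' @export
confirm_activity_change <- function(reference, validation_absolute, design,
                                    fc_cut = 1.2, eps = 0.001) {
  pr <- paired_samples(design)
  check_design_samples(as_design(design), colnames(validation_absolute))
  res <- lapply(seq_len(nrow(reference)), function(i) {
    pid <- reference$promoter_id[i]
    if (!pid %in% rownames(validation_absolute)) {
      return(data.frame(promoter_id = pid, status = "untestable",
                        n_pairs_confirming = NA_integer_))
    }
    lin <- 2^validation_absolute[pid, ] - 1
    ratio <- (lin[pr$tumor] + eps) / (lin[pr$normal] + eps)
    up <- reference$log2_fc_abs[i] > 0
    hits <- if (up) ratio > fc_cut else ratio < 1 / fc_cut
    data.frame(promoter_id = pid,
               status = if (any(hits, na.rm = TRUE)) "confirmed"
                        else "not_confirmed",
               n_pairs_confirming = sum(hits, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Confirm methylation changes in a validation WGBS cohort
#'
#' Each reference link (a representative CpG with its 450K delta beta) is
#' checked in validation WGBS data: the same genomic position is looked
#' up, and when it lacks data the +/- `window` bp promoter-region mean
#' (CpGs covered in all samples) is used as fallback. The change is
#' `confirmed` when the validation delta (mean tumor - mean normal)
#' exceeds `delta_cut` in magnitude with the same sign as the reference;
#' `untestable` when neither the site nor the region yields a value.
#'
#' @param links reference links with `promoter_id`, `probe_id`, `chrom`,
#'   `pos` and a `delta_beta` column (join [delta_beta()] output onto the
#'   links first). Only rows with `|delta_beta| > delta_cut` are sensible
#'   inputs; others are confirmed/not purely by the validation side.
#' @param validation_meth a `methylation_matrix` (WGBS) for the validation
#'   samples.
#' @param catalog a `promoter_annotation` locating the promoters (for the
#'   regional fallback).
#' @param design validation design table.
#' @param delta_cut methylation-change threshold (default 0.1).
#' @param window regional fallback half-width (default 1000).
#' @return data frame `promoter_id`, `probe_id`, `method`
#'   (`site`/`region`/`none`), `validation_delta`, `status`.
#' @export
confirm_methylation_change <- function(links, validation_meth, catalog,
                                       design, delta_cut = 0.1,
                                       window = 1000) {
  stopifnot("delta_beta" %in% names(links))
  design <- as_design(design)
  check_design_samples(design, colnames(validation_meth$beta))
  tum <- design$sample_id[design$condition == "tumor"]
  nor <- design$sample_id[design$condition == "normal"]
  vdb <- delta_beta(validation_meth, design)
  vkey <- paste0(validation_meth$probes$chrom, ":", validation_meth$probes$pos)

  region <- promoter_region_mean(validation_meth, catalog,
                                 promoter_ids = unique(links$promoter_id),
                                 window = window,
                                 require_full_coverage = TRUE)
  res <- lapply(seq_len(nrow(links)), function(i) {
    key <- paste0(links$chrom[i], ":", links$pos[i])
    vi <- match(key, vkey)
    delta <- if (!is.na(vi)) vdb$delta_beta[vi] else NA_real_
    method <- if (!is.na(delta)) "site" else "none"
    if (is.na(delta) && links$promoter_id[i] %in% rownames(region)) {
      rm_ <- region[links$promoter_id[i], ]
      dt <- mean(rm_[tum], na.rm = TRUE) - mean(rm_[nor], na.rm = TRUE)
      if (is.finite(dt)) {
        delta <- dt
        method <- "region"
      }
    }
    status <- if (is.na(delta)) {
      "untestable"
    } else if (abs(delta) > delta_cut &&
               sign(delta) == sign(links$delta_beta[i])) {
      "confirmed"
    } else "not_confirmed"
    data.frame(promoter_id = links$promoter_id[i],
               probe_id = links$probe_id[i], method = method,
               validation_delta = delta, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
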