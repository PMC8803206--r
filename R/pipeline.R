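#' Default pipeline thresholds
#'
#' The cutoffs applied throughout the pipeline: gene differential
#' expression (p 0.05, linear FC 2), minimum promoter activity (0.25 on
#' the log2 scale), promoter significance (p 0.05) and fold change
#' (linear 1.2), methylation change (delta beta 0.1), correlation
#' significance (p 0.05), plus the clinical-model settings (10 CV folds,
#' minprop 0.1, 10-year horizon in days).
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(gene_p = 0.05, gene_fc = 2, activity_min = 0.25,
       promoter_p = 0.05, promoter_fc = 1.2,
       meth_delta = 0.1, corr_p = 0.05,
       folds = 10, seed = 1, minprop = 0.1, horizon = 3652.5)
}

#' Run the promoter-methylation analysis pipeline
#'
#' Executes the stages in dependency order on a directory of input files:
#' gene models -> promoter catalog -> activity -> differential ->
#' alternative promoters -> methylation links -> integration -> clinical
#' models. Each stage writes TSV/JSON artifacts into `out_dir` and the
#' run ends with a `summary.json` of headline counts. The clinical stage
#' is skipped with a warning when no clinical table is configured.
#'
#' @param config named list (or path to a YAML file) with paths
#'   `gtf`, `design` (TSV: `sample_id`, `path`, `condition`, `pair_id`),
#'   optional `gene_counts`, `beta_matrix` + `manifest`, `cohort_beta` +
#'   `clinical`; and optional `thresholds` overriding
#'   [default_thresholds()].
#' @param out_dir output directory.
#' @return invisibly, a list with every stage result and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  design <- stage("design", {
    d <- utils::read.delim(config$design, stringsAsFactors = FALSE)
    as_design(d, require_pairs = TRUE)
  })
  catalog <- stage("promoters", {
    models <- parse_gene_models(config$gtf)
    cat_ <- build_promoters(models)
    write_promoter_catalog(cat_, bed = file.path(out_dir, "promoters.bed"),
                           tsv = file.path(out_dir, "promoters.tsv"))
    cat_
  })
  activity <- stage("activity", {
    jx <- read_junction_tables(design)
    act <- promoter_activity(jx, catalog, design = design)
    write_matrix_tsv(act$absolute, file.path(out_dir, "activity_absolute.tsv"),
                     id_col = "promoter_id")
    write_matrix_tsv(act$relative, file.path(out_dir, "activity_relative.tsv"),
                     id_col = "promoter_id")
    write_tsv(act$removed, file.path(out_dir, "removed_promoters.tsv"))
    act
  })
  gene_diff <- stage("gene_diff", {
    counts <- if (!is.null(config$gene_counts)) {
      m <- utils::read.delim(config$gene_counts, row.names = 1,
                             check.names = FALSE)
      as.matrix(m)
    } else {
      # fall back to promoter-count totals per gene
      rowsum(activity$raw_counts, activity$promoters$gene_id)
    }
    gd <- gene_differential(counts, design, p_cut = thr$gene_p)
    write_tsv(gd, file.path(out_dir, "gene_differential.tsv"))
    gd
  })
  promoter_diff <- stage("promoter_diff", {
    pd <- promoter_differential(activity, design, p_cut = thr$promoter_p,
                                fc_cut = thr$promoter_fc)
    write_tsv(pd, file.path(out_dir, "promoter_differential.tsv"))
    pd
  })
  ap_table <- stage("aps", {
    ap <- identify_aps(gene_diff, promoter_diff, gene_p = thr$gene_p,
                       gene_fc = thr$gene_fc,
                       activity_min = thr$activity_min,
                       p_cut = thr$promoter_p, fc_cut = thr$promoter_fc)
    write_tsv(ap, file.path(out_dir, "ap_table.tsv"))
    write_tsv(data.frame(gene_id = find_switch_genes(ap)),
              file.path(out_dir, "switch_genes.tsv"))
    ap
  })

  links <- integration <- NULL
  mraps <- character(0)
  if (!is.null(config$beta_matrix)) {
    links <- stage("methylation", {
      meth <- read_beta_matrix(config$beta_matrix, config$manifest)
      l <- select_representative_cpg(catalog, meth, activity)
      l <- classify_correlation(l, p_cut = thr$corr_p)
      db <- delta_beta(meth, design)
      l$delta_beta <- db$delta_beta[match(l$probe_id, db$probe_id)]
      write_tsv(l, file.path(out_dir, "cpg_links.tsv"))
      l
    })
    integration <- stage("integrate", {
      db <- data.frame(probe_id = links$probe_id,
                       delta_beta = links$delta_beta)
      it <- build_integration_table(ap_table, links, db,
                                    delta_cut = thr$meth_delta)
      write_tsv(it, file.path(out_dir, "integration.tsv"))
      it
    })
    mraps <- call_mraps(ap_table, links)
  }

  diagnostic <- survival_tab <- NULL
  if (length(mraps) >= 2L) {
    diagnostic <- stage("diagnose", {
      dm <- fit_diagnostic(activity$absolute[mraps, , drop = FALSE], design,
                           nfolds = thr$folds, seed = thr$seed)
      scores <- score_samples(dm, activity$absolute)
      labels <- design$condition[match(names(scores), design$sample_id)]
      auc <- if (length(dm$selected_promoters)) roc_auc(scores, labels)
             else NA_real_
      jsonlite::write_json(
        list(selected_promoters = dm$selected_promoters,
             coefficients = as.list(dm$coefficients),
             intercept = dm$intercept, lambda = dm$lambda,
             cv_folds = dm$cv_folds, training_auc = auc),
        file.path(out_dir, "diagnostic_model.json"),
        auto_unbox = TRUE, digits = NA)
      write_tsv(data.frame(sample_id = names(scores), score = scores,
                           condition = labels),
                file.path(out_dir, "diagnostic_scores.tsv"))
      list(model = dm, scores = scores, auc = auc)
    })
  }
  if (!is.null(config$clinical) && !is.null(config$cohort_beta) &&
      length(mraps)) {
    survival_tab <- stage("survive", {
      clin <- utils::read.delim(config$clinical, stringsAsFactors = FALSE)
      cb <- as.matrix(utils::read.delim(config$cohort_beta, row.names = 1,
                                        check.names = FALSE))
      ml <- links[links$promoter_id %in% mraps, ]
      st <- flag_prognostic_mraps(ml, cb, clin, minprop = thr$minprop,
                                  horizon = thr$horizon)
      write_tsv(st, file.path(out_dir, "prognostic_mraps.tsv"))
      st
    })
  } else if (!is.null(config$beta_matrix)) {
    warning("clinical table or cohort betas missing; survival stage skipped",
            call. = FALSE)
  }

  summary <- list(
    n_promoters = nrow(catalog$promoters),
    n_promoters_active = nrow(activity$raw_counts),
    n_genes = length(unique(catalog$promoters$gene_id)),
    n_degs = sum(gene_diff$is_deg, na.rm = TRUE),
    n_drps = sum(promoter_diff$is_drp),
    n_drpgs = attr(promoter_diff, "n_drpg"),
    n_aps = sum(ap_table$is_ap),
    n_ap_genes = length(unique(ap_table$gene_id[ap_table$is_ap])),
    n_switch_genes = length(find_switch_genes(ap_table)),
    n_mraps = length(mraps),
    n_diagnostic_features =
      if (!is.null(diagnostic)) length(diagnostic$model$selected_promoters)
      else NA,
    n_prognostic_mraps =
      if (!is.null(survival_tab)) sum(survival_tab$is_prognostic,
                                      na.rm = TRUE) else NA
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(design = design, catalog = catalog, activity = activity,
                 gene_diff = gene_diff, promoter_diff = promoter_diff,
                 ap_table = ap_table, links = links,
                 integration = integration, mraps = mraps,
                 diagnostic = diagnostic, survival = survival_tab,
                 summary = summary))
}
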