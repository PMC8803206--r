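#' Construct a simulation design
#'
#' Bundles every parameter of the synthetic paired tumor/normal study:
#' annotation geometry, negative-binomial junction counts with planted
#' differentially expressed genes (DEGs), alternative promoters (APs) and
#' switch-usage genes, methylation betas with planted negative
#' activity-methylation coupling, and a survival cohort with
#' methylation-group-dependent hazard.
#'
#' Defaults emulate the discovery-cohort conditions the pipeline is aimed
#' at: 19 tumor/normal pairs, genes carrying 1-3 promoters (about 57%
#' multi-promoter), a 4-fold expression effect for DEGs and a 2-fold
#' promoter-share shift for AP genes with the gene total held constant.
#'
#' @param n_genes number of genes (default 200).
#' @param n_pairs tumor/normal pairs (default 19).
#' @param promoter_probs probabilities of 1, 2 and 3 promoters per gene.
#' @param baseline_mean mean total junction reads per gene and sample.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param library_sdlog log-normal sd of per-sample library factors.
#' @param deg_fc linear expression fold change of planted DEGs.
#' @param ap_fc promoter-share shift factor of planted APs.
#' @param fraction_deg,fraction_ap,fraction_switch gene-class fractions
#'   (AP and switch classes are disjoint; switch genes need 3 promoters).
#' @param fraction_mrap fraction of true-AP promoters with planted
#'   methylation coupling.
#' @param fraction_prognostic fraction of coupled AP promoters whose CpGs
#'   carry a survival signal.
#' @param meth_coupling_slope logit-scale slope of beta on absolute
#'   activity for coupled CpGs (negative = canonical repression).
#' @param meth_noise_sd logit-scale Gaussian noise sd of coupled CpGs.
#' @param cpgs_per_promoter CpGs placed within +/-1 kb of each TSS.
#' @param baseline_hazard daily baseline hazard of the survival cohort.
#' @param hazard_ratio hazard ratio of the high- vs low-methylation group.
#' @param censor_rate fraction of subjects censored before their event.
#' @param n_subjects survival-cohort size.
#' @param transcripts_per_promoter probabilities of 1 or 2 member
#'   transcripts.
#' @param seed master seed; generator stages derive their streams from it.
#' @return an object of class `simulation_design` (a validated list).
#' @export
simulation_design <- function(n_genes = 200, n_pairs = 19,
                              promoter_probs = c(0.43, 0.37, 0.20),
                              baseline_mean = 30, nb_dispersion = 0.1,
                              library_sdlog = 0.15,
                              deg_fc = 4, ap_fc = 2,
                              fraction_deg = 0.15, fraction_ap = 0.20,
                              fraction_switch = 0.05,
                              fraction_mrap = 0.6,
                              fraction_prognostic = 0.5,
                              meth_coupling_slope = -1.5,
                              meth_noise_sd = 0.2,
                              cpgs_per_promoter = 5,
                              baseline_hazard = 4e-4, hazard_ratio = 3,
                              censor_rate = 0.3, n_subjects = 200,
                              transcripts_per_promoter = c(0.6, 0.4),
                              seed = 1) {
  d <- as.list(environment())
  stopifnot(n_genes >= 1, n_pairs >= 1, length(promoter_probs) == 3,
            abs(sum(promoter_probs) - 1) < 1e-8, baseline_mean > 0,
            nb_dispersion >= 0, deg_fc > 1, ap_fc > 1,
            all(c(fraction_deg, fraction_ap, fraction_switch,
                  fraction_mrap, fraction_prognostic) >= 0),
            fraction_deg + fraction_ap + fraction_switch <= 1,
            censor_rate >= 0, censor_rate <= 1,
            cpgs_per_promoter >= 1, n_subjects >= 2)
  d$seed <- as.integer(seed)
  structure(d, class = "simulation_design")
}

# Per-gene locus geometry (all 0-based half-open). Promoter first exons
# are spaced 3 kb apart so they never co-cluster; second transcripts gain
# a promoter-specific middle exon; all transcripts share a terminal exon.
sim_gene_layout <- function(gbase, strand, np, n_tx, first_lens) {
  if (strand == "+") {
    first_start <- gbase + (seq_len(np) - 1L) * 3000L
    first_end <- first_start + first_lens
    mid_start <- gbase + 15000L + (seq_len(np) - 1L) * 800L
    mid_end <- mid_start + 150L
    last_start <- gbase + 25000L
    last_end <- last_start + 500L
    tss <- first_start
    donor <- first_end
  } else {
    first_start <- gbase + 12000L + (seq_len(np) - 1L) * 3000L
    first_end <- first_start + first_lens
    mid_start <- gbase + 5000L + (seq_len(np) - 1L) * 800L
    mid_end <- mid_start + 150L
    last_start <- gbase
    last_end <- last_start + 500L
    tss <- first_end - 1L
    donor <- first_start
  }
  list(first_start = first_start, first_end = first_end,
       mid_start = mid_start, mid_end = mid_end,
       last_start = last_start, last_end = last_end,
       tss = tss, donor = donor)
}

#' Simulate a toy gene-model annotation
#'
#' Generates a deterministic (seeded) GTF annotation: one chromosome per
#' 100 genes, 1-3 promoters per gene, 1-2 multi-exon transcripts per
#' promoter (so every promoter has junction evidence), plus the gene
#' class assignment (stable / deg / ap / switch) used by the count
#' simulator.
#'
#' @param design a `simulation_design`.
#' @return list with `gtf_lines` (character vector of GTF records),
#'   `promoters` (layout table: `gene_id`, `prom_idx`, `chrom`, `strand`,
#'   `tss`, `donor`, `n_tx`) and `genes` (`gene_id`, `class`,
#'   `n_promoters`, `direction`).
#' @export
simulate_annotation <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  n <- design$n_genes
  gene_id <- sprintf("G%04d", seq_len(n))
  chrom <- paste0("chr", (seq_len(n) - 1L) %/% 100L + 1L)
  gbase <- as.integer(((seq_len(n) - 1L) %% 100L) * 50000L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  np <- sample(1:3, n, replace = TRUE, prob = design$promoter_probs)

  # gene classes: switch genes need 3 promoters, AP genes >= 2
  class <- rep("stable", n)
  n_switch <- round(design$fraction_switch * n)
  n_ap <- round(design$fraction_ap * n)
  n_deg <- round(design$fraction_deg * n)
  cand3 <- which(np == 3L)
  sw <- cand3[sample.int(length(cand3), min(n_switch, length(cand3)))]
  class[sw] <- "switch"
  cand2 <- setdiff(which(np >= 2L), sw)
  ap <- cand2[sample.int(length(cand2), min(n_ap, length(cand2)))]
  class[ap] <- "ap"
  rest <- which(class == "stable")
  dg <- rest[sample.int(length(rest), min(n_deg, length(rest)))]
  class[dg] <- "deg"
  if (length(sw) < n_switch || length(ap) < n_ap) {
    warning("fewer multi-promoter genes than requested AP/switch genes",
            call. = FALSE)
  }
  direction <- ifelse(class %in% c("ap", "deg"),
                      sample(c("up", "down"), n, replace = TRUE), "none")
  direction[class == "switch"] <- "both"

  gtf <- character(0)
  prom_rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- np[i]
    n_tx <- sample(1:2, k, replace = TRUE,
                   prob = design$transcripts_per_promoter)
    lay <- sim_gene_layout(gbase[i], strand[i], k,
                           n_tx, sample(150:400, k, replace = TRUE))
    prom_rows[[i]] <- data.frame(
      gene_id = gene_id[i], prom_idx = seq_len(k), chrom = chrom[i],
      strand = strand[i], tss = lay$tss, donor = lay$donor, n_tx = n_tx,
      stringsAsFactors = FALSE
    )
    for (p in seq_len(k)) {
      for (t in seq_len(n_tx[p])) {
        tx <- sprintf("%s.P%d.T%d", gene_id[i], p, t)
        ex <- rbind(c(lay$first_start[p], lay$first_end[p]),
                    if (t == 2L) c(lay$mid_start[p], lay$mid_end[p]),
                    c(lay$last_start, lay$last_end))
        ex <- ex[order(ex[, 1L]), , drop = FALSE]
        attr_str <- sprintf(
          'gene_id "%s"; transcript_id "%s"; gene_name "%s";',
          gene_id[i], tx, gene_id[i])
        gtf <- c(gtf, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                              chrom[i], ex[, 1L] + 1L, ex[, 2L],
                              strand[i], attr_str))
      }
    }
  }
  list(
    gtf_lines = gtf,
    promoters = do.call(rbind, prom_rows),
    genes = data.frame(gene_id = gene_id, class = class, n_promoters = np,
                       direction = direction, stringsAsFactors = FALSE)
  )
}

# Draw promoter shares for one gene; returns list(normal, tumor, target,
# target2). Target promoters of AP/switch genes get a small share so the
# planted shift clears the activity fold-change threshold at modest
# counts.
sim_gene_shares <- function(class, k, direction, ap_fc) {
  target <- NA_integer_; target2 <- NA_integer_
  if (class %in% c("stable", "deg") || k == 1L) {
    w <- stats::rgamma(k, 5)
    s <- w / sum(w)
    return(list(normal = s, tumor = s, target = target, target2 = target2))
  }
  if (class == "ap") {
    target <- sample.int(k, 1L)
    st <- stats::runif(1, 0.15, 0.30)
    w <- stats::rgamma(k - 1L, 5)
    s <- numeric(k)
    s[target] <- st
    s[-target] <- (1 - st) * w / sum(w)
    tum <- s
    if (direction == "up") {
      tum[target] <- st * ap_fc
      tum[-target] <- s[-target] * (1 - st * ap_fc) / (1 - st)
    } else {
      tum[target] <- st / ap_fc
      tum[-target] <- s[-target] * (1 - st / ap_fc) / (1 - st)
    }
    return(list(normal = s, tumor = tum, target = target, target2 = target2))
  }
  # switch: transfer share from promoter B to promoter A, others untouched
  idx <- sample.int(k, 2L)
  target <- idx[1L]; target2 <- idx[2L]
  sa <- stats::runif(1, 0.15, 0.25)
  sb <- sa * (ap_fc - 1) + stats::runif(1, 0.05, 0.10)
  w <- stats::rgamma(k - 2L, 5)
  s <- numeric(k)
  s[target] <- sa
  s[target2] <- sb
  s[-idx] <- (1 - sa - sb) * w / sum(w)
  tum <- s
  tum[target] <- sa * ap_fc
  tum[target2] <- sb - sa * (ap_fc - 1)
  list(normal = s, tumor = tum, target = target, target2 = target2)
}

#' Simulate paired tumor/normal junction counts
#'
#' Draws negative-binomial junction counts for every promoter and sample.
#' Stable promoters keep their share of a constant gene total; DEG genes
#' scale the whole gene by `deg_fc`; AP genes shift the target promoter's
#' share by `ap_fc` while the gene total stays constant; switch genes
#' transfer share from one promoter to another so that one promoter rises
#' and another falls. Per-sample library factors are log-normal.
#'
#' Promoter truth flags (`is_drp_true`, `is_ap_true`) are evaluated from
#' the generative means through the same formulas the caller applies
#' (log2 activity of means, fold change with the 0.001 pseudo-activity),
#' so borderline plantings are labelled consistently with the
#' definitions.
#'
#' @param design a `simulation_design`.
#' @param annotation output of [simulate_annotation()].
#' @return list with
#'   \describe{
#'     \item{design_table}{`sample_id`, `condition`, `pair_id`.}
#'     \item{junctions}{named list of per-sample junction tables (internal
#'       0-based convention, ready for [count_promoter_reads()]).}
#'     \item{junction_layout,junction_counts}{master junction table and
#'       its counts matrix (includes non-donor internal junctions).}
#'     \item{promoter_counts}{planted per-promoter count matrix.}
#'     \item{gene_counts,tx_counts}{gene- and transcript-level count
#'       matrices.}
#'     \item{truth}{promoter truth table keyed by (`gene_id`, `tss`).}
#'     \item{lib_factors}{per-sample library factors.}
#'   }
#' @export
simulate_junction_counts <- function(design, annotation) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed + 1L)
  prom <- annotation$promoters
  genes <- annotation$genes
  n_pairs <- design$n_pairs
  sample_id <- c(sprintf("T%02d", seq_len(n_pairs)),
                 sprintf("N%02d", seq_len(n_pairs)))
  condition <- rep(c("tumor", "normal"), each = n_pairs)
  pair_id <- rep(sprintf("P%02d", seq_len(n_pairs)), 2L)
  design_table <- data.frame(sample_id, condition, pair_id,
                             stringsAsFactors = FALSE)
  lib <- stats::rlnorm(length(sample_id), 0, design$library_sdlog)
  names(lib) <- sample_id

  # per-promoter generative means
  mu_n <- numeric(nrow(prom)); mu_t <- numeric(nrow(prom))
  is_target <- logical(nrow(prom)); is_target2 <- logical(nrow(prom))
  for (gi in seq_len(nrow(genes))) {
    rows <- which(prom$gene_id == genes$gene_id[gi])
    k <- length(rows)
    sh <- sim_gene_shares(genes$class[gi], k, genes$direction[gi],
                          design$ap_fc)
    tot_n <- design$baseline_mean
    tot_t <- if (genes$class[gi] == "deg") {
      if (genes$direction[gi] == "up") tot_n * design$deg_fc
      else tot_n / design$deg_fc
    } else tot_n
    mu_n[rows] <- tot_n * sh$normal
    mu_t[rows] <- tot_t * sh$tumor
    if (!is.na(sh$target)) is_target[rows[sh$target]] <- TRUE
    if (!is.na(sh$target2)) is_target2[rows[sh$target2]] <- TRUE
  }

  # promoter x sample counts
  mu_mat <- outer(mu_n, lib)
  mu_mat[, condition == "tumor"] <- outer(mu_t, lib[condition == "tumor"])
  cnt <- if (design$nb_dispersion > 0) {
    matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                          size = 1 / design$nb_dispersion),
           nrow = nrow(mu_mat))
  } else {
    matrix(stats::rpois(length(mu_mat), mu_mat), nrow = nrow(mu_mat))
  }
  dimnames(cnt) <- list(paste(prom$gene_id, prom$prom_idx, sep = "."),
                        sample_id)

  # junction layout and per-junction counts: each promoter's reads are
  # split across its transcripts; two-exon transcripts contribute one
  # donor junction, three-exon transcripts a donor junction plus an
  # internal (mid -> last) junction that promoter counting must ignore.
  lay_rows <- list(); jx_counts <- list(); tx_rows <- list()
  for (i in seq_len(nrow(prom))) {
    g <- prom$gene_id[i]; p <- prom$prom_idx[i]
    gi <- match(g, genes$gene_id)
    k <- genes$n_promoters[gi]
    gb <- as.integer(((match(g, genes$gene_id) - 1L) %% 100L) * 50000L)
    lay <- sim_gene_layout(gb, prom$strand[i], k, NULL,
                           rep(0L, k))  # geometry only for mid/last coords
    ci <- cnt[i, ]
    if (prom$n_tx[i] == 1L) {
      split1 <- ci
      split2 <- NULL
    } else {
      split1 <- stats::rbinom(length(ci), ci, 0.6)
      split2 <- ci - split1
    }
    mk_jx <- function(donor, acceptor_start, acceptor_end, strand, counts,
                      role) {
      if (strand == "+") {
        s1 <- donor + 1L; e1 <- acceptor_start  # 1-based intron bounds
      } else {
        s1 <- acceptor_end + 1L; e1 <- donor
      }
      list(row = data.frame(chrom = prom$chrom[i], intron_start1 = s1,
                            intron_end1 = e1,
                            strand_code = if (strand == "+") 1L else 2L,
                            role = role, promoter = rownames(cnt)[i],
                            stringsAsFactors = FALSE),
           counts = counts)
    }
    donor <- prom$donor[i]
    std <- prom$strand[i]
    j1 <- mk_jx(donor, lay$last_start, lay$last_end, std, split1, "donor")
    lay_rows <- c(lay_rows, list(j1$row)); jx_counts <- c(jx_counts, list(j1$counts))
    tx_rows <- c(tx_rows, list(stats::setNames(
      list(split1), sprintf("%s.P%d.T1", g, p))))
    if (!is.null(split2)) {
      j2 <- mk_jx(donor, lay$mid_start[p], lay$mid_end[p], std, split2,
                  "donor")
      jint <- if (std == "+") {
        mk_jx(lay$mid_end[p], lay$last_start, lay$last_end, std, split2,
              "internal")
      } else {
        mk_jx(lay$mid_start[p], lay$last_start, lay$last_end, std, split2,
              "internal")
      }
      lay_rows <- c(lay_rows, list(j2$row, jint$row))
      jx_counts <- c(jx_counts, list(j2$counts, jint$counts))
      tx_rows <- c(tx_rows, list(stats::setNames(
        list(split2), sprintf("%s.P%d.T2", g, p))))
    }
  }
  layout <- do.call(rbind, lay_rows)
  jx_mat <- do.call(rbind, jx_counts)
  colnames(jx_mat) <- sample_id
  tx_counts <- do.call(rbind, lapply(tx_rows, function(r) {
    m <- matrix(r[[1L]], nrow = 1L, dimnames = list(names(r)[1L], sample_id))
    m
  }))
  gene_counts <- rowsum(cnt, prom$gene_id)

  junctions <- lapply(sample_id, function(s) {
    data.table::data.table(
      chrom = layout$chrom,
      start = layout$intron_start1 - 1L,
      end = layout$intron_end1,
      strand = c("+", "-")[layout$strand_code],
      unique_reads = as.integer(jx_mat[, s])
    )
  })
  names(junctions) <- sample_id

  eps <- 0.001
  true_abs_n <- log2(mu_n + 1)
  true_abs_t <- log2(mu_t + 1)
  true_fc <- log2((true_abs_t + eps) / (true_abs_n + eps))
  gclass <- genes$class[match(prom$gene_id, genes$gene_id)]
  is_drp_true <- abs(true_fc) > log2(1.2)
  is_ap_true <- is_drp_true & gclass != "deg" &
    true_abs_t > 0.25 & true_abs_n > 0.25
  truth <- data.frame(
    gene_id = prom$gene_id, prom_idx = prom$prom_idx, chrom = prom$chrom,
    strand = prom$strand, tss = prom$tss, donor = prom$donor,
    gene_class = gclass,
    is_target = is_target, is_target2 = is_target2,
    mu_normal = mu_n, mu_tumor = mu_t,
    true_abs_normal = true_abs_n, true_abs_tumor = true_abs_t,
    true_log2_fc_abs = true_fc,
    is_drp_true = is_drp_true, is_ap_true = is_ap_true,
    direction_true = ifelse(is_drp_true,
                            ifelse(true_fc > 0, "up", "down"), "none"),
    stringsAsFactors = FALSE
  )
  list(design_table = design_table, junctions = junctions,
       junction_layout = layout, junction_counts = jx_mat,
       promoter_counts = cnt, gene_counts = gene_counts,
       tx_counts = tx_counts, truth = truth, lib_factors = lib)
}

#' Attach catalog promoter ids to a simulation truth table
#'
#' Truth rows and catalog promoters are joined on (`gene_id`, `tss`); the
#' generator guarantees this key is unique per promoter.
#'
#' @param truth truth table from [simulate_junction_counts()].
#' @param catalog a `promoter_annotation` built from the simulated GTF.
#' @return the truth table with a `promoter_id` column.
#' @export
match_truth_to_catalog <- function(truth, catalog) {
  key_t <- paste(truth$gene_id, truth$tss)
  key_c <- paste(catalog$promoters$gene_id, catalog$promoters$tss)
  truth$promoter_id <- catalog$promoters$promoter_id[match(key_t, key_c)]
  truth
}

#' Simulate CpG methylation betas coupled to promoter activity
#'
#' Places `cpgs_per_promoter` CpGs uniformly within +/-1 kb of every
#' promoter TSS. For a seeded subset of true-AP promoters
#' (`fraction_mrap`) about half of the CpGs are coupled to activity:
#' `beta = inverse-logit(a + slope * activity + noise)` with the
#' intercept centring betas at 0.5; all other CpGs are independent
#' Beta(2,2) draws. Betas are clipped to \[0.01, 0.99\].
#'
#' @param design a `simulation_design`.
#' @param truth truth table with `promoter_id` (see
#'   [match_truth_to_catalog()]).
#' @param activity an `activity_matrix` or promoters x samples absolute
#'   activity matrix (the activities the betas are coupled to).
#' @return list with `meth` (a `methylation_matrix`), `cpg_truth`
#'   (`probe_id`, `promoter_id`, `gene_id`, `is_coupled`, `true_r` — the
#'   correlation of the noiseless coupled component with activity), and
#'   the input `truth` extended by `is_coupled` and `is_mrap_true`
#'   (`is_ap_true & is_coupled`).
#' @export
simulate_methylation <- function(design, truth, activity) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed + 2L)
  absmat <- if (inherits(activity, "activity_matrix")) activity$absolute
            else activity
  samples <- colnames(absmat)
  k <- design$cpgs_per_promoter
  slope <- design$meth_coupling_slope
  noise <- design$meth_noise_sd

  coupled_prom <- truth$is_ap_true & !is.na(truth$promoter_id) &
    truth$promoter_id %in% rownames(absmat) &
    stats::runif(nrow(truth)) < design$fraction_mrap
  n_coupled_cpg <- ceiling(k / 2)

  probe_rows <- list(); beta_rows <- list(); truth_rows <- list()
  probe_n <- 0L
  for (i in seq_len(nrow(truth))) {
    offs <- sample(seq(-1000L, 1000L), k)
    pos <- truth$tss[i] + offs
    ids <- sprintf("cg%08d", probe_n + seq_len(k))
    probe_n <- probe_n + k
    betas <- matrix(NA_real_, k, length(samples))
    coupled <- logical(k)
    true_r <- rep(NA_real_, k)
    if (coupled_prom[i]) {
      act <- absmat[truth$promoter_id[i], samples]
      a <- -slope * mean(act)
      mu_logit <- a + slope * act
      for (cc in seq_len(n_coupled_cpg)) {
        coupled[cc] <- TRUE
        betas[cc, ] <- stats::plogis(mu_logit + stats::rnorm(length(act), 0, noise))
        true_r[cc] <- if (stats::sd(act) > 0) {
          stats::cor(stats::plogis(mu_logit), act)
        } else NA_real_
      }
    }
    nfree <- sum(!coupled)
    betas[!coupled, ] <- matrix(stats::rbeta(nfree * length(samples), 2, 2),
                                nfree)
    probe_rows[[i]] <- data.frame(probe_id = ids, chrom = truth$chrom[i],
                                  pos = pos, stringsAsFactors = FALSE)
    beta_rows[[i]] <- betas
    truth_rows[[i]] <- data.frame(
      probe_id = ids, promoter_id = truth$promoter_id[i],
      gene_id = truth$gene_id[i], is_coupled = coupled, true_r = true_r,
      stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, probe_rows)
  beta <- do.call(rbind, beta_rows)
  beta <- pmin(pmax(beta, 0.01), 0.99)
  dimnames(beta) <- list(probes$probe_id, samples)
  meth <- structure(list(probes = probes, beta = beta, source = "array"),
                    class = "methylation_matrix")
  truth$is_coupled <- coupled_prom
  truth$is_mrap_true <- truth$is_ap_true & coupled_prom
  list(meth = meth, cpg_truth = do.call(rbind, truth_rows), truth = truth)
}

#' Simulate a survival cohort with methylation-dependent hazard
#'
#' Subjects fall into a latent high/low methylation group (probability
#' 1/2). CpGs flagged prognostic take bimodal betas separating the
#' groups; the subject's hazard is `baseline_hazard * hazard_ratio^group`
#' and survival times are exponential. With probability `censor_rate` a
#' subject is censored uniformly before its event time, so the realised
#' censoring fraction equals `censor_rate` in expectation. Times are in
#' days.
#'
#' @param design a `simulation_design`.
#' @param cpg_truth CpG truth table from [simulate_methylation()]; the
#'   coupled CpGs of a `fraction_prognostic` subset of coupled promoters
#'   are flagged prognostic.
#' @param truth promoter truth table from [simulate_methylation()].
#' @return list with `clinical` (`sample_id`, `time`, `event`),
#'   `cohort_beta` (CpGs x subjects), `group` (latent indicator) and
#'   `cpg_truth` extended by `is_prognostic`.
#' @export
simulate_survival <- function(design, cpg_truth, truth) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed + 3L)
  n <- design$n_subjects
  subj <- sprintf("S%03d", seq_len(n))
  z <- stats::rbinom(n, 1L, 0.5)

  coupled_proms <- unique(truth$promoter_id[truth$is_mrap_true %in% TRUE])
  prog_proms <- coupled_proms[stats::runif(length(coupled_proms)) <
                                design$fraction_prognostic]
  cpg_truth$is_prognostic <- cpg_truth$is_coupled &
    cpg_truth$promoter_id %in% prog_proms

  beta <- matrix(stats::rbeta(nrow(cpg_truth) * n, 2, 2),
                 nrow(cpg_truth), n,
                 dimnames = list(cpg_truth$probe_id, subj))
  pr <- which(cpg_truth$is_prognostic)
  for (i in pr) {
    beta[i, ] <- 0.35 + 0.3 * z + stats::rnorm(n, 0, 0.05)
  }
  beta <- pmin(pmax(beta, 0.01), 0.99)

  hazard <- design$baseline_hazard * design$hazard_ratio^z
  times <- stats::rexp(n, hazard)
  cen <- stats::runif(n) < design$censor_rate
  event <- as.integer(!cen)
  times[cen] <- stats::runif(sum(cen), 0, times[cen])
  list(clinical = data.frame(sample_id = subj, time = times, event = event,
                             stringsAsFactors = FALSE),
       cohort_beta = beta, group = z, cpg_truth = cpg_truth)
}

#' Simulate a complete paired tumor/normal study
#'
#' Runs all generator stages and the annotation/activity part of the
#' analysis pipeline: annotation -> GTF -> promoter catalog -> junction
#' counts -> activity matrix -> methylation betas -> survival cohort.
#' With `dir` set, all inputs are also written as plain-text files (GTF,
#' per-sample SJ.out.tab, design/beta/manifest/clinical/truth TSVs and a
#' JSON copy of the design).
#'
#' @param design a `simulation_design`.
#' @param dir optional output directory.
#' @return list with the design, annotation, `gtf` path, parsed `models`,
#'   `catalog`, `counts` (see [simulate_junction_counts()]), `activity`,
#'   `truth` (with promoter ids and methylation flags), `meth`,
#'   `cpg_truth`, and `survival`.
#' @export
simulate_hcc_study <- function(design, dir = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  ann <- simulate_annotation(design)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- file.path(dir %||% tempdir(), sprintf("sim_%d.gtf", design$seed))
  writeLines(ann$gtf_lines, gtf)
  models <- parse_gene_models(gtf)
  catalog <- build_promoters(models)
  cnt <- simulate_junction_counts(design, ann)
  activity <- promoter_activity(cnt$junctions, catalog,
                                design = cnt$design_table)
  truth <- match_truth_to_catalog(cnt$truth, catalog)
  sim_meth <- simulate_methylation(design, truth, activity)
  surv <- simulate_survival(design, sim_meth$cpg_truth, sim_meth$truth)

  out <- list(design = design, annotation = ann, gtf = gtf,
              models = models, catalog = catalog, counts = cnt,
              activity = activity, truth = sim_meth$truth,
              meth = sim_meth$meth, cpg_truth = surv$cpg_truth,
              survival = surv)
  if (!is.null(dir)) write_study_files(out, dir)
  out
}

#' Write the plain-text input files of a simulated study
#'
#' @param study output of [simulate_hcc_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_study_files <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sjdir <- file.path(dir, "sj")
  dir.create(sjdir, showWarnings = FALSE)
  lay <- study$counts$junction_layout
  for (s in study$counts$design_table$sample_id) {
    cnts <- study$counts$junction_counts[, s]
    sj <- data.frame(lay$chrom, lay$intron_start1, lay$intron_end1,
                     lay$strand_code, 1L, 1L, cnts, 0L, 50L)
    utils::write.table(sj, file.path(sjdir, paste0(s, ".SJ.out.tab")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  dt <- study$counts$design_table
  dt$path <- file.path(sjdir, paste0(dt$sample_id, ".SJ.out.tab"))
  write_tsv(dt, file.path(dir, "design.tsv"))
  write_matrix_tsv(study$meth$beta, file.path(dir, "beta_matrix.tsv"),
                   id_col = "probe_id")
  man <- study$meth$probes
  man$pos <- man$pos + 1L  # manifest positions are 1-based on disk
  write_tsv(man, file.path(dir, "manifest.tsv"))
  write_tsv(study$survival$clinical, file.path(dir, "clinical.tsv"))
  write_matrix_tsv(study$survival$cohort_beta,
                   file.path(dir, "cohort_beta.tsv"), id_col = "probe_id")
  write_tsv(study$truth, file.path(dir, "truth_promoters.tsv"))
  write_tsv(study$cpg_truth, file.path(dir, "truth_cpgs.tsv"))
  write_tsv(study$annotation$genes, file.path(dir, "truth_genes.tsv"))
  write_matrix_tsv(study$counts$gene_counts, file.path(dir, "gene_counts.tsv"),
                   id_col = "gene_id")
  write_matrix_tsv(study$counts$tx_counts, file.path(dir, "tx_counts.tsv"),
                   id_col = "transcript_id")
  cfg <- unclass(study$design)
  jsonlite::write_json(cfg, file.path(dir, "design_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
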