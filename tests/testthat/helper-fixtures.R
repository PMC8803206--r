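# Shared fixtures: GTF snippets, random promoter/junction fixtures with
# brute-force oracles, and a cached small simulated study.

gtf_exon <- function(chrom, start1, end1, strand, gene, tx) {
  sprintf('%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, start1, end1, strand, gene, tx)
}

write_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

.fixtures <- new.env(parent = emptyenv())

# one small end-to-end study reused across test files
small_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulate_hcc_study(
      simulation_design(n_genes = 60, seed = 42))
  }
  .fixtures$study
}

small_analysis <- function() {
  if (is.null(.fixtures$analysis)) {
    st <- small_study()
    gd <- gene_differential(st$counts$gene_counts, st$counts$design_table)
    pd <- promoter_differential(st$activity, st$counts$design_table)
    ap <- identify_aps(gd, pd)
    links <- classify_correlation(
      select_representative_cpg(st$catalog, st$meth, st$activity))
    .fixtures$analysis <- list(study = st, gene_diff = gd,
                               promoter_diff = pd, ap_table = ap,
                               links = links,
                               mraps = call_mraps(ap, links))
  }
  .fixtures$analysis
}

# hand-built promoter catalog carrying only what junction counting needs
rand_catalog <- function(n_prom = 30, seed = 1) {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2"), n_prom, replace = TRUE)
  strand <- sample(c("+", "-"), n_prom, replace = TRUE)
  n_donors <- sample(1:2, n_prom, replace = TRUE)
  donor_pool <- sample(20000:200000, sum(n_donors))
  prom <- data.frame(
    promoter_id = sprintf("p%03d", seq_len(n_prom)),
    gene_id = sprintf("g%03d", seq_len(n_prom)),
    chrom = chrom, strand = strand, stringsAsFactors = FALSE
  )
  donors <- data.frame(
    promoter_id = rep(prom$promoter_id, n_donors),
    chrom = rep(chrom, n_donors),
    strand = rep(strand, n_donors),
    donor = donor_pool,
    stringsAsFactors = FALSE
  )
  structure(list(promoters = prom,
                 members = data.frame(promoter_id = prom$promoter_id,
                                      transcript_id = prom$promoter_id),
                 donors = donors),
            class = "promoter_annotation")
}

rand_junctions <- function(catalog, n_match = 40, n_miss = 30, seed = 1) {
  set.seed(seed)
  d <- catalog$donors[sample.int(nrow(catalog$donors), n_match,
                                 replace = TRUE), ]
  len <- sample(500:5000, n_match, replace = TRUE)
  start <- ifelse(d$strand == "+", d$donor, d$donor - len)
  end <- ifelse(d$strand == "+", d$donor + len, d$donor)
  jstrand <- ifelse(stats::runif(n_match) < 0.2, ".", d$strand)
  miss_start <- sample(300000:400000, n_miss)
  data.frame(
    chrom = c(d$chrom, sample(c("chr1", "chr2"), n_miss, replace = TRUE)),
    start = c(start, miss_start),
    end = c(end, miss_start + sample(500:5000, n_miss, replace = TRUE)),
    strand = c(jstrand, sample(c("+", "-", "."), n_miss, replace = TRUE)),
    unique_reads = sample(0:50, n_match + n_miss, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# quadratic all-pairs oracle for promoter read counting
brute_count <- function(junctions, catalog) {
  prom <- catalog$promoters
  out <- stats::setNames(numeric(nrow(prom)), prom$promoter_id)
  for (i in seq_len(nrow(prom))) {
    dn <- catalog$donors[catalog$donors$promoter_id == prom$promoter_id[i], ]
    tot <- 0
    for (j in seq_len(nrow(junctions))) {
      for (k in seq_len(nrow(dn))) {
        if (junctions$chrom[j] != dn$chrom[k]) next
        if (dn$strand[k] == "+") {
          if (junctions$strand[j] %in% c("+", ".") &&
              junctions$start[j] == dn$donor[k]) {
            tot <- tot + junctions$unique_reads[j]
          }
        } else {
          if (junctions$strand[j] %in% c("-", ".") &&
              junctions$end[j] == dn$donor[k]) {
            tot <- tot + junctions$unique_reads[j]
          }
        }
      }
    }
    out[i] <- tot
  }
  out
}

# direct covariance-formula Pearson oracle with t-distribution p
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# survival-only generator wrapper used by the calibration tests
sim_surv <- function(seed, hazard_ratio, n_subjects,
                     censor_rate = 0.3) {
  design <- simulation_design(hazard_ratio = hazard_ratio,
                              n_subjects = n_subjects,
                              censor_rate = censor_rate,
                              fraction_prognostic = 1, seed = seed)
  cpg_truth <- data.frame(probe_id = "cg1", promoter_id = "p1",
                          gene_id = "g1", is_coupled = TRUE, true_r = -0.9,
                          stringsAsFactors = FALSE)
  truth <- data.frame(promoter_id = "p1", is_mrap_true = TRUE,
                      stringsAsFactors = FALSE)
  simulate_survival(design, cpg_truth, truth)
}
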