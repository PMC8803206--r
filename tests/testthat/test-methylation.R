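write_beta_fixture <- function(beta, probes) {
  mp <- tempfile(); fp <- tempfile()
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(probes, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, manifest = fp)
}

test_that("450K-style beta matrices join against their manifest", {
  beta <- matrix(c(0.1, 0.5, 0.9, 0.2, 0.6, 0.8), 3, 2,
                 dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
  man <- data.frame(probe_id = c("cg1", "cg2", "cg3"), chrom = "chr1",
                    pos = c(101L, 201L, 301L))
  fx <- write_beta_fixture(beta, man)
  m <- read_beta_matrix(fx$matrix, fx$manifest)
  expect_equal(nrow(m$beta), 3L)
  expect_equal(m$probes$pos, c(100L, 200L, 300L))  # 1-based -> 0-based
  expect_equal(m$source, "array")

  # probe missing from the manifest is dropped with a message
  fx2 <- write_beta_fixture(beta, man[-2, ])
  expect_message(m2 <- read_beta_matrix(fx2$matrix, fx2$manifest), "dropped")
  expect_equal(rownames(m2$beta), c("cg1", "cg3"))

  # out-of-range beta is an error
  beta_bad <- beta; beta_bad[1, 1] <- 1.2
  fx3 <- write_beta_fixture(beta_bad, man)
  expect_error(read_beta_matrix(fx3$matrix, fx3$manifest), "outside")

  # duplicated probe ids are an error
  beta_dup <- rbind(beta, beta[1, , drop = FALSE])
  fx4 <- write_beta_fixture(beta_dup, man)
  expect_error(read_beta_matrix(fx4$matrix, fx4$manifest), "duplicate")
})

test_that("WGBS ratio files parse per CpG", {
  f <- tempfile()
  writeLines(c("chr1\t100\t101\t0.8\t12", "chr1\t150\t151\t0.5\t8",
               "chr2\t100\t101\t0.1\t30", "chr2\t300\t301\t0.9\t5"), f)
  m <- read_wgbs_ratios(f, "v1")
  expect_equal(nrow(m$beta), 4L)
  expect_equal(m$source, "wgbs")
  expect_equal(unname(m$coverage[, 1]), c(12L, 8L, 30L, 5L))
  expect_equal(rownames(m$beta)[1], "chr1:100")

  writeLines(c("chr1\t100\t101\t0.8", "chr1\t100\t101\t0.5"), f)
  expect_error(read_wgbs_ratios(f, "v1"), "duplicated CpG")

  writeLines("chr1\t100\t101\t1.4", f)
  expect_error(read_wgbs_ratios(f, "v1"), "line 1")
})

test_that("delta beta is the tumor-normal mean difference with NA guards", {
  beta <- rbind(cg1 = c(0.7, 0.5, 0.5, 0.3),
                cg2 = c(0.4, 0.4, 0.4, 0.4),
                cg3 = c(NA, NA, 0.2, 0.6))
  colnames(beta) <- c("T1", "T2", "N1", "N2")
  meth <- structure(list(probes = data.frame(probe_id = rownames(beta),
                                             chrom = "chr1", pos = 1:3),
                         beta = beta, source = "array"),
                    class = "methylation_matrix")
  design <- data.frame(sample_id = colnames(beta),
                       condition = c("tumor", "tumor", "normal", "normal"))
  db <- delta_beta(meth, design)
  expect_equal(db$delta_beta, c(0.2, 0, NA))
  expect_true(all(abs(db$delta_beta) <= 1, na.rm = TRUE))

  # antisymmetric under swapping condition labels
  design2 <- transform(design,
                       condition = ifelse(condition == "tumor",
                                          "normal", "tumor"))
  expect_equal(delta_beta(meth, design2)$delta_beta, -db$delta_beta)
})

test_that("Pearson test matches the closed-form oracle", {
  x <- 1:5
  r1 <- pearson_test(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-10)

  r2 <- pearson_test(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r2$r, 0.5, tolerance = 1e-12)
  expect_equal(r2$p, 2 / 3, tolerance = 1e-12)

  expect_true(is.na(pearson_test(1:5, rep(1, 5))$r))
  expect_true(is.na(pearson_test(1:2, 2:1)$r))

  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(sample(4:30, 1)); y <- rnorm(length(x))
    got <- pearson_test(x, y)
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

mk_meth <- function(pos, beta, chrom = "chr1") {
  structure(list(probes = data.frame(
    probe_id = sprintf("cg%03d", seq_along(pos)), chrom = chrom, pos = pos),
    beta = beta, source = "array"), class = "methylation_matrix")
}

test_that("representative CpG selection minimises the correlation p within +/-1 kb", {
  prom <- data.frame(promoter_id = "pr1", gene_id = "g1", chrom = "chr1",
                     strand = "+", tss = 5000L)
  set.seed(8)
  act <- matrix(seq(1, 4, length.out = 10), 1, 10,
                dimnames = list("pr1", paste0("s", 1:10)))
  # cg1 strongly anti-correlated, cg2 noise, cg3 outside the window,
  # cg4 sits exactly on the inclusive boundary
  beta <- rbind(0.9 - 0.15 * act[1, ] + rnorm(10, 0, 0.01),
                runif(10),
                0.9 - 0.2 * act[1, ],
                runif(10))
  beta <- pmin(pmax(beta, 0), 1)
  meth <- mk_meth(c(4800L, 5500L, 6500L, 6000L), beta)
  colnames(meth$beta) <- colnames(act)
  link <- select_representative_cpg(prom, meth, act)
  expect_equal(link$probe_id, "cg001")
  expect_equal(link$dist_to_tss, -200L)
  expect_lt(link$r, -0.9)

  # boundary at exactly +1000 is a candidate: drop cg1/cg2 to see it win
  meth2 <- mk_meth(c(6500L, 6000L), beta[3:4, ])
  colnames(meth2$beta) <- colnames(act)
  link2 <- select_representative_cpg(prom, meth2, act)
  expect_equal(link2$dist_to_tss, 1000L)

  # no CpG in the window -> promoter omitted with a message
  meth3 <- mk_meth(9000L, beta[2, , drop = FALSE])
  colnames(meth3$beta) <- colnames(act)
  expect_message(link3 <- select_representative_cpg(prom, meth3, act),
                 "without a usable CpG")
  expect_equal(nrow(link3), 0L)

  # invariance to sample ordering
  perm <- sample(colnames(act))
  link_p <- select_representative_cpg(prom, meth,
                                      act[, perm, drop = FALSE])
  expect_equal(link_p$probe_id, link$probe_id)
  expect_equal(link_p$r, link$r, tolerance = 1e-12)

  # minus-strand distances flip sign
  prom_m <- transform(prom, strand = "-")
  link_m <- select_representative_cpg(prom_m, meth, act)
  expect_equal(link_m$dist_to_tss, 200L)
})

test_that("TSS profiles average probes into 50/25 sliding windows", {
  prom <- data.frame(promoter_id = "pr1", gene_id = "g1", chrom = "chr1",
                     strand = "+", tss = 10000L)
  design <- data.frame(sample_id = c("a", "b"),
                       condition = c("tumor", "normal"))
  # a single probe at distance 0 with beta 0.5
  meth <- mk_meth(10000L, matrix(0.5, 1, 2,
                                 dimnames = list(NULL, c("a", "b"))))
  prof <- tss_methylation_profile(meth, prom, design)
  tum <- prof[prof$group == "tumor", ]
  covering <- tum$start <= 0 & tum$end > 0
  expect_true(all(tum$mean_beta[covering] == 0.5))
  expect_true(all(is.na(tum$mean_beta[!covering])))

  # two probes in one window average
  meth2 <- mk_meth(c(10001L, 10010L),
                   matrix(c(0.2, 0.2, 0.4, 0.4), 2, 2, byrow = TRUE,
                          dimnames = list(NULL, c("a", "b"))))
  prof2 <- tss_methylation_profile(meth2, prom, design)
  w0 <- prof2[prof2$group == "tumor" & prof2$start == 0, ]
  expect_equal(w0$mean_beta, 0.3)
  expect_equal(w0$n_probes, 2L)

  # dense profile equals a brute-force window recomputation
  set.seed(14)
  pos <- 10000L + sample(-2000:1999, 300)
  bmat <- matrix(runif(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  meth3 <- mk_meth(pos, bmat)
  prof3 <- tss_methylation_profile(meth3, prom, design)
  tum3 <- prof3[prof3$group == "tumor", ]
  d <- pos - 10000L
  for (i in sample(nrow(tum3), 25)) {
    inw <- d >= tum3$start[i] & d < tum3$end[i]
    want <- if (any(inw)) mean(bmat[inw, "a"]) else NA_real_
    expect_equal(tum3$mean_beta[i], want)
  }

  # gam mode returns a smooth evaluated on the same grid
  prof_gam <- tss_methylation_profile(meth3, prom, design, mode = "gam")
  expect_equal(nrow(prof_gam), nrow(prof3))
  expect_false(anyNA(prof_gam$mean_beta))
})

test_that("activity quartiles order TSS methylation under a planted monotone link", {
  n_prom <- 8
  prom <- data.frame(promoter_id = sprintf("pr%02d", 1:n_prom),
                     gene_id = sprintf("g%02d", 1:n_prom), chrom = "chr1",
                     strand = "+", tss = (1:n_prom) * 100000L)
  act <- matrix(rep(1:n_prom, 4), n_prom, 4,
                dimnames = list(prom$promoter_id, c("t1", "t2", "n1", "n2")))
  design <- data.frame(sample_id = colnames(act),
                       condition = c("tumor", "tumor", "normal", "normal"))
  # one CpG on each TSS whose methylation falls as activity rises
  beta <- matrix(rep(0.9 - (1:n_prom) * 0.08, 4), n_prom, 4,
                 dimnames = list(NULL, colnames(act)))
  meth <- mk_meth(prom$tss, beta)
  prof <- activity_quartile_profiles(act, meth, prom, design)
  at0 <- prof[prof$start == 0 & prof$condition == "tumor", ]
  expect_equal(at0$quartile, paste0("Q", 1:4))
  expect_true(all(diff(at0$mean_beta) < 0))  # Q4 lowest methylation
  expect_error(activity_quartile_profiles(act[1:3, ], meth, prom, design),
               ">= 4 promoters")
})

test_that("promoter-region means respect the full-coverage rule", {
  prom <- data.frame(promoter_id = c("pr1", "pr2"), gene_id = c("g1", "g2"),
                     chrom = "chr1", strand = "+",
                     tss = c(5000L, 50000L))
  beta <- rbind(c(0.2, 0.4), c(NA, 0.8), c(0.6, 0.6))
  colnames(beta) <- c("s1", "s2")
  meth <- mk_meth(c(4500L, 5200L, 5900L), beta)
  m <- promoter_region_mean(meth, prom)
  expect_equal(m["pr1", ], c(s1 = 0.4, s2 = 0.6))
  expect_true(all(is.na(m["pr2", ])))  # no CpG near pr2

  # full coverage drops the partially measured CpG for every sample
  mf <- promoter_region_mean(meth, prom, require_full_coverage = TRUE)
  expect_equal(mf["pr1", ], c(s1 = 0.4, s2 = 0.5))

  # single CpG returns its own beta
  meth1 <- mk_meth(5000L, beta[1, , drop = FALSE])
  expect_equal(promoter_region_mean(meth1, prom)["pr1", ],
               c(s1 = 0.2, s2 = 0.4))

  # 20-CpG fixture equals the direct mean oracle
  set.seed(15)
  b20 <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("s1", "s2")))
  meth20 <- mk_meth(5000L + sample(-1000:1000, 20), b20)
  expect_equal(promoter_region_mean(meth20, prom)["pr1", ],
               colMeans(b20))
})
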