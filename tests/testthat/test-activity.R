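test_that("junction tables parse with STAR column semantics", {
  f <- tempfile()
  writeLines("chr1\t1001\t2000\t1\t1\t1\t7\t3\t30", f)
  jt <- read_junction_table(f)
  expect_equal(jt$chrom, "chr1")
  expect_equal(jt$start, 1000L)  # 1-based intron start -> 0-based
  expect_equal(jt$end, 2000L)
  expect_equal(jt$strand, "+")
  expect_equal(jt$unique_reads, 7L)  # column 7 only; multimappers dropped

  # strand code 0 is kept as "."
  writeLines("chr1\t1001\t2000\t0\t0\t0\t4\t0\t20", f)
  expect_equal(read_junction_table(f)$strand, ".")

  # empty file -> empty table
  file.create(f2 <- tempfile())
  expect_equal(nrow(read_junction_table(f2)), 0L)

  # malformed row named by line
  writeLines(c("chr1\t1001\t2000\t1\t1\t1\t7\t3\t30",
               "chr1\t3000\t2500\t1\t1\t1\t7\t3\t30"), f)
  expect_error(read_junction_table(f), "line 2")
})

test_that("a 50-row junction fixture sums like a text column-sum oracle", {
  set.seed(3)
  f <- tempfile()
  rows <- sprintf("chr%d\t%d\t%d\t%d\t1\t1\t%d\t%d\t40",
                  sample(1:2, 50, TRUE), s <- sample(1e4:2e4, 50),
                  s + sample(100:999, 50), sample(1:2, 50, TRUE),
                  sample(0:30, 50, TRUE), sample(0:5, 50, TRUE))
  writeLines(rows, f)
  jt <- read_junction_table(f)
  oracle <- sum(as.numeric(vapply(strsplit(readLines(f), "\t"), `[[`, "", 7L)))
  expect_equal(sum(jt$unique_reads), oracle)
})

test_that("promoter counting matches donor-site semantics", {
  cat_ <- rand_catalog(5, seed = 2)
  # empty junction table -> all-zero counts
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      unique_reads = integer())
  expect_true(all(count_promoter_reads(empty, cat_) == 0))

  # two junctions leaving the same donor add up (isoform additivity)
  d <- cat_$donors[1, ]
  mk <- function(len, n) {
    if (d$strand == "+") {
      data.frame(chrom = d$chrom, start = d$donor, end = d$donor + len,
                 strand = d$strand, unique_reads = n)
    } else {
      data.frame(chrom = d$chrom, start = d$donor - len, end = d$donor,
                 strand = d$strand, unique_reads = n)
    }
  }
  j <- rbind(mk(1000, 4L), mk(2000, 6L))
  cnt <- count_promoter_reads(j, cat_)
  expect_equal(unname(cnt[d$promoter_id, 1]), 10L)
})

test_that("promoter counting equals the brute-force all-pairs oracle", {
  for (s in 1:3) {
    cat_ <- rand_catalog(30, seed = s)
    j <- rand_junctions(cat_, seed = s + 100)
    got <- count_promoter_reads(j, cat_)[, 1]
    expect_equal(got, brute_count(j, cat_))
    # permutation invariance in junction order
    shuffled <- j[sample.int(nrow(j)), ]
    expect_equal(count_promoter_reads(shuffled, cat_)[, 1], got)
  }
})

test_that("median-of-ratios size factors match closed forms and DESeq2", {
  m <- matrix(c(5, 10, 20, 5, 10, 20), ncol = 2)
  expect_equal(estimate_size_factors(m), c(1, 1))

  m2 <- cbind(c(4, 10, 50), c(8, 20, 100))  # col2 = 2 x col1
  expect_equal(estimate_size_factors(m2), c(1 / sqrt(2), sqrt(2)))

  set.seed(9)
  m3 <- matrix(rpois(15, 40) + 1, 5, 3)
  sf <- estimate_size_factors(m3)
  # direct formula oracle
  geo <- exp(rowMeans(log(m3)))
  oracle <- apply(m3 / geo, 2, median)
  expect_equal(sf, oracle)
  # independent implementation cross-check
  expect_equal(sf, unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-12)

  # no all-positive row -> total-count fallback with warning
  m4 <- rbind(c(0, 5), c(5, 0))
  expect_warning(sf4 <- estimate_size_factors(m4), "total-count")
  expect_true(all(sf4 > 0))
})

test_that("scaling one library rescales its relative size factor and normalized counts", {
  # the geometric-mean pseudo-reference itself moves by c^(1/m) when one
  # sample is scaled by c, so the exact invariant lives on ratios:
  # relative size factors scale by c and normalized counts are recovered
  # up to one common constant
  set.seed(10)
  m <- matrix(rpois(40, 60) + 1, 8, 5)
  sf <- estimate_size_factors(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 4
  sf2 <- estimate_size_factors(m2)
  expect_equal(sf2[3] / sf2[1], 4 * sf[3] / sf[1], tolerance = 1e-12)
  expect_equal(sf2[-3] / sf[-3], rep(4^(-1 / 5), 4), tolerance = 1e-12)
  norm1 <- sweep(m, 2, sf, "/")
  norm2 <- sweep(m2, 2, sf2, "/")
  ratio <- norm2 / norm1
  expect_lt(diff(range(ratio)), 1e-12)
})

test_that("absolute activity follows log2(raw/sf + 1)", {
  m <- matrix(c(0, 1, 7), 3, 1)
  got <- absolute_activity(m, 1)
  expect_equal(got[, 1], c(0, 1, 3))
  expect_equal(absolute_activity(matrix(7), 2)[1, 1], log2(4.5))
})

test_that("relative activity is the promoter share of gene activity", {
  abs_ <- matrix(c(2, 0, 0), 3, 1,
                 dimnames = list(c("p1", "p2", "p3"), "s1"))
  ra <- relative_activity(abs_, c("gA", "gA", "gB"))
  expect_equal(ra$relative["p1", 1], 1)      # single active promoter
  expect_equal(ra$relative["p2", 1], 0)      # zero promoter, active gene
  expect_true(is.na(ra$relative["p3", 1]))   # gene with zero activity

  # shares sum to one wherever the gene is active (study-wide property)
  st <- small_study()
  act <- st$activity
  sums <- rowsum(act$relative, act$promoters$gene_id)
  pos <- act$gene_absolute > 0
  expect_true(all(abs(sums[pos] - 1) < 1e-9))
  expect_true(all(is.na(act$relative[act$gene_absolute[
    act$promoters$gene_id, , drop = FALSE] == 0])))
})

test_that("promoter filters drop single-exon-only and all-zero-in-both promoters", {
  tm <- parse_gene_models(write_gtf(c(
    gtf_exon("chr1", 101, 200, "+", "g1", "t1"),
    gtf_exon("chr1", 901, 1000, "+", "g1", "t1"),
    gtf_exon("chr1", 5001, 5400, "+", "g2", "t2"),  # single exon
    gtf_exon("chr1", 9001, 9100, "+", "g3", "t3"),
    gtf_exon("chr1", 9901, 9999, "+", "g3", "t3")
  )))
  cat_ <- build_promoters(tm)
  design <- data.frame(sample_id = c("T1", "T2", "N1", "N2"),
                       condition = c("tumor", "tumor", "normal", "normal"),
                       pair_id = c("P1", "P2", "P1", "P2"))
  raw <- matrix(0L, nrow(cat_$promoters), 4,
                dimnames = list(cat_$promoters$promoter_id,
                                design$sample_id))
  g1 <- cat_$promoters$promoter_id[cat_$promoters$gene_id == "g1"]
  g2 <- cat_$promoters$promoter_id[cat_$promoters$gene_id == "g2"]
  g3 <- cat_$promoters$promoter_id[cat_$promoters$gene_id == "g3"]
  raw[g1, "T1"] <- 5L  # positive in one tumor only -> kept ("both" rule)
  raw[g2, ] <- 9L      # single-exon-only -> removed regardless of counts
  # g3 all zero -> removed
  act <- structure(list(raw_counts = raw, promoters = cat_$promoters,
                        removed = data.frame(promoter_id = character(),
                                             reason = character())),
                   class = "activity_matrix")
  filt <- filter_promoters(act, design)
  expect_equal(rownames(filt$raw_counts), g1)
  expect_setequal(filt$removed$promoter_id, c(g2, g3))
  expect_equal(filt$removed$reason[filt$removed$promoter_id == g2],
               "single_exon_only")

  bad_design <- data.frame(sample_id = c("T1", "X9"),
                           condition = c("tumor", "normal"))
  expect_error(filter_promoters(act, bad_design), "X9")
})
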