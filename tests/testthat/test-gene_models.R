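test_that("GTF exons become transcript models with the internal coordinate convention", {
  gtf <- write_gtf(c(
    gtf_exon("chr1", 101, 200, "+", "gA", "tA1"),
    gtf_exon("chr1", 301, 400, "+", "gA", "tA1"),
    gtf_exon("chr1", 101, 200, "-", "gB", "tB1"),
    gtf_exon("chr1", 301, 400, "-", "gB", "tB1")
  ))
  tm <- parse_gene_models(gtf)
  expect_equal(nrow(tm$transcripts), 2L)
  expect_equal(tm$transcripts$n_exons, c(2L, 2L))

  # plus strand: tss = 0-based start of first exon
  expect_equal(tm$transcripts$tss[tm$transcripts$transcript_id == "tA1"], 100L)
  # minus strand: tss = end - 1 of the most 3' (genomic) exon
  expect_equal(tm$transcripts$tss[tm$transcripts$transcript_id == "tB1"], 399L)
  # transcription order: first exon of the minus transcript is [300,400)
  fb <- tm$exons[tm$exons$transcript_id == "tB1" & tm$exons$rank == 1L, ]
  expect_equal(c(fb$start, fb$end), c(300L, 400L))
})

test_that("a 20-transcript annotation matches a text-scan oracle", {
  set.seed(11)
  lines <- character(0)
  expected <- integer(0)
  for (i in 1:20) {
    tx <- sprintf("t%02d", i)
    g <- sprintf("g%02d", (i - 1) %/% 2 + 1)
    n_ex <- sample(2:5, 1)
    starts <- cumsum(sample(500:2000, n_ex)) + i * 50000
    ends <- starts + sample(100:300, n_ex)
    lines <- c(lines, gtf_exon("chr1", starts, ends, "+", g, tx))
    expected[tx] <- n_ex
  }
  lines <- sample(lines)  # order must not matter
  tm <- parse_gene_models(write_gtf(lines))

  # oracle: count exon lines per transcript by scanning the text
  txt <- readLines(write_gtf(lines))
  oracle <- table(sub('.*transcript_id "([^"]+)".*', "\\1", txt))
  expect_equal(nrow(tm$transcripts), 20L)
  got <- setNames(tm$transcripts$n_exons, tm$transcripts$transcript_id)
  expect_equal(got[names(expected)], expected)
  expect_equal(as.integer(oracle[names(expected)]), unname(expected))
})

test_that("parse errors and skips are reported", {
  bad <- write_gtf('chr1\ttest\texon\t1\t100\t.\t+\t.\tgene_id "g1";')
  expect_error(parse_gene_models(bad), "transcript_id")

  orphan <- write_gtf(c(
    'chr1\ttest\ttranscript\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t0";',
    gtf_exon("chr1", 201, 300, "+", "g1", "t1"),
    gtf_exon("chr1", 401, 500, "+", "g1", "t1")
  ))
  expect_warning(tm <- parse_gene_models(orphan), "no exon records")
  expect_equal(tm$transcripts$transcript_id, "t1")
})

test_that("first-exon overlap clustering groups transcripts into promoters", {
  # one transcript -> one promoter
  tm1 <- parse_gene_models(write_gtf(c(
    gtf_exon("chr1", 101, 200, "+", "g1", "t1"),
    gtf_exon("chr1", 501, 600, "+", "g1", "t1"))))
  cat1 <- build_promoters(tm1)
  expect_equal(nrow(cat1$promoters), 1L)
  expect_equal(cat1$members$transcript_id, "t1")

  # identical first exons -> one promoter with two members;
  # a disjoint downstream first exon -> a second promoter
  tm2 <- parse_gene_models(write_gtf(c(
    gtf_exon("chr1", 101, 200, "+", "g1", "t1"),
    gtf_exon("chr1", 901, 1000, "+", "g1", "t1"),
    gtf_exon("chr1", 151, 260, "+", "g1", "t2"),   # overlaps t1's first exon
    gtf_exon("chr1", 901, 1000, "+", "g1", "t2"),
    gtf_exon("chr1", 501, 600, "+", "g1", "t3"),   # disjoint
    gtf_exon("chr1", 901, 1000, "+", "g1", "t3"))))
  cat2 <- build_promoters(tm2)
  expect_equal(nrow(cat2$promoters), 2L)
  sizes <- sort(cat2$promoters$n_members)
  expect_equal(sizes, c(1L, 2L))
  big <- cat2$promoters$promoter_id[cat2$promoters$n_members == 2L]
  expect_setequal(
    cat2$members$transcript_id[cat2$members$promoter_id == big],
    c("t1", "t2"))
  # representative TSS is the most 5' member TSS
  expect_equal(cat2$promoters$tss[cat2$promoters$promoter_id == big], 100L)
})

test_that("abutting half-open first exons do not merge", {
  tm <- parse_gene_models(write_gtf(c(
    gtf_exon("chr1", 101, 200, "+", "g1", "t1"),
    gtf_exon("chr1", 901, 1000, "+", "g1", "t1"),
    gtf_exon("chr1", 201, 300, "+", "g1", "t2"),  # starts where t1 ends
    gtf_exon("chr1", 901, 1000, "+", "g1", "t2"))))
  expect_equal(nrow(build_promoters(tm)$promoters), 2L)
})

test_that("clustering is order-independent and partitions transcripts", {
  st <- small_study()
  lines <- st$annotation$gtf_lines
  cat_a <- build_promoters(parse_gene_models(write_gtf(lines)))
  set.seed(5)
  cat_b <- build_promoters(parse_gene_models(write_gtf(sample(lines))))
  expect_equal(cat_a$promoters, cat_b$promoters)
  expect_equal(cat_a$members[order(cat_a$members$transcript_id), ],
               cat_b$members[order(cat_b$members$transcript_id), ],
               ignore_attr = TRUE)

  # every transcript in exactly one promoter
  tm <- parse_gene_models(write_gtf(lines))
  expect_equal(sort(cat_a$members$transcript_id),
               sort(tm$transcripts$transcript_id))
  # promoters per gene within [1, transcripts per gene]
  ppg <- table(cat_a$promoters$gene_id)
  tpg <- table(tm$transcripts$gene_id)
  expect_true(all(ppg >= 1 & ppg <= tpg[names(ppg)]))
})

test_that("internal promoters are flagged exactly as the all-pairs oracle", {
  # forced case: promoter first exon inside exon 2 of a sibling transcript
  tm <- parse_gene_models(write_gtf(c(
    gtf_exon("chr1", 101, 200, "+", "g1", "t1"),
    gtf_exon("chr1", 1001, 1400, "+", "g1", "t1"),
    gtf_exon("chr1", 1101, 1200, "+", "g1", "t2"),  # inside t1's exon 2
    gtf_exon("chr1", 2001, 2100, "+", "g1", "t2"))))
  cat_ <- build_promoters(tm)
  got <- merge(cat_$members, cat_$promoters)
  expect_true(got$is_internal[got$transcript_id == "t2"])
  expect_false(got$is_internal[got$transcript_id == "t1"])

  # single-transcript genes are never internal
  tm1 <- parse_gene_models(write_gtf(c(
    gtf_exon("chr1", 101, 200, "+", "g1", "t1"),
    gtf_exon("chr1", 501, 600, "+", "g1", "t1"))))
  expect_false(any(build_promoters(tm1)$promoters$is_internal))

  # random multi-transcript genes vs quadratic interval-overlap oracle
  set.seed(21)
  lines <- character(0)
  for (g in 1:10) {
    gid <- sprintf("g%02d", g)
    base <- g * 100000
    for (t in seq_len(sample(2:4, 1))) {
      tid <- sprintf("%s.t%d", gid, t)
      n_ex <- sample(2:3, 1)
      widths <- sample(100:800, n_ex, replace = TRUE)
      gaps <- sample(200:1500, n_ex, replace = TRUE)
      starts <- base + cumsum(gaps + c(0, widths[-n_ex]))
      ends <- starts + widths
      lines <- c(lines, gtf_exon("chr1", starts, ends, "+", gid, tid))
    }
  }
  tm_r <- parse_gene_models(write_gtf(lines))
  cat_r <- build_promoters(tm_r)
  ie <- tm_r$exons[tm_r$exons$rank > 1L, ]
  oracle <- vapply(seq_len(nrow(cat_r$promoters)), function(i) {
    p <- cat_r$promoters[i, ]
    own <- cat_r$members$transcript_id[cat_r$members$promoter_id ==
                                         p$promoter_id]
    hit <- FALSE
    for (j in seq_len(nrow(ie))) {
      if (ie$gene_id[j] != p$gene_id || ie$transcript_id[j] %in% own) next
      if (ie$start[j] < p$cluster_end && p$cluster_start < ie$end[j]) {
        hit <- TRUE
      }
    }
    hit
  }, TRUE)
  expect_equal(cat_r$promoters$is_internal, oracle)
})
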