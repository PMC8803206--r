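#' Read a splice-junction table (STAR SJ.out.tab dialect)
#'
#' Expects the 9-column whitespace-separated layout written by STAR:
#' chromosome, intron start (1-based), intron end (1-based, inclusive),
#' strand code (0 undefined / 1 `+` / 2 `-`), intron motif, annotation flag,
#' unique-mapping read count, multi-mapping read count, maximum overhang.
#' Only the unique read count is retained; multi-mapped reads are excluded
#' from promoter activity. Intron coordinates are converted to the internal
#' 0-based half-open convention, so the junction start equals the half-open
#' end of the donor exon and the junction end equals the 0-based start of
#' the acceptor exon.
#'
#' @param path path to an SJ.out.tab-style file. Empty files yield an empty
#'   table.
#' @return a `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open intron), `strand` (`"+"`, `"-"` or `"."` for undefined) and
#'   `unique_reads`.
#' @export
read_junction_table <- function(path) {
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  unique_reads = integer())
  if (!file.exists(path)) stop("junction file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, colClasses = list(character = 1))
  if (!nrow(dt)) return(empty)
  if (ncol(dt) != 9L) {
    stop("expected 9 columns in junction table '", path, "', found ", ncol(dt),
         call. = FALSE)
  }
  num_ok <- function(v) is.numeric(v) & !is.na(v)
  bad <- which(!num_ok(dt[[2]]) | !num_ok(dt[[3]]) | !num_ok(dt[[7]]) |
                 dt[[2]] > dt[[3]] | dt[[7]] < 0 | !(dt[[4]] %in% 0:2))
  if (length(bad)) {
    stop("malformed junction row at line ", bad[1L], " of '", path, "'",
         call. = FALSE)
  }
  data.table::data.table(
    chrom = as.character(dt[[1]]),
    start = as.integer(dt[[2]]) - 1L,
    end = as.integer(dt[[3]]),
    strand = c(".", "+", "-")[as.integer(dt[[4]]) + 1L],
    unique_reads = as.integer(dt[[7]])
  )
}

#' Read the junction tables of a cohort
#'
#' @param design design table with `sample_id` and `path` columns.
#' @return named list of junction tables, one per sample.
#' @export
read_junction_tables <- function(design) {
  design <- as.data.frame(design)
  if (!all(c("sample_id", "path") %in% names(design))) {
    stop("design must have sample_id and path columns", call. = FALSE)
  }
  out <- lapply(design$path, read_junction_table)
  names(out) <- design$sample_id
  out
}

#' Count unique junction reads per promoter
#'
#' A promoter's raw activity count in a sample is the total number of
#' uniquely mapping junction reads whose donor coordinate (the 5' end of
#' the intron, read strand-aware) coincides with one of the promoter's
#' first-exon donor sites. On `+` the donor coordinate is the 0-based
#' intron start; on `-` it is the half-open intron end. Junctions whose
#' donor matches no promoter (internal splicing) are ignored; junctions
#' with undefined strand (`"."`) are matched against promoters of either
#' strand at the corresponding coordinate.
#'
#' @param junctions a single junction table or a named list of them (one
#'   per sample), as returned by [read_junction_table()].
#' @param catalog a `promoter_annotation`.
#' @return integer matrix of raw counts, promoters x samples.
#' @export
count_promoter_reads <- function(junctions, catalog) {
  stopifnot(inherits(catalog, "promoter_annotation"))
  if (data.table::is.data.table(junctions) || is.data.frame(junctions)) {
    junctions <- list(sample = junctions)
  }
  if (is.null(names(junctions))) {
    names(junctions) <- paste0("sample", seq_along(junctions))
  }
  prom_ids <- catalog$promoters$promoter_id
  donors <- data.table::as.data.table(catalog$donors)
  counts <- matrix(0L, nrow = length(prom_ids), ncol = length(junctions),
                   dimnames = list(prom_ids, names(junctions)))
  if (!nrow(donors)) return(counts)
  dplus <- donors[donors$strand == "+", ]
  dminus <- donors[donors$strand == "-", ]
  for (s in seq_along(junctions)) {
    j <- data.table::as.data.table(junctions[[s]])
    if (!nrow(j)) next
    acc <- numeric(length(prom_ids))
    names(acc) <- prom_ids
    if (nrow(dplus)) {
      jp <- j[j$strand %in% c("+", "."), ]
      if (nrow(jp)) {
        m <- merge(dplus, jp, by.x = c("chrom", "donor"),
                   by.y = c("chrom", "start"))
        if (nrow(m)) {
          agg <- m[, list(n = sum(unique_reads)), by = "promoter_id"]
          acc[agg$promoter_id] <- acc[agg$promoter_id] + agg$n
        }
      }
    }
    if (nrow(dminus)) {
      jm <- j[j$strand %in% c("-", "."), ]
      if (nrow(jm)) {
        m <- merge(dminus, jm, by.x = c("chrom", "donor"),
                   by.y = c("chrom", "end"))
        if (nrow(m)) {
          agg <- m[, list(n = sum(unique_reads)), by = "promoter_id"]
          acc[agg$promoter_id] <- acc[agg$promoter_id] + agg$n
        }
      }
    }
    counts[, s] <- as.integer(acc)
  }
  counts
}

#' Median-of-ratios size factors
#'
#' Library-size normalisation for the promoter (or gene) count matrix: a
#' per-row geometric mean across samples is taken over rows with all
#' positive counts, and each sample's size factor is the median ratio of
#' its counts to those geometric means. When no row has all-positive
#' counts the function falls back, with a warning, to total-count
#' normalisation (column sums scaled to geometric mean 1).
#'
#' @param raw_counts non-negative count matrix, features x samples (>= 2
#'   samples).
#' @return numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(raw_counts) {
  raw_counts <- as.matrix(raw_counts)
  if (ncol(raw_counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  lc <- log(raw_counts)
  loggeo <- rowMeans(lc)
  use <- is.finite(loggeo)
  if (!any(use)) {
    warning("no feature with all-positive counts; ",
            "falling back to total-count normalization", call. = FALSE)
    tot <- colSums(raw_counts)
    if (any(tot == 0)) stop("sample(s) with zero total counts", call. = FALSE)
    return(tot / exp(mean(log(tot))))
  }
  apply(lc, 2L, function(col) exp(stats::median(col[use] - loggeo[use])))
}

#' Absolute promoter activity
#'
#' `log2(raw / size_factor + 1)` per promoter and sample; the log2 scale on
#' which all downstream activity thresholds (minimum activity 0.25, fold
#' changes of group means) are interpreted.
#'
#' @param raw_counts promoters x samples count matrix.
#' @param size_factors per-sample positive size factors.
#' @return numeric matrix of the same shape.
#' @export
absolute_activity <- function(raw_counts, size_factors) {
  stopifnot(all(size_factors > 0),
            length(size_factors) == ncol(raw_counts))
  log2(sweep(as.matrix(raw_counts), 2L, size_factors, "/") + 1)
}

#' Relative promoter activity and gene-level activity
#'
#' Gene activity is the sum of absolute activities over the gene's
#' promoters; relative activity is each promoter's share of that sum (NA
#' when the gene's activity is zero in a sample).
#'
#' @param absolute promoters x samples matrix of absolute activity.
#' @param gene_ids gene id per promoter (row).
#' @return list with `relative` (promoters x samples, in \[0,1\] or NA) and
#'   `gene_absolute` (genes x samples).
#' @export
relative_activity <- function(absolute, gene_ids) {
  stopifnot(length(gene_ids) == nrow(absolute))
  gene_abs <- rowsum(absolute, gene_ids)
  denom <- gene_abs[gene_ids, , drop = FALSE]
  rel <- absolute / denom
  rel[denom == 0] <- NA_real_
  dimnames(rel) <- dimnames(absolute)
  list(relative = rel, gene_absolute = gene_abs)
}

#' Quantify promoter activity from junction tables
#'
#' End-to-end activity estimation: count unique junction reads at each
#' promoter's donor sites, optionally apply the promoter filters (see
#' [filter_promoters()]), normalise with median-of-ratios size factors and
#' derive absolute (log2) and relative activities.
#'
#' @param junctions named list of junction tables.
#' @param catalog a `promoter_annotation`.
#' @param design optional design table; required for the
#'   zero-in-both-conditions filter.
#' @param filter apply the single-exon and all-zero filters before
#'   normalisation.
#' @return an object of class `activity_matrix`: list with `raw_counts`,
#'   `size_factors`, `absolute`, `relative`, `gene_absolute`, `promoters`
#'   (metadata rows of the kept promoters), and `removed` (removal log).
#' @export
promoter_activity <- function(junctions, catalog, design = NULL,
                              filter = TRUE) {
  raw <- count_promoter_reads(junctions, catalog)
  act <- structure(list(raw_counts = raw, size_factors = NULL,
                        absolute = NULL, relative = NULL, gene_absolute = NULL,
                        promoters = catalog$promoters,
                        removed = data.frame(promoter_id = character(),
                                             reason = character())),
                   class = "activity_matrix")
  if (filter) act <- filter_promoters(act, design)
  act$size_factors <- estimate_size_factors(act$raw_counts)
  act$absolute <- absolute_activity(act$raw_counts, act$size_factors)
  ra <- relative_activity(act$absolute, act$promoters$gene_id)
  act$relative <- ra$relative
  act$gene_absolute <- ra$gene_absolute
  act
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("activity_matrix:", nrow(x$raw_counts), "promoters x",
      ncol(x$raw_counts), "samples;", nrow(x$removed), "removed\n")
  invisible(x)
}

#' Apply the promoter filters
#'
#' Drops promoters whose member transcripts are all single-exon (no donor
#' site, so junction counting cannot measure them) and promoters whose raw
#' counts are zero or NA in every tumor sample and in every normal sample.
#' A promoter expressed in only one condition is kept.
#'
#' @param activity an `activity_matrix` (only `raw_counts` and `promoters`
#'   need to be populated).
#' @param design design table labelling each sample tumor or normal; when
#'   `NULL` the all-zero filter is applied across all samples together.
#' @return the filtered `activity_matrix` with the removal log in
#'   `$removed`. Derived matrices (absolute/relative) are dropped and must
#'   be recomputed.
#' @export
filter_promoters <- function(activity, design = NULL) {
  stopifnot(inherits(activity, "activity_matrix"))
  raw <- activity$raw_counts
  prom <- activity$promoters
  prom <- prom[match(rownames(raw), prom$promoter_id), ]

  single <- prom$is_single_exon_only
  zero <- is.na(raw) | raw == 0
  if (!is.null(design)) {
    design <- as_design(design)
    check_design_samples(design, colnames(raw))
    tum <- design$sample_id[design$condition == "tumor"]
    nor <- design$sample_id[design$condition == "normal"]
    dead <- rowSums(!zero[, tum, drop = FALSE]) == 0 &
      rowSums(!zero[, nor, drop = FALSE]) == 0
  } else {
    dead <- rowSums(!zero) == 0
  }
  removed <- rbind(
    data.frame(promoter_id = prom$promoter_id[single],
               reason = rep("single_exon_only", sum(single))),
    data.frame(promoter_id = prom$promoter_id[dead & !single],
               reason = rep("zero_in_tumor_and_normal", sum(dead & !single)))
  )
  keep <- !(single | dead)
  activity$raw_counts <- raw[keep, , drop = FALSE]
  activity$promoters <- prom[keep, ]
  activity$removed <- rbind(activity$removed, removed)
  activity$absolute <- activity$relative <- activity$gene_absolute <- NULL
  activity$size_factors <- NULL
  activity
}
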