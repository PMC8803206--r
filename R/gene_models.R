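#' Parse transcript models from a GTF annotation
#'
#' Reads exon features from a Gencode-style GTF file and assembles one
#' transcript model per `transcript_id`. GTF coordinates (1-based, closed)
#' are converted to the package-internal 0-based half-open convention at
#' this boundary; all downstream coordinates (TSS, donor sites, CpG
#' positions) live in that convention.
#'
#' Exons are ordered in transcription direction (5' to 3'), so `rank == 1`
#' always denotes the first exon regardless of strand. The transcription
#' start site (`tss`) is the 0-based coordinate of the first transcribed
#' base: `start` of the first exon on `+`, `end - 1` on `-`.
#'
#' @param gtf path to a GTF file (or connection accepted by
#'   [rtracklayer::import()]).
#' @return an object of class `transcript_models`: a list with
#'   \describe{
#'     \item{exons}{data frame `transcript_id`, `gene_id`, `chrom`, `strand`,
#'       `start`, `end` (0-based half-open), `rank` (1 = first exon).}
#'     \item{transcripts}{data frame `transcript_id`, `gene_id`, `chrom`,
#'       `strand`, `tss`, `n_exons`.}
#'   }
#' @export
parse_gene_models <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  feat <- as.character(gr$type)
  ex <- gr[feat == "exon"]
  if (!length(ex)) stop("no exon features found in annotation", call. = FALSE)

  gene_id <- if (is.null(ex$gene_id)) rep(NA_character_, length(ex))
             else as.character(ex$gene_id)
  tx_id <- if (is.null(ex$transcript_id)) rep(NA_character_, length(ex))
           else as.character(ex$transcript_id)
  bad <- which(is.na(gene_id) | is.na(tx_id) | gene_id == "" | tx_id == "")
  if (length(bad)) {
    stop("exon record(s) missing gene_id/transcript_id attribute at exon line ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  # transcript features with no exon records are skipped with a warning
  tx_feat <- unique(as.character(gr$transcript_id[feat == "transcript"]))
  tx_feat <- tx_feat[!is.na(tx_feat)]
  orphans <- setdiff(tx_feat, unique(tx_id))
  if (length(orphans)) {
    warning("skipping ", length(orphans),
            " transcript(s) with no exon records: ",
            paste(utils::head(orphans, 5L), collapse = ", "), call. = FALSE)
  }

  exons <- data.frame(
    transcript_id = tx_id,
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(ex),
    stringsAsFactors = FALSE
  )
  if (any(exons$strand == "*")) {
    stop("exon records with undefined strand are not supported", call. = FALSE)
  }
  # transcription order: increasing start on +, decreasing on -
  ord <- order(exons$transcript_id, ifelse(exons$strand == "+", 1L, -1L) * exons$start)
  exons <- exons[ord, ]
  exons$rank <- stats::ave(seq_len(nrow(exons)), exons$transcript_id,
                           FUN = seq_along)

  first <- exons[exons$rank == 1L, ]
  n_ex <- table(exons$transcript_id)
  transcripts <- data.frame(
    transcript_id = first$transcript_id,
    gene_id = first$gene_id,
    chrom = first$chrom,
    strand = first$strand,
    tss = ifelse(first$strand == "+", first$start, first$end - 1L),
    n_exons = as.integer(n_ex[first$transcript_id]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(exons = exons, transcripts = transcripts),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x$transcripts), "transcripts,",
      length(unique(x$transcripts$gene_id)), "genes\n")
  invisible(x)
}

#' Build a promoter catalog by clustering first exons
#'
#' Within each gene (and strand), transcripts whose first exons overlap are
#' grouped into one promoter by single-linkage interval clustering: two
#' transcripts share a promoter iff their first exons can be connected by a
#' chain of pairwise-overlapping first exons. A promoter's representative
#' TSS is the most 5' transcription start among its members; its donor
#' sites are the first-exon 3'-end coordinates of its multi-exon members
#' (the positions where splice junctions leave the first exon).
#'
#' Promoter ids are assigned deterministically (`prmtr.1`, `prmtr.2`, ...)
#' after sorting promoters by chromosome, TSS and gene id, so the same
#' annotation always yields the same catalog regardless of input order.
#'
#' @param models a `transcript_models` object from [parse_gene_models()].
#' @param flag_internal also run [flag_internal_promoters()] on the result.
#' @return an object of class `promoter_annotation`: a list with
#'   \describe{
#'     \item{promoters}{data frame `promoter_id`, `gene_id`, `chrom`,
#'       `strand`, `tss`, `cluster_start`, `cluster_end` (0-based half-open
#'       span of the first-exon cluster), `n_members`,
#'       `is_single_exon_only`, `is_internal`.}
#'     \item{members}{data frame `promoter_id`, `transcript_id`.}
#'     \item{donors}{data frame `promoter_id`, `chrom`, `strand`, `donor`
#'       (0-based coordinate matched against intron boundaries: the
#'       half-open first-exon end on `+`, the first-exon start on `-`).}
#'   }
#' @export
build_promoters <- function(models, flag_internal = TRUE) {
  stopifnot(inherits(models, "transcript_models"))
  tr <- models$transcripts
  ex <- models$exons
  first <- ex[ex$rank == 1L, ]
  first <- first[match(tr$transcript_id, first$transcript_id), ]

  strands_per_gene <- rowsum(as.integer(tr$strand == "+"), tr$gene_id)
  n_per_gene <- table(tr$gene_id)[rownames(strands_per_gene)]
  mixed <- rownames(strands_per_gene)[strands_per_gene > 0 &
                                      strands_per_gene < as.integer(n_per_gene)]
  if (length(mixed)) {
    warning("gene(s) with transcripts on both strands, clustered per strand: ",
            paste(utils::head(mixed, 5L), collapse = ", "), call. = FALSE)
  }

  key <- paste(tr$gene_id, tr$strand, tr$chrom, sep = "\r")
  idx_by_key <- split(seq_len(nrow(tr)), key)

  rows <- vector("list", length(idx_by_key))
  memb <- vector("list", length(idx_by_key))
  for (k in seq_along(idx_by_key)) {
    idx <- idx_by_key[[k]]
    # IRanges are 1-based closed; [s,e) half-open maps to [s+1, e]
    ir <- IRanges::IRanges(first$start[idx] + 1L, first$end[idx])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # merge only true overlaps
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    cl <- integer(length(ir))
    cl[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)

    g <- tr$gene_id[idx[1L]]
    std <- tr$strand[idx[1L]]
    chr <- tr$chrom[idx[1L]]
    sub <- lapply(seq_along(red), function(ci) {
      ii <- idx[cl == ci]
      tss <- if (std == "+") min(tr$tss[ii]) else max(tr$tss[ii])
      multi <- ii[tr$n_exons[ii] >= 2L]
      donors <- if (std == "+") unique(first$end[multi]) else unique(first$start[multi])
      list(
        row = data.frame(
          gene_id = g, chrom = chr, strand = std, tss = tss,
          cluster_start = min(first$start[ii]),
          cluster_end = max(first$end[ii]),
          n_members = length(ii),
          is_single_exon_only = all(tr$n_exons[ii] == 1L),
          stringsAsFactors = FALSE
        ),
        transcripts = tr$transcript_id[ii],
        donors = donors
      )
    })
    rows[[k]] <- do.call(rbind, lapply(sub, `[[`, "row"))
    memb[[k]] <- sub
  }
  prom <- do.call(rbind, rows)
  flat <- unlist(memb, recursive = FALSE)

  ord <- order(prom$chrom, prom$tss, prom$gene_id)
  prom <- prom[ord, ]
  flat <- flat[ord]
  prom$promoter_id <- paste0("prmtr.", seq_len(nrow(prom)))
  rownames(prom) <- NULL
  prom <- prom[, c("promoter_id", "gene_id", "chrom", "strand", "tss",
                   "cluster_start", "cluster_end", "n_members",
                   "is_single_exon_only")]
  prom$is_internal <- NA

  members <- data.frame(
    promoter_id = rep(prom$promoter_id,
                      vapply(flat, function(s) length(s$transcripts), 0L)),
    transcript_id = unlist(lapply(flat, `[[`, "transcripts")),
    stringsAsFactors = FALSE
  )
  nd <- vapply(flat, function(s) length(s$donors), 0L)
  donors <- data.frame(
    promoter_id = rep(prom$promoter_id, nd),
    chrom = rep(prom$chrom, nd),
    strand = rep(prom$strand, nd),
    donor = unlist(lapply(flat, `[[`, "donors")),
    stringsAsFactors = FALSE
  )
  # clustering guarantees distinct promoters of a gene cannot share a donor
  key_d <- paste(prom$gene_id[match(donors$promoter_id, prom$promoter_id)],
                 donors$chrom, donors$strand, donors$donor)
  if (anyDuplicated(key_d)) {
    warning("donor site shared by two promoters of one gene; ",
            "junction reads will count toward each", call. = FALSE)
  }

  catalog <- structure(list(promoters = prom, members = members,
                            donors = donors),
                       class = "promoter_annotation")
  if (flag_internal) catalog <- flag_internal_promoters(catalog, models)
  catalog
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat("promoter_annotation:", nrow(x$promoters), "promoters,",
      length(unique(x$promoters$gene_id)), "genes\n")
  invisible(x)
}

#' Flag internal promoters
#'
#' A promoter is internal when its first-exon cluster overlaps a non-first
#' exon of another transcript of the same gene (a transcript that is not one
#' of the promoter's own members). Junction counts at internal promoters can
#' be inflated by splicing from upstream promoters, so the flag is carried
#' through the pipeline; counts are not adjusted.
#'
#' @param catalog a `promoter_annotation` from [build_promoters()].
#' @param models the `transcript_models` the catalog was built from (needed
#'   for the sibling internal exons).
#' @return the catalog with `promoters$is_internal` filled in.
#' @export
flag_internal_promoters <- function(catalog, models) {
  stopifnot(inherits(catalog, "promoter_annotation"),
            inherits(models, "transcript_models"))
  prom <- catalog$promoters
  internal_ex <- models$exons[models$exons$rank > 1L, ]
  flags <- logical(nrow(prom))
  if (nrow(internal_ex)) {
    pg <- GenomicRanges::GRanges(
      prom$chrom,
      IRanges::IRanges(prom$cluster_start + 1L, prom$cluster_end),
      strand = prom$strand
    )
    eg <- GenomicRanges::GRanges(
      internal_ex$chrom,
      IRanges::IRanges(internal_ex$start + 1L, internal_ex$end),
      strand = internal_ex$strand
    )
    hit <- GenomicRanges::findOverlaps(pg, eg)
    qh <- S4Vectors::queryHits(hit)
    sh <- S4Vectors::subjectHits(hit)
    same_gene <- prom$gene_id[qh] == internal_ex$gene_id[sh]
    # exclude hits from the promoter's own member transcripts
    memb_key <- paste(catalog$members$promoter_id, catalog$members$transcript_id)
    own <- paste(prom$promoter_id[qh], internal_ex$transcript_id[sh]) %in% memb_key
    keep <- same_gene & !own
    flags[unique(qh[keep])] <- TRUE
  }
  catalog$promoters$is_internal <- flags
  catalog
}

#' Write a promoter catalog to BED6+ and/or TSV
#'
#' The BED record spans the first-exon cluster (0-based half-open, as BED
#' requires), with the member count in the score column and `gene_id`,
#' `is_internal` appended as extra columns.
#'
#' @param catalog a `promoter_annotation`.
#' @param bed,tsv output paths; either may be `NULL`.
#' @return invisibly, the catalog.
#' @export
write_promoter_catalog <- function(catalog, bed = NULL, tsv = NULL) {
  prom <- catalog$promoters
  if (!is.null(bed)) {
    bed_df <- data.frame(prom$chrom, prom$cluster_start, prom$cluster_end,
                         prom$promoter_id, prom$n_members, prom$strand,
                         prom$gene_id, as.integer(prom$is_internal))
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv)) write_tsv(prom, tsv)
  invisible(catalog)
}
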