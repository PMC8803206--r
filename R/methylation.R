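#' Read a 450K-style beta matrix with a probe manifest
#'
#' The matrix TSV has one row per probe (first column: probe id) and one
#' column per sample; the manifest TSV locates each probe (`probe_id`,
#' `chrom`, `pos` with 1-based positions, converted internally to
#' 0-based). Probes absent from the manifest are dropped with a message;
#' betas outside \[0, 1\] (beyond a 1e-6 numerical slack) are an error.
#'
#' @param matrix_path,manifest_path TSV paths.
#' @return an object of class `methylation_matrix`: list with `probes`
#'   (data frame `probe_id`, `chrom`, `pos`), `beta` (probes x samples) and
#'   `source = "array"`.
#' @export
read_beta_matrix <- function(matrix_path, manifest_path) {
  mat <- data.table::fread(matrix_path, header = TRUE)
  man <- data.table::fread(manifest_path, header = TRUE)
  if (!all(c("probe_id", "chrom", "pos") %in% names(man))) {
    stop("manifest needs probe_id, chrom, pos columns", call. = FALSE)
  }
  probe_id <- as.character(mat[[1]])
  if (anyDuplicated(probe_id)) {
    stop("duplicate probe ids in beta matrix", call. = FALSE)
  }
  if (anyDuplicated(man$probe_id)) {
    stop("duplicate probe ids in manifest", call. = FALSE)
  }
  beta <- as.matrix(mat[, -1, drop = FALSE])
  rownames(beta) <- probe_id
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6) {
    stop("beta values outside [0, 1]", call. = FALSE)
  }
  beta[beta < 0] <- 0
  beta[beta > 1] <- 1

  located <- probe_id %in% man$probe_id
  if (any(!located)) {
    message(sum(!located), " probe(s) absent from manifest; dropped")
    beta <- beta[located, , drop = FALSE]
    probe_id <- probe_id[located]
  }
  mi <- match(probe_id, man$probe_id)
  probes <- data.frame(probe_id = probe_id,
                       chrom = as.character(man$chrom[mi]),
                       pos = as.integer(man$pos[mi]) - 1L,
                       stringsAsFactors = FALSE)
  structure(list(probes = probes, beta = beta, source = "array"),
            class = "methylation_matrix")
}

#' Read per-CpG WGBS methylation ratios
#'
#' Parses a bedGraph-like TSV (`chrom`, `start` 0-based, `end`, `ratio`,
#' optional `coverage`) of per-CpG methylation ratios, one file per
#' sample. Probe ids are synthesised as `chrom:pos`.
#'
#' @param paths one path or a vector of paths.
#' @param sample_ids sample names (defaults to file base names). With
#'   several samples the per-sample CpG sets are unioned and missing
#'   positions are NA.
#' @return a `methylation_matrix` with `source = "wgbs"` and, when a
#'   coverage column is present, a parallel `coverage` matrix.
#' @export
read_wgbs_ratios <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(paths) == length(sample_ids))
  tabs <- lapply(seq_along(paths), function(i) {
    dt <- data.table::fread(paths[i], header = FALSE)
    if (ncol(dt) < 4L) {
      stop("expected >= 4 columns in WGBS ratio file '", paths[i], "'",
           call. = FALSE)
    }
    bad <- which(dt[[4]] < 0 | dt[[4]] > 1 | is.na(dt[[4]]))
    if (length(bad)) {
      stop("methylation ratio outside [0, 1] at line ", bad[1L], " of '",
           paths[i], "'", call. = FALSE)
    }
    key <- paste0(dt[[1]], ":", dt[[2]])
    if (anyDuplicated(key)) {
      stop("duplicated CpG position in '", paths[i], "': ",
           key[which(duplicated(key))[1L]], call. = FALSE)
    }
    data.table::data.table(probe_id = key, chrom = as.character(dt[[1]]),
                           pos = as.integer(dt[[2]]), ratio = dt[[4]],
                           coverage = if (ncol(dt) >= 5L) as.integer(dt[[5]])
                                      else NA_integer_)
  })
  all_probes <- unique(data.table::rbindlist(
    lapply(tabs, function(t) t[, c("probe_id", "chrom", "pos")])))
  data.table::setorder(all_probes, chrom, pos)
  beta <- matrix(NA_real_, nrow(all_probes), length(tabs),
                 dimnames = list(all_probes$probe_id, sample_ids))
  cov <- matrix(NA_integer_, nrow(all_probes), length(tabs),
                dimnames = list(all_probes$probe_id, sample_ids))
  for (i in seq_along(tabs)) {
    mi <- match(tabs[[i]]$probe_id, all_probes$probe_id)
    beta[mi, i] <- tabs[[i]]$ratio
    cov[mi, i] <- tabs[[i]]$coverage
  }
  out <- structure(list(probes = as.data.frame(all_probes), beta = beta,
                        source = "wgbs"),
                   class = "methylation_matrix")
  if (!all(is.na(cov))) out$coverage <- cov
  out
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("methylation_matrix (", x$source, "): ", nrow(x$beta), " CpGs x ",
      ncol(x$beta), " samples\n", sep = "")
  invisible(x)
}

#' Per-CpG methylation difference between tumor and normal
#'
#' Delta beta = mean beta in tumor minus mean beta in normal samples
#' (NAs excluded per group); positive values indicate tumor
#' hypermethylation. NA when a group has no non-NA value for a probe.
#'
#' @param meth a `methylation_matrix`.
#' @param design design table.
#' @return data frame `probe_id`, `mean_tumor`, `mean_normal`,
#'   `delta_beta`.
#' @export
delta_beta <- function(meth, design) {
  design <- as_design(design)
  check_design_samples(design, colnames(meth$beta))
  tum <- design$sample_id[design$condition == "tumor"]
  nor <- design$sample_id[design$condition == "normal"]
  mt <- rowMeans(meth$beta[, tum, drop = FALSE], na.rm = TRUE)
  mn <- rowMeans(meth$beta[, nor, drop = FALSE], na.rm = TRUE)
  mt[is.nan(mt)] <- NA_real_
  mn[is.nan(mn)] <- NA_real_
  data.frame(probe_id = meth$probes$probe_id, mean_tumor = unname(mt),
             mean_normal = unname(mn), delta_beta = unname(mt - mn),
             stringsAsFactors = FALSE)
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, as
#' provided by [stats::cor.test()]. Pairs with a missing value are
#' dropped; fewer than 3 complete pairs or a constant vector yields NA.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p` and the number of complete pairs `n`.
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

# signed strand-aware distance from a promoter TSS to probe positions:
# negative = upstream of the TSS in transcription direction
signed_tss_distance <- function(pos, tss, strand) {
  if (strand == "+") pos - tss else tss - pos
}

# candidate probes within +/- window of a promoter TSS (inclusive endpoints)
probes_near_tss <- function(probes, chrom, tss, window) {
  sel <- probes$chrom == chrom & abs(probes$pos - tss) <= window
  which(sel)
}

#' Select the representative CpG of each promoter
#'
#' For every promoter, all CpGs within +/- `window` bp of its TSS
#' (inclusive endpoints) are tested for Pearson correlation between their
#' methylation betas and the promoter's absolute activity across the
#' pooled tumor and normal samples; the CpG with the minimum correlation
#' p-value represents the promoter. Ties are broken by smaller
#' `|dist_to_tss|`, then by probe id. Promoters with no CpG in the window
#' or only undefined correlations are omitted.
#'
#' @param catalog a `promoter_annotation` (or an `activity_matrix`'s
#'   `promoters` data frame).
#' @param meth a `methylation_matrix`.
#' @param activity an `activity_matrix` or a promoters x samples absolute
#'   activity matrix.
#' @param window half-width around the TSS in bp (default 1000).
#' @param samples optional sample subset to correlate over (default: all
#'   samples shared between the two matrices).
#' @return data frame (`CpGPromoterLink`): `promoter_id`, `probe_id`,
#'   `chrom`, `pos`, `dist_to_tss` (signed, negative = upstream), `r`,
#'   `p`, `n_samples`.
#' @export
select_representative_cpg <- function(catalog, meth, activity,
                                      window = 1000, samples = NULL) {
  prom <- if (inherits(catalog, "promoter_annotation")) catalog$promoters
          else catalog
  absmat <- if (inherits(activity, "activity_matrix")) activity$absolute
            else activity
  prom <- prom[prom$promoter_id %in% rownames(absmat), ]
  shared <- intersect(colnames(absmat), colnames(meth$beta))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 3L) {
    stop("need >= 3 samples shared between activity and methylation",
         call. = FALSE)
  }
  probes <- meth$probes
  res <- vector("list", nrow(prom))
  for (i in seq_len(nrow(prom))) {
    cand <- probes_near_tss(probes, prom$chrom[i], prom$tss[i], window)
    if (!length(cand)) next
    act <- absmat[prom$promoter_id[i], shared]
    stats_i <- lapply(cand, function(ci) {
      pearson_test(meth$beta[ci, shared], act)
    })
    p <- vapply(stats_i, `[[`, 0, "p")
    if (all(is.na(p))) next
    d <- signed_tss_distance(probes$pos[cand], prom$tss[i], prom$strand[i])
    ord <- order(p, abs(d), probes$probe_id[cand], na.last = TRUE)
    b <- ord[1L]
    res[[i]] <- data.frame(
      promoter_id = prom$promoter_id[i],
      probe_id = probes$probe_id[cand[b]],
      chrom = probes$chrom[cand[b]],
      pos = probes$pos[cand[b]],
      dist_to_tss = d[b],
      r = stats_i[[b]]$r,
      p = stats_i[[b]]$p,
      n_samples = stats_i[[b]]$n,
      stringsAsFactors = FALSE
    )
  }
  dropped <- sum(vapply(res, is.null, TRUE))
  if (dropped) {
    message(dropped, " promoter(s) without a usable CpG within +/-",
            window, " bp")
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  out %||% data.frame(promoter_id = character(), probe_id = character(),
                      chrom = character(), pos = integer(),
                      dist_to_tss = integer(), r = numeric(), p = numeric(),
                      n_samples = integer())
}

#' Smoothed TSS methylation profile
#'
#' Aggregates CpG methylation around the TSSs of a promoter set into a
#' profile over \[-window, +window\] bp (strand-aware signed distances).
#' The default smoother is the mean beta per `win_size`-bp window advanced
#' by `step` bp (50/25 by default); `mode = "gam"` instead fits a
#' generalised additive model (thin-plate spline of distance) to the
#' probe-level group means and evaluates it at the window midpoints.
#'
#' @param meth a `methylation_matrix`.
#' @param catalog a `promoter_annotation` or promoters data frame.
#' @param design design table; one profile per condition.
#' @param promoter_ids optional subset of promoters.
#' @param window,win_size,step profile geometry in bp.
#' @param mode `"window"` or `"gam"`.
#' @return data frame `group`, `start`, `mid`, `end`, `mean_beta`,
#'   `n_probes` (windows without probes have NA mean).
#' @export
tss_methylation_profile <- function(meth, catalog, design,
                                    promoter_ids = NULL, window = 2000,
                                    win_size = 50, step = 25,
                                    mode = c("window", "gam")) {
  mode <- match.arg(mode)
  design <- as_design(design)
  check_design_samples(design, colnames(meth$beta))
  prom <- if (inherits(catalog, "promoter_annotation")) catalog$promoters
          else catalog
  if (!is.null(promoter_ids)) {
    prom <- prom[prom$promoter_id %in% promoter_ids, ]
  }
  starts <- seq(-window, window - win_size, by = step)
  groups <- split(design$sample_id, design$condition)

  # probe-to-promoter distances (a probe may flank several promoters)
  dist_tab <- do.call(rbind, lapply(seq_len(nrow(prom)), function(i) {
    cand <- probes_near_tss(meth$probes, prom$chrom[i], prom$tss[i], window)
    if (!length(cand)) return(NULL)
    data.frame(probe = cand,
               dist = signed_tss_distance(meth$probes$pos[cand],
                                          prom$tss[i], prom$strand[i]))
  }))
  out <- lapply(names(groups), function(g) {
    base <- data.frame(group = g, start = starts, mid = starts + win_size / 2,
                       end = starts + win_size, mean_beta = NA_real_,
                       n_probes = 0L, stringsAsFactors = FALSE)
    if (is.null(dist_tab) || !nrow(dist_tab)) return(base)
    pb <- rowMeans(meth$beta[dist_tab$probe, groups[[g]], drop = FALSE],
                   na.rm = TRUE)
    ok <- is.finite(pb)
    d <- dist_tab$dist[ok]; pb <- pb[ok]
    if (!length(pb)) return(base)
    if (mode == "window") {
      for (w in seq_along(starts)) {
        inw <- d >= starts[w] & d < starts[w] + win_size
        base$n_probes[w] <- sum(inw)
        if (any(inw)) base$mean_beta[w] <- mean(pb[inw])
      }
    } else {
      k <- max(4L, min(30L, length(unique(d)) - 1L))
      fit <- mgcv::gam(pb ~ s(d, k = k))
      base$mean_beta <- as.numeric(
        stats::predict(fit, newdata = data.frame(d = base$mid)))
      for (w in seq_along(starts)) {
        base$n_probes[w] <- sum(d >= starts[w] & d < starts[w] + win_size)
      }
    }
    base
  })
  do.call(rbind, out)
}

#' TSS methylation profiles by promoter-activity quartile
#'
#' Within each condition, promoters are ranked by their mean absolute
#' activity (ties broken by promoter id for determinism) and split into
#' four equal-size quartile groups (Q1 lowest activity ... Q4 highest); a
#' TSS methylation profile is computed per quartile from that condition's
#' samples.
#'
#' @inheritParams tss_methylation_profile
#' @param activity an `activity_matrix` or absolute activity matrix.
#' @return data frame `condition`, `quartile` (`Q1`..`Q4`) plus the
#'   [tss_methylation_profile()] columns.
#' @export
activity_quartile_profiles <- function(activity, meth, catalog, design,
                                       window = 2000, win_size = 50,
                                       step = 25, mode = c("window", "gam")) {
  mode <- match.arg(mode)
  design <- as_design(design)
  absmat <- if (inherits(activity, "activity_matrix")) activity$absolute
            else activity
  if (nrow(absmat) < 4L) stop("need >= 4 promoters", call. = FALSE)
  out <- lapply(unique(design$condition), function(cond) {
    ids <- design$sample_id[design$condition == cond]
    m <- rowMeans(absmat[, ids, drop = FALSE], na.rm = TRUE)
    ord <- order(m, rownames(absmat))
    q <- integer(length(m))
    q[ord] <- ceiling(4 * seq_along(ord) / length(ord))
    sub_design <- design[design$condition == cond, ]
    res <- lapply(1:4, function(k) {
      prof <- tss_methylation_profile(
        meth, catalog, sub_design,
        promoter_ids = rownames(absmat)[q == k],
        window = window, win_size = win_size, step = step, mode = mode)
      data.frame(condition = cond, quartile = paste0("Q", k),
                 prof[, setdiff(names(prof), "group")],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  do.call(rbind, out)
}

#' Mean promoter-region methylation per sample
#'
#' Per-sample mean of the betas of all CpGs within +/- `window` bp of each
#' promoter's TSS. With `require_full_coverage` only CpGs measured
#' (non-NA) in every sample enter the mean — the WGBS regional fallback
#' used when a single CpG is not covered in all samples.
#'
#' @param meth a `methylation_matrix`.
#' @param catalog a `promoter_annotation` or promoters data frame.
#' @param promoter_ids optional subset.
#' @param window half-width in bp (default 1000).
#' @param require_full_coverage restrict to CpGs non-NA in all samples.
#' @return matrix promoters x samples (NA where no CpG qualifies).
#' @export
promoter_region_mean <- function(meth, catalog, promoter_ids = NULL,
                                 window = 1000,
                                 require_full_coverage = FALSE) {
  prom <- if (inherits(catalog, "promoter_annotation")) catalog$promoters
          else catalog
  if (!is.null(promoter_ids)) {
    prom <- prom[prom$promoter_id %in% promoter_ids, ]
  }
  out <- matrix(NA_real_, nrow(prom), ncol(meth$beta),
                dimnames = list(prom$promoter_id, colnames(meth$beta)))
  for (i in seq_len(nrow(prom))) {
    cand <- probes_near_tss(meth$probes, prom$chrom[i], prom$tss[i], window)
    if (!length(cand)) next
    b <- meth$beta[cand, , drop = FALSE]
    if (require_full_coverage) {
      full <- rowSums(is.na(b)) == 0
      if (!any(full)) next
      b <- b[full, , drop = FALSE]
    }
    m <- colMeans(b, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    out[i, ] <- m
  }
  out
}
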