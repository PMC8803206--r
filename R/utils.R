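# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate and normalise a sample design table
#'
#' The design table maps samples to conditions and tumor/normal pairs. It is
#' accepted as a data frame with columns `sample_id`, `condition`
#' (`"tumor"` or `"normal"`) and `pair_id`, plus an optional `path` column
#' pointing at a per-sample splice-junction file.
#'
#' @param design data frame with at least `sample_id` and `condition`.
#' @param require_pairs require a `pair_id` column with complete tumor/normal
#'   pairs.
#' @return the design as a plain data frame with character `sample_id`,
#'   `condition` and (if present) `pair_id`.
#' @export
as_design <- function(design, require_pairs = FALSE) {
  design <- as.data.frame(design)
  needed <- c("sample_id", "condition")
  miss <- setdiff(needed, names(design))
  if (length(miss)) {
    stop("design table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  design$sample_id <- as.character(design$sample_id)
  design$condition <- as.character(design$condition)
  if (anyDuplicated(design$sample_id)) {
    stop("duplicated sample ids in design table", call. = FALSE)
  }
  bad <- setdiff(unique(design$condition), c("tumor", "normal"))
  if (length(bad)) {
    stop("condition must be 'tumor' or 'normal'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("pair_id" %in% names(design)) design$pair_id <- as.character(design$pair_id)
  if (require_pairs) {
    if (!"pair_id" %in% names(design)) {
      stop("design table lacks a pair_id column", call. = FALSE)
    }
    tab <- table(design$pair_id, design$condition)
    if (!all(tab == 1L)) {
      stop("each pair_id must map to exactly one tumor and one normal sample",
           call. = FALSE)
    }
  }
  design
}

# Match design rows against the columns of a sample matrix; errors name the
# unmatched samples (both directions).
check_design_samples <- function(design, sample_names) {
  missing_in_mat <- setdiff(design$sample_id, sample_names)
  if (length(missing_in_mat)) {
    stop("design samples absent from the matrix: ",
         paste(missing_in_mat, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Align tumor and normal columns of `mat` pair by pair. Returns a list with
# tumor and normal sample id vectors in matching pair order.
paired_samples <- function(design) {
  design <- as_design(design, require_pairs = TRUE)
  tum <- design[design$condition == "tumor", ]
  nor <- design[design$condition == "normal", ]
  nor <- nor[match(tum$pair_id, nor$pair_id), ]
  list(tumor = tum$sample_id, normal = nor$sample_id, pair_id = tum$pair_id)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

# make data.table syntax work inside the package namespace
.datatable.aware <- TRUE
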