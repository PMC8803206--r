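#' Fit the L1-penalised logistic diagnostic model
#'
#' LASSO logistic regression of tumor/normal status on promoter
#' activities. The penalty is chosen by k-fold cross-validation with a
#' fold assignment fixed by `seed` (binomial deviance loss); the default
#' rule takes the deviance-minimising lambda, `rule = "1se"` the sparsest
#' model within one standard error. Features are standardised internally
#' by glmnet; coefficients are returned on the original activity scale.
#'
#' @param activity features x samples matrix (promoters in rows).
#' @param labels condition per sample (`"tumor"`/`"normal"`), or a design
#'   table.
#' @param nfolds cross-validation folds (default 10).
#' @param seed integer fixing the fold assignment.
#' @param rule `"min"` or `"1se"`.
#' @return an object of class `diagnostic_model`: list with
#'   `selected_promoters`, `coefficients` (named, selected only),
#'   `intercept`, `lambda`, `cv_folds`, `rule` and the underlying
#'   `cv.glmnet` fit (`cv_fit`, absent for the degenerate all-zero case).
#' @export
fit_diagnostic <- function(activity, labels, nfolds = 10, seed = 1,
                           rule = c("min", "1se")) {
  rule <- match.arg(rule)
  if (is.data.frame(labels) || !is.null(dim(labels))) {
    design <- as_design(labels)
    labels <- design$condition[match(colnames(activity), design$sample_id)]
  }
  y <- as.integer(labels == "tumor")
  if (length(unique(y)) < 2L) {
    stop("both tumor and normal samples are required", call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("need >= 2 samples per class", call. = FALSE)
  }
  x <- t(as.matrix(activity))
  if (all(x == 0)) {
    p1 <- mean(y)
    return(structure(list(selected_promoters = character(0),
                          coefficients = numeric(0),
                          intercept = stats::qlogis(p1),
                          lambda = Inf, cv_folds = nfolds, rule = rule),
                     class = "diagnostic_model"))
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = length(y)))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance", standardize = TRUE)
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  co <- as.matrix(stats::coef(cv, s = lam))[, 1L]
  sel <- co[-1L][co[-1L] != 0]
  structure(list(selected_promoters = names(sel),
                 coefficients = sel,
                 intercept = unname(co[1L]),
                 lambda = lam, cv_folds = nfolds, rule = rule,
                 cv_fit = cv),
            class = "diagnostic_model")
}

#' @export
print.diagnostic_model <- function(x, ...) {
  cat("diagnostic_model:", length(x$selected_promoters),
      "selected promoter(s), lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}

#' Diagnostic model score per sample
#'
#' `score = sum(promoter activity x regression coefficient)` over the
#' selected promoters — the printed linear score without the intercept
#' (ROC performance is intercept-invariant).
#'
#' @param model a `diagnostic_model`.
#' @param activity features x samples matrix containing all selected
#'   promoters.
#' @return named numeric vector of scores, one per sample.
#' @export
score_samples <- function(model, activity) {
  sel <- model$selected_promoters
  if (!length(sel)) {
    return(stats::setNames(rep(0, ncol(activity)), colnames(activity)))
  }
  missing <- setdiff(sel, rownames(activity))
  if (length(missing)) {
    stop("selected promoter(s) missing from activity matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  colSums(activity[sel, , drop = FALSE] * model$coefficients)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed as the normalised Mann-Whitney U
#' statistic; tied scores contribute 1/2 via midranks.
#'
#' @param scores numeric score per sample (higher = more tumor-like).
#' @param labels `"tumor"`/`"normal"` (or logical/0-1 with `TRUE`/1 as the
#'   positive class).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels)) {
    as.character(labels) == "tumor"
  } else as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Standardised two-group log-rank statistic (O - E) / sqrt(V) for the
# group flagged TRUE; O(n log n), matches survival::survdiff's chi-square
# as stat^2.
logrank_stat <- function(time, event, group) {
  o <- order(time)
  t_ <- time[o]; e <- as.integer(event[o]); g <- as.integer(group[o])
  n <- length(t_)
  first <- which(!duplicated(t_))
  gid <- cumsum(!duplicated(t_))
  n_at <- n - first + 1L
  n1_at <- rev(cumsum(rev(g)))[first]
  d <- rowsum(e, gid)[, 1L]
  d1 <- rowsum(e * g, gid)[, 1L]
  keep <- d > 0
  nj <- n_at[keep]; n1j <- n1_at[keep]; dj <- d[keep]; d1j <- d1[keep]
  O <- sum(d1j)
  E <- sum(dj * n1j / nj)
  vterm <- ifelse(nj > 1, dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1), 0)
  V <- sum(vterm)
  list(o_minus_e = O - E, v = V,
       stat = if (V > 0) (O - E) / sqrt(V) else NA_real_)
}

#' Maximally selected survival cutpoint
#'
#' Reimplementation of the "best cutoff" dichotomisation: every midpoint
#' between consecutive distinct values of `betas` defines a candidate
#' high/low split; candidates leaving either group below `minprop * n`
#' subjects are discarded, and among the rest the threshold maximising
#' the absolute standardised log-rank statistic is returned (ties go to
#' the lower threshold). The associated p-value reported downstream is
#' the naive log-rank p at the chosen cutpoint, with no correction for
#' the selection.
#'
#' @param betas numeric marker values (e.g. CpG methylation betas).
#' @param times,events survival times and event indicators (1 = event).
#' @param minprop minimum fraction of subjects per group (default 0.1).
#' @return list with `cutpoint`, `statistic` (standardised log-rank at the
#'   cutpoint), `n_high`, `n_low`, and the `candidates` table.
#' @export
optimal_cutpoint <- function(betas, times, events, minprop = 0.1) {
  ok <- is.finite(betas) & is.finite(times) & !is.na(events)
  betas <- betas[ok]; times <- times[ok]; events <- as.integer(events[ok])
  n <- length(betas)
  u <- sort(unique(betas))
  if (length(u) < 2L) {
    stop("need >= 2 distinct marker values", call. = FALSE)
  }
  cand <- (u[-length(u)] + u[-1L]) / 2
  n_high <- vapply(cand, function(cc) sum(betas > cc), 0L)
  eligible <- n_high >= minprop * n & (n - n_high) >= minprop * n
  if (!any(eligible)) {
    stop("no candidate cutpoint satisfies the minprop constraint",
         call. = FALSE)
  }
  cand <- cand[eligible]; n_high <- n_high[eligible]
  stat <- vapply(cand, function(cc) {
    logrank_stat(times, events, betas > cc)$stat
  }, 0)
  best <- which(abs(stat) == max(abs(stat), na.rm = TRUE))[1L]
  list(cutpoint = cand[best], statistic = stat[best],
       n_high = n_high[best], n_low = n - n_high[best],
       candidates = data.frame(cutpoint = cand, statistic = stat,
                               n_high = n_high))
}

#' Kaplan-Meier comparison of two groups with a fixed horizon
#'
#' Administratively censors all follow-up at `horizon` (events beyond it
#' become censored at the horizon), estimates Kaplan-Meier curves per
#' group and tests the difference with the two-group log-rank test. The
#' direction reports which group's survival dominates, from the sign of
#' observed minus expected events.
#'
#' @param group logical or two-level vector; `TRUE` (or the second level)
#'   is the "high" group.
#' @param times,events survival data; times in the same unit as
#'   `horizon`.
#' @param horizon administrative censoring horizon (default 3652.5, ten
#'   years in days).
#' @return list with `logrank_p`, `chisq`, `direction`
#'   (`"high_better"`/`"low_better"`/`"equal"`), `n_high`, `n_low` and the
#'   [survival::survfit] object `fit`.
#' @export
km_logrank <- function(group, times, events, horizon = 3652.5) {
  if (is.factor(group)) group <- group == levels(group)[2L]
  if (!is.logical(group)) group <- as.logical(group)
  if (!any(group) || !any(!group)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  events <- as.integer(events)
  over <- times > horizon
  events[over] <- 0L
  times[over] <- horizon
  grp <- factor(ifelse(group, "high", "low"), levels = c("low", "high"))
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  # fewer observed than expected events in the high group = longer survival
  ome_high <- sd_$obs[2L] - sd_$exp[2L]
  direction <- if (ome_high < 0) "high_better"
               else if (ome_high > 0) "low_better" else "equal"
  fit <- survival::survfit(survival::Surv(times, events) ~ grp)
  list(logrank_p = p, chisq = unname(sd_$chisq), direction = direction,
       n_high = sum(group), n_low = sum(!group), fit = fit)
}

#' Prognostic evaluation of mrAP methylation markers
#'
#' For each mrAP's representative CpG found in the clinical cohort's beta
#' matrix, the cohort is split at the maximally selected cutpoint
#' ([optimal_cutpoint()]) and the two methylation groups are compared by
#' the 10-year log-rank test ([km_logrank()]). The marker is prognostic
#' when the log-rank p is below `p_cut`. Probes absent from the cohort
#' are reported `untestable` and excluded from the prognostic-fraction
#' denominator.
#'
#' @param links mrAP links (`promoter_id`, `probe_id`).
#' @param cohort_beta probes x subjects beta matrix.
#' @param clinical data frame `sample_id`, `time`, `event` matching the
#'   cohort columns.
#' @param minprop,horizon,p_cut see [optimal_cutpoint()] and
#'   [km_logrank()].
#' @return data frame `promoter_id`, `probe_id`, `testable`, `cutpoint`,
#'   `n_high`, `n_low`, `logrank_p`, `direction`
#'   (`high_meth_better`/`low_meth_better`), `is_prognostic`.
#' @export
flag_prognostic_mraps <- function(links, cohort_beta, clinical,
                                  minprop = 0.1, horizon = 3652.5,
                                  p_cut = 0.05) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(clinical)))
  subj <- intersect(colnames(cohort_beta), clinical$sample_id)
  ci <- match(subj, clinical$sample_id)
  times <- clinical$time[ci]
  events <- as.integer(clinical$event[ci])
  res <- lapply(seq_len(nrow(links)), function(i) {
    pid <- links$probe_id[i]
    base <- data.frame(promoter_id = links$promoter_id[i], probe_id = pid,
                       testable = FALSE, cutpoint = NA_real_,
                       n_high = NA_integer_, n_low = NA_integer_,
                       logrank_p = NA_real_, direction = NA_character_,
                       is_prognostic = NA, stringsAsFactors = FALSE)
    if (!pid %in% rownames(cohort_beta)) return(base)
    b <- cohort_beta[pid, subj]
    out <- tryCatch({
      cp <- optimal_cutpoint(b, times, events, minprop = minprop)
      km <- km_logrank(b > cp$cutpoint, times, events, horizon = horizon)
      base$testable <- TRUE
      base$cutpoint <- cp$cutpoint
      base$n_high <- km$n_high
      base$n_low <- km$n_low
      base$logrank_p <- km$logrank_p
      base$direction <- sub("^(high|low)_", "\\1_meth_", km$direction)
      base$is_prognostic <- km$logrank_p < p_cut
      base
    }, error = function(e) base)
    out
  })
  do.call(rbind, res)
}
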