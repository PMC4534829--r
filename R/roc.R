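#' Empirical AUC (Mann-Whitney estimator)
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic: the
#' proportion of case/control pairs in which the case outscores the control,
#' with ties credited one half. Equivalent to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param case_scores numeric vector of scores for cases.
#' @param control_scores numeric vector of scores for controls.
#' @return AUC in \[0, 1\].
#' @examples
#' empirical_auc(c(3, 1), c(2, 0))  # 0.75
#' @export
empirical_auc <- function(case_scores, control_scores) {
  m <- length(case_scores)
  n <- length(control_scores)
  if (m == 0L || n == 0L) {
    stop("empirical_auc: both score vectors must be non-empty")
  }
  r <- rank(c(case_scores, control_scores), ties.method = "average")
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u / (m * n)
}

#' Empirical ROC curve
#'
#' Returns the ROC operating points swept over all distinct score
#' thresholds, from (0, 0) to (1, 1). Tied scores share an operating point,
#' so the trapezoidal area under this curve equals [empirical_auc()].
#'
#' @inheritParams empirical_auc
#' @return data.frame with columns `fpr`, `tpr`, both monotone nondecreasing.
#' @export
roc_curve <- function(case_scores, control_scores) {
  thr <- sort(unique(c(case_scores, control_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(case_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(control_scores >= t), numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

# DeLong placement values: for each case, the fraction of controls it beats
# (ties half); for each control, the fraction of cases beating it. Computed
# with midranks in O((m+n) log(m+n)).
delong_placements <- function(case_scores, control_scores) {
  m <- length(case_scores)
  n <- length(control_scores)
  r_all <- rank(c(case_scores, control_scores), ties.method = "average")
  r_x <- rank(case_scores, ties.method = "average")
  r_y <- rank(control_scores, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n            # per-case placement
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m    # per-control placement
  list(v10 = v10, v01 = v01)
}

#' AUC with DeLong confidence interval
#'
#' Computes the empirical AUC together with a normal-approximation
#' confidence interval based on the DeLong variance estimator (the
#' structural-components variance of the Mann-Whitney statistic). The
#' interval is clamped to \[0, 1\]; degenerate data (zero variance, e.g.
#' perfect separation) yield a collapsed interval rather than an error.
#'
#' @inheritParams empirical_auc
#' @param level confidence level, default 0.95.
#' @param curve logical; include the ROC curve in the result (default TRUE).
#' @return object of class `roc_result`: list with `auc`, `ci_lower`,
#'   `ci_upper`, `ci_level`, `se`, and (optionally) `curve`.
#' @export
auc_ci <- function(case_scores, control_scores, level = 0.95, curve = TRUE) {
  m <- length(case_scores)
  n <- length(control_scores)
  if (m < 2L || n < 2L) {
    stop("auc_ci: need at least 2 scores per arm")
  }
  auc <- empirical_auc(case_scores, control_scores)
  pl <- delong_placements(case_scores, control_scores)
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  res <- list(
    auc = auc,
    ci_lower = max(0, auc - z * se),
    ci_upper = min(1, auc + z * se),
    ci_level = level,
    se = se,
    curve = if (curve) roc_curve(case_scores, control_scores) else NULL
  )
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$auc, 100 * x$ci_level, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Global ROC statistic across sub-phenotype groups
#'
#' Summarises multi-group classification accuracy as the case-count-weighted
#' mean of the per-group one-vs-controls AUCs. Weighting by case count
#' reflects that pooling genetically homogeneous sub-phenotypes should be
#' rewarded for the precision gained on the larger groups. An unweighted
#' mean is available via `weighted = FALSE`.
#'
#' @param group_aucs named numeric vector: one AUC per group.
#' @param case_counts named numeric vector of case counts, same names.
#' @param weighted logical; default TRUE (weights = case counts).
#' @return object of class `global_roc`: list with `value` and `per_group`
#'   (data.frame group, auc, weight).
#' @export
global_roc <- function(group_aucs, case_counts, weighted = TRUE) {
  stopifnot(length(group_aucs) == length(case_counts))
  if (!is.null(names(group_aucs)) && !is.null(names(case_counts))) {
    case_counts <- case_counts[names(group_aucs)]
  }
  if (any(case_counts <= 0)) {
    stop("global_roc: every group must have at least one case")
  }
  w <- if (weighted) as.numeric(case_counts) else rep(1, length(group_aucs))
  res <- list(
    value = sum(w * group_aucs) / sum(w),
    per_group = data.frame(
      group = if (is.null(names(group_aucs))) seq_along(group_aucs)
              else names(group_aucs),
      auc = as.numeric(group_aucs),
      weight = as.numeric(case_counts),
      row.names = NULL
    )
  )
  class(res) <- "global_roc"
  res
}

# AUC directly from per-cell case/control counts given a score per cell.
# Used in the forward-selection inner loop where scores are constant within
# each genotype combination: O(#cells log #cells) instead of O(n log n).
auc_from_cell_counts <- function(cell_scores, case_counts, control_counts) {
  a_tot <- sum(case_counts)
  b_tot <- sum(control_counts)
  if (a_tot == 0 || b_tot == 0) {
    stop("auc_from_cell_counts: empty arm")
  }
  keep <- case_counts > 0 | control_counts > 0
  cell_scores <- cell_scores[keep]
  case_counts <- case_counts[keep]
  control_counts <- control_counts[keep]
  o <- order(cell_scores)
  s <- cell_scores[o]
  # merge tied score values (comparison, not diff: robust to Inf scores)
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  ab <- rowsum(cbind(case_counts[o], control_counts[o]), grp)
  a <- ab[, 1]
  b <- ab[, 2]
  cum_b <- cumsum(b) - b  # controls strictly below each tied block
  (sum(a * cum_b) + 0.5 * sum(a * b)) / (a_tot * b_tot)
}
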