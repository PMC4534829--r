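#' Cross-validated choice of the number of sub-phenotype groups
#'
#' Splits samples into K stratified folds (by label, so every sub-phenotype
#' and the controls appear in every fold), builds the full agglomerative
#' merge path on each training set, and evaluates every level of that path
#' on the held-out fold: each training-fold model scores the held-out cases
#' of its group against the held-out controls, and the held-out global ROC
#' statistic is recorded per group count. The merge order is decided
#' entirely on the training folds; held-out samples never influence which
#' groups merge. The selected group count maximises the mean held-out
#' global ROC across folds, with ties resolved toward fewer groups
#' (parsimony, larger per-group sample size).
#'
#' @param geno a `genotype_matrix`.
#' @param pheno a `phenotype_table` (already filtered).
#' @param folds number of CV folds (default 5).
#' @param config a `selection_config`.
#' @param seed seed for the fold assignment.
#' @param grouping_initial initial grouping (default: one group per
#'   sub-phenotype).
#' @return object of class `cv_result`: `folds`, `per_fold` (matrix, group
#'   count x fold, held-out global ROC), `mean_cv_global_roc` (named
#'   vector), `selected_group_count`, `seed`.
#' @export
cross_validate_group_count <- function(geno, pheno, folds = 5,
                                       config = selection_config(),
                                       seed = 1L,
                                       grouping_initial = NULL) {
  stopifnot(folds >= 2)
  counts <- label_counts(pheno)
  small <- names(counts)[counts < folds]
  if (length(small) > 0) {
    stop("cross_validate_group_count: label(s) with fewer samples than folds (would leave a fold with an empty group): ",
         paste(small, collapse = ", "))
  }
  if (is.null(grouping_initial)) {
    grouping_initial <- stats::setNames(as.list(pheno$case_labels),
                                        pheno$case_labels)
  }
  k_init <- length(grouping_initial)
  set.seed(seed)
  fold_of <- stats::setNames(integer(nrow(pheno$samples)),
                             pheno$samples$sample_id)
  for (lab in c(pheno$control_label, pheno$case_labels)) {
    ids <- samples_with_label(pheno, lab)
    fold_of[ids] <- fold_assignment(length(ids), folds)
  }
  per_fold <- matrix(NA_real_, nrow = k_init, ncol = folds,
                     dimnames = list(as.character(k_init:1), NULL))
  for (f in seq_len(folds)) {
    test_ids <- names(fold_of)[fold_of == f]
    train <- subset_phenotypes(pheno, setdiff(pheno$samples$sample_id,
                                              test_ids))
    path <- merge_path(geno, train, config, grouping_initial)
    test_pheno <- subset_phenotypes(pheno, test_ids)
    test_controls <- samples_with_label(test_pheno,
                                        test_pheno$control_label)
    for (lv in path$levels) {
      aucs <- numeric(lv$n_groups)
      wts <- numeric(lv$n_groups)
      gi <- 0L
      for (g in names(lv$grouping)) {
        gi <- gi + 1L
        test_cases <- samples_with_label(test_pheno, lv$grouping[[g]])
        cs <- score_samples(lv$models[[g]], geno, test_cases)
        ns <- score_samples(lv$models[[g]], geno, test_controls)
        aucs[gi] <- empirical_auc(cs, ns)
        wts[gi] <- length(test_cases)
      }
      per_fold[as.character(lv$n_groups), f] <-
        global_roc(aucs, wts)$value
    }
  }
  mean_roc <- rowMeans(per_fold)
  best <- max(mean_roc)
  cand <- as.integer(names(mean_roc)[mean_roc >= best - 1e-12])
  structure(list(folds = folds, per_fold = per_fold,
                 mean_cv_global_roc = mean_roc,
                 selected_group_count = min(cand),
                 seed = seed),
            class = "cv_result")
}

# restrict a phenotype table to a subset of samples (control label kept
# even if no control remains is not allowed; callers keep controls in
# every fold by stratified assignment)
subset_phenotypes <- function(pheno, sample_ids) {
  keep <- pheno$samples$sample_id %in% sample_ids
  out <- phenotype_table(pheno$samples$sample_id[keep],
                         pheno$samples$label[keep],
                         pheno$control_label)
  # preserve the original case-label order for determinism
  out$case_labels <- intersect(pheno$case_labels, out$case_labels)
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV over group counts %s\n", x$folds,
              paste(rownames(x$per_fold), collapse = ", ")))
  for (k in rownames(x$per_fold)) {
    cat(sprintf("  %s group(s): mean held-out global ROC %.3f\n", k,
                x$mean_cv_global_roc[k]))
  }
  cat(sprintf("  selected: %d group(s)\n", x$selected_group_count))
  invisible(x)
}

#' Write the model-selection curve (group count vs held-out global ROC)
#' @param cv a `cv_result`.
#' @param path output TSV.
#' @export
write_cv_curve <- function(cv, path) {
  df <- data.frame(group_count = as.integer(rownames(cv$per_fold)),
                   mean_cv_global_roc = as.numeric(cv$mean_cv_global_roc))
  df <- cbind(df, as.data.frame(cv$per_fold))
  colnames(df)[-(1:2)] <- paste0("fold_", seq_len(cv$folds))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Final full-data fit at a chosen number of groups
#'
#' Re-runs the agglomerative merge path on all samples, stops at the
#' selected group count, and returns that level's grouping together with
#' each group's model and its AUC with a DeLong confidence interval
#' (apparent, i.e. computed on the same samples the model was fit on).
#'
#' @param geno a `genotype_matrix`.
#' @param pheno a `phenotype_table`.
#' @param selected_group_count number of groups to stop at (e.g. from
#'   [cross_validate_group_count()]).
#' @param config a `selection_config`.
#' @param grouping_initial initial grouping (default: singletons).
#' @return object of class `group_fit`: `grouping`, `models`, `rocs`
#'   (named lists) and `global_roc`.
#' @export
fit_final <- function(geno, pheno, selected_group_count,
                      config = selection_config(),
                      grouping_initial = NULL) {
  path <- merge_path(geno, pheno, config, grouping_initial)
  key <- as.character(selected_group_count)
  if (!(key %in% names(path$levels))) {
    stop("fit_final: no merge-path level with ", selected_group_count,
         " group(s)")
  }
  lv <- path$levels[[key]]
  control_ids <- path$control_ids
  rocs <- lapply(names(lv$grouping), function(g) {
    cases <- samples_with_label(pheno, lv$grouping[[g]])
    auc_ci(score_samples(lv$models[[g]], geno, cases),
           score_samples(lv$models[[g]], geno, control_ids))
  })
  names(rocs) <- names(lv$grouping)
  structure(list(grouping = lv$grouping, models = lv$models, rocs = rocs,
                 global_roc = lv$global_roc, path = path),
            class = "group_fit")
}

#' Fit models for a fixed, user-supplied grouping
#'
#' The conventional-comparison mode: instead of learning the grouping from
#' the data, fit a forward-selected model for each group of a grouping
#' supplied from prior knowledge (e.g. the traditional split into cleft lip
#' with or without palate versus cleft palate only, or all sub-phenotypes
#' pooled as a single entity).
#'
#' @param geno a `genotype_matrix`.
#' @param pheno a `phenotype_table`.
#' @param grouping named list group id -> member sub-phenotype labels;
#'   must cover the retained sub-phenotypes with disjoint groups.
#' @param config a `selection_config`.
#' @return object of class `group_fit` (no merge path).
#' @export
run_fixed_grouping <- function(geno, pheno, grouping,
                               config = selection_config()) {
  validate_grouping(grouping, pheno)
  control_ids <- samples_with_label(pheno, pheno$control_label)
  models <- list()
  rocs <- list()
  group_aucs <- numeric(0)
  case_counts <- numeric(0)
  for (g in names(grouping)) {
    cases <- samples_with_label(pheno, grouping[[g]])
    models[[g]] <- forward_select(geno, cases, control_ids, config,
                                  group_id = g)$model
    rocs[[g]] <- auc_ci(score_samples(models[[g]], geno, cases),
                        score_samples(models[[g]], geno, control_ids))
    group_aucs[g] <- rocs[[g]]$auc
    case_counts[g] <- length(cases)
  }
  structure(list(grouping = grouping, models = models, rocs = rocs,
                 global_roc = global_roc(group_aucs, case_counts)),
            class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("<group_fit> %d group(s); global ROC %.3f\n",
              length(x$grouping), x$global_roc$value))
  for (g in names(x$grouping)) {
    r <- x$rocs[[g]]
    cat(sprintf("  %s [%s]: AUC %.3f (%.3f, %.3f); SNPs: %s\n", g,
                paste(x$grouping[[g]], collapse = ", "),
                r$auc, r$ci_lower, r$ci_upper,
                if (length(x$models[[g]]$rsids) > 0)
                  paste(x$models[[g]]$rsids, collapse = ", ")
                else "(none)"))
  }
  invisible(x)
}
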