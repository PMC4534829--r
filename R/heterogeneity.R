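#' Pairwise genetic similarity between sub-phenotype groups
#'
#' Operationalises "genetic similarity" as symmetric cross-applied
#' discrimination: sim(i, j) is the mean of (a) the AUC of group i's model
#' scoring group j's cases against the shared controls and (b) the AUC of
#' group j's model scoring group i's cases. If one group's model captures
#' etiology shared with the other group, it discriminates the other group's
#' cases above chance. The diagonal holds each group's own (apparent) AUC.
#' Empty models yield constant scores, hence cross-AUCs of exactly 0.5.
#'
#' @param models named list of `lr_model`, one per group.
#' @param geno the `genotype_matrix`.
#' @param group_cases named list (same names): case sample ids per group.
#' @param control_ids shared control sample ids.
#' @return symmetric numeric matrix with group ids as dimnames.
#' @export
pairwise_similarity <- function(models, geno, group_cases, control_ids) {
  ids <- names(models)
  stopifnot(identical(sort(ids), sort(names(group_cases))))
  k <- length(ids)
  # scores of every model on the controls and on every group's cases
  ctrl_scores <- lapply(models, score_samples, geno = geno,
                        sample_ids = control_ids)
  cross_auc <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      case_scores <- score_samples(models[[ids[i]]], geno,
                                   group_cases[[ids[j]]])
      cross_auc[i, j] <- empirical_auc(case_scores, ctrl_scores[[ids[i]]])
    }
  }
  sim <- (cross_auc + t(cross_auc)) / 2  # diag stays the own AUC
  sim
}

# pick the pair to merge: highest similarity; ties -> larger combined case
# count, then lexicographically smallest (sorted) id pair
pick_merge_pair <- function(sim, case_counts) {
  ids <- rownames(sim)
  best <- NULL
  for (i in seq_len(nrow(sim) - 1)) {
    for (j in (i + 1):ncol(sim)) {
      cand <- list(i = ids[i], j = ids[j], sim = sim[i, j],
                   n = case_counts[[ids[i]]] + case_counts[[ids[j]]])
      if (is.null(best) ||
          cand$sim > best$sim + 1e-12 ||
          (abs(cand$sim - best$sim) <= 1e-12 &&
           (cand$n > best$n ||
            (cand$n == best$n &&
             paste(sort(c(cand$i, cand$j)), collapse = "\r") <
             paste(sort(c(best$i, best$j)), collapse = "\r"))))) {
        best <- cand
      }
    }
  }
  best
}

#' Agglomerative merging of sub-phenotype groups
#'
#' Starting from an initial grouping (by default one group per
#' sub-phenotype), repeatedly: fit a forward-selected likelihood-ratio
#' model per group, measure pairwise genetic similarity, merge the most
#' similar pair, and refit the merged group from scratch on its pooled
#' cases. Models of untouched groups are carried over between levels. The
#' trajectory is recorded from K groups down to 1, each level with its
#' grouping, per-group models and AUCs, the global ROC statistic
#' (case-count-weighted mean one-vs-controls AUC), and the pair whose merge
#' produced the level.
#'
#' @param geno a `genotype_matrix`.
#' @param pheno a `phenotype_table` (already filtered).
#' @param config a `selection_config`.
#' @param grouping_initial named list group id -> member sub-phenotype
#'   labels; default: singletons, one group per case label.
#' @return object of class `merge_path`: list of levels keyed by group
#'   count (as character), each a list with `n_groups`, `grouping`,
#'   `models`, `group_aucs`, `case_counts`, `global_roc`, `similarity`,
#'   and, for levels below the first, `merged_pair` and
#'   `merged_similarity`.
#' @export
merge_path <- function(geno, pheno, config = selection_config(),
                       grouping_initial = NULL) {
  stopifnot(inherits(pheno, "phenotype_table"))
  if (is.null(grouping_initial)) {
    grouping_initial <- stats::setNames(as.list(pheno$case_labels),
                                        pheno$case_labels)
  }
  validate_grouping(grouping_initial, pheno)
  if (length(grouping_initial) < 2) {
    stop("merge_path: initial grouping must have at least 2 groups")
  }
  control_ids <- samples_with_label(pheno, pheno$control_label)
  grouping <- grouping_initial
  models <- list()
  levels <- list()
  merged_pair <- NULL
  merged_sim <- NA_real_
  repeat {
    group_cases <- lapply(grouping, function(labs)
      samples_with_label(pheno, labs))
    for (g in names(grouping)) {
      if (is.null(models[[g]])) {
        models[[g]] <- forward_select(geno, group_cases[[g]], control_ids,
                                      config, group_id = g)$model
      }
    }
    models <- models[names(grouping)]
    case_counts <- lengths(group_cases)
    sim <- pairwise_similarity(models, geno, group_cases, control_ids)
    own_aucs <- stats::setNames(diag(sim), names(grouping))
    groc <- global_roc(own_aucs, case_counts)
    levels[[as.character(length(grouping))]] <- list(
      n_groups = length(grouping), grouping = grouping, models = models,
      group_aucs = own_aucs, case_counts = case_counts,
      global_roc = groc, similarity = sim,
      merged_pair = merged_pair, merged_similarity = merged_sim)
    if (length(grouping) == 1L) break
    pick <- pick_merge_pair(sim, as.list(case_counts))
    new_id <- paste(sort(c(grouping[[pick$i]], grouping[[pick$j]])),
                    collapse = "+")
    new_grouping <- grouping[!(names(grouping) %in% c(pick$i, pick$j))]
    new_grouping[[new_id]] <- sort(c(grouping[[pick$i]], grouping[[pick$j]]))
    grouping <- new_grouping
    models[[pick$i]] <- NULL
    models[[pick$j]] <- NULL
    merged_pair <- c(pick$i, pick$j)
    merged_sim <- pick$sim
  }
  structure(list(levels = levels, control_ids = control_ids,
                 config = config),
            class = "merge_path")
}

validate_grouping <- function(grouping, pheno) {
  labs <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(labs)) {
    stop("grouping: groups must be disjoint")
  }
  unknown <- setdiff(labs, pheno$case_labels)
  if (length(unknown) > 0) {
    stop("grouping: unknown sub-phenotype label(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!setequal(labs, pheno$case_labels)) {
    stop("grouping: must cover every retained sub-phenotype; missing: ",
         paste(setdiff(pheno$case_labels, labs), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.merge_path <- function(x, ...) {
  ks <- vapply(x$levels, `[[`, integer(1), "n_groups")
  cat(sprintf("<merge_path> %d -> 1 groups; global ROC by level:\n", max(ks)))
  for (lv in x$levels) {
    cat(sprintf("  %d group(s): global ROC %.3f%s\n", lv$n_groups,
                lv$global_roc$value,
                if (!is.null(lv$merged_pair)) {
                  sprintf("  (merged '%s' + '%s', sim %.3f)",
                          lv$merged_pair[1], lv$merged_pair[2],
                          lv$merged_similarity)
                } else ""))
  }
  invisible(x)
}

#' Export a merge path as JSON
#'
#' Serialises the trajectory (groupings, merged pairs and similarities,
#' per-group AUCs and selected rsids, global ROC per level) without the
#' full likelihood-ratio tables; suitable for dendrogram-style reports.
#'
#' @param path_obj a `merge_path`.
#' @param file output file.
#' @export
export_merge_path <- function(path_obj, file) {
  levels <- lapply(path_obj$levels, function(lv) {
    list(
      n_groups = lv$n_groups,
      grouping = lv$grouping,
      global_roc = lv$global_roc$value,
      group_aucs = as.list(lv$group_aucs),
      case_counts = as.list(lv$case_counts),
      selected_rsids = lapply(lv$models, `[[`, "rsids"),
      merged_pair = lv$merged_pair,
      merged_similarity = lv$merged_similarity,
      similarity = lv$similarity
    )
  })
  jsonlite::write_json(levels, file, auto_unbox = TRUE, digits = I(17),
                       null = "null", matrix = "rowmajor")
  invisible(file)
}
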