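#' Forward-selection configuration
#'
#' Controls the ROC-based greedy search for the SNPs of a group's
#' likelihood-ratio model. At each step the candidate SNP maximising the
#' selection AUC of the joint model is added; the search stops when the best
#' gain falls below `min_auc_gain` or `max_snps` is reached. With
#' `inner_folds > 0` the selection AUC is a stratified inner
#' cross-validation mean, which curbs the overfitting that a saturated
#' 3^k likelihood-ratio table invites; `inner_folds = 0` uses the apparent
#' (training) AUC, which is monotone in model size and therefore relies on
#' `min_auc_gain` and `max_snps` to stop.
#'
#' @param max_snps maximum model size (default 5; the 3^k table cap binds
#'   anyway via `max_cells`).
#' @param min_auc_gain minimum selection-AUC improvement to accept a SNP
#'   (default 0.005, half an AUC point).
#' @param inner_folds inner CV folds for the selection criterion; 0 means
#'   apparent AUC (default 5).
#' @param pseudo_count smoothing constant for the LR tables (default 0.5).
#' @param seed RNG seed for the inner fold assignment.
#' @param max_cells cap on the genotype-combination table size (default 3^6).
#' @return object of class `selection_config`.
#' @export
selection_config <- function(max_snps = 5, min_auc_gain = 0.005,
                             inner_folds = 5, pseudo_count = 0.5,
                             seed = 1L, max_cells = 3^6) {
  stopifnot(max_snps >= 1, min_auc_gain >= 0, inner_folds >= 0)
  structure(list(max_snps = as.integer(max_snps),
                 min_auc_gain = min_auc_gain,
                 inner_folds = as.integer(inner_folds),
                 pseudo_count = pseudo_count,
                 seed = as.integer(seed),
                 max_cells = max_cells),
            class = "selection_config")
}

# stratified fold labels: each arm split as evenly as possible
fold_assignment <- function(n, folds) sample(rep_len(seq_len(folds), n))

#' ROC-based forward selection of SNPs for one case group
#'
#' Greedily grows a genotype-combination likelihood-ratio model for the
#' given cases versus controls: at each step every remaining SNP is
#' evaluated by the AUC of the joint model including it (inner-CV mean or
#' apparent, per `config`), and the best is added if it improves the
#' selection AUC by at least `min_auc_gain`. Because the model is the
#' saturated joint table, a SNP whose marginal effect is null can still be
#' selected for its interaction with already-selected SNPs. Ties on the
#' selection AUC break to the lexicographically smallest rsid for
#' reproducibility. If no SNP clears the gain threshold at the first step,
#' an empty (constant-score) model is returned with a warning.
#'
#' @param geno a `genotype_matrix`.
#' @param case_ids,control_ids disjoint non-empty sample id vectors.
#' @param config a `selection_config`.
#' @param group_id optional label stored in the returned model.
#' @param candidates integer vector of candidate variant columns (default
#'   all).
#' @return list with `model` (an `lr_model`, refit on all provided samples,
#'   carrying the selection trace in `$trace`) and `trace` (data.frame:
#'   step, rsid, auc_before, auc_after, gain).
#' @export
forward_select <- function(geno, case_ids, control_ids,
                           config = selection_config(), group_id = NULL,
                           candidates = seq_len(ncol(geno$calls))) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(config, "selection_config"))
  if (length(case_ids) == 0L || length(control_ids) == 0L) {
    stop("forward_select: case and control sets must be non-empty")
  }
  if (length(intersect(case_ids, control_ids)) > 0L) {
    stop("forward_select: case and control sets must be disjoint")
  }
  A <- geno$calls[case_ids, , drop = FALSE]
  B <- geno$calls[control_ids, , drop = FALSE]
  if (anyNA(A) || anyNA(B)) {
    modes <- modal_genotypes(rbind(A, B))
    A <- impute_calls(A, modes)
    B <- impute_calls(B, modes)
  }
  m <- nrow(A); n <- nrow(B)
  folds <- min(config$inner_folds, m, n)
  if (folds > 0) {
    set.seed(config$seed)
    fold_case <- fold_assignment(m, folds)
    fold_ctrl <- fold_assignment(n, folds)
  }
  pc <- config$pseudo_count
  rsids <- geno$variants$rsid
  selected <- integer(0)
  key_case <- integer(m)
  key_ctrl <- integer(n)
  current_auc <- 0.5
  trace <- list()
  remaining <- candidates
  max_k <- min(config$max_snps, floor(log(config$max_cells) / log(3)))
  for (step in seq_len(max_k)) {
    n_cells <- 3^step
    mult <- 3^(step - 1)
    crit <- rep(NA_real_, length(remaining))
    for (ci in seq_along(remaining)) {
      j <- remaining[ci]
      kc <- key_case + A[, j] * mult
      kn <- key_ctrl + B[, j] * mult
      if (folds == 0) {
        crit[ci] <- fit_lr_from_keys(kc, kn, step, pc)$auc
      } else {
        fauc <- numeric(folds)
        for (f in seq_len(folds)) {
          tc <- fold_case == f
          tn <- fold_ctrl == f
          fit <- fit_lr_from_keys(kc[!tc], kn[!tn], step, pc)
          fauc[f] <- auc_from_cell_counts(
            fit$lr,
            tabulate(kc[tc] + 1L, nbins = n_cells),
            tabulate(kn[tn] + 1L, nbins = n_cells))
        }
        crit[ci] <- mean(fauc)
      }
    }
    best_auc <- max(crit)
    tied <- remaining[crit >= best_auc - 1e-12]
    j_best <- tied[order(rsids[tied])[1]]
    gain <- best_auc - current_auc
    if (gain < config$min_auc_gain) break
    trace[[step]] <- data.frame(
      step = step, rsid = rsids[j_best],
      auc_before = current_auc, auc_after = best_auc, gain = gain,
      stringsAsFactors = FALSE)
    selected <- c(selected, j_best)
    key_case <- key_case + A[, j_best] * mult
    key_ctrl <- key_ctrl + B[, j_best] * mult
    current_auc <- best_auc
    remaining <- setdiff(remaining, j_best)
    if (length(remaining) == 0L) break
  }
  trace <- if (length(trace) > 0) {
    do.call(rbind, trace)
  } else {
    data.frame(step = integer(0), rsid = character(0),
               auc_before = numeric(0), auc_after = numeric(0),
               gain = numeric(0))
  }
  if (length(selected) == 0L) {
    warning("forward_select: no SNP improved AUC by min_auc_gain; returning empty model")
    model <- empty_lr_model(group_id, m, n, pc)
  } else {
    model <- estimate_lr_model(geno, case_ids, control_ids, selected,
                               pseudo_count = pc,
                               max_cells = config$max_cells)
    model$group_id <- group_id
  }
  model$trace <- trace
  list(model = model, trace = trace)
}

#' Write a forward-selection trace
#' @param trace the trace data.frame from [forward_select()].
#' @param path output TSV.
#' @export
write_selection_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
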