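#' Genotype-combination likelihood-ratio models
#'
#' The risk score for a set of selected SNPs is the nonparametric likelihood
#' ratio P(genotype combination | case) / P(genotype combination | control),
#' estimated over the full joint table of 3^k additive genotype combinations
#' (k = number of selected SNPs). The saturated table assumes no mode of
#' inheritance and captures gene-gene interactions of any order among the
#' selected SNPs. Cell probabilities are smoothed with a Laplace-style
#' pseudo-count (default 0.5, Jeffreys) so every likelihood ratio, including
#' for combinations unseen in training, is positive and finite.
#'
#' @name lr_model
NULL

# encode genotype rows (values 0/1/2) into base-3 cell keys 0..3^k-1
encode_genotype_keys <- function(calls) {
  k <- ncol(calls)
  if (k == 0L) return(integer(nrow(calls)))
  as.integer(calls %*% 3^(seq_len(k) - 1))
}

# per-variant modal genotype (0/1/2) over the given rows, ignoring NA;
# all-missing columns default to 0
modal_genotypes <- function(calls) {
  apply(calls, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(0L)
    tab <- tabulate(g + 1L, nbins = 3L)
    as.integer(which.max(tab) - 1L)
  })
}

# impute missing calls to the supplied per-variant modal genotype
impute_calls <- function(calls, modes) {
  for (j in seq_len(ncol(calls))) {
    miss <- is.na(calls[, j])
    if (any(miss)) calls[miss, j] <- modes[j]
  }
  calls
}

#' Estimate a likelihood-ratio model for one case group
#'
#' Builds the smoothed 3^k genotype-combination likelihood-ratio table for
#' the given SNPs from the supplied case and control samples. Missing calls
#' are imputed to the per-variant modal genotype computed on these training
#' samples (the imputation map is stored in the model and reused when
#' scoring new samples).
#'
#' @param geno a `genotype_matrix` (see [read_genotypes()]).
#' @param case_ids,control_ids disjoint, non-empty sample id vectors.
#' @param variant_indices integer indices (columns of `geno`) of the model
#'   SNPs, in selection order; may be empty for the constant-score model.
#' @param pseudo_count smoothing constant added to every cell (default 0.5).
#' @param max_cells refuse to build tables larger than this many genotype
#'   combinations (default 3^6); larger models should be avoided rather than
#'   silently degraded.
#' @return object of class `lr_model`: selected variant indices and rsids,
#'   the 3^k-vector `lr` of likelihood ratios (cell key = base-3 encoding of
#'   the genotype tuple, first selected SNP least significant), the
#'   imputation map, training counts, and the apparent training AUC.
#' @export
estimate_lr_model <- function(geno, case_ids, control_ids, variant_indices,
                              pseudo_count = 0.5, max_cells = 3^6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (length(case_ids) == 0L || length(control_ids) == 0L) {
    stop("estimate_lr_model: case and control sets must be non-empty")
  }
  if (length(intersect(case_ids, control_ids)) > 0L) {
    stop("estimate_lr_model: case and control sets must be disjoint")
  }
  k <- length(variant_indices)
  if (3^k > max_cells) {
    stop(sprintf(
      "estimate_lr_model: %d SNPs give %d genotype combinations, above the cap of %d; use a smaller max model size",
      k, 3^k, max_cells))
  }
  sub <- geno$calls[c(case_ids, control_ids), variant_indices, drop = FALSE]
  modes <- modal_genotypes(sub)
  sub <- impute_calls(sub, modes)
  n_case <- length(case_ids)
  keys <- encode_genotype_keys(sub)
  fit <- fit_lr_from_keys(keys[seq_len(n_case)], keys[-seq_len(n_case)],
                          k, pseudo_count)
  model <- list(
    variant_indices = as.integer(variant_indices),
    rsids = geno$variants$rsid[variant_indices],
    lr = fit$lr,
    pseudo_count = pseudo_count,
    impute = as.integer(modes),
    group_id = NULL,
    n_cases = n_case,
    n_controls = length(control_ids),
    auc = fit$auc
  )
  class(model) <- "lr_model"
  model
}

# core LR-table fit from pre-encoded cell keys (selection inner loop)
fit_lr_from_keys <- function(case_keys, control_keys, k, pseudo_count) {
  n_cells <- 3^k
  a <- tabulate(case_keys + 1L, nbins = n_cells)
  b <- tabulate(control_keys + 1L, nbins = n_cells)
  lr <- ((a + pseudo_count) / (sum(a) + n_cells * pseudo_count)) /
        ((b + pseudo_count) / (sum(b) + n_cells * pseudo_count))
  list(lr = lr, case_counts = a, control_counts = b,
       auc = auc_from_cell_counts(lr, a, b))
}

#' Score samples with a likelihood-ratio model
#'
#' Maps each sample to the likelihood ratio of its genotype combination at
#' the model SNPs. Missing calls are imputed to the modal genotypes stored
#' in the model at training time. An empty model scores every sample 1.
#'
#' @param model an `lr_model`.
#' @param geno a `genotype_matrix` containing the model's variant columns.
#' @param sample_ids samples to score (default: all samples in `geno`).
#' @return named numeric vector of likelihood-ratio scores.
#' @export
score_samples <- function(model, geno, sample_ids = geno$sample_ids) {
  stopifnot(inherits(model, "lr_model"), inherits(geno, "genotype_matrix"))
  if (length(model$variant_indices) == 0L) {
    return(stats::setNames(rep(1, length(sample_ids)), sample_ids))
  }
  sub <- geno$calls[sample_ids, model$variant_indices, drop = FALSE]
  sub <- impute_calls(sub, model$impute)
  keys <- encode_genotype_keys(sub)
  stats::setNames(model$lr[keys + 1L], sample_ids)
}

#' The constant-score (empty) model
#'
#' Returned by forward selection when no SNP clears the minimum AUC gain;
#' scores every sample 1, so its AUC against any control set is 0.5.
#'
#' @param group_id optional group label.
#' @param n_cases,n_controls training counts (for the record).
#' @param pseudo_count smoothing constant carried for consistency.
#' @return an `lr_model` with no variants.
#' @export
empty_lr_model <- function(group_id = NULL, n_cases = 0L, n_controls = 0L,
                           pseudo_count = 0.5) {
  model <- list(
    variant_indices = integer(0), rsids = character(0), lr = numeric(0),
    pseudo_count = pseudo_count, impute = integer(0), group_id = group_id,
    n_cases = n_cases, n_controls = n_controls, auc = 0.5
  )
  class(model) <- "lr_model"
  model
}

#' @export
print.lr_model <- function(x, ...) {
  if (length(x$variant_indices) == 0L) {
    cat("<lr_model> empty (constant score, AUC 0.5)\n")
  } else {
    cat(sprintf("<lr_model> %d SNP(s): %s | training AUC %.3f (%d cases, %d controls)\n",
                length(x$rsids), paste(x$rsids, collapse = ", "),
                x$auc, x$n_cases, x$n_controls))
  }
  invisible(x)
}

#' Serialize / deserialize a likelihood-ratio model as JSON
#'
#' The JSON form carries the selected rsids, variant column indices, the
#' full likelihood-ratio table, the imputation map and smoothing constant:
#' everything needed to re-score new samples identically.
#'
#' @param model an `lr_model`.
#' @param path file to write / read.
#' @return `lr_model_from_json` returns the reconstructed `lr_model`.
#' @export
lr_model_to_json <- function(model, path) {
  stopifnot(inherits(model, "lr_model"))
  x <- unclass(model)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname lr_model_to_json
#' @export
lr_model_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(
    variant_indices = as.integer(x$variant_indices),
    rsids = as.character(x$rsids),
    lr = as.numeric(x$lr),
    pseudo_count = as.numeric(x$pseudo_count),
    impute = as.integer(x$impute),
    group_id = if (is.null(x$group_id)) NULL else x$group_id,
    n_cases = as.integer(x$n_cases),
    n_controls = as.integer(x$n_controls),
    auc = as.numeric(x$auc)
  )
  class(model) <- "lr_model"
  model
}
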