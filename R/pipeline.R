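#' End-to-end risk-prediction analysis
#'
#' Orchestrates the full analysis: read (or accept in-memory) genotype and
#' phenotype data, apply the sub-phenotype filter policy, then run one of
#' four modes and write every report artifact to `out_dir`:
#'
#' * `"mlre"` — the full heterogeneity-aware analysis: K-fold
#'   cross-validated selection of the number of sub-phenotype groups,
#'   then a final full-data fit at the selected count.
#' * `"fixed-grouping"` — forward selection per group of a user-supplied
#'   grouping (the conventional comparison mode).
#' * `"per-subtype"` — one model per retained sub-phenotype (no merging).
#' * `"single-entity"` — all sub-phenotypes pooled into one case group.
#'
#' Artifacts: `model_report.tsv` (one row per selected SNP with the group's
#' AUC and confidence bounds), one model JSON and one ROC-curve TSV per
#' group, per-group selection-trace TSVs, `grouping.json`, and for mode
#' `"mlre"` additionally `cv_curve.tsv` and `merge_path.json`, plus a run
#' `manifest.json` (configuration, seed, filter log, package version).
#' The run is deterministic given the seed.
#'
#' @param geno a `genotype_matrix`, or a path passed to [read_genotypes()].
#' @param pheno a `phenotype_table`, or a path passed to
#'   [read_phenotypes()].
#' @param out_dir output directory, created if needed.
#' @param mode one of `"mlre"`, `"fixed-grouping"`, `"per-subtype"`,
#'   `"single-entity"`.
#' @param control_label control label (needed when `pheno` is a path).
#' @param policy a `filter_policy` (NULL to skip filtering).
#' @param config a `selection_config`; its seed is overridden by `seed`.
#' @param grouping required for `mode = "fixed-grouping"`.
#' @param folds CV folds for mode `"mlre"` (default 5).
#' @param seed master seed for fold assignment and inner CV.
#' @param dialect genotype file dialect when `geno` is a path.
#' @param verbose print progress (filter decisions, merges) to the console.
#' @return list with the fitted `group_fit` (`$fit`), the `cv_result`
#'   (`$cv`, mode `"mlre"` only), the filtered `phenotype_table`
#'   (`$pheno`), and `out_dir`.
#' @export
run_pipeline <- function(geno, pheno, out_dir,
                         mode = c("mlre", "fixed-grouping", "per-subtype",
                                  "single-entity"),
                         control_label = NULL,
                         policy = filter_policy(),
                         config = selection_config(),
                         grouping = NULL,
                         folds = 5,
                         seed = 1L,
                         dialect = "tsv",
                         verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(geno)) geno <- read_genotypes(geno, dialect)
  if (is.character(pheno)) {
    if (is.null(control_label)) {
      stop("run_pipeline: control_label required when pheno is a path")
    }
    pheno <- read_phenotypes(pheno, control_label)
  }
  missing_samples <- setdiff(pheno$samples$sample_id, geno$sample_ids)
  if (length(missing_samples) > 0) {
    stop("run_pipeline: phenotype samples absent from genotypes: ",
         paste(utils::head(missing_samples, 5), collapse = ", "))
  }
  filter_log <- NULL
  if (!is.null(policy)) {
    pheno <- apply_filter(pheno, policy)
    filter_log <- attr(pheno, "filter_log")
    if (!is.null(filter_log) && nrow(filter_log) > 0) {
      for (i in seq_len(nrow(filter_log))) {
        say("filter: dropped '%s' (n=%d): %s", filter_log$label[i],
            filter_log$n[i], filter_log$reason[i])
      }
    }
  }
  config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cv <- NULL
  if (mode == "mlre") {
    cv <- cross_validate_group_count(geno, pheno, folds = folds,
                                     config = config, seed = seed)
    say("cross-validation selected %d group(s)", cv$selected_group_count)
    fit <- fit_final(geno, pheno, cv$selected_group_count, config)
    write_cv_curve(cv, file.path(out_dir, "cv_curve.tsv"))
    export_merge_path(fit$path, file.path(out_dir, "merge_path.json"))
  } else {
    grouping <- switch(mode,
      "fixed-grouping" = {
        if (is.null(grouping)) {
          stop("run_pipeline: mode 'fixed-grouping' requires a grouping")
        }
        grouping
      },
      "per-subtype" = stats::setNames(as.list(pheno$case_labels),
                                      pheno$case_labels),
      "single-entity" = list(all = pheno$case_labels))
    fit <- run_fixed_grouping(geno, pheno, grouping, config)
  }
  for (g in names(fit$models)) {
    say("group '%s': AUC %.3f, SNPs: %s", g, fit$rocs[[g]]$auc,
        paste(fit$models[[g]]$rsids, collapse = ", "))
    tr <- fit$models[[g]]$trace
    if (!is.null(tr)) {
      write_selection_trace(tr, file.path(
        out_dir, paste0("trace_", sanitize_id(g), ".tsv")))
    }
  }
  write_model_report(fit$models, fit$rocs, geno, fit$grouping, out_dir)
  manifest <- list(
    mode = mode, seed = as.integer(seed), folds = folds,
    selection_config = unclass(config),
    filter_policy = if (is.null(policy)) NULL else unclass(policy),
    filter_log = filter_log,
    n_samples = nrow(geno$calls), n_variants = ncol(geno$calls),
    control_label = pheno$control_label,
    retained_subphenotypes = pheno$case_labels,
    selected_group_count = length(fit$grouping),
    global_roc = fit$global_roc$value,
    package_version = as.character(utils::packageVersion("clefthet")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       pretty = TRUE)
  list(fit = fit, cv = cv, pheno = pheno, out_dir = out_dir)
}
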