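sim_two_groups <- function(shared, seed, n_cases = 250, n_controls = 1200) {
  # two sub-phenotypes; shared = TRUE gives identical causal SNPs,
  # FALSE gives disjoint causal sets
  causal <- if (shared) {
    list(g1 = data.frame(snp = 1:2, grr = 2),
         g2 = data.frame(snp = 1:2, grr = 2))
  } else {
    list(g1 = data.frame(snp = 1:2, grr = 2),
         g2 = data.frame(snp = 3:4, grr = 2))
  }
  simulate_dataset(sim_config(
    n_controls = n_controls,
    case_counts = c(A = n_cases, B = n_cases),
    n_snps = 40, maf = 0.3,
    latent_groups = list(g1 = "A", g2 = "B"),
    causal_sets = causal, seed = seed))
}

fit_groups <- function(d, cfg = selection_config(inner_folds = 0,
                                                 max_snps = 2)) {
  ctrl <- samples_with_label(d$pheno, "Control")
  cases <- list(A = samples_with_label(d$pheno, "A"),
                B = samples_with_label(d$pheno, "B"))
  models <- lapply(names(cases), function(g)
    forward_select(d$geno, cases[[g]], ctrl, cfg, group_id = g)$model)
  names(models) <- names(cases)
  list(models = models, cases = cases, ctrl = ctrl)
}

test_that("similarity is symmetric, in [0,1], and high for a shared etiology", {
  d <- sim_two_groups(shared = TRUE, seed = 61)
  f <- fit_groups(d)
  sim <- pairwise_similarity(f$models, d$geno, f$cases, f$ctrl)
  expect_identical(sim, t(sim))
  expect_true(all(sim >= 0 & sim <= 1))
  # cross-similarity within sampling error of the groups' own AUCs
  own <- mean(diag(sim))
  expect_gt(sim["A", "B"], own - 0.05)
})

test_that("disjoint etiologies give cross-similarity near 0.5", {
  d <- sim_two_groups(shared = FALSE, seed = 62)
  f <- fit_groups(d)
  sim <- pairwise_similarity(f$models, d$geno, f$cases, f$ctrl)
  expect_lt(abs(sim["A", "B"] - 0.5), 0.05)
  expect_gt(diag(sim)["A"], 0.55)
})

test_that("two empty models have similarity exactly 0.5", {
  d <- sim_two_groups(shared = FALSE, seed = 63, n_cases = 30,
                      n_controls = 60)
  cases <- list(A = samples_with_label(d$pheno, "A"),
                B = samples_with_label(d$pheno, "B"))
  models <- list(A = empty_lr_model("A"), B = empty_lr_model("B"))
  sim <- pairwise_similarity(models, d$geno, cases,
                             samples_with_label(d$pheno, "Control"))
  expect_identical(unname(sim), matrix(0.5, 2, 2))
})

test_that("a merge path is a strict coarsening ending in one group", {
  d <- simulate_dataset(two_etiology_config(seed = 64, n_cases = 100,
                                            n_controls = 600, n_snps = 30))
  mp <- merge_path(d$geno, d$pheno,
                   selection_config(inner_folds = 0, max_snps = 2))
  ks <- vapply(mp$levels, `[[`, integer(1), "n_groups")
  expect_identical(unname(ks), 4:1)
  for (k in 3:1) {
    prev <- mp$levels[[as.character(k + 1)]]$grouping
    cur <- mp$levels[[as.character(k)]]$grouping
    # every current group is a union of previous groups; exactly one merge
    expect_identical(length(cur), length(prev) - 1L)
    for (g in cur) {
      members <- lapply(prev, intersect, g)
      touched <- members[lengths(members) > 0]
      expect_identical(sort(unname(unlist(touched))), sort(g))
    }
    expect_length(mp$levels[[as.character(k)]]$merged_pair, 2)
    expect_true(is.finite(mp$levels[[as.character(k)]]$merged_similarity))
  }
  # global ROC at each level is the case-weighted mean of group AUCs
  for (lv in mp$levels) {
    expect_equal(lv$global_roc$value,
                 sum(lv$group_aucs * lv$case_counts) / sum(lv$case_counts))
  }
})

test_that("a two-group start yields exactly levels {2, 1}", {
  d <- sim_two_groups(shared = FALSE, seed = 65, n_cases = 80,
                      n_controls = 300)
  mp <- merge_path(d$geno, d$pheno,
                   selection_config(inner_folds = 0, max_snps = 2))
  expect_identical(names(mp$levels), c("2", "1"))
  expect_identical(sort(mp$levels[["1"]]$grouping[[1]]), c("A", "B"))
})

test_that("merging is invariant to the order groups are listed in", {
  d <- simulate_dataset(two_etiology_config(seed = 66, n_cases = 100,
                                            n_controls = 500, n_snps = 30))
  cfg <- selection_config(inner_folds = 0, max_snps = 2)
  mp1 <- merge_path(d$geno, d$pheno, cfg,
                    grouping_initial = list(A = "A", B = "B", C = "C",
                                            D = "D"))
  mp2 <- merge_path(d$geno, d$pheno, cfg,
                    grouping_initial = list(D = "D", B = "B", C = "C",
                                            A = "A"))
  for (k in as.character(4:1)) {
    g1 <- lapply(mp1$levels[[k]]$grouping, sort)
    g2 <- lapply(mp2$levels[[k]]$grouping, sort)
    expect_setequal(unname(vapply(g1, paste, "", collapse = "|")),
                    unname(vapply(g2, paste, "", collapse = "|")))
  }
})

test_that("groupings that are not a partition of the labels are rejected", {
  d <- sim_two_groups(shared = FALSE, seed = 67, n_cases = 30,
                      n_controls = 80)
  expect_error(merge_path(d$geno, d$pheno,
                          grouping_initial = list(x = "A", y = c("A", "B"))),
               "disjoint")
  expect_error(merge_path(d$geno, d$pheno,
                          grouping_initial = list(x = "A", y = "Z")),
               "unknown")
  expect_error(merge_path(d$geno, d$pheno,
                          grouping_initial = list(x = c("A", "B"))),
               "at least 2")
})
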