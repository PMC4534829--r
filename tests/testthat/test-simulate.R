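test_that("control genotypes follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_controls = 20000, case_counts = c(A = 10, B = 10),
                    n_snps = 2, maf = c(0.5, 0.2), seed = 101)
  d <- simulate_dataset(cfg)
  ctrl <- d$geno$calls[samples_with_label(d$pheno, "Control"), ]
  p1 <- tabulate(ctrl[, 1] + 1L, 3) / nrow(ctrl)
  expect_equal(p1, c(0.25, 0.5, 0.25), tolerance = 0.03)
  p2 <- tabulate(ctrl[, 2] + 1L, 3) / nrow(ctrl)
  expect_equal(p2, c(0.64, 0.32, 0.04), tolerance = 0.05)
  # realized control frequencies recorded in the truth manifest
  expect_equal(d$truth$control_freqs[, 1], p1)
})

test_that("with all GRR = 1 case and control genotypes are exchangeable", {
  cfg <- sim_config(n_controls = 3000, case_counts = c(A = 3000),
                    n_snps = 3,
                    latent_groups = list(g = "A"),
                    causal_sets = list(g = data.frame(snp = 1, grr = 1)),
                    seed = 7)
  d <- simulate_dataset(cfg)
  cases <- samples_with_label(d$pheno, "A")
  ctrl <- samples_with_label(d$pheno, "Control")
  for (j in 1:3) {
    tab <- rbind(tabulate(d$geno$calls[cases, j] + 1L, 3),
                 tabulate(d$geno$calls[ctrl, j] + 1L, 3))
    expect_gt(suppressWarnings(chisq.test(tab))$p.value, 1e-4)
  }
  expect_lt(abs(empirical_auc(d$geno$calls[cases, 1],
                              d$geno$calls[ctrl, 1]) - 0.5), 0.025)
})

test_that("case genotype distribution matches the closed-form enumeration", {
  # single causal SNP: P(g | case) proportional to HWE(g) * grr^g
  maf <- 0.3; grr <- 2
  cfg <- sim_config(n_controls = 10, case_counts = c(A = 20000),
                    n_snps = 1, maf = maf,
                    latent_groups = list(g = "A"),
                    causal_sets = list(g = data.frame(snp = 1, grr = grr)),
                    baseline_risk = 0.01, seed = 13)
  d <- simulate_dataset(cfg)
  g <- d$geno$calls[samples_with_label(d$pheno, "A"), 1]
  observed <- tabulate(g + 1L, 3) / length(g)
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  expected <- hwe * grr^(0:2) / sum(hwe * grr^(0:2))
  expect_equal(observed, expected, tolerance = 0.03)
})

test_that("identical configs give identical datasets; infeasible risk errors", {
  cfg <- sim_config(n_controls = 100, case_counts = c(A = 40, B = 20),
                    n_snps = 10, missing_rate = 0.1, seed = 55)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$geno$calls, d2$geno$calls)
  expect_identical(d1$pheno$samples, d2$pheno$samples)
  expect_error(
    sim_config(n_controls = 10, case_counts = c(A = 10), n_snps = 2,
               latent_groups = list(g = "A"),
               causal_sets = list(g = data.frame(snp = 1, grr = 20)),
               baseline_risk = 0.5),
    "lower baseline_risk")
})

test_that("two-locus interactions raise joint risk-allele carriage in cases", {
  cfg <- sim_config(n_controls = 4000, case_counts = c(A = 4000),
                    n_snps = 2, maf = 0.3,
                    latent_groups = list(g = "A"),
                    interactions = data.frame(snp_i = 1, snp_j = 2, grr = 3),
                    baseline_risk = 0.01, seed = 21)
  d <- simulate_dataset(cfg)
  cases <- d$geno$calls[samples_with_label(d$pheno, "A"), ]
  ctrl <- d$geno$calls[samples_with_label(d$pheno, "Control"), ]
  both_case <- mean(cases[, 1] >= 1 & cases[, 2] >= 1)
  both_ctrl <- mean(ctrl[, 1] >= 1 & ctrl[, 2] >= 1)
  # analytic: carrier prob q = 1-(1-maf)^2 per SNP; joint carriage is
  # enriched by the factor 3 / (1 + q^2 * (3-1)) among cases
  q <- 1 - 0.7^2
  expect_equal(both_ctrl, q^2, tolerance = 0.03)
  expect_equal(both_case, 3 * q^2 / (1 + q^2 * 2), tolerance = 0.03)
})

test_that("analytic single-SNP AUC matches its defining enumeration", {
  expect_equal(expected_auc(0.3, 1), 0.5)
  # huge GRR, vanishing baseline risk: case mass concentrates at g = 2
  expect_equal(expected_auc(0.5, 1e6, baseline_risk = 1e-20), 0.875,
               tolerance = 1e-6)
  # brute-force 9-cell enumeration, independently of the implementation
  maf <- 0.3; grr <- 2
  hwe <- c(0.49, 0.42, 0.09)
  case <- hwe * grr^(0:2) / sum(hwe * grr^(0:2))
  brute <- 0
  for (gc in 0:2) for (gn in 0:2) {
    brute <- brute + case[gc + 1] * hwe[gn + 1] *
      ((gc > gn) + 0.5 * (gc == gn))
  }
  expect_equal(expected_auc(maf, grr), brute)
})

test_that("non-causal SNPs pass case/control homogeneity at nominal rate", {
  # 40 replicates x 5 null SNPs; chi-square p-values should be uniform
  pvals <- unlist(lapply(1:40, function(r) {
    d <- simulate_dataset(sim_config(
      n_controls = 300, case_counts = c(A = 300), n_snps = 5,
      latent_groups = list(g = "A"),
      causal_sets = list(g = data.frame(snp = 1, grr = 2)), seed = 600 + r))
    cases <- samples_with_label(d$pheno, "A")
    ctrl <- samples_with_label(d$pheno, "Control")
    vapply(2:5, function(j) {
      tab <- rbind(tabulate(d$geno$calls[cases, j] + 1L, 3),
                   tabulate(d$geno$calls[ctrl, j] + 1L, 3))
      suppressWarnings(chisq.test(tab))$p.value
    }, numeric(1))
  }))
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.035)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("Monte-Carlo single-SNP model AUC converges to the analytic value", {
  maf <- 0.3; grr <- 2
  d <- simulate_dataset(sim_config(
    n_controls = 5000, case_counts = c(A = 5000), n_snps = 1, maf = maf,
    latent_groups = list(g = "A"),
    causal_sets = list(g = data.frame(snp = 1, grr = grr)), seed = 77))
  cases <- samples_with_label(d$pheno, "A")
  ctrl <- samples_with_label(d$pheno, "Control")
  m <- estimate_lr_model(d$geno, cases, ctrl, 1L)
  r <- auc_ci(score_samples(m, d$geno, cases),
              score_samples(m, d$geno, ctrl), curve = FALSE)
  expect_lt(abs(r$auc - expected_auc(maf, grr)), 3 * r$se)
})
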