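test_that("TSV genotypes parse, with NA cells mapped to missing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1\trs2",
               "s1\t0\t2", "s2\t1\t1", "s3\t2\tNA"), path)
  g <- read_genotypes(path, "tsv")
  expect_identical(dim(g$calls), c(3L, 2L))
  expect_identical(unname(g$calls[, 1]), c(0L, 1L, 2L))
  expect_true(is.na(g$calls[3, 2]))
  expect_identical(g$variants$rsid, c("rs1", "rs2"))
})

test_that("invalid genotype cells and malformed headers are rejected with location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\trs1", "s1\t3"), path)
  expect_error(read_genotypes(path, "tsv"), "s1.*rs1")
  writeLines(c("sample_id", "s1"), path)
  expect_error(read_genotypes(path, "tsv"), "malformed")
  path2 <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID SEX rs1_A", "f1 s1 1 0"), path2)
  expect_error(read_genotypes(path2, "plink_raw"), "malformed")
})

test_that("simulator output round-trips through both genotype dialects", {
  d <- simulate_dataset(sim_config(n_controls = 40,
                                   case_counts = c(A = 20, B = 20),
                                   n_snps = 8, missing_rate = 0.05,
                                   seed = 42))
  for (dialect in c("tsv", "plink_raw")) {
    f <- withr::local_tempfile()
    write_genotypes(d$geno, f, dialect)
    g2 <- read_genotypes(f, dialect)
    expect_identical(unname(g2$calls), unname(d$geno$calls))
    expect_identical(g2$sample_ids, d$geno$sample_ids)
    expect_identical(g2$variants$rsid, d$geno$variants$rsid)
  }
  # plink dialect recovers the counted allele from the column suffix
  f <- withr::local_tempfile()
  write_genotypes(d$geno, f, "plink_raw")
  g3 <- read_genotypes(f, "plink_raw")
  expect_identical(g3$variants$counted_allele,
                   d$geno$variants$counted_allele)
})

test_that("phenotype reading reproduces the consortium count profile", {
  pheno <- cleft_profile_phenotypes()
  f <- withr::local_tempfile()
  write_phenotypes(pheno, f)
  p2 <- read_phenotypes(f, "Control")
  expect_identical(label_counts(p2), cleft_profile_counts())
  expect_identical(p2$control_label, "Control")
  expect_identical(p2$case_labels, setdiff(names(cleft_profile_counts()),
                                           "Control"))
})

test_that("phenotype table rejects duplicates and a missing control label", {
  expect_error(phenotype_table(c("s1", "s1"), c("Control", "A"), "Control"),
               "duplicated")
  expect_error(phenotype_table(c("s1", "s2"), c("A", "B"), "Control"),
               "control label")
  p <- phenotype_table(c("s1", "s2"), c("Control", "Control"), "Control")
  expect_length(p$case_labels, 0)
})

test_that("the default filter retains the seven analyzed sub-phenotypes", {
  pheno <- cleft_profile_phenotypes()
  policy <- filter_policy(min_cases_per_subtype = 50,
                          excluded_labels = "Unknown")
  filtered <- apply_filter(pheno, policy)
  expect_setequal(filtered$case_labels,
                  c("CP-Soft", "CP-Hard", "Left CL", "Right CL",
                    "Left CLP", "Right CLP", "Bilateral CLP"))
  log <- attr(filtered, "filter_log")
  expect_setequal(log$label, c("Unknown", "Bilateral CL", "Microforms"))
  # controls never dropped
  expect_identical(sum(filtered$samples$label == "Control"), 3692L)
})

test_that("apply_filter is idempotent and errors when too few labels remain", {
  pheno <- cleft_profile_phenotypes()
  policy <- filter_policy(50, "Unknown")
  once <- apply_filter(pheno, policy)
  twice <- apply_filter(once, policy)
  expect_identical(twice$samples, once$samples)
  expect_identical(apply_filter(pheno, filter_policy(0))$samples,
                   pheno$samples)
  expect_error(apply_filter(pheno, filter_policy(10000)), "fewer than 2")
})

test_that("model report mirrors the per-group table layout and models round-trip", {
  d <- simulate_dataset(sim_config(n_controls = 150,
                                   case_counts = c(A = 60, B = 60),
                                   n_snps = 10,
                                   latent_groups = list(g = c("A", "B")),
                                   causal_sets = list(
                                     g = data.frame(snp = 1:2, grr = 2.5)),
                                   seed = 3))
  ctrl <- samples_with_label(d$pheno, "Control")
  fit <- run_fixed_grouping(d$geno, d$pheno,
                            list(AB = c("A", "B")),
                            selection_config(inner_folds = 0, max_snps = 2))
  dir <- withr::local_tempdir()
  write_model_report(fit$models, fit$rocs, d$geno, fit$grouping, dir)
  tab <- read.delim(file.path(dir, "model_report.tsv"))
  expect_identical(nrow(tab), length(fit$models$AB$rsids))
  expect_identical(tab$rsid, fit$models$AB$rsids)
  expect_true(all(c("group", "counted_allele", "chromosome", "gene",
                    "position", "auc", "ci_lower", "ci_upper")
                  %in% colnames(tab)))
  # AUC and CI only on the group's first row
  expect_equal(tab$auc[1], fit$rocs$AB$auc)
  expect_true(all(is.na(tab$auc[-1])))
  # ROC curve export exists and spans (0,0) to (1,1)
  curve <- read.delim(file.path(dir, "roc_AB.tsv"))
  expect_equal(curve[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(curve[nrow(curve), ]), c(fpr = 1, tpr = 1))
  # JSON round trip scores identically on fresh samples
  m2 <- lr_model_from_json(file.path(dir, "model_AB.json"))
  held <- simulate_dataset(sim_config(n_controls = 50,
                                      case_counts = c(A = 25, B = 25),
                                      n_snps = 10, seed = 99))
  expect_identical(score_samples(m2, held$geno),
                   score_samples(fit$models$AB, held$geno))
})

test_that("an empty model is reported as a single row with AUC 0.5", {
  d <- simulate_dataset(sim_config(n_controls = 60,
                                   case_counts = c(A = 30, B = 30),
                                   n_snps = 4, seed = 8))
  m <- empty_lr_model("A", 30, 60)
  r <- auc_ci(rep(1, 30), rep(1, 60))
  dir <- withr::local_tempdir()
  write_model_report(list(A = m), list(A = r), d$geno,
                     list(A = "A"), dir)
  tab <- read.delim(file.path(dir, "model_report.tsv"))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$rsid, NA)
  expect_equal(tab$auc, 0.5)
})
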