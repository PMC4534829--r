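#!/usr/bin/env Rscript

# Build the synthetic oral-cleft-style dataset used throughout the analysis.
#
# The generator mirrors the structure of a large cleft consortium panel:
# 148 candidate SNPs, a shared control pool, and seven retained
# sub-phenotypes with the published unbalanced case counts. The latent
# ground truth plants three etiology groups — all cleft-lip-involving
# subtypes share one set of causal SNPs, while soft and hard cleft palate
# each have their own — plus two causal SNPs shared by every group (an
# IRF6-like common factor). This is the truth the heterogeneity analysis
# in 03_mlre.R should rediscover.

suppressMessages(library(clefthet))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- sim_config(
  n_controls = 3692,
  case_counts = c("CP-Soft" = 223, "CP-Hard" = 172,
                  "Left CL" = 244, "Right CL" = 114,
                  "Left CLP" = 485, "Right CLP" = 271,
                  "Bilateral CLP" = 336),
  n_snps = 148,
  maf = 0.3,
  latent_groups = list(
    lip = c("Left CL", "Right CL", "Left CLP", "Right CLP",
            "Bilateral CLP"),
    palate_soft = "CP-Soft",
    palate_hard = "CP-Hard"),
  causal_sets = list(
    lip = data.frame(snp = 1:3, grr = 1.8),
    palate_soft = data.frame(snp = 4:5, grr = 2.0),
    palate_hard = data.frame(snp = 6:7, grr = 2.0)),
  shared_causal = data.frame(snp = 8:9, grr = 1.4),
  baseline_risk = 0.005,
  seed = 20260927)

d <- simulate_dataset(config)

write_genotypes(d$geno, file.path(out_dir, "genotypes.tsv"), "tsv")
write_genotypes(d$geno, file.path(out_dir, "genotypes.raw"), "plink_raw")
write_phenotypes(d$pheno, file.path(out_dir, "phenotypes.tsv"))
write_sim_truth(d$truth, file.path(out_dir, "truth.json"))

cat("Simulated dataset written to", out_dir, "\n")
print(d$geno)
print(d$pheno)
cat("\nLatent etiology groups (ground truth):\n")
for (g in names(config$latent_groups)) {
  cat(sprintf("  %-12s %s | causal SNPs: %s\n", g,
              paste(config$latent_groups[[g]], collapse = ", "),
              paste(config$causal_sets[[g]]$snp, collapse = ", ")))
}
cat("  shared causal SNPs:", paste(config$shared_causal$snp, collapse = ", "),
    "\n")
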