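# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except what a test writes itself.

# The published sub-phenotype count profile of the oral-cleft consortium
# dataset (controls plus ten case categories).
cleft_profile_counts <- function() {
  c("Control" = 3692L,
    "CP-Soft" = 223L, "CP-Hard" = 172L,
    "Left CL" = 244L, "Right CL" = 114L, "Bilateral CL" = 30L,
    "Left CLP" = 485L, "Right CLP" = 271L, "Bilateral CLP" = 336L,
    "Unknown" = 615L, "Microforms" = 3L)
}

# phenotype_table realizing the count profile
cleft_profile_phenotypes <- function() {
  counts <- cleft_profile_counts()
  labels <- rep(names(counts), counts)
  phenotype_table(sprintf("s%05d", seq_along(labels)), labels, "Control")
}

# small genotype matrix from an explicit call matrix
tiny_geno <- function(calls, rsids = sprintf("rs%03d", seq_len(ncol(calls)))) {
  genotype_matrix(calls, sprintf("s%03d", seq_len(nrow(calls))),
                  data.frame(rsid = rsids))
}

# genotype matrix holding per-cell counts for explicit 1- or 2-SNP designs:
# case_counts / control_counts are vectors over genotype cells in base-3
# key order (first SNP least significant)
geno_from_cell_counts <- function(case_counts, control_counts, k) {
  cells <- as.matrix(expand.grid(rep(list(0:2), k)))[, seq_len(k), drop = FALSE]
  rows_case <- cells[rep(seq_len(nrow(cells)), case_counts), , drop = FALSE]
  rows_ctrl <- cells[rep(seq_len(nrow(cells)), control_counts), , drop = FALSE]
  calls <- rbind(rows_case, rows_ctrl)
  n_case <- nrow(rows_case)
  g <- tiny_geno(calls)
  list(geno = g,
       case_ids = g$sample_ids[seq_len(n_case)],
       control_ids = g$sample_ids[-seq_len(n_case)])
}

# brute-force Mann-Whitney AUC by explicit pair enumeration
auc_by_pairs <- function(case_scores, control_scores) {
  tot <- 0
  for (x in case_scores) {
    for (y in control_scores) {
      tot <- tot + (x > y) + 0.5 * (x == y)
    }
  }
  tot / (length(case_scores) * length(control_scores))
}

# maximum empirical AUC over ALL strict orderings of genotype cells with
# case counts a and control counts b (exhaustive permutation enumeration)
max_auc_over_orderings <- function(a, b) {
  keep <- a > 0 | b > 0
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  perms <- all_permutations(n)
  A <- matrix(a[perms], nrow = nrow(perms))
  B <- matrix(b[perms], nrow = nrow(perms))
  U <- upper.tri(diag(n), diag = TRUE) * 1
  cumB <- B %*% U
  num <- rowSums(A * (cumB - B / 2))
  max(num) / (sum(a) * sum(b))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out[[i]] <- block
  }
  do.call(rbind, out)
}

# standard 2-etiology simulation design: 4 sub-phenotypes, two latent
# groups of two, 3 causal SNPs per etiology (GRR `grr`, MAF 0.3), 148 SNPs
two_etiology_config <- function(seed, n_cases = 300, n_controls = 2000,
                                grr = 2, n_snps = 148) {
  sim_config(
    n_controls = n_controls,
    case_counts = stats::setNames(rep(n_cases, 4), c("A", "B", "C", "D")),
    n_snps = n_snps, maf = 0.3,
    latent_groups = list(g1 = c("A", "B"), g2 = c("C", "D")),
    causal_sets = list(g1 = data.frame(snp = 1:3, grr = grr),
                       g2 = data.frame(snp = 4:6, grr = grr)),
    baseline_risk = 0.01, seed = seed)
}

# all-null simulation: 4 sub-phenotypes, no causal SNPs
null_config <- function(seed, n_cases = 150, n_controls = 1000,
                        n_snps = 148) {
  sim_config(
    n_controls = n_controls,
    case_counts = stats::setNames(rep(n_cases, 4), c("A", "B", "C", "D")),
    n_snps = n_snps, maf = 0.3, baseline_risk = 0.01, seed = seed)
}
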