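#' Simulation configuration
#'
#' Describes a synthetic case-control genotype dataset with known latent
#' etiology structure. Controls are drawn at Hardy-Weinberg equilibrium
#' from the per-SNP counted-allele frequencies. Each case sub-phenotype
#' belongs to one latent etiology group; cases are drawn from the population
#' genotype distribution weighted by a multiplicative disease risk:
#' `baseline_risk` times `grr^g` per copy of each of the group's causal
#' alleles, times any two-locus interaction factor (applied when both SNPs
#' of a pair carry at least one risk allele). Non-causal SNPs are therefore
#' identically distributed in cases and controls.
#'
#' @param n_controls number of controls.
#' @param case_counts named integer vector: cases per sub-phenotype label.
#'   The default mirrors the unbalanced sub-phenotype profile typical of
#'   oral-cleft consortium data (223, 172, 244, 114, 485, 271, 336), scaled
#'   by `profile_scale`.
#' @param n_snps number of SNPs on the panel (default 148, a candidate-gene
#'   panel size).
#' @param maf counted-allele frequency per SNP in (0, 0.5]; recycled.
#' @param latent_groups named list: latent group id -> character vector of
#'   sub-phenotype labels; must partition `names(case_counts)`. Default:
#'   all sub-phenotypes in one group.
#' @param causal_sets named list parallel to `latent_groups`: each element a
#'   data.frame with columns `snp` (column index) and `grr` (genotype
#'   relative risk per allele copy, > 0).
#' @param shared_causal data.frame (`snp`, `grr`) applied to all groups.
#' @param interactions data.frame (`snp_i`, `snp_j`, `grr`): multiplicative
#'   factor applied when both loci carry >= 1 counted allele.
#' @param baseline_risk scalar in (0, 1): disease probability of the
#'   all-reference genotype.
#' @param missing_rate fraction of calls set to missing (default 0).
#' @param control_label label used for controls (default "Control").
#' @param profile_scale multiplier on the default `case_counts` profile.
#' @param seed integer RNG seed; identical configs give identical datasets.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_controls = 1000,
                       case_counts = NULL,
                       n_snps = 148,
                       maf = 0.3,
                       latent_groups = NULL,
                       causal_sets = NULL,
                       shared_causal = NULL,
                       interactions = NULL,
                       baseline_risk = 0.01,
                       missing_rate = 0,
                       control_label = "Control",
                       profile_scale = 1,
                       seed = 1L) {
  if (is.null(case_counts)) {
    case_counts <- round(profile_scale * c(
      "CP-Soft" = 223, "CP-Hard" = 172, "Left CL" = 244, "Right CL" = 114,
      "Left CLP" = 485, "Right CLP" = 271, "Bilateral CLP" = 336))
  }
  if (is.null(names(case_counts))) {
    stop("sim_config: case_counts must be named by sub-phenotype label")
  }
  labels <- names(case_counts)
  if (is.null(latent_groups)) latent_groups <- list(g1 = labels)
  got <- sort(unlist(latent_groups, use.names = FALSE))
  if (!identical(got, sort(labels))) {
    stop("sim_config: latent_groups must partition the sub-phenotype labels")
  }
  maf <- rep_len(maf, n_snps)
  stopifnot(all(maf > 0), all(maf <= 0.5),
            baseline_risk > 0, baseline_risk < 1,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(causal_sets)) {
    causal_sets <- stats::setNames(
      rep(list(data.frame(snp = integer(0), grr = numeric(0))),
          length(latent_groups)),
      names(latent_groups))
  }
  empty_pair <- data.frame(snp = integer(0), grr = numeric(0))
  if (is.null(shared_causal)) shared_causal <- empty_pair
  if (is.null(interactions)) {
    interactions <- data.frame(snp_i = integer(0), snp_j = integer(0),
                               grr = numeric(0))
  }
  all_snps <- c(unlist(lapply(causal_sets, `[[`, "snp")), shared_causal$snp,
                interactions$snp_i, interactions$snp_j)
  all_grr <- c(unlist(lapply(causal_sets, `[[`, "grr")), shared_causal$grr,
               interactions$grr)
  stopifnot(all(all_snps >= 1), all(all_snps <= n_snps), all(all_grr > 0))
  cfg <- structure(list(
    n_controls = as.integer(n_controls),
    case_counts = stats::setNames(as.integer(case_counts), labels),
    n_snps = as.integer(n_snps), maf = maf,
    latent_groups = latent_groups, causal_sets = causal_sets,
    shared_causal = shared_causal, interactions = interactions,
    baseline_risk = baseline_risk, missing_rate = missing_rate,
    control_label = control_label, seed = as.integer(seed)
  ), class = "sim_config")
  # feasibility: the riskiest genotype must still have probability <= 1
  for (g in names(latent_groups)) {
    eff <- group_effects(cfg, g)
    pmax_g <- baseline_risk *
      prod(pmax(eff$grr, 1)^2) * prod(pmax(interactions$grr, 1))
    if (pmax_g > 1) {
      stop(sprintf(
        "sim_config: disease probability exceeds 1 for some genotype in latent group '%s' (max %.3g); lower baseline_risk",
        g, pmax_g))
    }
  }
  cfg
}

# combined per-SNP multiplicative effects for one latent group
# (group-specific causal set plus shared causal SNPs; GRRs multiply if a SNP
# appears in both)
group_effects <- function(config, group) {
  eff <- rbind(config$causal_sets[[group]], config$shared_causal)
  if (nrow(eff) == 0) return(data.frame(snp = integer(0), grr = numeric(0)))
  stats::aggregate(grr ~ snp, data = eff, FUN = prod)
}

hwe_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

# disease probability for a matrix of genotypes at the risk SNPs of a group
risk_probability <- function(gmat, risk_snps, eff, interactions, baseline) {
  logp <- rep(log(baseline), nrow(gmat))
  for (i in seq_len(nrow(eff))) {
    j <- match(eff$snp[i], risk_snps)
    logp <- logp + gmat[, j] * log(eff$grr[i])
  }
  for (i in seq_len(nrow(interactions))) {
    ji <- match(interactions$snp_i[i], risk_snps)
    jj <- match(interactions$snp_j[i], risk_snps)
    both <- gmat[, ji] >= 1 & gmat[, jj] >= 1
    logp <- logp + both * log(interactions$grr[i])
  }
  pmin(exp(logp), 1)
}

# draw n case genotype vectors at the risk SNPs of one latent group.
# When the risk-SNP set is small the conditional distribution
# HWE(g) * P(disease | g) is enumerated exactly and sampled directly;
# otherwise literal rejection sampling from the population distribution.
draw_case_risk_genotypes <- function(n, config, group) {
  eff <- group_effects(config, group)
  ints <- config$interactions
  risk_snps <- sort(unique(c(eff$snp, ints$snp_i, ints$snp_j)))
  k <- length(risk_snps)
  if (k == 0L) {
    return(list(risk_snps = integer(0),
                gmat = matrix(integer(0), nrow = n, ncol = 0)))
  }
  if (3^k <= 6561) {
    cells <- as.matrix(expand.grid(rep(list(0:2), k)))
    colnames(cells) <- NULL
    hwe <- rep(1, nrow(cells))
    for (j in seq_len(k)) {
      hwe <- hwe * hwe_probs(config$maf[risk_snps[j]])[cells[, j] + 1]
    }
    w <- hwe * risk_probability(cells, risk_snps, eff, ints,
                                config$baseline_risk)
    idx <- sample.int(nrow(cells), n, replace = TRUE, prob = w)
    list(risk_snps = risk_snps, gmat = cells[idx, , drop = FALSE])
  } else {
    out <- matrix(NA_integer_, nrow = n, ncol = k)
    filled <- 0L
    while (filled < n) {
      batch <- max(1000L, 4L * (n - filled))
      gb <- vapply(risk_snps,
                   function(s) stats::rbinom(batch, 2, config$maf[s]),
                   integer(batch))
      p <- risk_probability(gb, risk_snps, eff, ints, config$baseline_risk)
      acc <- which(stats::runif(batch) < p)
      take <- utils::head(acc, n - filled)
      if (length(take) > 0) {
        out[filled + seq_along(take), ] <- gb[take, , drop = FALSE]
        filled <- filled + length(take)
      }
    }
    list(risk_snps = risk_snps, gmat = out)
  }
}

#' Simulate a case-control genotype dataset with latent etiology groups
#'
#' Generates controls at Hardy-Weinberg equilibrium and cases under the
#' multiplicative genotype-risk model of [sim_config()], together with a
#' ground-truth manifest for method-validation experiments. Deterministic
#' given the config (including its seed).
#'
#' @param config a `sim_config`.
#' @return list with components `geno` (a `genotype_matrix`), `pheno`
#'   (a `phenotype_table`) and `truth` (a `sim_truth`: the config, each
#'   sample's latent group and status, and the realized control-pool
#'   genotype frequencies).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_snps <- config$n_snps
  labels <- names(config$case_counts)
  n_cases <- sum(config$case_counts)
  n <- config$n_controls + n_cases
  calls <- matrix(NA_integer_, nrow = n, ncol = n_snps)
  # controls: HWE draws at every SNP
  for (j in seq_len(n_snps)) {
    calls[seq_len(config$n_controls), j] <-
      stats::rbinom(config$n_controls, 2, config$maf[j])
  }
  sample_ids <- c(sprintf("ctrl_%05d", seq_len(config$n_controls)),
                  character(n_cases))
  sample_labels <- c(rep(config$control_label, config$n_controls),
                     character(n_cases))
  latent_of_label <- stats::setNames(
    rep(names(config$latent_groups),
        lengths(config$latent_groups)),
    unlist(config$latent_groups, use.names = FALSE))
  sample_latent <- c(rep(NA_character_, config$n_controls),
                     character(n_cases))
  row0 <- config$n_controls
  for (g in names(config$latent_groups)) {
    group_labels <- config$latent_groups[[g]]
    n_g <- sum(config$case_counts[group_labels])
    if (n_g == 0) next
    drawn <- draw_case_risk_genotypes(n_g, config, g)
    # rows for this latent group, in sub-phenotype blocks
    rows <- integer(0)
    for (lab in labels) {
      if (!(lab %in% group_labels)) next
      n_lab <- config$case_counts[[lab]]
      idx <- row0 + seq_len(n_lab)
      sample_ids[idx] <- sprintf("case_%s_%04d", sanitize_id(lab),
                                 seq_len(n_lab))
      sample_labels[idx] <- lab
      sample_latent[idx] <- g
      rows <- c(rows, idx)
      row0 <- row0 + n_lab
    }
    non_risk <- setdiff(seq_len(n_snps), drawn$risk_snps)
    for (j in non_risk) {
      calls[rows, j] <- stats::rbinom(length(rows), 2, config$maf[j])
    }
    if (length(drawn$risk_snps) > 0) {
      calls[rows, drawn$risk_snps] <- drawn$gmat
    }
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(calls)) < config$missing_rate
    calls[miss] <- NA_integer_
  }
  variants <- data.frame(
    rsid = sprintf("snp%03d", seq_len(n_snps)),
    chromosome = as.character(rep_len(1:22, n_snps)),
    position = 1000L * seq_len(n_snps),
    gene = NA_character_,
    counted_allele = rep_len(c("A", "C", "G", "T"), n_snps),
    other_allele = rep_len(c("G", "T", "A", "C"), n_snps))
  geno <- genotype_matrix(calls, sample_ids, variants)
  pheno <- phenotype_table(sample_ids, sample_labels, config$control_label)
  ctrl_calls <- calls[seq_len(config$n_controls), , drop = FALSE]
  control_freqs <- vapply(seq_len(n_snps), function(j) {
    g <- ctrl_calls[, j]; g <- g[!is.na(g)]
    tabulate(g + 1L, nbins = 3L) / max(length(g), 1L)
  }, numeric(3))
  truth <- structure(list(
    config = config,
    sample_info = data.frame(sample_id = sample_ids, label = sample_labels,
                             latent_group = sample_latent,
                             status = c(rep("control", config$n_controls),
                                        rep("case", n_cases)),
                             stringsAsFactors = FALSE),
    control_freqs = control_freqs
  ), class = "sim_truth")
  list(geno = geno, pheno = pheno, truth = truth)
}

#' Analytic AUC of a single-SNP multiplicative risk model
#'
#' Exact enumeration of the 3 x 3 case/control genotype pairs: controls at
#' Hardy-Weinberg equilibrium, case genotype distribution proportional to
#' HWE(g) times the (capped) disease probability `baseline_risk * grr^g`.
#' Ties receive half credit, matching the Mann-Whitney AUC.
#'
#' @param maf counted-allele frequency.
#' @param grr genotype relative risk per allele copy.
#' @param baseline_risk baseline disease probability (only matters if the
#'   risk is capped at 1 for some genotype).
#' @return the AUC of genotype (equivalently likelihood-ratio) scoring.
#' @export
expected_auc <- function(maf, grr, baseline_risk = 0.01) {
  ctrl <- hwe_probs(maf)
  w <- ctrl * pmin(baseline_risk * grr^(0:2), 1)
  case <- w / sum(w)
  auc <- 0
  for (gc in 0:2) {
    for (gn in 0:2) {
      auc <- auc + case[gc + 1] * ctrl[gn + 1] *
        (if (gc > gn) 1 else if (gc == gn) 0.5 else 0)
    }
  }
  auc
}

#' Write a simulation ground-truth manifest as JSON
#' @param truth a `sim_truth`.
#' @param path output file.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(list(
    config = unclass(truth$config),
    sample_info = truth$sample_info,
    control_freqs = truth$control_freqs
  ), path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}
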