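#' Construct a genotype matrix
#'
#' Container for additive-coded genotype calls: an integer matrix of 0/1/2
#' (count of the counted allele) or NA for missing, with samples in rows and
#' variants in columns, plus per-variant metadata.
#'
#' @param calls integer matrix, samples x variants, values in 0/1/2/NA.
#' @param sample_ids unique sample identifiers (one per row).
#' @param variants data.frame with at least `rsid`; optional `chromosome`,
#'   `position` (1-based), `gene`, `counted_allele`, `other_allele`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sample_ids, variants) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.character(variants)) variants <- data.frame(rsid = variants)
  stopifnot(nrow(calls) == length(sample_ids),
            ncol(calls) == nrow(variants))
  if (anyDuplicated(sample_ids)) {
    stop("genotype_matrix: duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(variants$rsid)) {
    stop("genotype_matrix: duplicated rsids")
  }
  bad <- which(!is.na(calls) & !(calls %in% 0:2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "genotype_matrix: call outside {0,1,2,NA} at sample '%s', variant '%s'",
      sample_ids[bad[1, 1]], variants$rsid[bad[1, 2]]))
  }
  for (col in c("chromosome", "gene", "counted_allele", "other_allele")) {
    if (is.null(variants[[col]])) variants[[col]] <- NA_character_
  }
  if (is.null(variants$position)) variants$position <- NA_integer_
  if (any(!is.na(variants$position) & variants$position < 1)) {
    stop("genotype_matrix: positions must be >= 1")
  }
  dimnames(calls) <- list(sample_ids, variants$rsid)
  structure(list(calls = calls, sample_ids = sample_ids, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Read a genotype file
#'
#' Two dialects are supported. `tsv`: a tab-separated table whose first
#' column is the sample id and remaining columns are one rsid each, cells
#' 0/1/2 or NA. `plink_raw`: the PLINK additive-recode format (space
#' delimited; leading columns FID IID PAT MAT SEX PHENOTYPE; one column per
#' SNP named `rsid_A` where the suffix is the counted allele). For
#' `plink_raw` the IID column provides the sample id; the PHENOTYPE column
#' is ignored, the phenotype table being the single source of truth.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_genotypes: no such file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2) stop("read_genotypes: malformed header (need sample_id plus >=1 variant column)")
    sample_ids <- df[[1]]
    rsids <- colnames(df)[-1]
    calls <- parse_call_block(df[-1], sample_ids, rsids)
    genotype_matrix(calls, sample_ids, data.frame(rsid = rsids))
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            colClasses = "character")
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(df) < 7 || !identical(colnames(df)[1:6], lead)) {
      stop("read_genotypes: malformed PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE ...)")
    }
    snp_cols <- colnames(df)[-(1:6)]
    us <- regexpr("_[^_]*$", snp_cols)
    if (any(us < 0)) {
      stop("read_genotypes: PLINK .raw SNP column without _allele suffix: ",
           snp_cols[which(us < 0)[1]])
    }
    rsids <- substr(snp_cols, 1, us - 1)
    counted <- substring(snp_cols, us + 1)
    sample_ids <- df$IID
    calls <- parse_call_block(df[-(1:6)], sample_ids, rsids)
    genotype_matrix(calls, sample_ids,
                    data.frame(rsid = rsids, counted_allele = counted))
  }
}

# character data.frame of calls -> validated integer matrix
parse_call_block <- function(block, sample_ids, rsids) {
  calls <- matrix(NA_integer_, nrow = length(sample_ids), ncol = length(rsids))
  for (j in seq_along(rsids)) {
    v <- trimws(block[[j]])
    v[v %in% c("NA", "", ".")] <- NA
    num <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(num) | !(num %in% 0:2)))
    if (length(bad) > 0) {
      stop(sprintf(
        "read_genotypes: invalid call '%s' at sample '%s', variant '%s'",
        v[bad[1]], sample_ids[bad[1]], rsids[j]))
    }
    calls[, j] <- num
  }
  calls
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()]; both dialects round-trip the call matrix
#' exactly. The `plink_raw` dialect writes the counted allele as the SNP
#' column suffix (falling back to "A" when unknown) and fills the pedigree
#' and PHENOTYPE columns with placeholders.
#'
#' @param geno a `genotype_matrix`.
#' @param path output file.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @export
write_genotypes <- function(geno, path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(geno, "genotype_matrix"))
  if (dialect == "tsv") {
    df <- data.frame(sample_id = geno$sample_ids, check.names = FALSE)
    df[geno$variants$rsid] <- as.data.frame(geno$calls)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    counted <- geno$variants$counted_allele
    counted[is.na(counted)] <- "A"
    df <- data.frame(FID = geno$sample_ids, IID = geno$sample_ids,
                     PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                     check.names = FALSE)
    df[paste0(geno$variants$rsid, "_", counted)] <- as.data.frame(geno$calls)
    utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a phenotype table
#'
#' Assigns each sample a label: one designated control label, every other
#' label a case sub-phenotype. Case labels keep first-appearance order.
#'
#' @param sample_ids sample identifiers (unique).
#' @param labels character vector of labels, parallel to `sample_ids`.
#' @param control_label the label marking controls; must occur.
#' @return object of class `phenotype_table`: data.frame-backed mapping plus
#'   `control_label` and ordered `case_labels`.
#' @export
phenotype_table <- function(sample_ids, labels, control_label) {
  stopifnot(length(sample_ids) == length(labels))
  if (anyDuplicated(sample_ids)) {
    stop("phenotype_table: duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (!(control_label %in% labels)) {
    stop("phenotype_table: control label '", control_label, "' not present")
  }
  structure(list(
    samples = data.frame(sample_id = sample_ids, label = labels,
                         stringsAsFactors = FALSE),
    control_label = control_label,
    case_labels = setdiff(unique(labels), control_label)
  ), class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("<phenotype_table> %d samples: %d controls ('%s'), %d case sub-phenotypes\n",
              nrow(x$samples), sum(x$samples$label == x$control_label),
              x$control_label, length(x$case_labels)))
  invisible(x)
}

#' Per-label sample counts of a phenotype table
#' @param pheno a `phenotype_table`.
#' @return named integer vector, control label first then case labels.
#' @export
label_counts <- function(pheno) {
  tab <- table(pheno$samples$label)
  ord <- c(pheno$control_label, pheno$case_labels)
  stats::setNames(as.integer(tab[ord]), ord)
}

#' Sample ids carrying a given label
#' @param pheno a `phenotype_table`.
#' @param label a label (or vector of labels).
#' @return character vector of sample ids.
#' @export
samples_with_label <- function(pheno, label) {
  pheno$samples$sample_id[pheno$samples$label %in% label]
}

#' Read a phenotype table from a two-column TSV
#'
#' Expects a header line `sample_id<TAB>label`.
#'
#' @param path file path.
#' @param control_label label marking controls.
#' @return a `phenotype_table`.
#' @export
read_phenotypes <- function(path, control_label) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "label") %in% colnames(df))) {
    stop("read_phenotypes: expected columns sample_id and label")
  }
  phenotype_table(df$sample_id, df$label, control_label)
}

#' Write a phenotype table
#' @param pheno a `phenotype_table`.
#' @param path output TSV.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sub-phenotype filter policy
#'
#' Small or uninformative sub-phenotypes are dropped before analysis: any
#' case label in `excluded_labels` (e.g. a catch-all "Unknown" category,
#' whose genetic causes are likely highly heterogeneous) and any
#' sub-phenotype with fewer cases than `min_cases_per_subtype`. The default
#' threshold of 50 separates the sub-phenotype sizes typically retained in
#' candidate-SNP cleft panels (>= 114) from those excluded for small sample
#' size (<= 30).
#'
#' @param min_cases_per_subtype drop sub-phenotypes with fewer cases.
#' @param excluded_labels labels dropped outright.
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(min_cases_per_subtype = 50,
                          excluded_labels = character(0)) {
  stopifnot(min_cases_per_subtype >= 0)
  structure(list(min_cases_per_subtype = min_cases_per_subtype,
                 excluded_labels = excluded_labels),
            class = "filter_policy")
}

#' Apply a sub-phenotype filter policy
#'
#' Drops case samples whose label is excluded or whose sub-phenotype is
#' below the size threshold. Controls are never dropped. Idempotent.
#'
#' @param pheno a `phenotype_table`.
#' @param policy a `filter_policy`.
#' @return the filtered `phenotype_table`, with attribute `"filter_log"`:
#'   a data.frame (label, n, reason) of dropped sub-phenotypes.
#' @export
apply_filter <- function(pheno, policy) {
  stopifnot(inherits(pheno, "phenotype_table"),
            inherits(policy, "filter_policy"))
  counts <- table(pheno$samples$label)
  drop <- character(0); reason <- character(0); n <- integer(0)
  for (lab in pheno$case_labels) {
    if (lab %in% policy$excluded_labels) {
      drop <- c(drop, lab); reason <- c(reason, "excluded label")
      n <- c(n, as.integer(counts[lab]))
    } else if (counts[lab] < policy$min_cases_per_subtype) {
      drop <- c(drop, lab); reason <- c(reason, sprintf(
        "fewer than %d cases", policy$min_cases_per_subtype))
      n <- c(n, as.integer(counts[lab]))
    }
  }
  keep <- !(pheno$samples$label %in% drop)
  out <- phenotype_table(pheno$samples$sample_id[keep],
                         pheno$samples$label[keep],
                         pheno$control_label)
  if (length(out$case_labels) < 2) {
    stop("apply_filter: fewer than 2 case sub-phenotypes remain; merging needs at least 2 groups")
  }
  attr(out, "filter_log") <- data.frame(label = drop, n = n, reason = reason,
                                        stringsAsFactors = FALSE)
  out
}

#' Write the per-group model report
#'
#' Emits the analysis artifacts for a set of fitted group models: a TSV with
#' one row per selected SNP (group, rsid, alleles, chromosome, gene,
#' position, group AUC with confidence bounds on the group's first row), a
#' JSON serialization of each model sufficient to re-score new samples, and
#' a per-group ROC curve TSV (fpr, tpr) for plotting.
#'
#' @param models named list of `lr_model`, one per group.
#' @param rocs named list of `roc_result`, parallel to `models`.
#' @param geno the `genotype_matrix` the models refer to.
#' @param grouping named list: group id -> character vector of member
#'   sub-phenotype labels.
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the model table.
#' @export
write_model_report <- function(models, rocs, geno, grouping, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (g in names(models)) {
    m <- models[[g]]; r <- rocs[[g]]
    if (length(m$variant_indices) == 0L) {
      rows[[g]] <- data.frame(
        group = g, rsid = "", counted_allele = "", other_allele = "",
        chromosome = "", gene = "", position = NA_integer_,
        auc = 0.5, ci_lower = NA_real_, ci_upper = NA_real_)
      next
    }
    v <- geno$variants[m$variant_indices, , drop = FALSE]
    rows[[g]] <- data.frame(
      group = g, rsid = v$rsid,
      counted_allele = v$counted_allele, other_allele = v$other_allele,
      chromosome = v$chromosome, gene = v$gene, position = v$position,
      auc = c(r$auc, rep(NA_real_, nrow(v) - 1)),
      ci_lower = c(r$ci_lower, rep(NA_real_, nrow(v) - 1)),
      ci_upper = c(r$ci_upper, rep(NA_real_, nrow(v) - 1)))
    lr_model_to_json(m, file.path(dir, paste0("model_", sanitize_id(g), ".json")))
    if (!is.null(r$curve)) {
      utils::write.table(r$curve,
        file.path(dir, paste0("roc_", sanitize_id(g), ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  path <- file.path(dir, "model_report.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  jsonlite::write_json(grouping, file.path(dir, "grouping.json"))
  invisible(path)
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)
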