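#' Transcripts per million
#'
#' TPM for gene g in sample s is
#' `1e6 * (counts[g,s]/length[g]) / sum_g'(counts[g',s]/length[g'])`, so each
#' non-empty sample column sums to one million. An all-zero sample yields an
#' all-zero column with a warning.
#'
#' @param counts A [count_matrix()], or a counts tibble (first column
#'   `gene_id`) together with `gene_lengths`.
#' @param gene_lengths Tibble `gene_id`, `length`; ignored when `counts` is a
#'   `count_matrix`.
#' @return Tibble of TPM values with the same shape as the count table.
#' @export
compute_tpm <- function(counts, gene_lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    gene_lengths <- counts$gene_lengths
    counts <- counts$counts
  }
  if (is.null(gene_lengths)) abort("gene_lengths required")
  lens <- gene_lengths$length[match(counts$gene_id, gene_lengths$gene_id)]
  if (anyNA(lens)) {
    abort(paste0("no gene length for gene(s): ",
                 paste(head(counts$gene_id[is.na(lens)], 5), collapse = ", ")))
  }
  m <- as.matrix(counts[, -1, drop = FALSE])
  rate <- m / lens
  denom <- colSums(rate)
  if (any(denom == 0)) {
    warn(paste0("all-zero sample column(s): ",
                paste(colnames(m)[denom == 0], collapse = ", ")))
    denom[denom == 0] <- NA_real_
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  tpm[is.na(tpm)] <- 0
  out <- as_tibble(tpm)
  out <- bind_cols(tibble(gene_id = counts$gene_id), out)
  out
}

#' Build the in-silico parental mix
#'
#' Emulates 1:1 read mixing of the two diploid parents at the count level:
#' the MIX sample for (tissue, replicate i) stacks the A-subgenome counts
#' from the AA sample and the D-subgenome counts from the DD sample of the
#' same tissue and replicate index. TPM for MIX is computed over the union
#' gene set, so the denominator spans both subgenomes exactly as 1:1 read
#' mixing would halve each genome's share.
#'
#' @param counts_AA,counts_DD [count_matrix()] objects for the two parents
#'   with disjoint gene sets.
#' @param sheet Sample sheet covering the AA and DD samples.
#' @return List with `counts` (a `count_matrix` for the MIX genotype) and
#'   `sample_sheet`.
#' @export
build_mix <- function(counts_AA, counts_DD, sheet) {
  stopifnot(inherits(counts_AA, "count_matrix"),
            inherits(counts_DD, "count_matrix"))
  sheet <- sample_sheet(sheet)
  shared <- intersect(counts_AA$counts$gene_id, counts_DD$counts$gene_id)
  if (length(shared)) {
    abort(paste0("parent gene sets must be disjoint; shared: ",
                 paste(head(shared, 5), collapse = ", ")))
  }
  aa_sheet <- sheet %>% filter(.data$genotype == "AA")
  dd_sheet <- sheet %>% filter(.data$genotype == "DD")
  key <- function(df) paste(df$tissue, df$replicate)
  if (!setequal(key(aa_sheet), key(dd_sheet))) {
    abort("AA and DD must cover the same (tissue, replicate) combinations")
  }
  aa_sheet <- aa_sheet %>% arrange(match(.data$tissue, tissue_levels()),
                                   .data$replicate)
  cols <- list(); ids <- character(0)
  for (i in seq_len(nrow(aa_sheet))) {
    ti <- aa_sheet$tissue[i]; ri <- aa_sheet$replicate[i]
    sid_aa <- aa_sheet$sample_id[i]
    sid_dd <- dd_sheet$sample_id[dd_sheet$tissue == ti &
                                   dd_sheet$replicate == ri]
    if (length(sid_dd) != 1) {
      abort(sprintf("missing DD counterpart for tissue %s replicate %d", ti, ri))
    }
    sid <- sprintf("MIX_%s_r%d", ti, ri)
    cols[[sid]] <- c(counts_AA$counts[[sid_aa]], counts_DD$counts[[sid_dd]])
    ids <- c(ids, sid)
  }
  counts <- as_tibble(c(
    list(gene_id = c(counts_AA$counts$gene_id, counts_DD$counts$gene_id)),
    cols
  ))
  lens <- bind_rows(counts_AA$gene_lengths, counts_DD$gene_lengths)
  mix_sheet <- sample_sheet(tibble(
    sample_id = ids, genotype = "MIX",
    tissue = aa_sheet$tissue, replicate = aa_sheet$replicate
  ))
  ps_log("build_mix", "%d MIX samples over %d genes", length(ids), nrow(counts))
  list(counts = count_matrix(counts, lens), sample_sheet = mix_sheet)
}

#' Categorize genes by expression ubiquity across tissues
#'
#' A gene counts as expressed in a tissue when its replicate TPM passes the
#' threshold (mean over replicates by default; `rule = "all"` requires every
#' replicate to pass). With nine tissues the categories are: silent (0
#' tissues), specific (1), intermediate (2-7), conserved (8-9).
#'
#' @param tpm TPM tibble (first column `gene_id`).
#' @param sheet Sample sheet describing the TPM columns (one genotype).
#' @param tpm_threshold Expression threshold (strict >).
#' @param rule `"mean"` or `"all"` over replicates.
#' @return Tibble `gene_id`, `n_tissues_expressed`, `category`.
#' @export
categorize_ubiquity <- function(tpm, sheet, tpm_threshold = 1,
                                rule = c("mean", "all")) {
  rule <- match.arg(rule)
  sheet <- sample_sheet(sheet)
  if (length(unique(sheet$tissue)) != 9) {
    abort("ubiquity categories are defined for the full nine-tissue design")
  }
  m <- as.matrix(tpm[, -1, drop = FALSE])
  expressed <- vapply(unique(sheet$tissue), function(ti) {
    cols <- sheet$sample_id[sheet$tissue == ti]
    sub <- m[, cols, drop = FALSE]
    if (rule == "mean") rowMeans(sub) > tpm_threshold
    else apply(sub > tpm_threshold, 1, all)
  }, logical(nrow(m)))
  ntis <- rowSums(expressed)
  tibble(
    gene_id = tpm$gene_id,
    n_tissues_expressed = as.integer(ntis),
    category = dplyr::case_when(
      ntis == 0 ~ "silent",
      ntis == 1 ~ "specific",
      ntis <= 7 ~ "intermediate",
      TRUE ~ "conserved"
    )
  )
}

#' Per-tissue expression calls
#'
#' @inheritParams categorize_ubiquity
#' @return Tibble `gene_id`, `tissue`, `mean_tpm`, `expressed`.
#' @export
tissue_expression_calls <- function(tpm, sheet, tpm_threshold = 1,
                                    rule = c("mean", "all")) {
  rule <- match.arg(rule)
  sheet <- sample_sheet(sheet)
  m <- as.matrix(tpm[, -1, drop = FALSE])
  purrr::map_dfr(unique(sheet$tissue), function(ti) {
    cols <- sheet$sample_id[sheet$tissue == ti]
    sub <- m[, cols, drop = FALSE]
    tibble(
      gene_id = tpm$gene_id, tissue = ti, mean_tpm = rowMeans(sub),
      expressed = if (rule == "mean") rowMeans(sub) > tpm_threshold
                  else apply(sub > tpm_threshold, 1, all)
    )
  })
}

#' Sample-level PCA of log-scaled TPM
#'
#' PCA of `log2(TPM + 1)` with genes as features and samples as
#' observations, centered (not scaled). Constant expression matrices are an
#' error.
#'
#' @param tpm TPM tibble (first column `gene_id`).
#' @return Object of class `expression_pca`; use [tidy()] for per-sample
#'   coordinates and [glance()] for variance explained.
#' @export
sample_pca <- function(tpm) {
  m <- t(as.matrix(tpm[, -1, drop = FALSE]))
  if (nrow(m) < 2) abort("PCA needs at least two samples")
  lm2 <- log2(m + 1)
  if (diff(range(lm2)) < 1e-12) {
    abort("constant expression matrix; PCA undefined")
  }
  fit <- prcomp(lm2, center = TRUE, scale. = FALSE)
  structure(list(fit = fit, sample_ids = rownames(m)),
            class = "expression_pca")
}

#' @export
tidy.expression_pca <- function(x, ...) {
  sc <- x$fit$x
  out <- as_tibble(sc)
  bind_cols(tibble(sample_id = x$sample_ids), out)
}

#' @export
glance.expression_pca <- function(x, ...) {
  v <- x$fit$sdev^2
  ve <- if (sum(v) > 0) v / sum(v) else rep(0, length(v))
  tibble(component = paste0("PC", seq_along(v)),
         variance_explained = ve)
}

#' @export
print.expression_pca <- function(x, ...) {
  ve <- glance(x)$variance_explained
  cat(sprintf("<expression_pca> %d samples; PC1+PC2 explain %.1f%% variance\n",
              length(x$sample_ids), 100 * sum(ve[1:min(2, length(ve))])))
  invisible(x)
}

#' Hierarchical clustering of expression profiles
#'
#' Reporting utility: average-linkage clustering of samples under the
#' 1 - Pearson correlation distance of log2(TPM + 1) profiles.
#'
#' @param tpm TPM tibble.
#' @return An [stats::hclust] object.
#' @export
profile_hclust <- function(tpm) {
  m <- log2(as.matrix(tpm[, -1, drop = FALSE]) + 1)
  d <- as.dist(1 - cor(m))
  hclust(d, method = "average")
}
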