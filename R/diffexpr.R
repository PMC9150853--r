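#' Median-of-ratios size factors
#'
#' Size factor of a sample is the median across genes of its counts divided
#' by the gene's geometric mean over all samples, computed over genes with
#' strictly positive counts everywhere. When fewer than 10 such genes exist,
#' falls back to library-size ratios. Factors are rescaled to geometric
#' mean 1.
#'
#' @param m Numeric matrix, genes x samples.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(m) {
  m <- as.matrix(m)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (sum(all_pos) >= 10) {
    logg <- rowMeans(log(m[all_pos, , drop = FALSE]))
    sf <- apply(m[all_pos, , drop = FALSE], 2, function(col) {
      exp(median(log(col) - logg))
    })
  } else {
    lib <- colSums(m)
    if (any(lib == 0)) abort("sample with zero total counts")
    sf <- lib / exp(mean(log(lib)))
  }
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test for two groups of replicate counts
#'
#' A self-contained DESeq2-like (but not bit-compatible) test. Counts are
#' normalized by median-of-ratios size factors; a per-gene dispersion is
#' estimated by method of moments from within-group residuals (floored at
#' 1e-8) and moderated by shrinking toward the across-gene median dispersion
#' with `prior_df` pseudo-degrees of freedom (raw method-of-moments
#' dispersions at two or three replicates are too unstable to test
#' against); the Wald statistic is the log2 fold change of group 2 over
#' group 1 divided by its NB-based delta-method standard error, referred to
#' a t distribution with `n1 + n2 - 2 + prior_df` degrees of freedom
#' (two-sided).
#'
#' Genes with zero counts in every sample of the contrast are reported `NA`
#' and are meant to be excluded from multiple-testing correction. A group
#' whose every gene is all-zero is an error.
#'
#' @param counts1,counts2 Matrices (genes x replicates) with identical row
#'   order, or vectors for a single gene.
#' @param size_factors Optional per-sample size factors for
#'   `cbind(counts1, counts2)`; estimated when `NULL`.
#' @param gene_ids Optional gene ids (defaults to rownames or an index).
#' @param prior_df Prior degrees of freedom for dispersion moderation.
#' @return Tibble `gene_id`, `base_mean`, `log2fc`, `se`, `stat`, `p`.
#' @export
nb_wald_test <- function(counts1, counts2, size_factors = NULL,
                         gene_ids = NULL, prior_df = 10) {
  if (is.null(dim(counts1))) counts1 <- matrix(counts1, nrow = 1)
  if (is.null(dim(counts2))) counts2 <- matrix(counts2, nrow = 1)
  n1 <- ncol(counts1); n2 <- ncol(counts2)
  if (n1 < 2 || n2 < 2) abort("need at least two replicates per group")
  if (nrow(counts1) != nrow(counts2)) abort("groups must share the gene axis")
  if (all(counts1 == 0) || all(counts2 == 0)) {
    abort("a group with all-zero counts in every gene cannot be tested")
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(counts1) %||% as.character(seq_len(nrow(counts1)))
  }
  full <- cbind(counts1, counts2)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(full)
  if (any(size_factors <= 0)) abort("size factors must be positive")
  x <- sweep(full, 2, size_factors, "/")
  x1 <- x[, seq_len(n1), drop = FALSE]
  x2 <- x[, n1 + seq_len(n2), drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  res_df <- n1 + n2 - 2
  varhat <- ss / res_df
  mbar <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha <- pmax((varhat - mbar) / pmax(mbar, 1e-8)^2, 1e-8)
  if (prior_df > 0 && length(alpha) > 1) {
    informative <- mbar > 5
    prior <- if (any(informative)) median(alpha[informative]) else median(alpha)
    alpha <- (res_df * alpha + prior_df * prior) / (res_df + prior_df)
  }

  eps <- 0.5
  m1e <- m1 + eps; m2e <- m2 + eps
  lfc <- log2(m2e / m1e)
  v1 <- (m1e + alpha * m1e^2) / n1
  v2 <- (m2e + alpha * m2e^2) / n2
  se <- sqrt(v1 / m1e^2 + v2 / m2e^2) / log(2)
  stat <- lfc / se
  p <- 2 * pt(-abs(stat), df = res_df + prior_df)
  untested <- rowSums(full) == 0
  lfc[untested] <- NA_real_; se[untested] <- NA_real_
  stat[untested] <- NA_real_; p[untested] <- NA_real_
  tibble(gene_id = gene_ids, base_mean = mbar, log2fc = lfc, se = se,
         stat = stat, p = p)
}

#' Call differentially expressed genes
#'
#' Benjamini-Hochberg adjustment is applied within the supplied table (one
#' contrast); untested genes (`NA` p) are excluded from the correction.
#' Calls follow the fold-change and FDR thresholds (defaults: fold change
#' > 2, FDR < 0.05); the `strong` flag marks the greatest responders
#' (fold change > `strong_fold`, default 4).
#'
#' @param de Tibble from [nb_wald_test()].
#' @param fc_threshold Fold-change threshold (linear scale, strict >).
#' @param fdr_threshold FDR threshold (strict <).
#' @param strong_fold Fold change defining strong responders.
#' @return Input tibble with `fdr`, `call` (up/down/none) and `strong`.
#' @export
call_degs <- function(de, fc_threshold = 2, fdr_threshold = 0.05,
                      strong_fold = 4) {
  lfc_min <- log2(fc_threshold)
  de$fdr <- p.adjust(de$p, method = "BH")
  de %>% mutate(
    call = dplyr::case_when(
      is.na(.data$p) | .data$fdr >= fdr_threshold ~ "none",
      .data$log2fc > lfc_min ~ "up",
      .data$log2fc < -lfc_min ~ "down",
      TRUE ~ "none"
    ),
    strong = .data$call != "none" & abs(.data$log2fc) > log2(strong_fold)
  )
}

#' Categorize differential-expression calls across tissues
#'
#' Genes are grouped by the number of tissues in which they are called DE
#' (specific_DE: 1; intermediate_DE: 2-7; conserved_DE: 8-9) and, for genes
#' DE in at least two tissues, by direction concordance: up_conserved (up in
#' every DE tissue), down_conserved (down in every DE tissue), divergent
#' (mixed). Genes with no DE tissue are excluded.
#'
#' @param calls Tibble with `gene_id`, `tissue`, `call`.
#' @return Tibble `gene_id`, `n_de_tissues`, `ubiquity_DE`, `direction`.
#' @export
categorize_degs <- function(calls) {
  calls %>%
    filter(.data$call %in% c("up", "down")) %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_de_tissues = n(),
      n_up = sum(.data$call == "up"),
      n_down = sum(.data$call == "down"),
      .groups = "drop"
    ) %>%
    mutate(
      ubiquity_DE = dplyr::case_when(
        .data$n_de_tissues == 1 ~ "specific_DE",
        .data$n_de_tissues <= 7 ~ "intermediate_DE",
        TRUE ~ "conserved_DE"
      ),
      direction = dplyr::case_when(
        .data$n_de_tissues < 2 ~ NA_character_,
        .data$n_down == 0 ~ "up_conserved",
        .data$n_up == 0 ~ "down_conserved",
        TRUE ~ "divergent"
      )
    ) %>%
    select("gene_id", "n_de_tissues", "ubiquity_DE", "direction")
}

#' Identify spike-development-related genes
#'
#' A gene is an SDRG when its parental-mix expression in at least one spike
#' developmental stage is at least `fold` times the reference of the four
#' non-spike tissue means (reference = their max by default, the stricter
#' reading; `"mean"` is also supported). Given allotetraploid-vs-mix calls
#' for the spike stages, an SDRG down-called in at least `min_down_stages`
#' of the five spike stages is flagged stably downregulated.
#'
#' @param tpm_mix TPM tibble for the parental mix.
#' @param sheet_mix Sample sheet for the MIX samples (all nine tissues).
#' @param de_calls Optional tibble (`gene_id`, `tissue`, `call`) of
#'   AT2-vs-Mix calls for spike tissues.
#' @param fold Upregulation factor (>=).
#' @param min_down_stages Spike stages required for the stable-down flag.
#' @param reference `"max"` or `"mean"` of non-spike tissue means.
#' @return Tibble `gene_id`, `max_spike_tpm`, `nonspike_ref`, `sdrg`,
#'   `stably_down`.
#' @export
identify_sdrgs <- function(tpm_mix, sheet_mix, de_calls = NULL, fold = 2,
                           min_down_stages = 3,
                           reference = c("max", "mean")) {
  reference <- match.arg(reference)
  sheet_mix <- sample_sheet(sheet_mix)
  missing_spike <- setdiff(spike_tissues(), unique(sheet_mix$tissue))
  if (length(missing_spike)) {
    abort(paste0("missing spike tissue(s): ",
                 paste(missing_spike, collapse = ", ")))
  }
  m <- as.matrix(tpm_mix[, -1, drop = FALSE])
  tissue_mean <- vapply(unique(sheet_mix$tissue), function(ti) {
    rowMeans(m[, sheet_mix$sample_id[sheet_mix$tissue == ti], drop = FALSE])
  }, numeric(nrow(m)))
  spikes <- intersect(colnames(tissue_mean), spike_tissues())
  nonspikes <- setdiff(colnames(tissue_mean), spikes)
  max_spike <- apply(tissue_mean[, spikes, drop = FALSE], 1, max)
  ref <- if (reference == "max") {
    apply(tissue_mean[, nonspikes, drop = FALSE], 1, max)
  } else {
    rowMeans(tissue_mean[, nonspikes, drop = FALSE])
  }
  sdrg <- max_spike > 0 & max_spike >= fold * ref
  out <- tibble(gene_id = tpm_mix$gene_id, max_spike_tpm = max_spike,
                nonspike_ref = ref, sdrg = sdrg)
  if (!is.null(de_calls)) {
    downs <- de_calls %>%
      filter(.data$tissue %in% spike_tissues(), .data$call == "down") %>%
      count(.data$gene_id, name = "n_down_spike")
    out <- out %>%
      left_join(downs, by = "gene_id") %>%
      mutate(n_down_spike = dplyr::coalesce(.data$n_down_spike, 0L),
             stably_down = .data$sdrg &
               .data$n_down_spike >= min_down_stages)
  } else {
    out$stably_down <- NA
  }
  out
}
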