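#' Call homoeolog expression bias
#'
#' Tests A-homoeolog vs D-homoeolog counts within one genotype context
#' (parental mix: Ad vs Dd; allotetraploid: At vs Dt) per tissue with the
#' package's negative-binomial Wald test. Counts are first rescaled to a
#' common per-kilobase basis (`1000 / CDS length`) because homoeologs may
#' differ in length and raw-count fold changes would absorb the length
#' ratio. A pair is A-biased when the A/D fold change exceeds
#' `fc_threshold` at `fdr < fdr_threshold` (BH within tissue), D-biased
#' symmetric, otherwise unbiased.
#'
#' @param quad_counts Long quadruplet count table (`pair_id`, `tissue`,
#'   `replicate`, `Ad`, `Dd`, `At`, `Dt`).
#' @param pairs Pair table with `pair_id`, `length_A`, `length_D`.
#' @param context `"MIX"` or `"AT2"`.
#' @param fc_threshold,fdr_threshold Bias thresholds (fold change > 2, FDR
#'   < 0.05 by default).
#' @return Tibble `pair_id`, `tissue`, `context`, `log2fc_AvsD`, `p`,
#'   `fdr`, `bias`.
#' @export
call_heb <- function(quad_counts, pairs, context = c("MIX", "AT2"),
                     fc_threshold = 2, fdr_threshold = 0.05) {
  context <- match.arg(context)
  cols <- if (context == "MIX") c("Ad", "Dd") else c("At", "Dt")
  lfc_min <- log2(fc_threshold)
  len <- pairs[match(unique(sort(quad_counts$pair_id)), pairs$pair_id), ]
  out <- purrr::map_dfr(sort(unique(quad_counts$tissue)), function(ti) {
    qm <- quad_to_matrices(quad_counts %>% filter(.data$tissue == ti), cols)
    scale_A <- 1000 / len$length_A[match(qm$index$pair_id, len$pair_id)]
    scale_D <- 1000 / len$length_D[match(qm$index$pair_id, len$pair_id)]
    a <- qm$mats[[cols[1]]] * scale_A
    d <- qm$mats[[cols[2]]] * scale_D
    de <- nb_wald_test(d, a, gene_ids = qm$index$pair_id)  # lfc = A over D
    tibble(pair_id = qm$index$pair_id, tissue = ti, context = context,
           log2fc_AvsD = de$log2fc, p = de$p,
           fdr = p.adjust(de$p, method = "BH"))
  })
  out %>% mutate(
    bias = dplyr::case_when(
      is.na(.data$p) | .data$fdr >= fdr_threshold ~ "none",
      .data$log2fc_AvsD > lfc_min ~ "A",
      .data$log2fc_AvsD < -lfc_min ~ "D",
      TRUE ~ "none"
    )
  )
}

#' Trace homoeolog-bias trajectories between the parental mix and the
#' allotetraploid
#'
#' Maps the (mix bias, allotetraploid bias) pair onto the four trajectory
#' groups: identical bias direction in both contexts (including none/none)
#' is parental legacy; bias present in the mix but gone in the
#' allotetraploid is convergence; de-novo bias only in the allotetraploid is
#' divergence; opposite directions is reversion. The mapping is total over
#' the nine bias combinations.
#'
#' @param mix_bias,at2_bias Character vectors over `{"A", "D", "none"}`.
#' @return Character vector of trajectory groups.
#' @export
classify_heb_group <- function(mix_bias, at2_bias) {
  ok <- c("A", "D", "none")
  if (!all(mix_bias %in% ok) || !all(at2_bias %in% ok)) {
    abort("bias values must be 'A', 'D' or 'none'")
  }
  dplyr::case_when(
    mix_bias == at2_bias ~ "parental_legacy",
    mix_bias != "none" & at2_bias == "none" ~ "convergence",
    mix_bias == "none" & at2_bias != "none" ~ "divergence",
    TRUE ~ "reversion"
  )
}

#' Net homoeolog expression bias (ratio-of-ratios)
#'
#' Following the Flagel-Wendel approach, each pair's TPM values are
#' converted per replicate to the log2 A/D ratio (pseudo-TPM `epsilon`
#' guards zeros), and the allotetraploid ratios are compared with the
#' parental-mix ratios by a two-sided Welch t-test. The net bias call
#' requires the ratio shift to exceed the fold-change threshold
#' (`|delta| > log2(fc_threshold)`) at `p < alpha`: A when the
#' allotetraploid ratio moved toward A, D symmetric. Pairs with both
#' members zero in every replicate of both contexts get `p = NA` and call
#' none.
#'
#' @param quad_tpm Long quadruplet TPM table.
#' @param epsilon Pseudo-TPM added to both members.
#' @param fc_threshold Fold-change threshold on the ratio shift.
#' @param alpha Significance threshold.
#' @return Tibble `pair_id`, `tissue`, `delta`, `p`, `call`.
#' @export
net_heb <- function(quad_tpm, epsilon = 0.5, fc_threshold = 2, alpha = 0.05) {
  lfc_min <- log2(fc_threshold)
  qm <- quad_to_matrices(quad_tpm, c("Ad", "Dd", "At", "Dt"))
  r_mix <- log2((qm$mats$Ad + epsilon) / (qm$mats$Dd + epsilon))
  r_at2 <- log2((qm$mats$At + epsilon) / (qm$mats$Dt + epsilon))
  wt <- row_t_welch(r_at2, r_mix)
  all_zero <- rowSums(qm$mats$Ad + qm$mats$Dd + qm$mats$At + qm$mats$Dt) == 0
  p <- wt$p; p[all_zero] <- NA_real_
  delta <- wt$delta; delta[all_zero] <- NA_real_
  tibble(
    pair_id = qm$index$pair_id, tissue = qm$index$tissue,
    delta = delta, p = p,
    call = dplyr::case_when(
      is.na(p) | p >= alpha ~ "none",
      delta > lfc_min ~ "A",
      delta < -lfc_min ~ "D",
      TRUE ~ "none"
    )
  )
}

#' Stable spike-stage homoeolog bias
#'
#' A pair is stably A-biased when it shows A-bias in at least
#' `min_stages` of the five spike developmental stages (D symmetric).
#'
#' @param calls Bias calls (tibble `pair_id`, `tissue`, `bias`) for the
#'   allotetraploid spike stages.
#' @param min_stages Required number of biased spike stages.
#' @return Tibble `pair_id`, `n_A`, `n_D`, `stable_A`, `stable_D`.
#' @export
stable_spike_heb <- function(calls, min_stages = 3) {
  calls %>%
    filter(.data$tissue %in% spike_tissues()) %>%
    group_by(.data$pair_id) %>%
    summarise(n_A = sum(.data$bias == "A"), n_D = sum(.data$bias == "D"),
              .groups = "drop") %>%
    mutate(stable_A = .data$n_A >= min_stages,
           stable_D = .data$n_D >= min_stages)
}
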