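#' Ratio statistics for homoeolog-specific expression
#'
#' Per pair and tissue, the parental divergence A is the replicate mean of
#' `a_i = log2((Ad_i + eps)/(Dd_i + eps))` and the allotetraploid divergence
#' B the mean of `b_i = log2((At_i + eps)/(Dt_i + eps))`; the trans estimate
#' is A - B. Three two-sided tests accompany the estimates: one-sample t of
#' the `a_i` against zero (`p_A`), likewise for `b_i` (`p_B`), and a
#' two-sample Welch t of `a_i` vs `b_i` (`p_AB`; the contexts are
#' independent samples). Degenerate zero-variance cases use the convention
#' p = 1 at zero mean, p = 0 otherwise.
#'
#' @param quad_tpm Long quadruplet TPM table (`pair_id`, `tissue`,
#'   `replicate`, `Ad`, `Dd`, `At`, `Dt`).
#' @param epsilon Pseudo-TPM.
#' @return Tibble `pair_id`, `tissue`, `A`, `B`, `trans_est`, `p_A`, `p_B`,
#'   `p_AB`, `expressed` (FALSE when all four members are zero in every
#'   replicate).
#' @export
hse_statistics <- function(quad_tpm, epsilon = 0.5) {
  qm <- quad_to_matrices(quad_tpm, c("Ad", "Dd", "At", "Dt"))
  if (qm$n_reps < 2) abort("need at least two replicates per context")
  a <- log2((qm$mats$Ad + epsilon) / (qm$mats$Dd + epsilon))
  b <- log2((qm$mats$At + epsilon) / (qm$mats$Dt + epsilon))
  tA <- row_t_one_sample(a)
  tB <- row_t_one_sample(b)
  tAB <- row_t_welch(a, b)
  n_degen <- sum(tA$p %in% c(0, 1) | tB$p %in% c(0, 1))
  ps_log("hse_statistics", "%d records, %d with degenerate variance",
         nrow(qm$index), n_degen)
  tibble(
    pair_id = qm$index$pair_id, tissue = qm$index$tissue,
    A = tA$mean, B = tB$mean, trans_est = tA$mean - tB$mean,
    p_A = tA$p, p_B = tB$p, p_AB = tAB$p,
    expressed = rowSums(qm$mats$Ad + qm$mats$Dd +
                          qm$mats$At + qm$mats$Dt) > 0
  )
}

#' Seven-category cis/trans classification
#'
#' Classifies each pair-tissue record from the three significance outcomes
#' ("X = 0" means p_X >= alpha, "A = B" means p_AB >= alpha) and the signs
#' of A and B:
#'
#' * conserved: A = B, A = 0, B = 0
#' * cis_only: A = B, A != 0, B != 0
#' * trans_only: A != B, A != 0, B = 0
#' * cis_plus_trans: A != B, A != 0, B != 0, same signs
#' * cis_times_trans: A != B, A != 0, B != 0, opposite signs
#' * compensatory: A != B, A = 0, B != 0
#' * ambiguous: every remaining significance pattern
#'
#' The table is total and mutually exclusive. Pairs failing the expression
#' filter (column `expressed` FALSE) are reported `NA` rather than
#' conserved.
#'
#' @param stats Tibble from [hse_statistics()].
#' @param alpha Per-test significance level (unadjusted by default).
#' @param adjust `"none"` (the default) or `"BH"` across pairs within each
#'   test and tissue.
#' @return Input tibble with `sig_A`, `sig_B`, `sig_AB` and `category`.
#' @export
classify_hse <- function(stats, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p_A <- stats$p_A; p_B <- stats$p_B; p_AB <- stats$p_AB
  if (adjust == "BH") {
    adj <- function(p) stats::ave(p, stats$tissue,
                                  FUN = function(x) p.adjust(x, "BH"))
    p_A <- adj(p_A); p_B <- adj(p_B); p_AB <- adj(p_AB)
  }
  out <- stats %>% mutate(
    sig_A = p_A < alpha, sig_B = p_B < alpha, sig_AB = p_AB < alpha,
    category = hse_decision_table(.data$sig_A, .data$sig_B, .data$sig_AB,
                                  sign(.data$A), sign(.data$B))
  )
  if ("expressed" %in% names(out)) {
    out$category[!out$expressed] <- NA_character_
  }
  out
}

# the decision table proper; total over all significance/sign combinations
hse_decision_table <- function(sig_A, sig_B, sig_AB, sign_A, sign_B) {
  dplyr::case_when(
    !sig_A & !sig_B & !sig_AB ~ "conserved",
    sig_A & sig_B & !sig_AB ~ "cis_only",
    sig_A & !sig_B & sig_AB ~ "trans_only",
    sig_A & sig_B & sig_AB & sign_A == sign_B ~ "cis_plus_trans",
    sig_A & sig_B & sig_AB & sign_A != sign_B ~ "cis_times_trans",
    !sig_A & sig_B & sig_AB ~ "compensatory",
    TRUE ~ "ambiguous"
  )
}

# noiseless category implied by planted cis/trans effects (A = c + t, B = c)
derive_hse_category <- function(c_eff, t_eff, tol = 1e-9) {
  A <- c_eff + t_eff
  B <- c_eff
  zA <- abs(A) < tol; zB <- abs(B) < tol; zAB <- abs(A - B) < tol
  hse_decision_table(!zA, !zB, !zAB, sign(A), sign(B))
}

#' Summarise cis/trans categories across pairs and tissues
#'
#' @param results Classified tibble from [classify_hse()].
#' @return List with `by_tissue` (per-tissue category proportions over
#'   classified pairs) and `conservation` (per pair: modal category and the
#'   number of tissues sharing it).
#' @export
hse_summary <- function(results) {
  classified <- results %>% filter(!is.na(.data$category))
  by_tissue <- classified %>%
    count(.data$tissue, .data$category) %>%
    group_by(.data$tissue) %>%
    mutate(proportion = .data$n / sum(.data$n)) %>%
    ungroup()
  conservation <- classified %>%
    count(.data$pair_id, .data$category) %>%
    group_by(.data$pair_id) %>%
    arrange(dplyr::desc(.data$n), .data$category, .by_group = TRUE) %>%
    summarise(modal_category = first(.data$category),
              n_tissues_modal = first(.data$n), .groups = "drop")
  list(by_tissue = by_tissue, conservation = conservation)
}
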