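# standard genetic code, keyed by codon
GENETIC_CODE_TABLE <- as.list(Biostrings::GENETIC_CODE)

#' Call one-to-one homoeolog pairs from tabular alignments
#'
#' Alignment records between A-subgenome and D-subgenome CDS are filtered by
#' the pairing criteria (E-value below `max_evalue`, percent identity at
#' least `100 * min_ident`, and aligned region covering more than `min_cov`
#' of the CDS length of *both* sequences), then paired by reciprocal best
#' bitscore. Ties are broken by higher percent identity, then lexicographic
#' partner id. Each gene appears in at most one pair. Multiple HSPs for a
#' (query, subject) pair are not chained; the best-bitscore HSP represents
#' the pair.
#'
#' @param alignments Tibble from [read_alignments()].
#' @param annotation Tibble from [gene_annotation()] with a `cds_length`
#'   column (bp) used as the coverage denominator.
#' @param min_cov Minimum aligned fraction of each CDS (strict >).
#' @param min_ident Minimum identity as a fraction (0.90 = 90%).
#' @param max_evalue Maximum E-value (strict <).
#' @return Tibble with `pair_id`, `gene_A`, `gene_D`, `pct_identity`,
#'   `bitscore`.
#' @export
call_pairs <- function(alignments, annotation, min_cov = 0.60,
                       min_ident = 0.90, max_evalue = 1e-5) {
  annotation <- gene_annotation(annotation)
  if (!"cds_length" %in% names(annotation)) {
    abort("annotation needs a cds_length column for coverage")
  }
  unknown <- setdiff(unique(c(alignments$query, alignments$subject)),
                     annotation$gene_id)
  if (length(unknown)) {
    abort(paste0("alignment names gene(s) absent from annotation: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  look <- function(ids, col) annotation[[col]][match(ids, annotation$gene_id)]
  aln <- alignments %>%
    mutate(
      qlen = look(.data$query, "cds_length"),
      slen = look(.data$subject, "cds_length"),
      qsub = look(.data$query, "subgenome"),
      ssub = look(.data$subject, "subgenome")
    )
  if (any(aln$qsub == aln$ssub)) {
    abort("alignments must be between A-subgenome and D-subgenome genes")
  }
  keep <- aln %>%
    filter(.data$evalue < max_evalue,
           .data$pct_identity >= 100 * min_ident,
           .data$aln_length / .data$qlen > min_cov,
           .data$aln_length / .data$slen > min_cov)
  ps_log("call_pairs", "%d/%d records survive filters", nrow(keep),
         nrow(alignments))
  if (!nrow(keep)) {
    return(tibble(pair_id = character(), gene_A = character(),
                  gene_D = character(), pct_identity = double(),
                  bitscore = double()))
  }
  # orient every record A -> D, keep the best HSP per gene pair
  oriented <- keep %>%
    mutate(gene_A = if_else(.data$qsub == "A", .data$query, .data$subject),
           gene_D = if_else(.data$qsub == "A", .data$subject, .data$query)) %>%
    arrange(dplyr::desc(.data$bitscore), dplyr::desc(.data$pct_identity),
            .data$gene_A, .data$gene_D) %>%
    distinct(.data$gene_A, .data$gene_D, .keep_all = TRUE)
  best_of <- function(df, key, partner) {
    df %>%
      group_by(.data[[key]]) %>%
      arrange(dplyr::desc(.data$bitscore), dplyr::desc(.data$pct_identity),
              .data[[partner]], .by_group = TRUE) %>%
      slice(1) %>%
      ungroup()
  }
  best_A <- best_of(oriented, "gene_A", "gene_D")
  best_D <- best_of(oriented, "gene_D", "gene_A")
  rbh <- inner_join(
    best_A %>% select("gene_A", "gene_D", "pct_identity", "bitscore"),
    best_D %>% select("gene_A", "gene_D"),
    by = c("gene_A", "gene_D")
  ) %>% arrange(.data$gene_A)
  rbh %>% mutate(pair_id = sprintf("pair%05d", row_number()),
                 .before = "gene_A")
}

# NG86 synonymous/non-synonymous site counts for one gap-free CDS.
# Fractional 1/3 counting; substitutions creating a stop codon count as
# non-synonymous. Codons containing non-ACGT symbols contribute nothing.
ng86_sites <- function(cds) {
  codons <- codon_split(cds)
  s <- 0; total <- 0
  for (cd in codons) {
    if (is.na(cd)) next
    aa <- GENETIC_CODE_TABLE[[cd]]
    ch <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
        alt <- ch; alt[pos] <- b
        alt_aa <- GENETIC_CODE_TABLE[[paste(alt, collapse = "")]]
        if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
      }
    }
    total <- total + 3
  }
  c(S = s, N = total - s)
}

codon_split <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) abort("CDS length must be divisible by 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  ok <- !grepl("[^ACGT]", codons)
  if (any(GENETIC_CODE_TABLE[codons[ok]] == "*")) {
    abort("internal stop codon in CDS")
  }
  ifelse(ok, codons, NA_character_)
}

perms <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# average synonymous/non-synonymous differences between two codons over all
# minimal substitution paths; paths through stop codons are excluded (all
# paths are used if every path hits a stop)
codon_path_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  orders <- perms(k)
  paths <- matrix(NA_real_, nrow = nrow(orders), ncol = 2)
  valid <- logical(nrow(orders))
  for (r in seq_len(nrow(orders))) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (step in orders[r, ]) {
      pos <- diff_pos[step]
      nxt <- cur; nxt[pos] <- b[pos]
      aa1 <- GENETIC_CODE_TABLE[[paste(cur, collapse = "")]]
      aa2 <- GENETIC_CODE_TABLE[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !identical(nxt, b)) ok <- FALSE
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    paths[r, ] <- c(sd, nd)
    valid[r] <- ok
  }
  use <- if (any(valid)) paths[valid, , drop = FALSE] else paths
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Operates on an equal-length, gap-free, in-frame codon alignment.
#' Synonymous and non-synonymous sites are counted fractionally (1/3 per
#' position) and averaged over the two sequences; substitution paths between
#' differing codons are averaged over all orderings, excluding paths that
#' pass through a stop codon. Proportions are corrected with
#' d = -3/4 log(1 - 4p/3); saturation (p >= 3/4) yields `NaN` with a
#' warning. Codons containing `N` are excluded from both sites and
#' differences.
#'
#' @param cds_A,cds_D Aligned CDS strings of equal length.
#' @param correction `"jc"` (Jukes-Cantor, the default) or `"none"` to
#'   return the raw substitution proportions Sd/S and Nd/N.
#' @return Named numeric vector `c(Ka, Ks)`. A rate is `NaN` when the
#'   corresponding site class is absent or saturated.
#' @export
ng86_ka_ks <- function(cds_A, cds_D, correction = c("jc", "none")) {
  correction <- match.arg(correction)
  if (nchar(cds_A) != nchar(cds_D)) abort("aligned CDS must have equal length")
  ca <- codon_split(cds_A)
  cb <- codon_split(cds_D)
  ok <- !is.na(ca) & !is.na(cb)
  sites <- (ng86_sites(paste(ca[ok], collapse = "")) +
              ng86_sites(paste(cb[ok], collapse = ""))) / 2
  sd_tot <- 0; nd_tot <- 0
  for (i in which(ok)) {
    d <- codon_path_diffs(ca[i], cb[i])
    sd_tot <- sd_tot + d["sd"]; nd_tot <- nd_tot + d["nd"]
  }
  jc <- function(p) {
    if (is.nan(p) || correction == "none") return(p)
    if (p >= 3 / 4) {
      warn("substitution proportion saturated (p >= 3/4); returning NaN")
      return(NaN)
    }
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ps <- if (sites["S"] > 0) sd_tot / sites["S"] else NaN
  pn <- if (sites["N"] > 0) nd_tot / sites["N"] else NaN
  c(Ka = unname(jc(pn)), Ks = unname(jc(ps)))
}

#' Promoter p-distance
#'
#' Proportion of mismatching positions over aligned, comparable columns;
#' columns where either sequence has `N` or a gap are excluded. With zero
#' comparable columns the distance is `NaN`.
#'
#' @param prom_A,prom_D Aligned promoter strings of equal length.
#' @return A proportion in [0, 1], or `NaN`.
#' @export
promoter_pdistance <- function(prom_A, prom_D) {
  if (nchar(prom_A) != nchar(prom_D)) {
    abort("aligned promoters must have equal length")
  }
  a <- strsplit(toupper(prom_A), "")[[1]]
  b <- strsplit(toupper(prom_D), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NaN)
  mean(a[ok] != b[ok])
}

#' Sequence divergence for a homoeolog pair table
#'
#' @param pairs Tibble with `pair_id`, `gene_A`, `gene_D`.
#' @param cds Named character vector of CDS (names = gene ids).
#' @param promoters Optional named character vector of promoters.
#' @return Tibble `pair_id`, `Ka`, `Ks`, `promoter_pdist`.
#' @export
pair_divergence <- function(pairs, cds, promoters = NULL) {
  res <- purrr::map2(pairs$gene_A, pairs$gene_D, function(ga, gd) {
    ng86_ka_ks(cds[[ga]], cds[[gd]])
  })
  out <- tibble(
    pair_id = pairs$pair_id,
    Ka = purrr::map_dbl(res, "Ka"),
    Ks = purrr::map_dbl(res, "Ks")
  )
  out$promoter_pdist <- if (is.null(promoters)) NA_real_ else {
    purrr::map2_dbl(pairs$gene_A, pairs$gene_D, function(ga, gd) {
      promoter_pdistance(promoters[[ga]], promoters[[gd]])
    })
  }
  out
}

#' Compare sequence divergence across connectivity groups
#'
#' Reporting utility: one-way ANOVA with Tukey HSD of a divergence measure
#' (Ka, Ks or promoter p-distance) across homoeolog connectivity groups.
#'
#' @param divergence Tibble from [pair_divergence()].
#' @param groups Tibble with `pair_id` and `group`.
#' @param measure One of "Ka", "Ks", "promoter_pdist".
#' @return List with the per-group means, the ANOVA p-value and the Tukey
#'   table.
#' @export
divergence_by_group <- function(divergence, groups,
                                measure = c("Ka", "Ks", "promoter_pdist")) {
  measure <- match.arg(measure)
  df <- inner_join(divergence, groups, by = "pair_id") %>%
    filter(is.finite(.data[[measure]]), !is.na(.data$group))
  df$group <- factor(df$group)
  if (nlevels(df$group) < 2) abort("need at least two groups")
  fit <- aov(df[[measure]] ~ group, data = df)
  list(
    means = df %>% group_by(.data$group) %>%
      summarise(mean = mean(.data[[measure]]), n = n(), .groups = "drop"),
    anova_p = summary(fit)[[1]][["Pr(>F)"]][1],
    tukey = as.data.frame(TukeyHSD(fit)$group)
  )
}
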