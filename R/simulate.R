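#' Configuration for the quadruplet count simulator
#'
#' The generator emits negative-binomial gene-level counts for a homoeolog
#' quadruplet design: each gene pair is observed in four expression contexts
#' (Ad, Dd in the two diploid parents; At, Dt in the allotetraploid) across
#' tissues and replicates, together with a per-pair ground-truth table.
#'
#' The generative model places each pair's expected parental log-ratio at
#' `c + t` and its allotetraploid log-ratio at `c`, where `c` is the planted
#' cis effect and `t` the planted trans effect (the trans effect is shared in
#' the common nucleus, so it cancels from the homoeolog ratio). The planted
#' cis/trans category therefore fixes the expectations of the A = log2(Ad/Dd)
#' and B = log2(At/Dt) statistics that the classifier estimates.
#'
#' @param n_pairs Number of homoeolog pairs.
#' @param n_tissues Number of tissues (<= 9, taken from [tissue_levels()]).
#' @param n_reps Replicates per (genotype, tissue).
#' @param dispersion Negative-binomial dispersion shared across genes
#'   (`0` means Poisson noise).
#' @param lib_size_mean Library size per sample.
#' @param category_mix Named proportions over the seven cis/trans categories
#'   (`conserved`, `cis_only`, `trans_only`, `cis_plus_trans`,
#'   `cis_times_trans`, `compensatory`, `ambiguous`). Must sum to 1.
#' @param effect_size Planted effect magnitude in log2 units.
#' @param heb_trajectory_mix Optional named proportions over the four bias
#'   trajectories (`parental_legacy`, `convergence`, `divergence`,
#'   `reversion`). When given, it overrides `category_mix` and plants the
#'   (parental ratio, allotetraploid ratio) pattern of each trajectory.
#' @param heb_effect Bias magnitude (log2) used for planted trajectories.
#' @param de_fraction Fraction of genes per subgenome with planted
#'   differential expression (allotetraploid context vs its parent).
#' @param de_log2fc Planted differential-expression effect (log2).
#' @param n_modules Number of planted co-expression modules (0 disables
#'   module structure).
#' @param module_cohesion Weight in [0, 1] of the shared module factor in
#'   each node's tissue profile (1 = identical profiles within a module).
#' @param module_amplitude Standard deviation (log2 units) of the tissue
#'   profile component.
#' @param rewiring_mix Named proportions over the five quadruplet rewiring
#'   classes (`conserved_same`, `conserved_different`, `convergence`,
#'   `divergence`, `other`); used only when `n_modules >= 2`.
#' @param p_silent Probability that a pair is silent (zero counts
#'   everywhere).
#' @param base_log2_mean,base_log2_sd Location/scale of the expressed mass of
#'   the bimodal baseline log2-expression distribution.
#' @param tissue_sd Standard deviation of the pair-shared tissue effect used
#'   when no module structure is planted.
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration including the seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pairs = 1000,
                         n_tissues = 9,
                         n_reps = 3,
                         dispersion = 0.05,
                         lib_size_mean = 2e7,
                         category_mix = c(conserved = 0.40, cis_only = 0.30,
                                          trans_only = 0.10,
                                          cis_plus_trans = 0.05,
                                          cis_times_trans = 0.01,
                                          compensatory = 0.06,
                                          ambiguous = 0.08),
                         effect_size = 1.5,
                         heb_trajectory_mix = NULL,
                         heb_effect = 2,
                         de_fraction = 0,
                         de_log2fc = 2,
                         n_modules = 0,
                         module_cohesion = 0.8,
                         module_amplitude = 2,
                         rewiring_mix = c(conserved_same = 0.55,
                                          conserved_different = 0.19,
                                          convergence = 0.15,
                                          divergence = 0.09,
                                          other = 0.02),
                         p_silent = 0.1,
                         base_log2_mean = 5,
                         base_log2_sd = 1.5,
                         tissue_sd = 1,
                         seed = 1L) {
  if (n_reps <= 0) abort("n_reps must be positive")
  if (n_pairs <= 0) abort("n_pairs must be positive")
  if (n_tissues < 1 || n_tissues > length(tissue_levels())) {
    abort("n_tissues must be between 1 and 9")
  }
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (module_cohesion < 0 || module_cohesion > 1) {
    abort("module_cohesion must be in [0, 1]")
  }
  check_mix <- function(mix, levels, what) {
    if (!all(names(mix) %in% levels) || abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
      abort(paste0(what, " must be non-negative proportions over {",
                   paste(levels, collapse = ", "), "} summing to 1"))
    }
    full <- setNames(numeric(length(levels)), levels)
    full[names(mix)] <- mix
    full
  }
  category_mix <- check_mix(category_mix, hse_categories(), "category_mix")
  if (!is.null(heb_trajectory_mix)) {
    heb_trajectory_mix <- check_mix(heb_trajectory_mix, heb_groups(),
                                    "heb_trajectory_mix")
  }
  rewiring_mix <- check_mix(rewiring_mix, rewiring_classes(), "rewiring_mix")
  structure(list(
    n_pairs = as.integer(n_pairs), n_tissues = as.integer(n_tissues),
    n_reps = as.integer(n_reps), dispersion = dispersion,
    lib_size_mean = lib_size_mean, category_mix = category_mix,
    effect_size = effect_size, heb_trajectory_mix = heb_trajectory_mix,
    heb_effect = heb_effect, de_fraction = de_fraction,
    de_log2fc = de_log2fc, n_modules = as.integer(n_modules),
    module_cohesion = module_cohesion, module_amplitude = module_amplitude,
    rewiring_mix = rewiring_mix, p_silent = p_silent,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    tissue_sd = tissue_sd, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Category and class vocabularies
#' @return Character vector of level names.
#' @export
hse_categories <- function() {
  c("conserved", "cis_only", "trans_only", "cis_plus_trans",
    "cis_times_trans", "compensatory", "ambiguous")
}

#' @rdname hse_categories
#' @export
heb_groups <- function() {
  c("parental_legacy", "convergence", "divergence", "reversion")
}

#' @rdname hse_categories
#' @export
rewiring_classes <- function() {
  c("conserved_same", "conserved_different", "convergence", "divergence",
    "other")
}

# deterministic allocation of n items to named proportions (largest remainder)
allocate_mix <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

#' Planted module structure for the quadruplet network
#'
#' Assigns each node context (Ad, Dd, At, Dt) of each pair to a planted
#' co-expression module under a planted-partition model: nodes in a module
#' share a latent tissue-profile factor with weight `module_cohesion`. The
#' five quadruplet rewiring classes are planted by giving node contexts the
#' same or different factors: e.g. a planted "convergence" quadruplet has Ad
#' and Dd in different modules but At and Dt in the same module.
#'
#' @param config A [synth_config()] with `n_modules >= 2`.
#' @return A list with `assignment` (tibble: pair_id, module per context,
#'   rewiring_class) and `factors` (n_modules x n_tissues matrix of latent
#'   tissue profiles).
#' @export
simulate_module_structure <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_modules < 2) abort("n_modules must be >= 2")
  n <- config$n_pairs
  k <- config$n_modules
  classes <- sample(allocate_mix(config$rewiring_mix, n))
  pick2 <- function() sample.int(k, 2)  # two distinct modules
  m <- matrix(NA_integer_, nrow = n, ncol = 4,
              dimnames = list(NULL, c("Ad", "Dd", "At", "Dt")))
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "conserved_same") {
      m[i, ] <- sample.int(k, 1)
    } else if (cl == "conserved_different") {
      mm <- pick2()
      m[i, ] <- c(mm[1], mm[2], mm[1], mm[2])
    } else if (cl == "convergence") {
      mm <- pick2()
      m[i, ] <- c(mm[1], mm[2], mm[1], mm[1])
    } else if (cl == "divergence") {
      mm <- pick2()
      shared <- sample.int(k, 1)
      m[i, ] <- c(shared, shared, mm[1], mm[2])
    } else {
      mm <- pick2()  # crossed pattern matches none of the four rules
      m[i, ] <- c(mm[1], mm[2], mm[2], mm[1])
    }
  }
  if (k > config$n_tissues) {
    abort("n_modules must not exceed n_tissues (factors are orthogonalized)")
  }
  # mutually uncorrelated tissue profiles: orthogonalize centered draws so
  # that module identities stay distinguishable at any cohesion
  raw <- matrix(rnorm(config$n_tissues * k), ncol = k)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(raw))
  factors <- t(apply(q, 2, function(col) col / sd(col)))
  list(
    assignment = tibble(
      pair_id = sprintf("p%05d", seq_len(n)),
      module_Ad = m[, 1], module_Dd = m[, 2],
      module_At = m[, 3], module_Dt = m[, 4],
      rewiring_class = classes
    ),
    factors = factors
  )
}

# expected (parental, allotetraploid) log-ratios for one planted label
plant_effects <- function(label, e, mode = c("hse", "heb")) {
  mode <- match.arg(mode)
  s <- sample(c(-1, 1), 1)
  if (mode == "hse") {
    ct <- switch(label,
      conserved = c(0, 0),
      cis_only = c(s * e, 0),
      trans_only = c(0, s * e),
      cis_plus_trans = c(s * e, s * e),
      cis_times_trans = c(s * e, -2 * s * e),
      compensatory = c(s * e, -s * e),
      ambiguous = runif(2, -0.2, 0.2)
    )
    c(d_mix = ct[1] + ct[2], d_at2 = ct[1], c = ct[1], t = ct[2])
  } else {
    d <- switch(label,
      parental_legacy = c(s * e, s * e),
      convergence = c(s * e, 0),
      divergence = c(0, s * e),
      reversion = c(s * e, -s * e)
    )
    c(d_mix = d[1], d_at2 = d[2], c = d[2], t = d[1] - d[2])
  }
}

derive_heb_trajectory <- function(d_mix, d_at2, tol = 1e-9) {
  bm <- abs(d_mix) > tol
  ba <- abs(d_at2) > tol
  dplyr::case_when(
    bm & ba & sign(d_mix) == sign(d_at2) ~ "parental_legacy",
    !bm & !ba ~ "parental_legacy",
    bm & !ba ~ "convergence",
    !bm & ba ~ "divergence",
    TRUE ~ "reversion"
  )
}

#' Simulate quadruplet count data with ground truth
#'
#' Generates per-genotype count matrices (AA and DD parents carry only their
#' own subgenome's genes; AT2 carries both), a sample sheet, gene lengths,
#' the homoeolog pair table, and a ground-truth tibble recording the planted
#' cis/trans effects, bias trajectory, differential expression and module
#' membership of every pair. Convenience long tables of quadruplet counts
#' and TPM (Ad/Dd taken from the in-silico parental mix, At/Dt from AT2) are
#' included so downstream statistics can be computed directly.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_data` with elements `counts` (named list
#'   of [count_matrix()] for AA, DD, AT2), `sample_sheet`, `pairs`, `truth`,
#'   `quad_counts`, `quad_tpm`, `mix` (the derived MIX count matrix and
#'   sheet) and `config`.
#' @export
simulate_quadruplets <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  nt <- config$n_tissues
  nr <- config$n_reps
  tissues <- tissue_levels()[seq_len(nt)]
  pair_id <- sprintf("p%05d", seq_len(n))
  gene_A <- sprintf("gA%05d", seq_len(n))
  gene_D <- sprintf("gD%05d", seq_len(n))

  # planted effects ----------------------------------------------------------
  heb_mode <- !is.null(config$heb_trajectory_mix)
  labels <- if (heb_mode) {
    sample(allocate_mix(config$heb_trajectory_mix, n))
  } else {
    sample(allocate_mix(config$category_mix, n))
  }
  eff <- t(vapply(labels, plant_effects,
                  e = if (heb_mode) config$heb_effect else config$effect_size,
                  mode = if (heb_mode) "heb" else "hse",
                  FUN.VALUE = numeric(4)))
  d_mix <- eff[, "d_mix"]; d_at2 <- eff[, "d_at2"]
  cis <- eff[, "c"]; trans <- eff[, "t"]
  hse_category <- if (heb_mode) {
    derive_hse_category(cis, trans)
  } else labels
  heb_trajectory <- derive_heb_trajectory(d_mix, d_at2)

  silent <- runif(n) < config$p_silent
  mu <- rnorm(n, config$base_log2_mean, config$base_log2_sd)

  # planted DE (allotetraploid context vs its parent), constant across tissues
  de_status_A <- de_status_D <- rep("none", n)
  if (config$de_fraction > 0) {
    pick <- function() {
      idx <- sample.int(n, max(1, round(config$de_fraction * n)))
      dir <- sample(c("up", "down"), length(idx), replace = TRUE)
      out <- rep("none", n); out[idx] <- dir; out
    }
    de_status_A <- pick(); de_status_D <- pick()
  }
  de_shift <- function(status) {
    ifelse(status == "up", config$de_log2fc,
           ifelse(status == "down", -config$de_log2fc, 0))
  }

  # tissue structure ----------------------------------------------------------
  contexts <- c("Ad", "Dd", "At", "Dt")
  if (config$n_modules >= 2) {
    ms <- simulate_module_structure(config)
    modules <- ms$assignment
    w <- sqrt(config$module_cohesion)
    profile_of <- function(ctx) {
      mods <- modules[[paste0("module_", ctx)]]
      base <- ms$factors[mods, , drop = FALSE]
      noise <- matrix(rnorm(n * nt), nrow = n)
      config$module_amplitude * (w * base + sqrt(1 - w^2) * noise)
    }
    tissue_eff <- lapply(setNames(contexts, contexts), profile_of)
  } else {
    modules <- tibble(pair_id = pair_id,
                      module_Ad = 0L, module_Dd = 0L,
                      module_At = 0L, module_Dt = 0L,
                      rewiring_class = NA_character_)
    shared <- matrix(rnorm(n * nt, sd = config$tissue_sd), nrow = n)
    tissue_eff <- lapply(setNames(contexts, contexts), function(ctx) shared)
  }

  # expected log2 expression per context x tissue -----------------------------
  log2_expr <- function(ctx) {
    shift <- switch(ctx,
      Ad = d_mix / 2, Dd = -d_mix / 2,
      At = d_at2 / 2 + de_shift(de_status_A),
      Dt = -d_at2 / 2 + de_shift(de_status_D))
    mu + shift + tissue_eff[[ctx]]  # n x nt matrix
  }
  expr <- lapply(setNames(contexts, contexts), log2_expr)
  for (ctx in contexts) expr[[ctx]][silent, ] <- -Inf

  gene_lengths <- tibble(
    gene_id = c(gene_A, gene_D),
    length = as.integer(sample(seq(600, 3000, by = 3), 2 * n, replace = TRUE))
  )
  len_A <- gene_lengths$length[seq_len(n)]
  len_D <- gene_lengths$length[n + seq_len(n)]

  draw_counts <- function(rate) {
    # rate: expected relative transcript mass per gene (length-weighted)
    tot <- sum(rate)
    if (tot == 0) return(integer(length(rate)))
    mu_counts <- rate / tot * config$lib_size_mean
    if (config$dispersion <= 0) {
      rpois(length(rate), mu_counts)
    } else {
      rnbinom(length(rate), mu = mu_counts, size = 1 / config$dispersion)
    }
  }

  make_samples <- function(genotype, gene_ids, ctxs, lens) {
    cols <- list()
    ids <- character(0)
    for (s in seq_len(nt)) {
      for (r in seq_len(nr)) {
        x <- unlist(lapply(ctxs, function(ctx) 2^expr[[ctx]][, s]))
        rate <- x * rep(lens, length.out = length(x)) / 1000
        sid <- sprintf("%s_%s_r%d", genotype, tissues[s], r)
        cols[[sid]] <- draw_counts(rate)
        ids <- c(ids, sid)
      }
    }
    counts <- as_tibble(c(list(gene_id = gene_ids), cols))
    sheet <- tibble(
      sample_id = ids, genotype = genotype,
      tissue = rep(tissues, each = nr), replicate = rep(seq_len(nr), nt)
    )
    list(counts = counts, sheet = sheet)
  }

  aa <- make_samples("AA", gene_A, "Ad", len_A)
  dd <- make_samples("DD", gene_D, "Dd", len_D)
  at2 <- make_samples("AT2", c(gene_A, gene_D), c("At", "Dt"),
                      c(len_A, len_D))

  counts <- list(
    AA = count_matrix(aa$counts, gene_lengths[seq_len(n), ]),
    DD = count_matrix(dd$counts, gene_lengths[n + seq_len(n), ]),
    AT2 = count_matrix(at2$counts, gene_lengths)
  )
  sheet <- sample_sheet(bind_rows(aa$sheet, dd$sheet, at2$sheet))

  pairs <- tibble(pair_id = pair_id, gene_A = gene_A, gene_D = gene_D,
                  length_A = len_A, length_D = len_D)

  truth <- tibble(
    pair_id = pair_id, gene_A = gene_A, gene_D = gene_D,
    silent = silent, mu = mu, c = cis, t = trans,
    d_mix = d_mix, d_at2 = d_at2,
    hse_category = hse_category, heb_trajectory = heb_trajectory,
    de_status_A = de_status_A, de_status_D = de_status_D
  ) %>% left_join(modules, by = "pair_id")

  mix <- build_mix(counts$AA, counts$DD,
                   dplyr::filter(sheet, .data$genotype %in% c("AA", "DD")))

  quad_counts <- quadruplet_table(counts, mix, pairs, sheet, what = "counts")
  quad_tpm <- quadruplet_table(counts, mix, pairs, sheet, what = "tpm")

  structure(list(counts = counts, sample_sheet = sheet, pairs = pairs,
                 truth = truth, mix = mix, quad_counts = quad_counts,
                 quad_tpm = quad_tpm, config = config),
            class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("<synth_data> %d pairs, %d tissues, %d reps (seed %d)\n",
              x$config$n_pairs, x$config$n_tissues, x$config$n_reps,
              x$config$seed))
  invisible(x)
}

# assemble the long quadruplet table from per-genotype matrices
quadruplet_table <- function(counts, mix, pairs, sheet, what = c("counts", "tpm")) {
  what <- match.arg(what)
  grab <- function(cm, genes) {
    tb <- if (what == "tpm") compute_tpm(cm) else cm$counts
    m <- as.matrix(tb[, -1, drop = FALSE])
    rownames(m) <- tb$gene_id
    m[genes, , drop = FALSE]
  }
  mix_sheet <- mix$sample_sheet
  at2_sheet <- dplyr::filter(sheet, .data$genotype == "AT2")
  m_mix_A <- grab(mix$counts, pairs$gene_A)
  m_mix_D <- grab(mix$counts, pairs$gene_D)
  m_at2_A <- grab(counts$AT2, pairs$gene_A)
  m_at2_D <- grab(counts$AT2, pairs$gene_D)
  out <- list()
  for (i in seq_len(nrow(mix_sheet))) {
    ti <- mix_sheet$tissue[i]; ri <- mix_sheet$replicate[i]
    sid_mix <- mix_sheet$sample_id[i]
    sid_at2 <- at2_sheet$sample_id[at2_sheet$tissue == ti &
                                     at2_sheet$replicate == ri]
    out[[i]] <- tibble(
      pair_id = pairs$pair_id, tissue = ti, replicate = ri,
      Ad = m_mix_A[, sid_mix], Dd = m_mix_D[, sid_mix],
      At = m_at2_A[, sid_at2], Dt = m_at2_D[, sid_at2]
    )
  }
  bind_rows(out)
}

#' Simulate diverged CDS and promoter pairs
#'
#' Builds toy in-frame CDS pairs whose synonymous and non-synonymous
#' substitution loads are controlled so that NG86 estimates recover the
#' targets, plus promoter pairs mutated at a fixed per-site rate. At most one
#' substitution is introduced per codon; the number of synonymous
#' (non-synonymous) substitutions is drawn binomially from the sequence's
#' NG86 synonymous (non-synonymous) site count at the Jukes-Cantor-inverted
#' target rate, so observed Ka/Ks scatter around the target with binomial
#' error.
#'
#' @param n_pairs Number of sequence pairs.
#' @param n_codons CDS length in codons.
#' @param ka_target,ks_target Target substitution rates (per-site, in
#'   [0, 0.5]; larger values approach saturation and are refused).
#' @param promoter_div Per-site promoter divergence rate in [0, 0.75].
#' @param promoter_len Promoter length (bp).
#' @param seed Integer seed.
#' @return List with named character vectors `cds_A`, `cds_D`, `prom_A`,
#'   `prom_D`, and a `truth` tibble with the planted substitution counts.
#' @export
simulate_sequence_pairs <- function(n_pairs = 50, n_codons = 200,
                                    ka_target = 0.05, ks_target = 0.2,
                                    promoter_div = 0.05, promoter_len = 500,
                                    seed = 1L) {
  if (ka_target < 0 || ka_target > 0.5 || ks_target < 0 || ks_target > 0.5) {
    abort("ka_target and ks_target must lie in [0, 0.5] (saturation guard)")
  }
  if (promoter_div < 0 || promoter_div > 0.75) {
    abort("promoter_div must lie in [0, 0.75]")
  }
  set.seed(seed)
  codons <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  bases <- c("A", "C", "G", "T")
  # inverse Jukes-Cantor: per-site difference probability hitting the target
  p_raw <- function(d) 3 / 4 * (1 - exp(-4 / 3 * d))

  cds_A <- cds_D <- prom_A <- prom_D <- character(n_pairs)
  n_syn <- n_nonsyn <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    seq_codons <- sample(codons, n_codons, replace = TRUE)
    # candidate single-nucleotide variants per codon, split by effect
    syn_var <- lapply(seq_codons, codon_variants, synonymous = TRUE)
    non_var <- lapply(seq_codons, codon_variants, synonymous = FALSE)
    sites <- ng86_sites(paste(seq_codons, collapse = ""))
    m_s <- rbinom(1, round(sites["S"]), p_raw(ks_target))
    m_a <- rbinom(1, round(sites["N"]), p_raw(ka_target))
    can_s <- which(lengths(syn_var) > 0)
    can_a <- which(lengths(non_var) > 0)
    m_s <- min(m_s, length(can_s))
    idx_s <- if (m_s > 0) sample(can_s, m_s) else integer(0)
    can_a <- setdiff(can_a, idx_s)  # one substitution per codon
    m_a <- min(m_a, length(can_a))
    idx_a <- if (m_a > 0) sample(can_a, m_a) else integer(0)
    mut <- seq_codons
    for (j in idx_s) mut[j] <- sample(syn_var[[j]], 1)
    for (j in idx_a) mut[j] <- sample(non_var[[j]], 1)
    cds_A[i] <- paste(seq_codons, collapse = "")
    cds_D[i] <- paste(mut, collapse = "")
    n_syn[i] <- m_s; n_nonsyn[i] <- m_a

    pa <- sample(bases, promoter_len, replace = TRUE)
    pd <- pa
    hit <- which(runif(promoter_len) < promoter_div)
    for (j in hit) pd[j] <- sample(setdiff(bases, pa[j]), 1)
    prom_A[i] <- paste(pa, collapse = "")
    prom_D[i] <- paste(pd, collapse = "")
  }
  ids <- sprintf("p%05d", seq_len(n_pairs))
  nm <- function(x, pre) setNames(x, paste0(pre, ids))
  list(
    cds_A = nm(cds_A, "gA"), cds_D = nm(cds_D, "gD"),
    prom_A = nm(prom_A, "gA"), prom_D = nm(prom_D, "gD"),
    truth = tibble(pair_id = ids, n_syn = n_syn, n_nonsyn = n_nonsyn,
                   ka_target = ka_target, ks_target = ks_target,
                   promoter_div = promoter_div)
  )
}

# single-nucleotide codon variants of the requested effect class
# (stop-producing changes are never offered)
codon_variants <- function(codon, synonymous) {
  aa <- GENETIC_CODE_TABLE[[codon]]
  out <- character(0)
  s <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), s[pos])) {
      alt <- s; alt[pos] <- b
      alt_codon <- paste(alt, collapse = "")
      alt_aa <- GENETIC_CODE_TABLE[[alt_codon]]
      if (alt_aa == "*") next
      if (synonymous == (alt_aa == aa)) out <- c(out, alt_codon)
    }
  }
  out
}
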