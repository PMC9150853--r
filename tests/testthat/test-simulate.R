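test_that("generation is a pure function of the configuration", {
  cfg <- synth_config(n_pairs = 40, n_tissues = 3, n_reps = 2, seed = 9,
                      de_fraction = 0.1, n_modules = 2)
  d1 <- simulate_quadruplets(cfg)
  d2 <- simulate_quadruplets(cfg)
  expect_identical(d1$counts$AT2$counts, d2$counts$AT2$counts)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$quad_tpm, d2$quad_tpm)
  d3 <- simulate_quadruplets(synth_config(n_pairs = 40, n_tissues = 3,
                                          n_reps = 2, seed = 10))
  expect_false(identical(d1$counts$AT2$counts, d3$counts$AT2$counts))
})

test_that("planted effects drive the expected ratio statistics", {
  # Note: parental-mix ratios carry a genome-composition offset
  # log2(sum rate_D / sum rate_A) because the two parents are normalized
  # separately before 1:1 mixing; it shrinks with the number of pairs, so
  # these null checks use a few hundred pairs.
  # all conserved, near-zero noise: both log-ratios vanish
  cfg0 <- synth_config(n_pairs = 400, n_tissues = 1, n_reps = 6,
                       dispersion = 1e-6, p_silent = 0, base_log2_sd = 1,
                       category_mix = c(conserved = 1), seed = 2)
  d0 <- simulate_quadruplets(cfg0)
  st0 <- hse_statistics(d0$quad_tpm)
  expect_lt(max(abs(st0$A)), 0.1)
  expect_lt(max(abs(st0$B)), 0.1)
  # all cis-only at effect 2: A and B land on +-2 together
  cfg1 <- synth_config(n_pairs = 400, n_tissues = 1, n_reps = 6,
                       dispersion = 1e-6, p_silent = 0, base_log2_sd = 1,
                       effect_size = 2, category_mix = c(cis_only = 1),
                       seed = 3)
  d1 <- simulate_quadruplets(cfg1)
  st1 <- hse_statistics(d1$quad_tpm)
  expect_lt(max(abs(abs(st1$A) - 2)), 0.15)
  expect_lt(max(abs(st1$A - st1$B)), 0.15)
})

test_that("A and B converge to c + t and c with many low-noise replicates", {
  cfg <- synth_config(n_pairs = 60, n_tissues = 1, n_reps = 50,
                      dispersion = 1e-4, p_silent = 0, seed = 4,
                      category_mix = setNames(rep(1 / 7, 7),
                                              hse_categories()))
  d <- simulate_quadruplets(cfg)
  st <- hse_statistics(d$quad_tpm)
  joined <- dplyr::inner_join(st, d$truth, by = "pair_id")
  expect_lt(max(abs(joined$A - (joined$c + joined$t))), 0.05)
  expect_lt(max(abs(joined$B - joined$c)), 0.05)
})

test_that("silent pairs yield all-zero counts and non-negative libraries", {
  cfg <- synth_config(n_pairs = 40, n_tissues = 2, n_reps = 2,
                      p_silent = 0.5, seed = 5)
  d <- simulate_quadruplets(cfg)
  silent_genes <- d$truth$gene_A[d$truth$silent]
  m <- as.matrix(d$counts$AT2$counts[, -1])
  rownames(m) <- d$counts$AT2$counts$gene_id
  expect_true(all(m[silent_genes, ] == 0))
  expect_true(all(m >= 0))
})

test_that("module cohesion controls within-module correlation", {
  base <- function(coh, seed) {
    synth_config(n_pairs = 60, n_tissues = 9, n_reps = 2, n_modules = 3,
                 module_cohesion = coh, dispersion = 1e-6, p_silent = 0,
                 rewiring_mix = c(conserved_same = 1), seed = seed)
  }
  prof_cor <- function(cfg) {
    d <- simulate_quadruplets(cfg)
    tpm <- compute_tpm(d$counts$AT2)
    sheet <- dplyr::filter(d$sample_sheet, genotype == "AT2")
    prof <- node_profiles(tpm, sheet)
    m <- as.matrix(prof[, -1])
    rownames(m) <- prof$node_id
    mods <- setNames(d$truth$module_At, d$truth$gene_A)
    within <- c()
    for (k in unique(mods)) {
      mm <- m[names(mods)[mods == k], ]
      cc <- cor(t(mm))
      within <- c(within, cc[upper.tri(cc)])
    }
    mean(within)
  }
  expect_gt(prof_cor(base(1, 6)), 0.95)
  expect_lt(abs(prof_cor(base(0, 7))), 0.2)
})

test_that("rewiring classes are planted as defined", {
  cfg <- synth_config(n_pairs = 200, n_modules = 3, seed = 8,
                      rewiring_mix = c(conserved_same = 0.2,
                                       conserved_different = 0.2,
                                       convergence = 0.2, divergence = 0.2,
                                       other = 0.2))
  ms <- simulate_module_structure(cfg)
  a <- ms$assignment
  expect_setequal(unique(a$rewiring_class), rewiring_classes())
  for (i in seq_len(nrow(a))) {
    expect_equal(
      oracle_rewiring(a$module_Ad[i], a$module_Dd[i],
                      a$module_At[i], a$module_Dt[i]),
      a$rewiring_class[i]
    )
  }
  conv <- a[a$rewiring_class == "convergence", ]
  expect_true(all(conv$module_Ad != conv$module_Dd))
  expect_true(all(conv$module_At == conv$module_Dt))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(synth_config(n_reps = 0), "n_reps")
  expect_error(synth_config(module_cohesion = 1.2), "cohesion")
  expect_error(synth_config(category_mix = c(conserved = 0.5)), "summing")
  expect_error(simulate_module_structure(synth_config(n_modules = 1)),
               "n_modules")
})

test_that("sequence pairs hit their divergence targets", {
  sp0 <- simulate_sequence_pairs(n_pairs = 5, n_codons = 50, ka_target = 0,
                                 ks_target = 0, promoter_div = 0, seed = 1)
  expect_identical(unname(sp0$cds_A), unname(sp0$cds_D))
  expect_identical(unname(sp0$prom_A), unname(sp0$prom_D))

  sp <- simulate_sequence_pairs(n_pairs = 20, n_codons = 200,
                                ka_target = 0, ks_target = 0,
                                promoter_div = 0.1, promoter_len = 1000,
                                seed = 2)
  pd <- mapply(promoter_pdistance, sp$prom_A, sp$prom_D)
  # binomial sd at p = 0.1, n = 1000 is ~0.0095; allow 4 sd per pair
  expect_true(all(abs(pd - 0.1) < 4 * sqrt(0.1 * 0.9 / 1000)))

  sp1 <- simulate_sequence_pairs(n_pairs = 3, seed = 3)
  sp2 <- simulate_sequence_pairs(n_pairs = 3, seed = 3)
  expect_identical(sp1$cds_D, sp2$cds_D)
  expect_error(simulate_sequence_pairs(ks_target = 0.6), "saturation")
})
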