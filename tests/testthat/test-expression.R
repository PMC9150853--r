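cm_of <- function(counts, lens) count_matrix(counts, lens)

test_that("TPM normalization is forced by its definition", {
  one <- cm_of(tibble::tibble(gene_id = "g1", s1 = 7L, s2 = 123L),
               tibble::tibble(gene_id = "g1", length = 500L))
  tpm1 <- compute_tpm(one)
  expect_equal(unlist(tpm1[1, -1], use.names = FALSE), c(1e6, 1e6))

  two <- cm_of(tibble::tibble(gene_id = c("g1", "g2"),
                              s1 = c(100L, 100L)),
               tibble::tibble(gene_id = c("g1", "g2"),
                              length = c(1000L, 2000L)))
  tpm2 <- compute_tpm(two)
  expect_equal(tpm2$s1[1] / tpm2$s1[2], 2)

  # 5 x 3 fixture against hand-computed normalization
  set.seed(3)
  counts <- tibble::tibble(gene_id = paste0("g", 1:5))
  for (s in paste0("s", 1:3)) counts[[s]] <- rpois(5, 50)
  lens <- tibble::tibble(gene_id = counts$gene_id,
                         length = c(500L, 1000L, 1500L, 800L, 2500L))
  got <- compute_tpm(cm_of(counts, lens))
  for (s in paste0("s", 1:3)) {
    rate <- counts[[s]] / lens$length
    expect_equal(got[[s]], rate / sum(rate) * 1e6, tolerance = 1e-9)
  }
  expect_warning(
    compute_tpm(cm_of(tibble::tibble(gene_id = "g1", s1 = 0L),
                      tibble::tibble(gene_id = "g1", length = 100L))),
    "all-zero"
  )
})

test_that("TPM columns sum to one million, mix included", {
  d <- simulate_quadruplets(synth_config(n_pairs = 60, n_tissues = 2,
                                         n_reps = 2, seed = 14))
  for (tb in list(compute_tpm(d$counts$AA), compute_tpm(d$counts$AT2),
                  compute_tpm(d$mix$counts))) {
    sums <- colSums(as.matrix(tb[, -1]))
    expect_true(all(abs(sums - 1e6) < 1e6 * 1e-6))
  }
})

test_that("the in-silico mix stacks parents and doubles the denominator", {
  sheet <- sample_sheet(tibble::tibble(
    sample_id = c("AA_leaf_r1", "DD_leaf_r1"),
    genotype = c("AA", "DD"), tissue = "leaf", replicate = 1L
  ))
  # one A gene carrying 50% of the AA library; equal DD library size
  aa <- cm_of(tibble::tibble(gene_id = c("a1", "a2"),
                             AA_leaf_r1 = c(500L, 500L)),
              tibble::tibble(gene_id = c("a1", "a2"), length = 1000L))
  dd <- cm_of(tibble::tibble(gene_id = c("d1", "d2"),
                             DD_leaf_r1 = c(500L, 500L)),
              tibble::tibble(gene_id = c("d1", "d2"), length = 1000L))
  mix <- build_mix(aa, dd, sheet)
  tpm_aa <- compute_tpm(aa)
  tpm_mix <- compute_tpm(mix$counts)
  expect_equal(tpm_mix$MIX_leaf_r1[tpm_mix$gene_id == "a1"],
               tpm_aa$AA_leaf_r1[tpm_aa$gene_id == "a1"] / 2)

  shared <- cm_of(tibble::tibble(gene_id = c("a1", "x"),
                                 DD_leaf_r1 = c(1L, 1L)),
                  tibble::tibble(gene_id = c("a1", "x"), length = 100L))
  expect_error(build_mix(aa, shared, sheet), "disjoint")

  sheet_bad <- sample_sheet(tibble::tibble(
    sample_id = c("AA_leaf_r1", "DD_root_r1"),
    genotype = c("AA", "DD"), tissue = c("leaf", "root"), replicate = 1L
  ))
  expect_error(build_mix(aa, dd, sheet_bad), "same")
})

test_that("mix-then-TPM equals TPM on the concatenated matrix", {
  d <- simulate_quadruplets(synth_config(n_pairs = 50, n_tissues = 2,
                                         n_reps = 2, seed = 15))
  tpm_mix <- compute_tpm(d$mix$counts)
  # concatenate the parents by hand, matching sample pairing
  concat <- d$mix$counts$counts
  lens <- d$mix$counts$gene_lengths
  by_hand <- compute_tpm(concat, lens)
  expect_equal(tpm_mix, by_hand, tolerance = 1e-12)
})

test_that("ubiquity categories follow the tissue-count boundaries", {
  tissues <- tissue_levels()
  sheet <- sample_sheet(tibble::tibble(
    sample_id = paste0("AT2_", rep(tissues, each = 2), "_r", rep(1:2, 9)),
    genotype = "AT2", tissue = rep(tissues, each = 2),
    replicate = rep(1:2, 9)
  ))
  tpm <- tibble::tibble(gene_id = c("silent", "one", "eight", "mid"))
  for (i in seq_len(nrow(sheet))) {
    ti <- sheet$tissue[i]
    tpm[[sheet$sample_id[i]]] <- c(
      0,
      ifelse(ti == "leaf", 5, 0),
      ifelse(ti == "shoot", 0, 5),
      ifelse(ti %in% tissues[1:3], 5, 0)
    )
  }
  cats <- categorize_ubiquity(tpm, sheet)
  expect_equal(cats$category,
               c("silent", "specific", "conserved", "intermediate"))
  expect_equal(cats$n_tissues_expressed, c(0L, 1L, 8L, 3L))
  # invariant to replicate order
  perm <- c(1, rbind(seq(3, 19, 2), seq(2, 18, 2)))
  cats2 <- categorize_ubiquity(tpm[, c(1, sample(2:19))], sheet)
  expect_equal(cats2$category, cats$category)
  short_sheet <- sheet[sheet$tissue %in% tissues[1:3], ]
  expect_error(
    categorize_ubiquity(tpm[, c("gene_id", short_sheet$sample_id)],
                        short_sheet),
    "nine"
  )
})

test_that("sample PCA separates planted groups and orders variance", {
  set.seed(16)
  base_a <- rpois(200, 60)
  base_b <- rpois(200, 60)
  tpm <- tibble::tibble(gene_id = paste0("g", 1:200))
  for (s in 1:3) tpm[[paste0("a", s)]] <- base_a + rpois(200, 3)
  for (s in 1:3) tpm[[paste0("b", s)]] <- base_b + rpois(200, 3)
  pca <- sample_pca(tpm)
  sc <- tidy(pca)
  expect_true(all(sc$PC1[1:3] * sc$PC1[4:6][1] > 0) ||
                all(sc$PC1[1:3] * sc$PC1[4] < 0))
  expect_gt(min(abs(sc$PC1[1:3] - mean(sc$PC1[4:6]))), 0)
  grp_gap <- abs(mean(sc$PC1[1:3]) - mean(sc$PC1[4:6]))
  within <- max(sd(sc$PC1[1:3]), sd(sc$PC1[4:6]))
  expect_gt(grp_gap, 3 * within)
  ve <- glance(pca)$variance_explained
  expect_true(all(ve >= 0))
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-8)

  # two identical samples: no variance anywhere
  flat <- tibble::tibble(gene_id = paste0("g", 1:10),
                         s1 = c(1:10) * 1.0, s2 = c(1:10) * 1.0)
  pf <- sample_pca(flat)
  expect_lt(max(glance(pf)$variance_explained[-1], 0), 1e-12)
  const <- tibble::tibble(gene_id = "g1", s1 = 1, s2 = 1)
  expect_error(sample_pca(const), "constant")
})
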