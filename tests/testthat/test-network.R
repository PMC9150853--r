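fake_network <- function(tom, node_ids = NULL) {
  if (is.null(node_ids)) node_ids <- paste0("n", seq_len(nrow(tom)))
  dimnames(tom) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, tom = tom, beta = 1,
                 modules = setNames(rep(1L, length(node_ids)), node_ids)),
            class = "coexpression_network")
}

test_that("topological overlap matches hand and brute-force computation", {
  a3 <- matrix(c(0, 0.5, 0.2,
                 0.5, 0, 0.8,
                 0.2, 0.8, 0), 3, 3)
  tom <- tom_similarity(a3)
  k <- rowSums(a3)
  hand12 <- (a3[1, 3] * a3[3, 2] + a3[1, 2]) / (min(k[1], k[2]) + 1 - a3[1, 2])
  expect_equal(tom[1, 2], hand12, tolerance = 1e-12)
  expect_equal(tom, oracle_tom(a3), tolerance = 1e-12)

  set.seed(61)
  r <- matrix(runif(100), 10, 10)
  a10 <- (r + t(r)) / 2
  diag(a10) <- 0
  tom10 <- tom_similarity(a10)
  expect_equal(tom10, oracle_tom(a10), tolerance = 1e-12)
  expect_equal(tom10, t(tom10))
  expect_true(all(tom10 >= 0 & tom10 <= 1))
  expect_equal(unname(diag(tom10)), rep(1, 10))
})

test_that("planted blocks are recovered as modules", {
  set.seed(62)
  ns <- 9
  f1 <- rnorm(ns)
  f2 <- rnorm(ns)
  f2 <- f2 - f1 * sum(f1 * f2) / sum(f1^2)  # decorrelate the planted blocks
  prof <- rbind(
    t(replicate(40, f1 + rnorm(ns, sd = 1e-3))),
    t(replicate(40, f2 + rnorm(ns, sd = 1e-3)))
  )
  rownames(prof) <- paste0("n", 1:80)
  net <- build_network(prof, beta = 6, min_module_size = 20)
  td <- tidy(net)
  expect_equal(glance(net)$n_modules, 2)
  truth <- rep(1:2, each = 40)
  expect_equal(mclust::adjustedRandIndex(td$module, truth), 1)
  # a module of identical profiles has an eigengene matching each member
  prof_same <- t(replicate(35, f1)) + rnorm(35 * ns, sd = 1e-9)
  rownames(prof_same) <- paste0("m", 1:35)
  net2 <- build_network(prof_same, beta = 2, min_module_size = 10)
  eig <- net2$eigengenes[, 1]
  cors <- apply(prof_same, 1, function(x) cor(eig, x))
  expect_true(all(abs(cors) > 0.999))
  expect_gt(mean(cors), 0)  # sign-oriented toward members
})

test_that("module recovery on generator data reaches high agreement", {
  cfg <- synth_config(n_pairs = 150, n_tissues = 9, n_reps = 3, seed = 63,
                      n_modules = 3, module_cohesion = 0.9, p_silent = 0,
                      rewiring_mix = c(conserved_same = 1))
  d <- simulate_quadruplets(cfg)
  prof <- node_profiles(compute_tpm(d$mix$counts), d$mix$sample_sheet, "d")
  net <- build_network(prof, beta = 6, min_module_size = 30)
  td <- tidy(net)
  truth <- c(setNames(d$truth$module_Ad, paste0(d$truth$gene_A, "_d")),
             setNames(d$truth$module_Dd, paste0(d$truth$gene_D, "_d")))
  ari <- mclust::adjustedRandIndex(td$module, truth[td$node_id])
  expect_gte(ari, 0.8)
})

test_that("soft-threshold diagnostics behave as expected", {
  set.seed(64)
  ns <- 12; n <- 400
  hub <- rnorm(ns)
  load <- runif(n)^3
  prof <- t(sapply(seq_len(n), function(i) {
    load[i] * hub + sqrt(1 - load[i]^2) * rnorm(ns)
  }))
  rownames(prof) <- paste0("n", 1:n)
  res <- pick_soft_threshold(prof, c(2, 4, 6, 9, 12))
  expect_true(all(diff(res$mean_k) < 0))
  expect_gt(max(res$r_squared, na.rm = TRUE), 0.8)
  # identical profiles: all correlations 1, connectivity n - 1 at any power
  same <- matrix(rep(rnorm(ns), each = 20), nrow = 20)
  rownames(same) <- paste0("s", 1:20)
  res_same <- pick_soft_threshold(same, c(2, 6))
  expect_equal(res_same$mean_k, c(19, 19))
  expect_error(pick_soft_threshold(prof, 6), "two candidate")
})

test_that("HEC scores agree with combinatorial enumeration", {
  set.seed(65)
  # engineered TOM: nodes n1, n2 share all top neighbors
  n <- 20
  tom <- matrix(runif(n * n, 0, 0.3), n, n)
  tom <- (tom + t(tom)) / 2
  hubs <- 3:6
  tom[1, hubs] <- tom[hubs, 1] <- 0.9
  tom[2, hubs] <- tom[hubs, 2] <- 0.9
  diag(tom) <- 1
  net <- fake_network(tom)
  res <- hec_score(net, tibble::tibble(pair_id = "p1", node_a = "n1",
                                       node_b = "n2"),
                   neighbor_quantile = 0.8)
  expect_equal(res$connectivity, 1)
  expect_lt(res$p_hyper, 0.01)
  expect_equal(res$group, "A")
  # p-value equals brute-force hypergeometric tail on small networks
  for (rep in 1:10) {
    m <- 12
    tm <- matrix(runif(m * m), m, m); tm <- (tm + t(tm)) / 2; diag(tm) <- 1
    netm <- fake_network(tm)
    got <- hec_score(netm, tibble::tibble(pair_id = "p", node_a = "n1",
                                          node_b = "n2"),
                     neighbor_quantile = 0.7)
    # reconstruct neighbor sets independently
    nb <- function(i) {
      row <- tm[i, -i]
      names(row) <- paste0("n", seq_len(m))[-i]
      hits <- names(row)[row >= quantile(row, 0.7)]
      setdiff(hits, c("n1", "n2"))
    }
    na_set <- nb(1); nb_set <- nb(2)
    k <- length(intersect(na_set, nb_set))
    want_p <- oracle_hyper_upper(k, length(na_set), length(nb_set), m - 2)
    expect_equal(got$p_hyper, want_p, tolerance = 1e-12)
  }
  # disjoint neighborhoods
  tom0 <- matrix(0.01, 10, 10)
  tom0[1, 3] <- tom0[3, 1] <- 0.9
  tom0[2, 4] <- tom0[4, 2] <- 0.9
  diag(tom0) <- 1
  res0 <- hec_score(fake_network(tom0),
                    tibble::tibble(pair_id = "p", node_a = "n1",
                                   node_b = "n2"),
                    neighbor_quantile = 0.95)
  expect_equal(res0$connectivity, 0)
})

test_that("HEC group thresholds are applied exactly", {
  got <- hec_group(
    connectivity = c(0.51, 0.5, 0.35, 0.29, 0.29, 0.51),
    p_hyper = c(0.005, 0.005, 0.005, 0.995, 0.5, 0.5)
  )
  expect_equal(got, c("A", "B", "B", "C", "unclassified", "unclassified"))
})

test_that("rewiring classes match a brute-force evaluator on all 81 tuples", {
  grid <- expand.grid(ad = 1:3, dd = 1:3, at = 1:3, dt = 1:3)
  got <- classify_rewiring(grid$ad, grid$dd, grid$at, grid$dt)
  want <- mapply(oracle_rewiring, grid$ad, grid$dd, grid$at, grid$dt)
  expect_equal(got, unname(want))
  expect_equal(classify_rewiring(3, 3, 3, 3), "conserved_same")
  expect_equal(classify_rewiring(1, 2, 1, 1), "convergence")
  expect_equal(classify_rewiring(0, 1, 1, 1), "other")
})

test_that("module subgenome composition uses the exact binomial test", {
  mem <- tibble::tibble(
    module = rep(c(1L, 2L, 3L), c(20, 5, 359)),
    subgenome = c(rep(c("A", "D"), 10), rep("D", 5),
                  rep(c("A", "D"), c(259, 100)))
  )
  res <- module_subgenome_test(mem)
  expect_equal(res$p[res$module == 1], 1, tolerance = 1e-9)
  expect_equal(res$p[res$module == 2], 2 * 0.5^5)
  expect_lt(res$p[res$module == 3], 1e-15)
  expect_equal(res$p[res$module == 3],
               binom.test(259, 359, 0.5)$p.value)
})
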