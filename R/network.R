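#' Topological overlap from an adjacency matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' diagonal of the adjacency treated as zero for connectivity
#' (`k_i = sum_u a_iu`) and the TOM diagonal set to 1 by convention.
#'
#' @param adjacency Symmetric matrix with entries in [0, 1].
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Build a weighted co-expression network
#'
#' Unsigned WGCNA-style pipeline: adjacency `|cor|^beta` over node profiles,
#' topological overlap, average-linkage clustering of `1 - TOM`, module
#' detection by a height sweep (the cut maximising the number of clusters of
#' size >= `min_module_size` is kept, ties resolved toward the cut covering
#' the most nodes, then toward the finest cut; nodes in undersized clusters
#' go to module 0), and iterative merging of
#' modules whose eigengenes correlate above `1 - merge_cut`. The module
#' eigengene is the sign-oriented first principal component of the
#' standardized member profiles.
#'
#' @param profiles Tibble (first column `node_id`, one column per sample)
#'   or matrix (nodes x samples) of expression profiles.
#' @param beta Soft-thresholding power.
#' @param min_module_size Minimum module size.
#' @param merge_cut Eigengene dissimilarity below which modules merge.
#' @return Object of class `coexpression_network` with the adjacency, TOM,
#'   module labels (0 = unassigned) and eigengenes. Zero-variance nodes are
#'   dropped with a warning.
#' @export
build_network <- function(profiles, beta, min_module_size = 30,
                         merge_cut = 0.25) {
  m <- profiles_matrix(profiles)
  if (ncol(m) < 4) abort("need at least four samples per profile")
  keep <- apply(m, 1, sd) > 0
  if (!all(keep)) {
    warn(sprintf("dropping %d constant profile(s)", sum(!keep)))
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < min_module_size) {
    abort("fewer nodes than min_module_size")
  }
  adj <- abs(cor(t(m)))^beta
  diag(adj) <- 0
  tom <- tom_similarity(adj)
  tree <- hclust(as.dist(1 - tom), method = "average")

  heights <- sort(unique(tree$height))
  best <- NULL
  for (ht in heights) {
    labels <- cutree(tree, h = ht)
    sizes <- table(labels)
    valid_sizes <- sizes[sizes >= min_module_size]
    n_valid <- length(valid_sizes)
    covered <- sum(valid_sizes)
    better <- is.null(best) || n_valid > best$n_valid ||
      (n_valid == best$n_valid && covered > best$covered)
    if (better) {
      best <- list(n_valid = n_valid, covered = covered, labels = labels,
                   h = ht)
    }
  }
  labels <- best$labels
  sizes <- table(labels)
  valid <- as.integer(names(sizes)[sizes >= min_module_size])
  modules <- integer(length(labels))
  if (length(valid)) {
    ord <- valid[order(-sizes[as.character(valid)], valid)]
    for (i in seq_along(ord)) modules[labels == ord[i]] <- i
  }
  names(modules) <- rownames(m)

  eig <- module_eigengenes(m, modules)
  # merge close modules
  while (ncol(eig) >= 2) {
    cc <- cor(eig)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - merge_cut) break
    keep_id <- as.integer(colnames(eig)[min(top)])
    drop_id <- as.integer(colnames(eig)[max(top)])
    modules[modules == drop_id] <- keep_id
    # compact labels
    ids <- sort(unique(modules[modules > 0]))
    modules <- ifelse(modules > 0, match(modules, ids), 0L)
    names(modules) <- rownames(m)
    eig <- module_eigengenes(m, modules)
  }
  ps_log("build_network", "%d nodes, %d modules (beta = %g)", nrow(m),
         ncol(eig), beta)
  structure(list(
    node_ids = rownames(m), beta = beta, adjacency = adj, tom = tom,
    modules = modules, eigengenes = eig, tree = tree,
    min_module_size = min_module_size, merge_cut = merge_cut
  ), class = "coexpression_network")
}

profiles_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    if (is.null(rownames(profiles))) {
      rownames(profiles) <- paste0("node", seq_len(nrow(profiles)))
    }
    return(profiles)
  }
  m <- as.matrix(profiles[, -1, drop = FALSE])
  rownames(m) <- profiles[[1]]
  m
}

module_eigengenes <- function(m, modules) {
  ids <- sort(unique(modules[modules > 0]))
  if (!length(ids)) {
    return(matrix(numeric(0), nrow = ncol(m), ncol = 0))
  }
  eig <- vapply(ids, function(id) {
    x <- t(m[modules == id, , drop = FALSE])  # samples x members
    x <- scale(x)
    pc <- prcomp(x, center = FALSE, scale. = FALSE)$x[, 1]
    if (mean(cor(pc, x)) < 0) pc <- -pc
    pc / sqrt(sum(pc^2))
  }, numeric(ncol(m)))
  colnames(eig) <- ids
  rownames(eig) <- colnames(m)
  eig
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "<coexpression_network> %d nodes, beta = %g, %d modules (%d unassigned)\n",
    length(x$node_ids), x$beta, length(unique(x$modules[x$modules > 0])),
    sum(x$modules == 0)))
  invisible(x)
}

#' @export
tidy.coexpression_network <- function(x, ...) {
  tibble(node_id = x$node_ids, module = unname(x$modules))
}

#' @export
glance.coexpression_network <- function(x, ...) {
  tibble(n_nodes = length(x$node_ids),
         n_modules = length(unique(x$modules[x$modules > 0])),
         n_unassigned = sum(x$modules == 0),
         beta = x$beta)
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each power, bins the connectivity distribution, fits
#' `log10 p(k) ~ log10 k` and reports the signed fit
#' (`-sign(slope) * R^2`) and the mean connectivity.
#'
#' @param profiles As in [build_network()].
#' @param candidate_betas Integer vector of powers (>= 2 values).
#' @param n_bins Number of connectivity bins.
#' @return Tibble `beta`, `r_squared`, `slope`, `mean_k`.
#' @export
pick_soft_threshold <- function(profiles,
                                candidate_betas = c(1:10, 12, 14, 16, 18, 20),
                                n_bins = 10) {
  if (length(candidate_betas) < 2) abort("need at least two candidate powers")
  m <- profiles_matrix(profiles)
  m <- m[apply(m, 1, sd) > 0, , drop = FALSE]
  r <- abs(cor(t(m)))
  diag(r) <- 0
  purrr::map_dfr(candidate_betas, function(b) {
    k <- rowSums(r^b)
    mean_k <- mean(k)
    k <- k[k > 0]
    if (length(unique(k)) < 3 || diff(range(k)) == 0) {
      return(tibble(beta = b, r_squared = NA_real_, slope = NA_real_,
                    mean_k = mean_k))
    }
    breaks <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    kmid <- tapply(k, bin, mean)
    ok <- !is.na(freq) & freq > 0 & kmid > 0
    if (sum(ok) < 3) {
      return(tibble(beta = b, r_squared = NA_real_, slope = NA_real_,
                    mean_k = mean_k))
    }
    fit <- lm(log10(freq[ok] / sum(freq[ok])) ~ log10(kmid[ok]))
    s <- coef(fit)[2]
    r2 <- summary(fit)$r.squared
    tibble(beta = b, r_squared = -sign(s) * r2, slope = unname(s),
           mean_k = mean_k)
  })
}

#' Homoeolog expression connectivity (HEC)
#'
#' The neighborhood of a node is the set of nodes whose topological overlap
#' with it reaches its own row's `neighbor_quantile` quantile (self and the
#' scored partner excluded). The connectivity score of a pair is the shared
#' fraction `|N(a) and N(b)| / min(|N(a)|, |N(b)|)`; the upper-tail
#' hypergeometric p-value asks whether the observed overlap is at least as
#' large as expected when drawing `|N(a)|` nodes from the `n - 2` other
#' nodes of which `|N(b)|` are successes. Groups: A (connectivity > 0.5 and
#' p < 0.01), B (0.3 < connectivity <= 0.5 and p < 0.01), C (connectivity
#' < 0.3 and p > 0.99), otherwise unclassified. Empty neighborhoods give
#' connectivity 0 and p = 1.
#'
#' @param network A `coexpression_network`.
#' @param pairs Tibble with `pair_id`, `node_a`, `node_b`.
#' @param neighbor_quantile Per-node TOM quantile defining neighborhoods.
#' @return Tibble `pair_id`, `connectivity`, `p_hyper`, `group`.
#' @export
hec_score <- function(network, pairs, neighbor_quantile = 0.95) {
  stopifnot(inherits(network, "coexpression_network"))
  tom <- network$tom
  nodes <- network$node_ids
  missing <- setdiff(c(pairs$node_a, pairs$node_b), nodes)
  if (length(missing)) {
    abort(paste0("node(s) not in network: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  n <- length(nodes)
  res <- purrr::map2(pairs$node_a, pairs$node_b, function(a, b) {
    ia <- match(a, nodes); ib <- match(b, nodes)
    nb_of <- function(i) {
      row <- tom[i, -i]
      thr <- quantile(row, neighbor_quantile, names = FALSE)
      hits <- names(row)[row >= thr]
      setdiff(hits, c(a, b))
    }
    na_set <- nb_of(ia); nb_set <- nb_of(ib)
    ka <- length(na_set); kb <- length(nb_set)
    inter <- length(intersect(na_set, nb_set))
    if (ka == 0 || kb == 0) {
      return(c(conn = 0, p = 1))
    }
    conn <- inter / min(ka, kb)
    p <- phyper(inter - 1, kb, (n - 2) - kb, ka, lower.tail = FALSE)
    c(conn = conn, p = p)
  })
  conn <- purrr::map_dbl(res, "conn")
  p <- purrr::map_dbl(res, "p")
  tibble(
    pair_id = pairs$pair_id, connectivity = conn, p_hyper = p,
    group = hec_group(conn, p)
  )
}

#' @rdname hec_score
#' @param connectivity,p_hyper Connectivity scores and hypergeometric
#'   p-values.
#' @export
hec_group <- function(connectivity, p_hyper) {
  dplyr::case_when(
    connectivity > 0.5 & p_hyper < 0.01 ~ "A",
    connectivity > 0.3 & connectivity <= 0.5 & p_hyper < 0.01 ~ "B",
    connectivity < 0.3 & p_hyper > 0.99 ~ "C",
    TRUE ~ "unclassified"
  )
}

#' Classify quadruplet rewiring from module labels
#'
#' Evaluates, in order: conserved_same (all four contexts in one module);
#' conserved_different (parents in different modules, each matching its
#' allotetraploid context); convergence (parents in different modules,
#' allotetraploid contexts together); divergence (parents together,
#' allotetraploid contexts apart); other. Any context in module 0
#' (unassigned) yields "other".
#'
#' @param module_Ad,module_Dd,module_At,module_Dt Integer module labels.
#' @return Character vector of rewiring classes.
#' @export
classify_rewiring <- function(module_Ad, module_Dd, module_At, module_Dt) {
  unassigned <- module_Ad == 0 | module_Dd == 0 | module_At == 0 |
    module_Dt == 0
  if (any(unassigned)) {
    ps_log("classify_rewiring", "%d quadruplet(s) with unassigned context",
           sum(unassigned))
  }
  dplyr::case_when(
    unassigned ~ "other",
    module_Ad == module_Dd & module_Dd == module_At &
      module_At == module_Dt ~ "conserved_same",
    module_Ad != module_Dd & module_Ad == module_At &
      module_Dd == module_Dt ~ "conserved_different",
    module_Ad != module_Dd & module_At == module_Dt ~ "convergence",
    module_Ad == module_Dd & module_At != module_Dt ~ "divergence",
    TRUE ~ "other"
  )
}

#' Subgenome composition test per module
#'
#' Two-sided exact binomial test of the A-subgenome member count against
#' p = 0.5 within each module.
#'
#' @param membership Tibble with `module` and `subgenome` ("A"/"D") per
#'   node.
#' @return Tibble `module`, `n_A`, `n_D`, `p`.
#' @export
module_subgenome_test <- function(membership) {
  membership %>%
    filter(.data$module > 0) %>%
    group_by(.data$module) %>%
    summarise(n_A = sum(.data$subgenome == "A"),
              n_D = sum(.data$subgenome == "D"), .groups = "drop") %>%
    mutate(p = purrr::map2_dbl(.data$n_A, .data$n_A + .data$n_D,
                               function(x, n) binom.test(x, n, 0.5)$p.value))
}

#' Replicate-mean log2 TPM node profiles for network construction
#'
#' Builds the node x tissue profile matrix used by the quadruplet network:
#' one node per gene (or per pair context), profiled as the replicate-mean
#' `log2(TPM + 1)` across tissues.
#'
#' @param tpm TPM tibble (first column `gene_id`).
#' @param sheet Sample sheet describing the TPM columns.
#' @param node_suffix Optional suffix appended to gene ids (e.g. the
#'   genotype context) so profiles from several contexts can share one
#'   network.
#' @return Tibble, first column `node_id`, one column per tissue.
#' @export
node_profiles <- function(tpm, sheet, node_suffix = NULL) {
  sheet <- sample_sheet(sheet)
  m <- as.matrix(tpm[, -1, drop = FALSE])
  prof <- vapply(unique(sheet$tissue), function(ti) {
    cols <- sheet$sample_id[sheet$tissue == ti]
    rowMeans(log2(m[, cols, drop = FALSE] + 1))
  }, numeric(nrow(m)))
  ids <- tpm$gene_id
  if (!is.null(node_suffix)) ids <- paste0(ids, "_", node_suffix)
  bind_cols(tibble(node_id = ids), as_tibble(prof))
}
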