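# Independent rule evaluators and brute-force references used to check the
# package implementations. These are deliberately coded from the verbal rule
# definitions, not by calling package internals.

oracle_hse <- function(sig_A, sig_B, sig_AB, sign_A, sign_B) {
  zA <- !sig_A; zB <- !sig_B; eqAB <- !sig_AB
  if (eqAB && zA && zB) return("conserved")
  if (eqAB && !zA && !zB) return("cis_only")
  if (!eqAB && !zA && zB) return("trans_only")
  if (!eqAB && !zA && !zB) {
    if (sign_A > 0 && sign_B > 0) return("cis_plus_trans")
    if (sign_A < 0 && sign_B < 0) return("cis_plus_trans")
    return("cis_times_trans")
  }
  if (!eqAB && zA && !zB) return("compensatory")
  "ambiguous"
}

oracle_heb_group <- function(mix, at2) {
  if (mix == "A" && at2 == "A") return("parental_legacy")
  if (mix == "D" && at2 == "D") return("parental_legacy")
  if (mix == "none" && at2 == "none") return("parental_legacy")
  if (at2 == "none") return("convergence")
  if (mix == "none") return("divergence")
  "reversion"
}

oracle_rewiring <- function(ad, dd, at, dt) {
  if (any(c(ad, dd, at, dt) == 0)) return("other")
  if (length(unique(c(ad, dd, at, dt))) == 1) return("conserved_same")
  if (ad != dd && ad == at && dd == dt) return("conserved_different")
  if (ad != dd && at == dt) return("convergence")
  if (ad == dd && at != dt) return("divergence")
  "other"
}

# upper-tail hypergeometric by direct combinatorial summation
oracle_hyper_upper <- function(k, n_a, n_b, n_pop) {
  imax <- min(n_a, n_b)
  if (k > imax) return(0)
  sum(vapply(k:imax, function(i) {
    choose(n_b, i) * choose(n_pop - n_b, n_a - i) / choose(n_pop, n_a)
  }, numeric(1)))
}

# topological overlap by direct triple loop
oracle_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# NG86 by brute force: fractional site counting and full path enumeration,
# returning raw proportions (no distance correction)
oracle_ng86 <- function(s1, s2) {
  code <- as.list(Biostrings::GENETIC_CODE)
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  count_sites <- function(codon) {
    aa <- code[[codon]]
    ch <- strsplit(codon, "")[[1]]
    syn <- 0
    for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == ch[pos]) next
      alt <- ch; alt[pos] <- b
      aa2 <- code[[paste(alt, collapse = "")]]
      if (aa2 != "*" && aa2 == aa) syn <- syn + 1 / 3
    }
    c(syn = syn, non = 3 - syn)
  }
  all_orders <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in all_orders(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  c1 <- split3(toupper(s1)); c2 <- split3(toupper(s2))
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (idx in seq_along(c1)) {
    st1 <- count_sites(c1[idx]); st2 <- count_sites(c2[idx])
    S <- S + (st1["syn"] + st2["syn"]) / 2
    N <- N + (st1["non"] + st2["non"]) / 2
    a <- strsplit(c1[idx], "")[[1]]; b <- strsplit(c2[idx], "")[[1]]
    dpos <- which(a != b)
    if (!length(dpos)) next
    paths <- all_orders(dpos)
    tallies <- lapply(paths, function(ord) {
      cur <- a; syn <- 0; non <- 0; hits_stop <- FALSE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b[pos]
        aa1 <- code[[paste(cur, collapse = "")]]
        aa2 <- code[[paste(nxt, collapse = "")]]
        if (aa2 == "*" && !identical(nxt, b)) hits_stop <- TRUE
        if (aa1 == aa2) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      c(syn, non, hits_stop)
    })
    tl <- do.call(rbind, tallies)
    use <- if (any(tl[, 3] == 0)) tl[tl[, 3] == 0, , drop = FALSE] else tl
    Sd <- Sd + mean(use[, 1]); Nd <- Nd + mean(use[, 2])
  }
  c(ps = unname(Sd / S), pn = unname(Nd / N),
    S = unname(S), N = unname(N))
}

# reciprocal best hit by exhaustive search over a filtered record table
oracle_rbh <- function(records) {
  if (!nrow(records)) return(records[0, c("gene_A", "gene_D")])
  best <- function(df) df[order(-df$bitscore, -df$pct_identity), ][1, ]
  pairs <- list()
  for (ga in unique(records$gene_A)) {
    hit_a <- best(records[records$gene_A == ga, ])
    hit_d <- best(records[records$gene_D == hit_a$gene_D, ])
    if (hit_d$gene_A == ga) {
      pairs[[length(pairs) + 1]] <- data.frame(gene_A = ga,
                                               gene_D = hit_a$gene_D)
    }
  }
  do.call(rbind, pairs)
}
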