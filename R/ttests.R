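# Row-wise t-tests used by the ratio statistics. Degenerate conventions
# (zero variance): p = 1 when the mean effect is also zero, p = 0 otherwise.

row_t_one_sample <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  s2 <- rowSums((m - mu)^2) / (n - 1)
  p <- rep(NA_real_, nrow(m))
  degen <- s2 <= 0
  tt <- mu / sqrt(s2 / n)
  p[!degen] <- 2 * pt(-abs(tt[!degen]), df = n - 1)
  p[degen] <- ifelse(abs(mu[degen]) < 1e-12, 1, 0)
  list(mean = mu, p = p)
}

row_t_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  delta <- ma - mb
  p <- rep(NA_real_, nrow(a))
  degen <- se2 <= 0
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  tt <- delta / sqrt(se2)
  p[!degen] <- 2 * pt(-abs(tt[!degen]), df = df[!degen])
  p[degen] <- ifelse(abs(delta[degen]) < 1e-12, 1, 0)
  list(delta = delta, p = p)
}

# reshape one value column of the long quadruplet table into a matrix with
# one row per (pair, tissue) and one column per replicate
quad_to_matrices <- function(quad, cols) {
  quad <- quad %>% arrange(.data$pair_id, .data$tissue, .data$replicate)
  reps <- sort(unique(quad$replicate))
  nrep <- length(reps)
  idx <- quad %>% distinct(.data$pair_id, .data$tissue)
  mats <- lapply(cols, function(cl) {
    matrix(quad[[cl]], ncol = nrep, byrow = TRUE)
  })
  names(mats) <- cols
  list(index = idx, mats = mats, n_reps = nrep)
}
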