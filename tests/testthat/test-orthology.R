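toy_annotation <- function(n_A = 3, n_D = 3, len = 900) {
  tibble::tibble(
    gene_id = c(sprintf("gA%d", seq_len(n_A)), sprintf("gD%d", seq_len(n_D))),
    subgenome = rep(c("A", "D"), c(n_A, n_D)),
    cds_length = len
  )
}

aln_record <- function(q, s, ident = 95, len = 800, evalue = 1e-50,
                       bits = 500) {
  tibble::tibble(query = q, subject = s, pct_identity = ident,
                 aln_length = len, mismatch = 0L, gap_open = 0L,
                 qstart = 1L, qend = len, sstart = 1L, send = len,
                 evalue = evalue, bitscore = bits)
}

test_that("pairing filters follow the coverage/identity/E-value criteria", {
  ann <- toy_annotation()
  # 800/900 = 0.89 coverage both sides, 95% identity: retained
  keep <- call_pairs(aln_record("gA1", "gD1"), ann)
  expect_equal(nrow(keep), 1)
  expect_equal(keep$gene_A, "gA1")
  # identity below 90%: dropped regardless of coverage
  expect_equal(nrow(call_pairs(aln_record("gA1", "gD1", ident = 85), ann)), 0)
  # coverage at most 0.60 on either side: dropped (strict >)
  expect_equal(nrow(call_pairs(aln_record("gA1", "gD1", len = 540), ann)), 0)
  # E-value at threshold: dropped (strict <)
  expect_equal(nrow(call_pairs(aln_record("gA1", "gD1", evalue = 1e-5),
                               ann)), 0)
  expect_error(call_pairs(aln_record("gA9", "gD1"), ann), "absent")
})

test_that("reciprocal best hit resolves competing hits one-to-one", {
  ann <- toy_annotation()
  aln <- dplyr::bind_rows(
    aln_record("gA1", "gD1", bits = 900),
    aln_record("gD1", "gA1", bits = 900),
    aln_record("gA2", "gD1", bits = 700),
    aln_record("gD2", "gA2", bits = 650),
    aln_record("gA2", "gD2", bits = 650)
  )
  # gA2 prefers gD1, which reciprocates gA1 only; so despite the mutual
  # gA2/gD2 hits, gA2 stays unpaired under strict RBH
  pairs <- call_pairs(aln, ann)
  expect_equal(pairs$gene_A, "gA1")
  expect_equal(pairs$gene_D, "gD1")
  # with no competing hit, both reciprocal pairs form
  aln2 <- dplyr::bind_rows(
    aln_record("gA1", "gD1", bits = 900),
    aln_record("gD1", "gA1", bits = 900),
    aln_record("gD2", "gA2", bits = 650),
    aln_record("gA2", "gD2", bits = 650)
  )
  p2 <- call_pairs(aln2, ann)
  expect_equal(p2$gene_A, c("gA1", "gA2"))
  expect_equal(p2$gene_D, c("gD1", "gD2"))
  # three-record case: gA2's best hit gD1 is already taken reciprocally
  aln3 <- dplyr::bind_rows(
    aln_record("gA1", "gD1", bits = 900),
    aln_record("gD1", "gA1", bits = 900),
    aln_record("gA2", "gD1", bits = 700)
  )
  p3 <- call_pairs(aln3, ann)
  expect_equal(nrow(p3), 1)
  expect_equal(p3$gene_A, "gA1")
})

test_that("pairing matches brute-force RBH and honours its thresholds", {
  set.seed(11)
  ann <- toy_annotation(6, 6)
  for (rep in 1:5) {
    n <- 15
    aln <- aln_record(
      sample(sprintf("gA%d", 1:6), n, replace = TRUE),
      sample(sprintf("gD%d", 1:6), n, replace = TRUE),
      ident = runif(n, 88, 99), len = sample(500:900, n),
      bits = runif(n, 100, 1000)
    )
    aln <- dplyr::distinct(aln, query, subject, .keep_all = TRUE)
    got <- call_pairs(aln, ann)
    # oracle works on the same filtered, A->D oriented table
    kept <- aln[aln$pct_identity >= 90 & aln$aln_length / 900 > 0.6 &
                  aln$evalue < 1e-5, ]
    names(kept)[1:2] <- c("gene_A", "gene_D")
    want <- oracle_rbh(as.data.frame(kept))
    expect_setequal(paste(got$gene_A, got$gene_D),
                    paste(want$gene_A, want$gene_D))
    # each gene appears at most once
    expect_false(anyDuplicated(got$gene_A) > 0)
    expect_false(anyDuplicated(got$gene_D) > 0)
    # every returned pair satisfies the stricter identity threshold it was
    # called with
    strict <- call_pairs(aln, ann, min_ident = 0.95)
    expect_true(all(strict$pct_identity >= 95))
  }
})

test_that("NG86 matches exhaustive path enumeration on random codon pairs", {
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  set.seed(21)
  for (rep in 1:40) {
    s1 <- paste(sample(codons, 5, replace = TRUE), collapse = "")
    s2 <- paste(sample(codons, 5, replace = TRUE), collapse = "")
    want <- oracle_ng86(s1, s2)
    got <- ng86_ka_ks(s1, s2, correction = "none")
    expect_equal(unname(got["Ks"]), unname(want["ps"]), tolerance = 1e-12)
    expect_equal(unname(got["Ka"]), unname(want["pn"]), tolerance = 1e-12)
  }
})

test_that("NG86 handles canonical hand cases and degenerate input", {
  expect_equal(ng86_ka_ks("TTTGCT", "TTTGCT"), c(Ka = 0, Ks = 0))
  # TTT vs TTC: one synonymous difference over 1/3 synonymous sites
  raw <- ng86_ka_ks("TTT", "TTC", correction = "none")
  expect_equal(unname(raw["Ka"]), 0)
  expect_equal(unname(raw["Ks"]), 3)  # 1 / (1/3)
  # in a longer context the corrected Ks is finite and positive, Ka zero
  jc <- ng86_ka_ks("TTTGCCGGA", "TTCGCCGGA")
  expect_equal(unname(jc["Ka"]), 0)
  expect_gt(unname(jc["Ks"]), 0)
  expect_error(ng86_ka_ks("TTTG", "TTTG"), "divisible")
  expect_error(ng86_ka_ks("TTTTAAGGG", "TTTTAAGGG"), "stop")
  expect_warning(ng86_ka_ks("TTT", "TTC"), "saturated")
})

test_that("generated sequence pairs recover Ka/Ks targets", {
  sp <- simulate_sequence_pairs(n_pairs = 15, n_codons = 300,
                                ka_target = 0, ks_target = 0.1, seed = 13)
  kk <- t(mapply(ng86_ka_ks, sp$cds_A, sp$cds_D))
  expect_true(all(kk[, "Ka"] == 0))
  # S ~ 230 sites at 300 codons; binomial sd of Ks ~ sqrt(.1*.9/230) ~ 0.02
  expect_lt(abs(mean(kk[, "Ks"]) - 0.1), 0.02)
  expect_true(all(abs(kk[, "Ks"] - 0.1) < 5 * sqrt(0.1 * 0.9 / 230)))
})

test_that("promoter p-distance follows its definition", {
  expect_equal(promoter_pdistance(strrep("ACGT", 125), strrep("ACGT", 125)), 0)
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 99), "C")
  expect_equal(promoter_pdistance(a, b), 0.01)
  # N columns are excluded from the denominator
  a2 <- paste0("N", strrep("A", 99))
  b2 <- paste0("C", strrep("A", 98), "G")
  expect_equal(promoter_pdistance(a2, b2), 1 / 99)
  expect_true(is.nan(promoter_pdistance("NNN", "ACG")))
  expect_error(promoter_pdistance("AC", "ACG"), "equal length")
})

test_that("pair_divergence assembles per-pair tables", {
  sp <- simulate_sequence_pairs(n_pairs = 4, n_codons = 60, seed = 5)
  pairs <- tibble::tibble(pair_id = sp$truth$pair_id,
                          gene_A = names(sp$cds_A),
                          gene_D = names(sp$cds_D))
  div <- pair_divergence(pairs, c(sp$cds_A, sp$cds_D),
                         c(sp$prom_A, sp$prom_D))
  expect_equal(nrow(div), 4)
  expect_true(all(div$Ka >= 0 & div$Ks >= 0))
  expect_true(all(div$promoter_pdist >= 0 & div$promoter_pdist <= 1))
})
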