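# polyshock

Transcriptome-shock analysis for synthetic allopolyploids.

When two diploid genomes are merged and doubled into one nucleus — here the
AADD design: an allotetraploid built from an A-genome parent and a D-genome
parent, observed alongside both parents across nine tissues/stages with
three replicates — gene expression reorganizes in characteristic ways.
polyshock implements the complete downstream analysis from gene-level
RNA-seq counts, and a synthetic-data generator with known ground truth so
that every stage is testable without any external data.

## What it computes

For each homoeolog pair the four expression contexts form a *quadruplet*:
Ad and Dd in the diploid parents (combined 1:1 into an in-silico parental
mix) and At and Dt in the allotetraploid. With
`A = log2(Ad/Dd)` and `B = log2(At/Dt)` (TPM ratios), divergence between
parents carries cis + trans regulatory differences while divergence between
homoeologs sharing a nucleus carries cis only, so `A − B` estimates the
trans component. On this backbone the package provides:

- **TPM and parental mix** — `compute_tpm()`, `build_mix()` (count-level
  1:1 mixing; TPM over the union gene set), expression-ubiquity categories
  (silent / specific / intermediate / conserved), sample PCA.
- **Homoeolog pairing and divergence** — `call_pairs()` (reciprocal best
  hit over BLAST outfmt-6 records at E < 1e-5, identity ≥ 90%, coverage
  > 60% both sides), `ng86_ka_ks()` (Nei–Gojobori 1986 + Jukes–Cantor),
  `promoter_pdistance()`.
- **Differential expression** — `nb_wald_test()`, a self-contained
  negative-binomial Wald test with median-of-ratios size factors and
  moderated method-of-moments dispersion; calls at fold change > 2,
  BH FDR < 0.05; DEG ubiquity/direction categories; spike-development gene
  (SDRG) rules.
- **Homoeolog expression bias (HEB)** — `call_heb()` per context,
  four-group trajectory tracing mix→allotetraploid
  (`classify_heb_group()`), Flagel–Wendel net bias (`net_heb()`), stable
  spike-stage bias.
- **Cis/trans classification (HSE)** — `hse_statistics()` +
  `classify_hse()` into the seven categories conserved, cis-only,
  trans-only, cis + trans, cis × trans, compensatory, ambiguous.
- **Co-expression networks** — `build_network()` (unsigned `|cor|^beta`,
  topological overlap, height-sweep module detection, eigengene merging),
  `hec_score()` (shared-neighbor connectivity of a pair with a
  hypergeometric test; groups A/B/C), `classify_rewiring()` (five
  quadruplet classes), `module_subgenome_test()`.
- **Simulation** — `simulate_quadruplets()` emits NB counts per genotype,
  sample sheet, pair table and a truth table (planted cis/trans effects,
  bias trajectories, DE status, module membership);
  `simulate_sequence_pairs()` emits CDS/promoter pairs at controlled
  Ka/Ks/promoter divergence.
- **Orchestration** — `pipeline_config()` + `run_pipeline()` run
  everything end to end, write one TSV per stage plus a summary report,
  and are byte-for-byte reproducible under a fixed seed.

Functions take tibbles first and return tibbles; fitted objects
(`sample_pca()`, `build_network()`) have `tidy()`/`glance()` methods and
plot helpers (`autoplot()`, `plot_hse_proportions()`, `plot_heb_groups()`,
`plot_module_eigengenes()`).

## Worked example

```r
library(polyshock)
library(dplyr)

cfg <- synth_config(n_pairs = 500, n_tissues = 9, n_reps = 3, seed = 1,
                    de_fraction = 0.1, n_modules = 3, module_cohesion = 0.9)
d <- simulate_quadruplets(cfg)

hse <- classify_hse(hse_statistics(d$quad_tpm))
hse %>% filter(tissue == "leaf", !is.na(category)) %>% count(category)
#>   category            n
#> 1 ambiguous          79
#> 2 cis_only           73
#> 3 cis_plus_trans     59
#> 4 cis_times_trans    39
#> 5 compensatory       54
#> 6 conserved          68
#> 7 trans_only         68
```

Each classified row carries the underlying statistics, e.g.

```r
hse %>% filter(tissue == "leaf") %>%
  select(pair_id, A, B, trans_est, p_A, p_B, p_AB, category) %>% head(2)
#>   pair_id       A     B trans_est      p_A    p_B    p_AB category
#> 1 p00001  -2.37   -1.11     -1.25 0.000429 0.0107 0.00333 cis_plus_trans
#> 2 p00002  -0.0425 -1.96      1.92 0.874    0.0406 0.0235  compensatory
```

`p00002` reads: parents agree (A ≈ 0) but the homoeologs diverge in the
shared nucleus (B ≈ −2, significant), so a cis difference must exist that
was masked by an opposing trans difference in the parents — compensatory.

Bias trajectories between the mix and the allotetraploid:

```r
hm <- call_heb(d$quad_counts, d$pairs, "MIX")  %>% filter(tissue == "leaf")
ha <- call_heb(d$quad_counts, d$pairs, "AT2") %>% filter(tissue == "leaf")
table(classify_heb_group(hm$bias, ha$bias))
#>     convergence      divergence parental_legacy       reversion
#>             103              81             275              41
```

Most pairs inherit their parental bias state (parental legacy); the rest
lose, gain or flip bias after allopolyploidization.

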