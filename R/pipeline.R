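#' Pipeline configuration
#'
#' One flat configuration object drives [run_pipeline()]. Thresholds default
#' to the study's printed parameters: fold change > 2 and FDR < 0.05 for
#' differential expression and bias calls, t-test alpha 0.05 for the
#' cis/trans classification, TPM > 1 expression filter, pairing criteria of
#' 60% coverage and 90% identity at E-value < 1e-5, soft powers 18 (homoeolog
#' and quadruplet networks) and 9 (spike network), minModuleSize 30 and
#' mergeCutHeight 0.25.
#'
#' @param simulate Optional named list of [synth_config()] arguments; when
#'   present the pipeline generates its inputs.
#' @param input Optional named list of file paths (`counts_AA`,
#'   `lengths_AA`, `counts_DD`, `lengths_DD`, `counts_AT2`, `lengths_AT2`,
#'   `sample_sheet`, `pairs`) used when `simulate` is absent.
#' @param fc,fdr,alpha,tpm Thresholds (fold change, FDR, t-test alpha,
#'   expression filter).
#' @param min_cov,min_ident,max_evalue Pairing criteria.
#' @param beta_homoeolog,beta_quadruplet,beta_spike Soft powers.
#' @param min_module_size,merge_cut,neighbor_quantile Network parameters.
#' @param epsilon Pseudo-TPM for ratio statistics.
#' @param expression_rule `"mean"` or `"all"` replicate rule for the
#'   expression filter.
#' @param seed Root seed for the simulated path.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL,
                            fc = 2, fdr = 0.05, alpha = 0.05, tpm = 1,
                            min_cov = 0.60, min_ident = 0.90,
                            max_evalue = 1e-5,
                            beta_homoeolog = 18, beta_quadruplet = 18,
                            beta_spike = 9,
                            min_module_size = 30, merge_cut = 0.25,
                            neighbor_quantile = 0.95, epsilon = 0.5,
                            expression_rule = c("mean", "all"),
                            seed = 1L) {
  expression_rule <- match.arg(expression_rule)
  if (is.null(simulate) && is.null(input)) {
    abort("config needs either a simulate block or input paths")
  }
  if (is.null(simulate)) {
    need <- c("counts_AA", "lengths_AA", "counts_DD", "lengths_DD",
              "counts_AT2", "lengths_AT2", "sample_sheet", "pairs")
    missing_keys <- setdiff(need, names(input))
    if (length(missing_keys)) {
      abort(paste0("input block is missing: ",
                   paste(missing_keys, collapse = ", ")))
    }
    missing_files <- unlist(input[need])[!file.exists(unlist(input[need]))]
    if (length(missing_files)) {
      abort(paste0("input file(s) not found: ",
                   paste(missing_files, collapse = ", ")))
    }
  }
  structure(list(
    simulate = simulate, input = input, fc = fc, fdr = fdr, alpha = alpha,
    tpm = tpm, min_cov = min_cov, min_ident = min_ident,
    max_evalue = max_evalue, beta_homoeolog = beta_homoeolog,
    beta_quadruplet = beta_quadruplet, beta_spike = beta_spike,
    min_module_size = min_module_size, merge_cut = merge_cut,
    neighbor_quantile = neighbor_quantile, epsilon = epsilon,
    expression_rule = expression_rule, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file whose keys mirror the
#'   [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis
#'
#' Orchestrates simulate/ingest, TPM and parental-mix construction,
#' expression-ubiquity categorisation, per-tissue differential expression of
#' each allotetraploid subgenome against its parent, homoeolog-bias calling
#' and trajectory tracing, net bias, cis/trans classification, co-expression
#' networks (parental-mix, allotetraploid and joint quadruplet), homoeolog
#' expression connectivity, quadruplet rewiring, and spike-development gene
#' calls. Every stage writes a TSV into `out_dir`; a summary report
#' (category counts per stage) is written alongside. All outputs are a pure
#' function of (config, seed).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list with the stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(out_dir, name)

  # ingest or simulate -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- do.call(synth_config,
                   c(config$simulate, list(seed = config$seed)))
    data <- simulate_quadruplets(sim)
    readr::write_tsv(data$truth, out("truth.tsv"))
  } else {
    inp <- config$input
    counts <- list(
      AA = read_counts(inp$counts_AA, inp$lengths_AA),
      DD = read_counts(inp$counts_DD, inp$lengths_DD),
      AT2 = read_counts(inp$counts_AT2, inp$lengths_AT2)
    )
    sheet <- read_sample_sheet(inp$sample_sheet)
    pairs <- readr::read_tsv(inp$pairs, col_types = readr::cols(
      pair_id = readr::col_character(), gene_A = readr::col_character(),
      gene_D = readr::col_character(), .default = readr::col_double()
    ))
    if (!all(c("length_A", "length_D") %in% names(pairs))) {
      all_len <- bind_rows(counts$AA$gene_lengths, counts$DD$gene_lengths)
      pairs$length_A <- all_len$length[match(pairs$gene_A, all_len$gene_id)]
      pairs$length_D <- all_len$length[match(pairs$gene_D, all_len$gene_id)]
    }
    mix <- build_mix(counts$AA, counts$DD,
                     sheet %>% filter(.data$genotype %in% c("AA", "DD")))
    data <- list(counts = counts, sample_sheet = sheet, pairs = pairs,
                 truth = NULL, mix = mix,
                 quad_counts = quadruplet_table(counts, mix, pairs, sheet,
                                                "counts"),
                 quad_tpm = quadruplet_table(counts, mix, pairs, sheet,
                                             "tpm"))
  }
  sheet <- data$sample_sheet
  pairs <- data$pairs
  write_sample_sheet(sheet %>% filter(.data$genotype != "MIX"),
                     out("sample_sheet.tsv"))
  readr::write_tsv(pairs, out("pairs.tsv"))
  for (g in names(data$counts)) {
    write_counts(data$counts[[g]], out(paste0("counts_", g, ".tsv")))
  }

  # TPM ----------------------------------------------------------------------
  tpm <- lapply(data$counts, compute_tpm)
  tpm$MIX <- compute_tpm(data$mix$counts)
  for (g in names(tpm)) {
    readr::write_tsv(tpm[[g]], out(paste0("tpm_", g, ".tsv")))
  }
  mix_sheet <- data$mix$sample_sheet
  at2_sheet <- sheet %>% filter(.data$genotype == "AT2")
  tissues <- sort(unique(at2_sheet$tissue))
  full_design <- setequal(tissues, tissue_levels())

  # ubiquity -----------------------------------------------------------------
  ubiquity <- NULL
  if (full_design) {
    ubiquity <- bind_rows(
      categorize_ubiquity(tpm$AT2, at2_sheet, config$tpm,
                          config$expression_rule) %>%
        mutate(context = "AT2"),
      categorize_ubiquity(tpm$MIX, mix_sheet, config$tpm,
                          config$expression_rule) %>%
        mutate(context = "MIX")
    )
    readr::write_tsv(ubiquity, out("ubiquity.tsv"))
  }

  # differential expression: allotetraploid context vs parent ----------------
  de_calls <- purrr::map_dfr(tissues, function(ti) {
    purrr::map_dfr(c(A = "AA", D = "DD"), function(parent) {
      sub <- if (parent == "AA") "A" else "D"
      genes <- if (sub == "A") pairs$gene_A else pairs$gene_D
      par_cm <- data$counts[[parent]]
      par_sheet <- sheet %>%
        filter(.data$genotype == parent, .data$tissue == ti)
      at2_cols <- at2_sheet$sample_id[at2_sheet$tissue == ti]
      m_par <- as.matrix(par_cm$counts[, -1])[
        match(genes, par_cm$counts$gene_id), par_sheet$sample_id,
        drop = FALSE]
      m_at2 <- as.matrix(data$counts$AT2$counts[, -1])[
        match(genes, data$counts$AT2$counts$gene_id), at2_cols,
        drop = FALSE]
      de <- nb_wald_test(m_par, m_at2, gene_ids = genes)
      call_degs(de, config$fc, config$fdr) %>%
        mutate(tissue = ti, subgenome = sub)
    })
  })
  readr::write_tsv(de_calls, out("de_calls.tsv"))
  deg_categories <- de_calls %>%
    group_by(.data$subgenome) %>%
    dplyr::group_modify(~categorize_degs(.x)) %>%
    ungroup()
  readr::write_tsv(deg_categories, out("deg_categories.tsv"))

  # homoeolog expression bias -------------------------------------------------
  heb_mix <- call_heb(data$quad_counts, pairs, "MIX", config$fc, config$fdr)
  heb_at2 <- call_heb(data$quad_counts, pairs, "AT2", config$fc, config$fdr)
  heb_calls <- bind_rows(heb_mix, heb_at2)
  readr::write_tsv(heb_calls, out("heb_calls.tsv"))
  heb_groups_tbl <- inner_join(
    heb_mix %>% select("pair_id", "tissue", mix_bias = "bias"),
    heb_at2 %>% select("pair_id", "tissue", at2_bias = "bias"),
    by = c("pair_id", "tissue")
  ) %>% mutate(group = classify_heb_group(.data$mix_bias, .data$at2_bias))
  readr::write_tsv(heb_groups_tbl, out("heb_groups.tsv"))
  net <- net_heb(data$quad_tpm, config$epsilon, config$fc, config$alpha)
  readr::write_tsv(net, out("net_heb.tsv"))
  stable <- NULL
  if (all(spike_tissues() %in% tissues)) {
    stable <- stable_spike_heb(heb_at2)
    readr::write_tsv(stable, out("stable_heb.tsv"))
  }

  # cis/trans classification --------------------------------------------------
  hse <- classify_hse(hse_statistics(data$quad_tpm, config$epsilon),
                      config$alpha)
  readr::write_tsv(hse, out("hse.tsv"))
  hse_sum <- hse_summary(hse)
  readr::write_tsv(hse_sum$by_tissue, out("hse_by_tissue.tsv"))

  # networks ------------------------------------------------------------------
  keep_tpm <- function(tb, genes) tb[match(genes, tb$gene_id), ]
  prof_mix <- node_profiles(
    keep_tpm(tpm$MIX, c(pairs$gene_A, pairs$gene_D)), mix_sheet, "d")
  prof_at2 <- node_profiles(
    keep_tpm(tpm$AT2, c(pairs$gene_A, pairs$gene_D)), at2_sheet, "t")
  nets <- list(
    mix = build_network(prof_mix, config$beta_homoeolog,
                        config$min_module_size, config$merge_cut),
    at2 = build_network(prof_at2, config$beta_homoeolog,
                        config$min_module_size, config$merge_cut),
    quad = build_network(bind_rows(prof_mix, prof_at2),
                         config$beta_quadruplet, config$min_module_size,
                         config$merge_cut)
  )
  for (nm in names(nets)) {
    readr::write_tsv(tidy(nets[[nm]]), out(paste0("modules_", nm, ".tsv")))
  }
  hec_pairs <- function(net, suffix) {
    pairs %>%
      mutate(node_a = paste0(.data$gene_A, "_", suffix),
             node_b = paste0(.data$gene_D, "_", suffix)) %>%
      filter(.data$node_a %in% net$node_ids, .data$node_b %in% net$node_ids)
  }
  hec <- bind_rows(
    hec_score(nets$mix, hec_pairs(nets$mix, "d"),
              config$neighbor_quantile) %>% mutate(context = "MIX"),
    hec_score(nets$at2, hec_pairs(nets$at2, "t"),
              config$neighbor_quantile) %>% mutate(context = "AT2")
  )
  readr::write_tsv(hec, out("hec.tsv"))
  qmod <- setNames(unname(nets$quad$modules), nets$quad$node_ids)
  lookup <- function(ids) {
    v <- qmod[ids]
    v[is.na(v)] <- 0L
    unname(v)
  }
  rewiring <- tibble(
    pair_id = pairs$pair_id,
    module_Ad = lookup(paste0(pairs$gene_A, "_d")),
    module_Dd = lookup(paste0(pairs$gene_D, "_d")),
    module_At = lookup(paste0(pairs$gene_A, "_t")),
    module_Dt = lookup(paste0(pairs$gene_D, "_t"))
  ) %>% mutate(class = classify_rewiring(.data$module_Ad, .data$module_Dd,
                                         .data$module_At, .data$module_Dt))
  readr::write_tsv(rewiring, out("rewiring.tsv"))

  # spike-development genes ---------------------------------------------------
  sdrg <- NULL
  if (full_design) {
    sdrg <- identify_sdrgs(tpm$MIX, mix_sheet,
                           de_calls %>% select("gene_id", "tissue", "call"),
                           fold = config$fc)
    readr::write_tsv(sdrg, out("sdrg.tsv"))
  }

  # report --------------------------------------------------------------------
  report <- bind_rows(
    de_calls %>% filter(.data$call != "none") %>%
      count(.data$subgenome, .data$tissue, .data$call) %>%
      mutate(stage = "de",
             item = paste(.data$subgenome, .data$tissue, .data$call)) %>%
      select("stage", "item", "n"),
    heb_groups_tbl %>% count(.data$tissue, .data$group) %>%
      mutate(stage = "heb_group",
             item = paste(.data$tissue, .data$group)) %>%
      select("stage", "item", "n"),
    hse %>% filter(!is.na(.data$category)) %>%
      count(.data$tissue, .data$category) %>%
      mutate(stage = "hse",
             item = paste(.data$tissue, .data$category)) %>%
      select("stage", "item", "n"),
    hec %>% count(.data$context, .data$group) %>%
      mutate(stage = "hec", item = paste(.data$context, .data$group)) %>%
      select("stage", "item", "n"),
    rewiring %>% count(.data$class) %>%
      mutate(stage = "rewiring", item = .data$class) %>%
      select("stage", "item", "n"),
    if (!is.null(sdrg)) {
      tibble(stage = "sdrg", item = c("sdrg", "stably_down"),
             n = c(sum(sdrg$sdrg), sum(sdrg$stably_down, na.rm = TRUE)))
    }
  )
  readr::write_tsv(report, out("report.tsv"))

  invisible(list(
    data = data, tpm = tpm, ubiquity = ubiquity, de_calls = de_calls,
    deg_categories = deg_categories, heb_calls = heb_calls,
    heb_groups = heb_groups_tbl, net_heb = net, stable_heb = stable,
    hse = hse, hse_summary = hse_sum, networks = nets, hec = hec,
    rewiring = rewiring, sdrg = sdrg, report = report
  ))
}
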