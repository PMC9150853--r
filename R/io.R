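#' Controlled vocabularies for samples
#'
#' The experiment design covers three genotypes (the two diploid progenitors
#' `AA` and `DD` and the allotetraploid `AT2`; the in-silico parental mix
#' `MIX` is derived, never read from disk) across nine tissues/stages:
#' primary root and shoot at germination, root and leaf at the trefoil stage,
#' and five successive spike (inflorescence) stages from 0.5 to 2.5 cm.
#'
#' @return Character vector of level names.
#' @export
tissue_levels <- function() {
  c("primary_root", "shoot", "root", "leaf",
    "spike_0.5", "spike_1.0", "spike_1.5", "spike_2.0", "spike_2.5")
}

#' @rdname tissue_levels
#' @export
spike_tissues <- function() {
  grep("^spike", tissue_levels(), value = TRUE)
}

#' @rdname tissue_levels
#' @export
genotype_levels <- function() {
  c("AA", "DD", "AT2", "MIX")
}

ps_log <- function(stage, ...) {
  if (isTRUE(getOption("polyshock.verbose", FALSE))) {
    inform(paste0("[", stage, "] ", sprintf(...)))
  }
  invisible(NULL)
}

#' Validate a sample sheet
#'
#' A sample sheet is a tibble with columns `sample_id`, `genotype`, `tissue`
#' and `replicate`. Sample ids and (genotype, tissue, replicate) triples must
#' be unique; tissue labels must come from [tissue_levels()] and genotypes
#' from [genotype_levels()]. Unknown labels are a hard error, never silently
#' dropped.
#'
#' @param df A data frame with the four columns above.
#' @return A validated tibble (invisibly the same data, ordered columns).
#' @export
sample_sheet <- function(df) {
  df <- as_tibble(df)
  need <- c("sample_id", "genotype", "tissue", "replicate")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[, need]
  bad_tissue <- setdiff(unique(df$tissue), tissue_levels())
  if (length(bad_tissue)) {
    abort(paste0("unknown tissue label(s): ", paste(bad_tissue, collapse = ", ")))
  }
  bad_geno <- setdiff(unique(df$genotype), genotype_levels())
  if (length(bad_geno)) {
    abort(paste0("unknown genotype label(s): ", paste(bad_geno, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    abort("duplicated sample_id in sample sheet")
  }
  key <- paste(df$genotype, df$tissue, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicated (genotype, tissue, replicate) triple in sample sheet")
  }
  if (!is.numeric(df$replicate) || any(df$replicate < 1) ||
      any(df$replicate != as.integer(df$replicate))) {
    abort("replicate must be an integer >= 1")
  }
  df$replicate <- as.integer(df$replicate)
  df
}

#' Read or write a sample sheet TSV
#'
#' @param path File path of a tab-separated sample sheet.
#' @return [read_sample_sheet()] returns a validated tibble.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    genotype = readr::col_character(),
    tissue = readr::col_character(),
    replicate = readr::col_integer()
  ))
  if (any(df$genotype == "MIX")) {
    abort("MIX samples are derived in code, never read from disk")
  }
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet A validated sample sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(sample_sheet(sheet), path)
  invisible(path)
}

#' Count matrices with gene lengths
#'
#' A count matrix couples a tibble of non-negative integer counts (first
#' column `gene_id`, one column per sample) with a tibble of per-gene lengths
#' in bp (`gene_id`, `length`). Lengths are required downstream for TPM.
#'
#' @param counts Tibble of counts, first column `gene_id`.
#' @param gene_lengths Tibble with columns `gene_id` and `length` (bp > 0).
#' @return A list of class `count_matrix` with elements `counts` and
#'   `gene_lengths`.
#' @export
count_matrix <- function(counts, gene_lengths) {
  counts <- as_tibble(counts)
  gene_lengths <- as_tibble(gene_lengths)
  if (names(counts)[1] != "gene_id") {
    abort("first column of a count table must be 'gene_id'")
  }
  if (!all(c("gene_id", "length") %in% names(gene_lengths))) {
    abort("gene_lengths needs columns gene_id and length")
  }
  vals <- as.matrix(counts[, -1, drop = FALSE])
  if (anyNA(vals)) abort("count matrix has missing cells")
  if (any(vals < 0)) abort("counts must be non-negative")
  if (any(vals != round(vals))) abort("counts must be integral")
  missing_len <- setdiff(counts$gene_id, gene_lengths$gene_id)
  if (length(missing_len)) {
    abort(paste0("no gene length for gene(s): ",
                 paste(head(missing_len, 5), collapse = ", ")))
  }
  if (any(gene_lengths$length <= 0)) abort("gene lengths must be positive")
  counts[, -1] <- lapply(counts[, -1, drop = FALSE], as.integer)
  gene_lengths <- gene_lengths[match(counts$gene_id, gene_lengths$gene_id), ]
  structure(list(counts = counts, gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts) - 1L))
  print(x$counts, n = 5)
  invisible(x)
}

#' Read a gene-level count matrix and its gene lengths
#'
#' Counts are a TSV whose header row holds sample ids and whose first column
#' is literally named `gene_id`; lengths are a two-column TSV (`gene_id`,
#' `length`). A counted gene without a length is a hard error naming the
#' gene; non-integer counts are a hard error.
#'
#' @param path Path to the count TSV.
#' @param lengths_path Path to the gene-length TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, lengths_path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  lens <- readr::read_tsv(lengths_path, col_types = readr::cols(
    gene_id = readr::col_character(), length = readr::col_double()
  ))
  cm <- count_matrix(counts, lens)
  ps_log("read_counts", "%s: %d genes, %d samples",
         path, nrow(cm$counts), ncol(cm$counts) - 1L)
  cm
}

#' @rdname read_counts
#' @param x A `count_matrix`.
#' @export
write_counts <- function(x, path, lengths_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  readr::write_tsv(x$counts, path)
  if (!is.null(lengths_path)) {
    lens <- x$gene_lengths
    lens$length <- as.integer(lens$length)
    readr::write_tsv(lens, lengths_path)
  }
  invisible(path)
}

#' Read tabular pairwise alignments (BLAST outfmt-6 dialect)
#'
#' Twelve tab-separated columns: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore. A line with the wrong number of
#' columns is a hard error reporting the line number. Records are returned in
#' file order.
#'
#' @param path Path to the alignment table (no header).
#' @return Tibble with one row per alignment record.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(
      query = character(), subject = character(), pct_identity = double(),
      aln_length = integer(), mismatch = integer(), gap_open = integer(),
      qstart = integer(), qend = integer(), sstart = integer(),
      send = integer(), evalue = double(), bitscore = double()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    abort(sprintf("line %d of %s has %d columns, expected 12", bad, path, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  out <- tibble(
    query = m[, 1], subject = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gap_open = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  if (any(out$evalue < 0)) abort("negative E-value in alignment table")
  ps_log("read_alignments", "%s: %d records", path, nrow(out))
  out
}

#' Read or write FASTA sequences as a named character vector
#'
#' Thin wrappers over Biostrings, returning plain named character vectors so
#' downstream code stays tidy-friendly.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Gene annotation table
#'
#' @param df Data frame with `gene_id` and `subgenome` (one of "A", "D"),
#'   optionally `cds_length` (bp).
#' @return Validated tibble.
#' @export
gene_annotation <- function(df) {
  df <- as_tibble(df)
  if (!all(c("gene_id", "subgenome") %in% names(df))) {
    abort("gene annotation needs columns gene_id and subgenome")
  }
  bad <- setdiff(unique(df$subgenome), c("A", "D"))
  if (length(bad)) abort(paste0("unknown subgenome label(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(df$gene_id)) abort("duplicated gene_id in annotation")
  df
}
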