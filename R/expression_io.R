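#' Read a gene x sample count matrix and its sample metadata
#'
#' Reads a delimited count matrix (genes as rows, first column the gene
#' identifier, header row the sample identifiers) together with a sample
#' metadata sheet, validates both, and returns them as tibbles. The
#' delimiter (tab or comma) is sniffed from the header line of each file.
#'
#' @param path Path to the count matrix (TSV or CSV).
#' @param metadata_path Path to the sample metadata sheet with columns
#'   `sample_id`, `group` and optionally `intron_spanning_reads`.
#' @return A list with components `counts` (tibble, first column
#'   `gene_id`, one column per sample, non-negative integer counts) and
#'   `metadata` (tibble with one row per sample).
#' @details Validation errors are raised for malformed numeric cells
#'   (naming the gene row and sample column), duplicated gene or sample
#'   identifiers, negative counts, and samples present in the matrix but
#'   absent from the metadata.
#' @examples
#' cm <- simulate_counts(n_genes = 40, n_normal = 4, n_tumor = 4, seed = 1)
#' tf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
#' write_counts(cm$counts, cm$metadata, tf, mf)
#' rt <- read_counts(tf, mf)
#' all.equal(rt$counts, cm$counts)
#' @export
read_counts <- function(path, metadata_path) {
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  if (!file.exists(metadata_path)) {
    stop("metadata file not found: ", metadata_path)
  }
  counts <- read_delim_sniff(path)
  names(counts)[1] <- "gene_id"
  counts$gene_id <- as.character(counts$gene_id)

  metadata <- read_delim_sniff(metadata_path)
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    stop("metadata must have columns 'sample_id' and 'group'")
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$group <- as.character(metadata$group)

  validate_counts(counts, metadata)
  message(sprintf("read %d genes x %d samples from %s",
                  nrow(counts), ncol(counts) - 1L, path))
  list(counts = counts, metadata = metadata)
}

# Delimiter-sniffing reader: tab wins if the header contains one.
read_delim_sniff <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Validate a count tibble against its metadata
#'
#' Checks the invariants of the count-matrix contract: unique gene and
#' sample identifiers, numeric non-negative counts, and metadata coverage
#' of every sample (exactly one group label per sample).
#'
#' @param counts Count tibble (first column `gene_id`).
#' @param metadata Sample metadata tibble (`sample_id`, `group`).
#' @return Invisibly `TRUE`; raises an error on any violation.
#' @export
validate_counts <- function(counts, metadata) {
  stopifnot(is.data.frame(counts), is.data.frame(metadata))
  if (names(counts)[1] != "gene_id") {
    stop("first column of counts must be 'gene_id'")
  }
  dup_g <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup_g) > 0) {
    stop("duplicated gene id(s): ", paste(unique(dup_g), collapse = ", "))
  }
  samples <- names(counts)[-1]
  if (anyDuplicated(samples)) stop("duplicated sample id(s) in counts")
  for (s in samples) {
    col <- counts[[s]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("malformed numeric cell at gene '%s', sample '%s'",
                   counts$gene_id[bad %||% 1], s))
    }
    if (anyNA(col)) {
      stop(sprintf("malformed numeric cell at gene '%s', sample '%s'",
                   counts$gene_id[which(is.na(col))[1]], s))
    }
    if (any(col < 0)) {
      stop(sprintf("negative count at gene '%s', sample '%s'",
                   counts$gene_id[which(col < 0)[1]], s))
    }
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicated sample id(s) in metadata")
  }
  missing_meta <- setdiff(samples, metadata$sample_id)
  if (length(missing_meta) > 0) {
    stop("samples missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a count matrix and metadata to delimited files
#'
#' Deterministic writer (row and column order preserved) producing the
#' same dialect [read_counts()] accepts.
#'
#' @inheritParams validate_counts
#' @param path,metadata_path Output file paths; delimiter chosen from the
#'   extension (`.csv` gives comma, anything else tab).
#' @return Invisibly, the count file path.
#' @export
write_counts <- function(counts, metadata, path, metadata_path) {
  delim <- function(p) if (grepl("\\.csv$", p)) "," else "\t"
  readr::write_delim(counts, path, delim = delim(path))
  readr::write_delim(metadata, metadata_path, delim = delim(metadata_path))
  invisible(path)
}

#' Transform counts to log2 counts per million
#'
#' Computes `log2(count / library_size * 1e6 + prior)` per cell, where
#' the library size is the column sum of the supplied matrix (so it
#' reflects whatever sample filtering has already been applied). With the
#' default `prior = 1`, a zero count maps to exactly 0.
#'
#' @param counts Count tibble (first column `gene_id`).
#' @param prior Positive pseudo-count added to CPM before taking log2.
#' @return A tibble of the same shape holding log2CPM values, with an
#'   attribute `transform_params` recording the prior and the per-sample
#'   library sizes used.
#' @examples
#' counts <- tibble::tibble(gene_id = c("A", "B"), s1 = c(3, 999997))
#' log2cpm(counts)  # gene A: log2(3 + 1) = 2
#' @export
log2cpm <- function(counts, prior = 1) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "gene_id",
            is.numeric(prior), length(prior) == 1, prior > 0)
  m <- as.matrix(counts[-1])
  lib <- colSums(m)
  zero_lib <- names(lib)[lib == 0]
  if (length(zero_lib) > 0) {
    stop("zero library size for sample(s): ",
         paste(zero_lib, collapse = ", "))
  }
  vals <- log2(sweep(m, 2, lib, "/") * 1e6 + prior)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = counts$gene_id),
                          tibble::as_tibble(vals))
  attr(out, "transform_params") <- list(prior = prior, lib_sizes = lib)
  out
}
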