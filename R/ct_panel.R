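#' Read a cycle-threshold (Ct) panel
#'
#' Accepts either the long dialect — columns `sample_id`, `group`,
#' `gene`, `replicate`, `ct` (replicate optional) — or the wide dialect
#' (first column the gene id, one column per sample, one value per cell),
#' auto-detected from the header. Wide input needs a metadata sheet for
#' the group labels.
#'
#' @param path Path to the Ct file (TSV or CSV).
#' @param metadata_path Optional metadata path (`sample_id`, `group`);
#'   required for wide input.
#' @return A long tibble with columns `gene`, `sample_id`, `group`,
#'   `replicate`, `ct`.
#' @export
read_ct_panel <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("Ct file not found: ", path)
  dat <- read_delim_sniff(path)
  long_cols <- c("sample_id", "group", "gene", "ct")
  if (all(long_cols %in% names(dat))) {
    if (!"replicate" %in% names(dat)) dat$replicate <- 1L
    panel <- tibble::as_tibble(dat[c("gene", "sample_id", "group",
                                     "replicate", "ct")])
  } else {
    if (is.null(metadata_path)) {
      stop("wide Ct input requires a metadata file for group labels")
    }
    meta <- read_delim_sniff(metadata_path)
    names(dat)[1] <- "gene"
    panel <- tidyr::pivot_longer(dat, -"gene", names_to = "sample_id",
                                 values_to = "ct")
    panel$group <- meta$group[match(panel$sample_id, meta$sample_id)]
    if (anyNA(panel$group)) {
      stop("samples missing from metadata: ",
           paste(unique(panel$sample_id[is.na(panel$group)]),
                 collapse = ", "))
    }
    panel$replicate <- 1L
    panel <- panel[c("gene", "sample_id", "group", "replicate", "ct")]
  }
  validate_ct_panel(panel)
  panel
}

#' Validate a long Ct panel
#'
#' Checks the Ct-panel contract: required columns, strictly positive Ct
#' where present, unique replicate indices within each (gene, sample),
#' and exactly one group label per sample.
#'
#' @param panel Long Ct tibble.
#' @return Invisibly `TRUE`; raises an error on any violation.
#' @export
validate_ct_panel <- function(panel) {
  need <- c("gene", "sample_id", "group", "replicate", "ct")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) {
    stop("Ct panel missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(panel$ct <= 0, na.rm = TRUE)) {
    stop("Ct values must be strictly positive where present")
  }
  dup <- duplicated(panel[c("gene", "sample_id", "replicate")])
  if (any(dup)) {
    stop("duplicated (gene, sample, replicate) measurement(s)")
  }
  grp <- unique(panel[c("sample_id", "group")])
  if (anyDuplicated(grp$sample_id)) {
    stop("a sample carries more than one group label")
  }
  invisible(TRUE)
}

#' Apply the Ct inclusion rule
#'
#' Measurements with Ct at or above `max_ct` are set to missing (the
#' rule is strictly "less than 35": a Ct of exactly 35 is excluded,
#' 34.99 is kept). Attrition is reported per gene via the
#' `ct_attrition` attribute.
#'
#' @param panel Long Ct tibble (see [read_ct_panel()]).
#' @param max_ct Exclusive upper bound on usable Ct values; default 35.
#' @return The panel with excluded measurements set to `NA`.
#' @export
apply_ct_inclusion <- function(panel, max_ct = 35) {
  excluded <- !is.na(panel$ct) & panel$ct >= max_ct
  out <- panel
  out$ct[excluded] <- NA_real_
  attr(out, "ct_attrition") <- dplyr::count(panel[excluded, ], .data$gene,
                                            name = "n_excluded")
  out
}

#' Collapse technical/biological replicates to one Ct per gene and sample
#'
#' Takes the arithmetic mean of the surviving (non-missing) replicate Ct
#' values within each (gene, sample) cell; cells with fewer than
#' `min_reps` surviving replicates become missing.
#'
#' @param panel Long Ct tibble with a `replicate` column.
#' @param min_reps Minimum surviving replicates for a cell to produce a
#'   value; default 2.
#' @return A long tibble `gene`, `sample_id`, `group`, `ct` with one row
#'   per (gene, sample).
#' @export
collapse_replicates <- function(panel, min_reps = 2) {
  dplyr::summarise(
    dplyr::group_by(panel, .data$gene, .data$sample_id, .data$group),
    ct = if (sum(!is.na(.data$ct)) >= min_reps) {
      mean(.data$ct, na.rm = TRUE)
    } else NA_real_,
    .groups = "drop")
}

# Collapsed long panel -> gene x sample matrix (NA for missing cells).
# Accepts already-collapsed panels only; call collapse_replicates first.
ct_matrix <- function(panel) {
  if ("replicate" %in% names(panel) &&
      anyDuplicated(panel[c("gene", "sample_id")])) {
    stop("panel still has replicate structure; collapse_replicates first")
  }
  wide <- tidyr::pivot_wider(panel[c("gene", "sample_id", "ct")],
                             names_from = "sample_id",
                             values_from = "ct")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene
  m
}

# Sample -> group lookup from a long panel, ordered as the matrix columns.
panel_groups <- function(panel, sample_ids) {
  grp <- unique(panel[c("sample_id", "group")])
  setNames(grp$group, grp$sample_id)[sample_ids]
}
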