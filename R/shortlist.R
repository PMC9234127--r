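#' Remove samples with insufficient sequencing depth
#'
#' Drops samples whose intron-spanning read total is strictly below
#' `min_reads` (a sample with exactly `min_reads` is retained). Depth is
#' taken from the `intron_spanning_reads` column of the metadata.
#'
#' @param counts Count tibble (first column `gene_id`).
#' @param metadata Sample metadata tibble; must carry
#'   `intron_spanning_reads` unless `on_missing_depth = "keep"`.
#' @param min_reads Minimum intron-spanning reads; default 400000.
#' @param on_missing_depth What to do when depth metadata is absent or
#'   `NA` for some samples: `"error"` (default) or `"keep"` (pass those
#'   samples through with a warning).
#' @return A list with filtered `counts` and `metadata` plus `removed`,
#'   the ids of the dropped samples.
#' @export
filter_samples_by_depth <- function(counts, metadata, min_reads = 400000,
                                    on_missing_depth = c("error", "keep")) {
  on_missing_depth <- match.arg(on_missing_depth)
  samples <- names(counts)[-1]
  meta <- metadata[match(samples, metadata$sample_id), ]
  depth <- meta[["intron_spanning_reads"]]
  if (is.null(depth)) depth <- rep(NA_real_, length(samples))
  if (anyNA(depth)) {
    if (on_missing_depth == "error") {
      stop("missing intron_spanning_reads for sample(s): ",
           paste(samples[is.na(depth)], collapse = ", "))
    }
    warning("depth unknown for ", sum(is.na(depth)),
            " sample(s); passing them through")
  }
  drop <- !is.na(depth) & depth < min_reads
  keep <- samples[!drop]
  out_meta <- metadata[metadata$sample_id %in% keep, ]
  if (length(unique(out_meta$group)) < 2) {
    stop("depth filter left fewer than two sample groups")
  }
  list(counts = counts[, c("gene_id", keep)],
       metadata = out_meta,
       removed = samples[drop])
}

#' Remove genes with too many zero counts
#'
#' Drops genes whose fraction of zero counts across the retained samples
#' is strictly greater than `max_zero_frac` (a gene at exactly the
#' threshold is retained).
#'
#' @inheritParams filter_samples_by_depth
#' @param max_zero_frac Maximum tolerated zero fraction; default 0.70.
#' @return A list with filtered `counts`, the `removed` gene ids, and
#'   `report`, a one-row attrition tibble.
#' @export
filter_genes_by_zero_fraction <- function(counts, max_zero_frac = 0.70) {
  m <- as.matrix(counts[-1])
  zero_frac <- rowMeans(m == 0)
  drop <- zero_frac > max_zero_frac
  list(counts = counts[!drop, ],
       removed = counts$gene_id[drop],
       report = tibble::tibble(stage = "zero_fraction_filter",
                               n_in = nrow(counts),
                               n_out = sum(!drop),
                               n_removed = sum(drop)))
}

#' Per-gene expression summaries for the normal and tumor classes
#'
#' Computes, for every gene, the mean, sample standard deviation
#' (n - 1 denominator) and coefficient of variation (CV = SD / mean) of
#' expression in the normal class and in the pooled tumor class (every
#' group label other than `normal_label`). The CV is undefined, and
#' flagged as such, when the class mean is not strictly positive.
#'
#' @param expr Expression tibble (first column `gene_id`), typically
#'   log2CPM from [log2cpm()].
#' @param metadata Sample metadata tibble (`sample_id`, `group`).
#' @param normal_label Group label identifying the normal/healthy class;
#'   all other labels are pooled as tumor.
#' @return A tibble with columns `gene_id`, `class` (`"normal"` or
#'   `"tumor"`), `mean`, `sd`, `cv`, `cv_defined`.
#' @examples
#' expr <- tibble::tibble(gene_id = "g", a = 20, b = 21, c = 22, d = 23)
#' md <- tibble::tibble(sample_id = letters[1:4],
#'                      group = c("normal", "normal", "NSCLC", "CRC"))
#' # normal-class SD uses the n - 1 denominator
#' group_stats(expr, md)
#' @export
group_stats <- function(expr, metadata, normal_label = "normal") {
  samples <- names(expr)[-1]
  meta <- metadata[match(samples, metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("samples missing from metadata: ",
         paste(samples[is.na(meta$sample_id)], collapse = ", "))
  }
  cls <- ifelse(meta$group == normal_label, "normal", "tumor")
  for (k in c("normal", "tumor")) {
    if (sum(cls == k) < 2) {
      stop("class '", k, "' has fewer than 2 samples")
    }
  }
  m <- as.matrix(expr[-1])
  per_class <- function(k) {
    sub <- m[, cls == k, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1, sd)
    tibble::tibble(gene_id = expr$gene_id, class = k, mean = mu, sd = s,
                   cv = ifelse(mu > 0, s / mu, NA_real_),
                   cv_defined = mu > 0)
  }
  dplyr::arrange(dplyr::bind_rows(per_class("normal"), per_class("tumor")),
                 .data$gene_id, .data$class)
}

#' Three-way stability criteria filter
#'
#' Evaluates the three shortlisting criteria on one common gene universe
#' (the post-zero-filter genes the statistics were computed on) and keeps
#' the genes passing all three:
#'
#' 1. balanced means: `mean(normal)/mean(tumor) < fold_max` and
#'    `mean(tumor)/mean(normal) < fold_max` (both means must be > 0);
#' 2. high expression: rank by mean (rank 1 = largest) at most
#'    `ceiling(top_frac * G)` in the normal class *and* in the tumor
#'    class, ties at the boundary all kept;
#' 3. low dispersion: CV `< cv_max` in both classes (an undefined CV
#'    fails).
#'
#' @param stats Output of [group_stats()].
#' @param fold_max Upper bound (exclusive) on the two mean ratios;
#'   default 1.2.
#' @param top_frac Fraction of the universe kept by the expression-rank
#'   criterion; default 0.10.
#' @param cv_max Upper bound (exclusive) on the class CVs; default 0.10.
#' @return A tibble with one row per gene: `gene_id`, logical columns
#'   `pass_fold`, `pass_top`, `pass_cv`, and `pass` (their conjunction).
#' @export
stability_criteria_filter <- function(stats, fold_max = 1.2,
                                      top_frac = 0.10, cv_max = 0.10) {
  wide <- tidyr::pivot_wider(stats, id_cols = "gene_id",
                             names_from = "class",
                             values_from = c("mean", "cv"))
  g_univ <- nrow(wide)
  cutoff <- ceiling(top_frac * g_univ)
  # rank 1 = largest mean; ties.method = "min" keeps all genes tied at
  # the boundary
  rank_n <- rank(-wide$mean_normal, ties.method = "min")
  rank_t <- rank(-wide$mean_tumor, ties.method = "min")
  pos <- wide$mean_normal > 0 & wide$mean_tumor > 0
  ratio_ok <- pos &
    wide$mean_normal / wide$mean_tumor < fold_max &
    wide$mean_tumor / wide$mean_normal < fold_max
  cv_ok <- !is.na(wide$cv_normal) & !is.na(wide$cv_tumor) &
    wide$cv_normal < cv_max & wide$cv_tumor < cv_max
  tibble::tibble(gene_id = wide$gene_id,
                 pass_fold = ratio_ok,
                 pass_top = rank_n <= cutoff & rank_t <= cutoff,
                 pass_cv = cv_ok,
                 pass = ratio_ok & rank_n <= cutoff & rank_t <= cutoff &
                   cv_ok)
}

#' Refinement filter on mean and CV
#'
#' Applied to the survivors of [stability_criteria_filter()]: keeps genes
#' with class mean strictly above `mean_min` and CV strictly below
#' `cv_max_refine` in both the normal and the tumor class. The default
#' `cv_max_refine = 0.01` reads the refinement CV bound as 1 percent;
#' set it to 1 for the absolute-value reading.
#'
#' @inheritParams stability_criteria_filter
#' @param mean_min Lower bound (exclusive) on the class means; default 1.
#' @param cv_max_refine Upper bound (exclusive) on the class CVs;
#'   default 0.01.
#' @return A tibble with `gene_id`, `pass_mean`, `pass_cv`, `pass`.
#' @export
refine_filter <- function(stats, mean_min = 1.0, cv_max_refine = 0.01) {
  wide <- tidyr::pivot_wider(stats, id_cols = "gene_id",
                             names_from = "class",
                             values_from = c("mean", "cv"))
  mean_ok <- wide$mean_normal > mean_min & wide$mean_tumor > mean_min
  cv_ok <- !is.na(wide$cv_normal) & !is.na(wide$cv_tumor) &
    wide$cv_normal < cv_max_refine & wide$cv_tumor < cv_max_refine
  tibble::tibble(gene_id = wide$gene_id, pass_mean = mean_ok,
                 pass_cv = cv_ok, pass = mean_ok & cv_ok)
}

#' Normalize gene identifiers for list intersection
#'
#' Strips surrounding whitespace, upper-cases symbols, and removes the
#' version suffix from Ensembl gene ids (`ENSG00000111640.14` becomes
#' `ENSG00000111640`), so that lists curated from heterogeneous sources
#' can be intersected reliably.
#'
#' @param ids Character vector of gene identifiers.
#' @return Normalized character vector of the same length.
#' @export
normalize_gene_ids <- function(ids) {
  ids <- toupper(trimws(ids))
  sub("^(ENSG[0-9]+)\\.[0-9]+$", "\\1", ids)
}

#' Intersect candidates with a known-reference-gene list
#'
#' Keeps the candidate genes whose normalized identifier occurs in the
#' known list, preserving candidate order. An empty intersection yields
#' an empty tibble with a warning (not an error).
#'
#' @param candidates Tibble with a `gene_id` column (or a character
#'   vector of gene ids).
#' @param known Character vector of known reference-gene identifiers.
#' @param known_list_name Optional label recorded in the result's
#'   provenance attribute.
#' @return A tibble with the surviving `gene_id` rows; attribute
#'   `provenance` records the list name and its deduplicated size.
#' @export
intersect_known <- function(candidates, known, known_list_name = "known") {
  if (is.character(candidates)) {
    candidates <- tibble::tibble(gene_id = candidates)
  }
  if (length(known) == 0) stop("known reference-gene list is empty")
  known_norm <- unique(normalize_gene_ids(known))
  hit <- normalize_gene_ids(candidates$gene_id) %in% known_norm
  if (!any(hit)) {
    warning("no candidate gene found in known list '", known_list_name, "'")
  }
  out <- candidates[hit, , drop = FALSE]
  attr(out, "provenance") <- list(known_list_name = known_list_name,
                                  known_list_size = length(known_norm))
  out
}

#' Read a known-reference-gene list file
#'
#' Plain-text list, one identifier per line; `#` starts a comment and
#' blank lines are ignored.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_known_genes <- function(path) {
  if (!file.exists(path)) stop("known-gene list file not found: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines[nzchar(lines)]
}

#' Run the full reference-gene shortlisting cascade
#'
#' Executes, in order: sample-depth filter, zero-count filter, log2CPM
#' transformation, per-class statistics, the three-way stability criteria
#' filter, the mean/CV refinement filter, and (when a known list is
#' supplied) the known-reference intersection. Attrition is recorded at
#' every stage.
#'
#' @inheritParams filter_samples_by_depth
#' @inheritParams stability_criteria_filter
#' @inheritParams refine_filter
#' @inheritParams filter_genes_by_zero_fraction
#' @inheritParams log2cpm
#' @inheritParams group_stats
#' @param known Character vector of known reference-gene ids, or `NULL`
#'   to stop before the intersection.
#' @param known_list_name Label for the known list in the report.
#' @param apply_depth_filter Set `FALSE` to skip the sample-depth stage
#'   (for matrices without depth metadata).
#' @return An object of class `shortlist_result`: a list with
#'   `candidates` (tibble of final gene ids), `pre_intersection`
#'   (gene ids surviving the cascade before the known-list step),
#'   `report` (per-stage attrition tibble), `gene_flags` (per-gene
#'   pass/fail flags for each named filter), `stats` (the class
#'   statistics) and `params`.
#' @seealso [tidy.shortlist_result()], [glance.shortlist_result()],
#'   [autoplot.shortlist_result()]
#' @export
run_shortlist <- function(counts, metadata, known = NULL,
                          min_reads = 400000, max_zero_frac = 0.70,
                          fold_max = 1.2, top_frac = 0.10, cv_max = 0.10,
                          mean_min = 1.0, cv_max_refine = 0.01,
                          prior = 1, normal_label = "normal",
                          known_list_name = "known",
                          apply_depth_filter = TRUE,
                          on_missing_depth = "error") {
  validate_counts(counts, metadata)
  if (!is.null(known) && length(known) == 0) {
    stop("known reference-gene list is empty")
  }
  report <- list()
  n_samples_in <- ncol(counts) - 1L

  if (apply_depth_filter) {
    sf <- filter_samples_by_depth(counts, metadata, min_reads,
                                  on_missing_depth)
    counts <- sf$counts
    metadata <- sf$metadata
    report$depth <- tibble::tibble(stage = "sample_depth_filter",
                                   n_in = n_samples_in,
                                   n_out = ncol(counts) - 1L,
                                   n_removed = length(sf$removed),
                                   unit = "samples")
  }

  zf <- filter_genes_by_zero_fraction(counts, max_zero_frac)
  counts <- zf$counts
  report$zero <- dplyr::mutate(zf$report, unit = "genes")

  expr <- log2cpm(counts, prior)
  stats <- group_stats(expr, metadata, normal_label)

  crit <- stability_criteria_filter(stats, fold_max, top_frac, cv_max)
  survivors1 <- crit$gene_id[crit$pass]
  report$criteria <- tibble::tibble(stage = "stability_criteria_filter",
                                    n_in = nrow(crit),
                                    n_out = length(survivors1),
                                    n_removed = nrow(crit) -
                                      length(survivors1),
                                    unit = "genes")

  ref <- refine_filter(stats[stats$gene_id %in% survivors1, ],
                       mean_min, cv_max_refine)
  survivors2 <- ref$gene_id[ref$pass]
  report$refine <- tibble::tibble(stage = "refine_filter",
                                  n_in = length(survivors1),
                                  n_out = length(survivors2),
                                  n_removed = length(survivors1) -
                                    length(survivors2),
                                  unit = "genes")

  gene_flags <- dplyr::left_join(
    dplyr::rename(crit, pass_criteria = "pass"),
    dplyr::rename(ref, pass_refine_mean = "pass_mean",
                  pass_refine_cv = "pass_cv", pass_refine = "pass"),
    by = "gene_id")

  pre_intersection <- tibble::tibble(gene_id = survivors2)
  if (!is.null(known)) {
    candidates <- intersect_known(pre_intersection, known, known_list_name)
    report$known <- tibble::tibble(stage = "known_list_intersection",
                                   n_in = nrow(pre_intersection),
                                   n_out = nrow(candidates),
                                   n_removed = nrow(pre_intersection) -
                                     nrow(candidates),
                                   unit = "genes")
  } else {
    candidates <- pre_intersection
  }

  structure(list(candidates = candidates,
                 pre_intersection = pre_intersection,
                 report = dplyr::bind_rows(report),
                 gene_flags = gene_flags,
                 stats = stats,
                 params = list(min_reads = min_reads,
                               max_zero_frac = max_zero_frac,
                               fold_max = fold_max, top_frac = top_frac,
                               cv_max = cv_max, mean_min = mean_min,
                               cv_max_refine = cv_max_refine,
                               prior = prior,
                               normal_label = normal_label)),
            class = "shortlist_result")
}

#' @export
print.shortlist_result <- function(x, ...) {
  cat("Reference-gene shortlist\n")
  cat("Stage attrition:\n")
  print(as.data.frame(x$report), row.names = FALSE)
  cat("Candidates (", nrow(x$candidates), "): ",
      paste(head(x$candidates$gene_id, 20), collapse = ", "),
      if (nrow(x$candidates) > 20) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tidy a shortlist result into per-gene filter flags
#'
#' @param x A `shortlist_result`.
#' @param ... Unused.
#' @return A tibble with one row per gene in the post-zero-filter
#'   universe and one logical column per filter.
#' @export
tidy.shortlist_result <- function(x, ...) x$gene_flags

#' One-row summary of a shortlist run
#'
#' @param x A `shortlist_result`.
#' @param ... Unused.
#' @return A tibble with the candidate counts at the key stages.
#' @export
glance.shortlist_result <- function(x, ...) {
  genes <- x$report[x$report$unit == "genes", ]
  tibble::tibble(n_genes_post_zero_filter = genes$n_out[
                   genes$stage == "zero_fraction_filter"],
                 n_candidates_criteria = genes$n_out[
                   genes$stage == "stability_criteria_filter"],
                 n_candidates_refined = genes$n_out[
                   genes$stage == "refine_filter"],
                 n_candidates_final = nrow(x$candidates))
}

#' Attrition plot for a shortlist run
#'
#' Bar chart of the number of genes surviving each stage of the cascade.
#'
#' @param object A `shortlist_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shortlist_result <- function(object, ...) {
  rep <- object$report[object$report$unit == "genes", ]
  rep$stage <- factor(rep$stage, levels = rep$stage)
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "genes surviving",
                  title = "Shortlist attrition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20,
                                                       hjust = 1))
}
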