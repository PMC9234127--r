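#' Log2 relative quantities from a collapsed Ct panel
#'
#' Converts cycle-threshold values to log2-scale relative quantities,
#' calibrated per gene to its lowest observed Ct:
#' `a(g, s) = (min Ct(g) - Ct(g, s)) * log2(E)`. With perfect doubling
#' (`efficiency = 2`) this is simply `min Ct - Ct`. The per-gene
#' calibration is a constant shift and therefore affects no pairwise
#' difference or standard deviation downstream.
#'
#' @param panel Collapsed long Ct tibble (`gene`, `sample_id`, `group`,
#'   `ct`), one value per gene and sample (see [collapse_replicates()]).
#' @param efficiency PCR amplification efficiency E; default 2 (perfect
#'   doubling per cycle).
#' @param min_samples Minimum non-missing samples a gene needs; genes
#'   below it are dropped with a warning, all-missing genes likewise.
#' @return A gene x sample numeric matrix of log2 relative quantities
#'   (`NA` where Ct was missing).
#' @export
prepare_log_quantities <- function(panel, efficiency = 2,
                                   min_samples = 3) {
  stopifnot(efficiency > 1)
  m <- ct_matrix(panel)
  n_ok <- rowSums(!is.na(m))
  if (any(n_ok < min_samples)) {
    warning("dropping gene(s) with fewer than ", min_samples,
            " usable samples: ",
            paste(rownames(m)[n_ok < min_samples], collapse = ", "))
    m <- m[n_ok >= min_samples, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no gene has enough usable samples")
  cal <- apply(m, 1, min, na.rm = TRUE)
  (cal - m) * log2(efficiency)
}

# Drop samples with any missing value among the retained genes
# (complete-case policy shared by geNorm, NormFinder and BestKeeper).
complete_case_matrix <- function(m) {
  keep <- colSums(is.na(m)) == 0
  if (sum(keep) < 3) stop("fewer than 3 complete-case samples")
  m[, keep, drop = FALSE]
}

#' Comparative delta-Ct stability
#'
#' For each candidate gene, the stability value is the mean over all
#' other genes of the sample standard deviation (n - 1 denominator) of
#' the per-sample Ct differences: `S(i) = mean_k sd_s(Ct_i - Ct_k)`,
#' computed on pairwise-complete samples. Lower values indicate more
#' stable expression; ranks are ascending with average ranks on ties.
#'
#' @inheritParams prepare_log_quantities
#' @param on_incomplete_pair Policy when a gene pair has fewer than 3
#'   samples with both values present: `"error"` (default, naming the
#'   pair) or `"drop"` (omit that pair from both genes' means).
#' @return A tibble `gene`, `stability`, `rank` (class
#'   `"delta_ct_stability"` prepended).
#' @examples
#' panel <- tidyr::crossing(gene = c("A", "B", "C"),
#'                          sample_id = paste0("s", 1:4)) |>
#'   dplyr::mutate(group = "g",
#'                 ct = c(20, 21, 22, 23, 20, 21, 22, 23, 20, 22, 21, 25))
#' delta_ct_stability(panel)  # S(A) = S(B) ~ 0.6455, S(C) ~ 1.2910
#' @export
delta_ct_stability <- function(panel,
                               on_incomplete_pair = c("error", "drop")) {
  on_incomplete_pair <- match.arg(on_incomplete_pair)
  m <- ct_matrix(panel)
  genes <- rownames(m)
  k <- length(genes)
  if (k < 3) stop("comparative delta-Ct requires at least 3 genes")
  pair_sd <- matrix(NA_real_, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- m[i, ] - m[j, ]
      d <- d[!is.na(d)]
      if (length(d) < 3) {
        if (on_incomplete_pair == "error") {
          stop(sprintf(
            "gene pair (%s, %s) has fewer than 3 complete samples",
            genes[i], genes[j]))
        }
      } else {
        pair_sd[i, j] <- pair_sd[j, i] <- sd(d)
      }
    }
  }
  s <- vapply(seq_len(k),
              function(i) mean(pair_sd[i, -i], na.rm = TRUE), 0)
  if (anyNA(s)) {
    stop("gene(s) with no valid pair: ",
         paste(genes[is.na(s)], collapse = ", "))
  }
  out <- tibble::tibble(gene = genes, stability = s,
                        rank = rank(s, ties.method = "average"))
  class(out) <- c("delta_ct_stability", class(out))
  out
}

#' geNorm stability analysis
#'
#' Implements the geNorm algorithm on log2 relative quantities. The
#' pairwise variation of genes i and k is
#' `V(i, k) = sd_s(a_i - a_k)`; the stability of gene i is
#' `M(i) = mean_k V(i, k)`. The gene with the largest M is removed and M
#' recomputed, iterating until two genes remain (the most stable pair,
#' which cannot be resolved further and shares average rank 1.5). The
#' pairwise-variation series `V(n/n+1)` is the standard deviation across
#' samples of the log2 ratio of normalization factors built from the top
#' n versus top n+1 ranked genes, where the normalization factor
#' `NF_n(s)` is the geometric mean of the relative quantities of those n
#' genes in sample s.
#'
#' Samples missing any retained gene are dropped (complete-case policy).
#' Ties in M during elimination are broken by removing the
#' lexicographically last gene id, making runs deterministic.
#'
#' @inheritParams prepare_log_quantities
#' @return An object of class `genorm`: list with `ranks` (tibble
#'   `gene`, `M`, `rank`, where `M` is the gene's stability when it was
#'   removed, or the final-pair M), `trace` (per-step tibble of M values
#'   and the gene removed), `final_pair`, `v_series` (tibble `n`, `v`
#'   with k - 2 rows) and `nf` (sample x n matrix of normalization
#'   factors).
#' @export
genorm <- function(panel, efficiency = 2) {
  a <- complete_case_matrix(prepare_log_quantities(panel, efficiency))
  genes <- rownames(a)
  k <- length(genes)
  if (k < 3) stop("geNorm requires at least three genes")

  m_of <- function(mat) {
    g <- rownames(mat)
    vapply(seq_along(g), function(i) {
      mean(vapply(seq_along(g)[-i],
                  function(j) sd(mat[i, ] - mat[j, ]), 0))
    }, 0, USE.NAMES = FALSE)
  }

  remaining <- a
  trace <- list()
  removed <- character()
  removed_m <- numeric()
  step <- 0L
  while (nrow(remaining) > 2) {
    step <- step + 1L
    m_vals <- m_of(remaining)
    g <- rownames(remaining)
    # argmax M; on ties remove the lexicographically last gene id
    worst_m <- max(m_vals)
    worst <- max(g[m_vals == worst_m])
    trace[[step]] <- tibble::tibble(step = step, gene = g, M = m_vals,
                                    removed = g == worst)
    removed <- c(removed, worst)
    removed_m <- c(removed_m, worst_m)
    remaining <- remaining[rownames(remaining) != worst, , drop = FALSE]
  }
  final_pair <- sort(rownames(remaining))
  final_m <- m_of(remaining)  # both equal sd(a_i - a_k)
  trace[[step + 1L]] <- tibble::tibble(step = step + 1L,
                                       gene = rownames(remaining),
                                       M = final_m, removed = FALSE)

  rank_order <- c(final_pair, rev(removed))
  ranks <- tibble::tibble(
    gene = rank_order,
    M = c(final_m[match(final_pair, rownames(remaining))],
          rev(removed_m)),
    rank = c(1.5, 1.5, seq(3, k)))
  ranks <- ranks[match(genes, ranks$gene), ]

  # normalization factors from the top-n genes, n = 2 .. k
  nf_log2 <- vapply(2:k, function(n) {
    colMeans(a[rank_order[seq_len(n)], , drop = FALSE])
  }, numeric(ncol(a)))
  colnames(nf_log2) <- paste0("NF", 2:k)
  v_series <- tibble::tibble(
    n = seq(2, k - 1),
    v = vapply(seq(2, k - 1),
               function(n) sd(nf_log2[, n - 1] - nf_log2[, n]), 0))

  structure(list(ranks = ranks,
                 trace = dplyr::bind_rows(trace),
                 final_pair = final_pair,
                 v_series = v_series,
                 nf = 2^nf_log2,
                 efficiency = efficiency),
            class = "genorm")
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNorm stability ranking\n")
  print(as.data.frame(dplyr::arrange(x$ranks, .data$rank)),
        row.names = FALSE)
  cat("most stable pair:", paste(x$final_pair, collapse = " / "), "\n")
  invisible(x)
}

#' @export
tidy.genorm <- function(x, ...) x$ranks

#' @export
glance.genorm <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$ranks),
                 final_pair = paste(x$final_pair, collapse = "/"),
                 v_2_3 = x$v_series$v[x$v_series$n == 2])
}

#' Stepwise M plot for a geNorm analysis
#'
#' Average expression stability M of the genes remaining at each
#' elimination step (the classic geNorm ranking chart).
#'
#' @param object A `genorm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genorm <- function(object, ...) {
  avg <- dplyr::summarise(dplyr::group_by(object$trace, .data$step),
                          mean_M = mean(.data$M), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$step, y = .data$mean_M)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "elimination step",
                  y = "average expression stability M",
                  title = "geNorm stepwise exclusion") +
    ggplot2::theme_minimal()
}

#' NormFinder-style stability value
#'
#' Model-based stability estimate separating intra-group variability
#' from inter-group bias, computed on sample-centered log2 relative
#' quantities `x(g, s) = a(g, s) - mean_g a(., s)`:
#' per group, the gene's mean `m(g, grp)` and sample variance
#' `v(g, grp)`; the inter-group deviation `d = m(g, grp) - m(g)` (m(g)
#' the size-weighted overall mean) is shrunk by its sampling variance,
#' `d2 = max(d^2 - v/n, 0)`; the stability value is the size-weighted
#' sum `rho(g) = sum_grp (n_grp/N) (sqrt(d2) + sqrt(v/n_grp))`. Lower is
#' more stable. With a single group the value falls back to the
#' intra-group standard deviation of the centered quantities.
#'
#' @inheritParams prepare_log_quantities
#' @return A tibble `gene`, `stability`, `rank` (class
#'   `"normfinder"` prepended).
#' @export
normfinder <- function(panel, efficiency = 2) {
  a <- complete_case_matrix(prepare_log_quantities(panel, efficiency))
  if (nrow(a) < 3) stop("NormFinder requires at least 3 genes")
  grp <- panel_groups(panel, colnames(a))
  x <- sweep(a, 2, colMeans(a))  # sample-center
  groups <- unique(grp)
  n_g <- table(grp)[groups]
  if (length(groups) >= 2 && any(n_g < 2)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(n_g)[n_g < 2], collapse = ", "))
  }
  genes <- rownames(x)
  if (length(groups) == 1) {
    rho <- apply(x, 1, sd)
  } else {
    n_total <- ncol(x)
    rho <- vapply(genes, function(g) {
      m_gg <- vapply(groups, function(gg) mean(x[g, grp == gg]), 0)
      v_gg <- vapply(groups, function(gg) var(x[g, grp == gg]), 0)
      w <- as.numeric(n_g) / n_total
      m_overall <- sum(w * m_gg)
      d <- m_gg - m_overall
      d2 <- pmax(d^2 - v_gg / as.numeric(n_g), 0)
      sum(w * (sqrt(d2) + sqrt(v_gg / as.numeric(n_g))))
    }, 0)
  }
  out <- tibble::tibble(gene = genes, stability = unname(rho),
                        rank = unname(rank(rho, ties.method = "average")))
  class(out) <- c("normfinder", class(out))
  out
}

#' BestKeeper descriptive stability analysis
#'
#' Works on the raw Ct scale. Per gene it reports n, the geometric and
#' arithmetic mean, min, max, `sd` — by default the mean absolute
#' deviation around the arithmetic Ct mean, the convention of the
#' original tool's descriptive table (`sd_method = "sd"` switches to the
#' classical n - 1 standard deviation) — and `cv_pct = 100 * sd / mean`.
#' Genes with `sd` above `sd_flag_cutoff` are flagged inconsistent. The
#' BestKeeper index is the per-sample geometric mean of the candidate
#' Ct values (complete cases); each gene's Pearson correlation r with
#' the index, and its two-sided p-value, are reported. For rank
#' aggregation genes are ordered by ascending `sd`.
#'
#' @inheritParams prepare_log_quantities
#' @param sd_flag_cutoff Dispersion above which a gene is flagged
#'   inconsistent; default 1 cycle.
#' @param sd_method `"mad"` (mean absolute deviation, default) or
#'   `"sd"` (classical n - 1 standard deviation).
#' @return An object of class `bestkeeper`: list with `descriptors`
#'   (per-gene tibble: `gene`, `n`, `geo_mean`, `ar_mean`, `min`, `max`,
#'   `sd`, `cv_pct`, `inconsistent`, `r`, `r_p_value`, `rank`) and
#'   `index` (per-sample tibble of the BestKeeper index).
#' @export
bestkeeper <- function(panel, sd_flag_cutoff = 1.0,
                       sd_method = c("mad", "sd")) {
  sd_method <- match.arg(sd_method)
  m <- ct_matrix(panel)
  if (nrow(m) < 2) stop("BestKeeper requires at least 2 genes")
  if (any(m <= 0, na.rm = TRUE)) {
    stop("BestKeeper needs strictly positive Ct values")
  }
  desc <- dplyr::bind_rows(lapply(rownames(m), function(g) {
    x <- m[g, ][!is.na(m[g, ])]
    am <- mean(x)
    disp <- if (sd_method == "mad") mean(abs(x - am)) else sd(x)
    tibble::tibble(gene = g, n = length(x), geo_mean = geomean(x),
                   ar_mean = am, min = min(x), max = max(x), sd = disp,
                   cv_pct = 100 * disp / am)
  }))
  desc$inconsistent <- desc$sd > sd_flag_cutoff

  cc <- complete_case_matrix(m)
  bki <- apply(cc, 2, geomean)
  cors <- lapply(rownames(cc), function(g) {
    x <- cc[g, ]
    if (sd(x) == 0 || sd(bki) == 0) {
      tibble::tibble(gene = g, r = NA_real_, r_p_value = NA_real_)
    } else {
      ct <- cor.test(x, bki)
      tibble::tibble(gene = g, r = unname(ct$estimate),
                     r_p_value = ct$p.value)
    }
  })
  desc <- dplyr::left_join(desc, dplyr::bind_rows(cors), by = "gene")
  desc$rank <- rank(desc$sd, ties.method = "average")

  structure(list(descriptors = desc,
                 index = tibble::tibble(sample_id = colnames(cc),
                                        bki = unname(bki)),
                 sd_method = sd_method),
            class = "bestkeeper")
}

#' @export
print.bestkeeper <- function(x, ...) {
  cat("BestKeeper descriptive analysis (dispersion: ",
      if (x$sd_method == "mad") "mean absolute deviation" else "SD",
      ")\n", sep = "")
  print(as.data.frame(dplyr::arrange(x$descriptors, .data$rank)),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.bestkeeper <- function(x, ...) x$descriptors

#' Aggregate per-method rankings into a comprehensive ranking
#'
#' Combines the rank vectors of several stability methods by taking,
#' per gene, the geometric mean of its ranks; genes are then ordered by
#' ascending aggregate score (ties broken alphabetically by gene id).
#' This is the geometric-mean-of-ranks scheme behind "recommended
#' comprehensive ranking" tables.
#'
#' @param method_ranks A tibble with a `gene` column and one numeric
#'   column of ranks per method (tied ranks such as a geNorm final pair
#'   at 1.5 are allowed).
#' @return A tibble with the input rank columns plus `aggregate_score`
#'   and `comprehensive_rank`, ordered by the comprehensive rank.
#' @examples
#' aggregate_ranks(tibble::tibble(
#'   gene = c("GAPDH", "B2M", "ACTB"),
#'   delta_ct = c(1, 2, 3), bestkeeper = c(1, 3, 2),
#'   normfinder = c(1, 2, 3), genorm = c(1.5, 1.5, 3)))
#' @export
aggregate_ranks <- function(method_ranks) {
  stopifnot(is.data.frame(method_ranks), "gene" %in% names(method_ranks))
  methods <- setdiff(names(method_ranks), "gene")
  if (length(methods) < 2) {
    stop("rank aggregation needs at least 2 methods")
  }
  rk <- as.matrix(method_ranks[methods])
  if (anyNA(rk)) {
    bad <- method_ranks$gene[rowSums(is.na(rk)) > 0]
    stop("gene(s) missing a rank in at least one method: ",
         paste(bad, collapse = ", "))
  }
  score <- apply(rk, 1, geomean)
  out <- method_ranks
  out$aggregate_score <- score
  out <- out[order(score, out$gene), ]
  out$comprehensive_rank <- seq_len(nrow(out))
  tibble::as_tibble(out)
}

#' Full expression-stability analysis of a Ct panel
#'
#' Runs the four stability algorithms (comparative delta-Ct, geNorm,
#' NormFinder, BestKeeper) on a collapsed Ct panel and aggregates their
#' ranks into the comprehensive ranking via [aggregate_ranks()].
#'
#' @inheritParams prepare_log_quantities
#' @inheritParams bestkeeper
#' @param drop_gene_first Drop genes missing in more than half the
#'   samples before the complete-case analyses (useful when one
#'   mostly-missing gene would otherwise discard most samples).
#' @return An object of class `ct_stability`: list with `table` (per
#'   gene: each method's stability value and rank, the aggregate score
#'   and the comprehensive rank), `genorm` (the full [genorm()] object),
#'   `bestkeeper` (the full [bestkeeper()] object) and `params`.
#' @examples
#' sim <- simulate_ct(seed = 42)
#' fit <- sim$panel |> apply_ct_inclusion() |> collapse_replicates() |>
#'   ct_stability()
#' fit$table
#' @export
ct_stability <- function(panel, efficiency = 2, sd_flag_cutoff = 1.0,
                         sd_method = "mad", drop_gene_first = FALSE) {
  if (anyDuplicated(panel[c("gene", "sample_id")])) {
    message("panel has replicate structure; collapsing replicates")
    panel <- collapse_replicates(panel)
  }
  if (drop_gene_first) {
    miss <- dplyr::summarise(dplyr::group_by(panel, .data$gene),
                             frac = mean(is.na(.data$ct)),
                             .groups = "drop")
    bad <- miss$gene[miss$frac > 0.5]
    if (length(bad) > 0) {
      warning("dropping mostly-missing gene(s): ",
              paste(bad, collapse = ", "))
      panel <- panel[!panel$gene %in% bad, ]
    }
  }
  dct <- delta_ct_stability(panel)
  gn <- genorm(panel, efficiency)
  nf <- normfinder(panel, efficiency)
  bk <- bestkeeper(panel, sd_flag_cutoff, sd_method)

  ranks <- tibble::tibble(gene = dct$gene, delta_ct = dct$rank)
  ranks$genorm <- gn$ranks$rank[match(ranks$gene, gn$ranks$gene)]
  ranks$normfinder <- nf$rank[match(ranks$gene, nf$gene)]
  ranks$bestkeeper <-
    bk$descriptors$rank[match(ranks$gene, bk$descriptors$gene)]
  agg <- aggregate_ranks(ranks)

  tab <- agg
  tab$delta_ct_value <- dct$stability[match(tab$gene, dct$gene)]
  tab$genorm_m <- gn$ranks$M[match(tab$gene, gn$ranks$gene)]
  tab$normfinder_value <- nf$stability[match(tab$gene, nf$gene)]
  tab$bestkeeper_sd <-
    bk$descriptors$sd[match(tab$gene, bk$descriptors$gene)]
  tab$bestkeeper_cv <-
    bk$descriptors$cv_pct[match(tab$gene, bk$descriptors$gene)]
  tab$bestkeeper_r <-
    bk$descriptors$r[match(tab$gene, bk$descriptors$gene)]

  structure(list(table = tab, genorm = gn, bestkeeper = bk,
                 params = list(efficiency = efficiency,
                               sd_flag_cutoff = sd_flag_cutoff,
                               sd_method = sd_method)),
            class = "ct_stability")
}

#' @export
print.ct_stability <- function(x, ...) {
  cat("Expression-stability ranking (lower rank = more stable)\n")
  cols <- c("gene", "delta_ct", "genorm", "normfinder", "bestkeeper",
            "aggregate_score", "comprehensive_rank")
  print(as.data.frame(x$table[cols]), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Long per-gene, per-method view of a stability analysis
#'
#' @param x A `ct_stability` object.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `method`, `value`, `rank`.
#' @export
tidy.ct_stability <- function(x, ...) {
  t <- x$table
  dplyr::bind_rows(
    tibble::tibble(gene = t$gene, method = "delta_ct",
                   value = t$delta_ct_value, rank = t$delta_ct),
    tibble::tibble(gene = t$gene, method = "genorm",
                   value = t$genorm_m, rank = t$genorm),
    tibble::tibble(gene = t$gene, method = "normfinder",
                   value = t$normfinder_value, rank = t$normfinder),
    tibble::tibble(gene = t$gene, method = "bestkeeper",
                   value = t$bestkeeper_sd, rank = t$bestkeeper),
    tibble::tibble(gene = t$gene, method = "comprehensive",
                   value = t$aggregate_score,
                   rank = as.numeric(t$comprehensive_rank)))
}

#' One-row summary of a stability analysis
#'
#' @param x A `ct_stability` object.
#' @param ... Unused.
#' @return A tibble with the gene count and the top-ranked gene.
#' @export
glance.ct_stability <- function(x, ...) {
  best <- x$table$gene[x$table$comprehensive_rank == 1]
  tibble::tibble(n_genes = nrow(x$table),
                 most_stable = best,
                 genorm_pair = paste(x$genorm$final_pair,
                                     collapse = "/"))
}

#' Stability-value chart for a stability analysis
#'
#' Per-method bar charts of stability values, genes ordered by the
#' comprehensive ranking (most stable first).
#'
#' @param object A `ct_stability` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_stability <- function(object, ...) {
  long <- tidy(object)
  long <- long[long$method != "comprehensive", ]
  ord <- object$table$gene[order(object$table$comprehensive_rank)]
  long$gene <- factor(long$gene, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "stability value (lower = more stable)",
                  title = "Candidate reference-gene stability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
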