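#' Simulate an RNA-seq count matrix with planted reference genes
#'
#' Draws a gene x sample matrix of negative-binomial counts with
#' log-normal library sizes, planting four gene roles with known ground
#' truth:
#'
#' * `housekeeping` — top-decile expression, identical mean in both
#'   classes, near-Poisson dispersion (so the empirical log2CPM CV is
#'   far below any filtering threshold);
#' * `shifted` — low dispersion but a between-class ratio of mean
#'   log2CPM of `fold_ratio`, placed beyond the balanced-means
#'   criterion;
#' * `noisy` — identical class means but dispersion inflating the class
#'   CV well beyond the 10% criterion;
#' * `low` — zero-heavy genes (mean count `low_mean_count`), removed by
#'   the zero-fraction filter.
#'
#' Counts per million are a closed composition (they always sum to 1e6
#' within a sample), so per-gene expression is specified in relative
#' log2-abundance space and the realized log2CPM levels — relative
#' abundance plus the per-class compositional offset — are computed
#' analytically and reported in the returned `truth` table. Shifted
#' genes receive a log2 fold change sized on that realized scale so the
#' realized ratio of class mean log2CPM equals `fold_ratio` (up to the
#' small tumor-class compositional offset, also accounted for in
#' `truth`); the shift direction is upward for low-abundance genes and
#' downward for high-abundance ones, so shifted genes never invade the
#' housekeeping expression band in either class. The generator is fully
#' determined by `seed`.
#'
#' @param n_genes Total genes; default 500.
#' @param n_normal,n_tumor Samples per class; default 50 each.
#' @param frac_housekeeping,frac_shifted,frac_noisy,frac_low Role
#'   fractions; must sum to 1. Defaults 0.02 / 0.34 / 0.34 / 0.30.
#' @param mean_log2cpm_range Range of relative log2 abundance for
#'   shifted and noisy genes; default `c(2, 10)`.
#' @param hk_log2cpm_range Range of relative log2 abundance for
#'   housekeeping genes (kept above `mean_log2cpm_range` so they occupy
#'   the top decile); default `c(11.2, 12)`.
#' @param fold_ratio Planted ratio of class mean log2CPM for shifted
#'   genes; default 1.3 (beyond the 1.2 criterion).
#' @param dispersion_by_role Named vector of negative-binomial size
#'   parameters per role (larger = less dispersed).
#' @param low_mean_count Mean count of the zero-heavy genes; default 0.1.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size
#'   parameters; defaults `log(1e6)` and 0.2.
#' @param prior Pseudo-count convention the reported truth means refer
#'   to; default 1 (matching [log2cpm()]).
#' @param seed Integer seed (mandatory; the generator is deterministic
#'   given it).
#' @return A list with `counts` (tibble, first column `gene_id`),
#'   `metadata` (tibble `sample_id`, `group`, `intron_spanning_reads`),
#'   `truth` (per-gene tibble: `gene_id`, `role`, the analytically
#'   expected class mean log2CPM, dispersion) and `params`.
#' @export
simulate_counts <- function(n_genes = 500, n_normal = 50, n_tumor = 50,
                            frac_housekeeping = 0.02,
                            frac_shifted = 0.34, frac_noisy = 0.34,
                            frac_low = 0.30,
                            mean_log2cpm_range = c(2, 10),
                            hk_log2cpm_range = c(11.2, 12),
                            fold_ratio = 1.3,
                            dispersion_by_role = c(housekeeping = 1e8,
                                                   shifted = 1e8,
                                                   noisy = 1, low = 0.5),
                            low_mean_count = 0.1,
                            libsize_meanlog = log(1e6),
                            libsize_sdlog = 0.2,
                            prior = 1, seed) {
  if (missing(seed)) stop("a seed is required")
  fr <- c(frac_housekeeping, frac_shifted, frac_noisy, frac_low)
  stopifnot(all(fr >= 0), frac_housekeeping > 0, frac_housekeeping < 1,
            n_genes > 0, n_normal >= 2, n_tumor >= 2, fold_ratio > 1)
  if (abs(sum(fr) - 1) > 1e-8) stop("role fractions must sum to 1")
  if (hk_log2cpm_range[1] <= mean_log2cpm_range[2]) {
    stop("hk_log2cpm_range must lie above mean_log2cpm_range")
  }
  n_hk <- max(1L, round(frac_housekeeping * n_genes))
  n_sh <- round(frac_shifted * n_genes)
  n_no <- round(frac_noisy * n_genes)
  n_lo <- n_genes - n_hk - n_sh - n_no
  if (n_lo < 0) stop("role fractions leave no room for low genes")
  if (n_hk > floor(0.10 * (n_genes - n_lo))) {
    stop("frac_housekeeping too large to fit the top decile of the ",
         "post-zero-filter universe")
  }
  set.seed(seed)

  roles <- rep(c("housekeeping", "shifted", "noisy", "low"),
               c(n_hk, n_sh, n_no, n_lo))
  gene_id <- sprintf("GENE%04d", seq_len(n_genes))
  n_s <- n_normal + n_tumor
  sample_id <- sprintf("S%03d", seq_len(n_s))
  group <- rep(c("normal", "tumor"), c(n_normal, n_tumor))
  lib <- rlnorm(n_s, libsize_meanlog, libsize_sdlog)

  # relative log2 abundance (arbitrary scale; CPM normalization below
  # turns it into realized log2CPM via a common per-class offset)
  rel <- numeric(n_genes)
  rel[roles == "housekeeping"] <-
    seq(hk_log2cpm_range[1], hk_log2cpm_range[2], length.out = n_hk)
  rel[roles == "shifted"] <- runif(n_sh, mean_log2cpm_range[1],
                                   mean_log2cpm_range[2])
  rel[roles == "noisy"] <- runif(n_no, mean_log2cpm_range[1],
                                 mean_log2cpm_range[2])
  express <- roles != "low"

  w_norm <- ifelse(express, 2^rel, 0)
  offset_n <- log2(1e6 / sum(w_norm))
  realized_n <- ifelse(express, rel + offset_n, NA_real_)
  hk_floor <- min(realized_n[roles == "housekeeping"])

  # size the shift on the realized scale; shift upward only when the
  # shifted class mean stays clear of the housekeeping band
  is_sh <- roles == "shifted"
  up <- is_sh & (fold_ratio * realized_n <= hk_floor - 1)
  down <- is_sh & !up
  realized_t_target <- realized_n
  realized_t_target[up] <- realized_n[up] * fold_ratio
  realized_t_target[down] <- realized_n[down] / fold_ratio
  w_tum <- ifelse(express, 2^(realized_t_target - offset_n), 0)
  offset_t <- log2(1e6 / sum(w_tum))
  realized_t <- ifelse(express,
                       realized_t_target - offset_n + offset_t,
                       NA_real_)

  size <- unname(dispersion_by_role[roles])
  frac_n <- w_norm / sum(w_norm)
  frac_t <- w_tum / sum(w_tum)
  counts <- matrix(0L, n_genes, n_s,
                   dimnames = list(gene_id, sample_id))
  for (s in seq_len(n_s)) {
    frac <- if (group[s] == "normal") frac_n else frac_t
    mu <- frac * lib[s]
    mu[roles == "low"] <- low_mean_count
    counts[, s] <- rnbinom(n_genes, mu = mu, size = size)
  }

  truth <- tibble::tibble(
    gene_id = gene_id, role = roles,
    mean_log2cpm_normal = ifelse(express,
                                 log2(2^realized_n + prior), NA_real_),
    mean_log2cpm_tumor = ifelse(express,
                                log2(2^realized_t + prior), NA_real_),
    dispersion_size = size)
  list(counts = dplyr::bind_cols(tibble::tibble(gene_id = gene_id),
                                 tibble::as_tibble(counts)),
       metadata = tibble::tibble(sample_id = sample_id, group = group,
                                 intron_spanning_reads = round(lib)),
       truth = truth,
       params = list(seed = seed, n_genes = n_genes,
                     n_normal = n_normal, n_tumor = n_tumor,
                     fold_ratio = fold_ratio, prior = prior,
                     offset_normal = offset_n, offset_tumor = offset_t))
}

#' Default gene specification for the Ct-panel simulator
#'
#' Seven genes mirroring a small validation panel: one planted stable
#' gene (no group shift, 0.1-cycle noise), three genes with group shifts
#' of at least one cycle, and three genes with noise SD of at least 0.8
#' cycles.
#'
#' @param groups Character vector of group labels (default the five
#'   validation groups `HC`, `NSCLC`, `CRC`, `HBC`, `BrCa`).
#' @return A gene-specification tibble usable as the `gene_specs`
#'   argument of [simulate_ct()]: columns `gene`, `baseline_ct`,
#'   `noise_sd`, then one shift column per group.
#' @export
default_ct_gene_specs <- function(groups = c("HC", "NSCLC", "CRC",
                                             "HBC", "BrCa")) {
  k <- length(groups)
  pad <- function(x) rep_len(x, k)
  specs <- tibble::tibble(
    gene = c("STAB1", "SHIFT1", "SHIFT2", "SHIFT3",
             "NOISY1", "NOISY2", "NOISY3"),
    baseline_ct = c(22, 20, 24, 26, 21, 23, 25),
    noise_sd = c(0.1, 0.1, 0.1, 0.1, 0.8, 1.0, 1.2))
  shifts <- rbind(pad(0),
                  pad(c(0, 1, -1, 1.5, -1.5)),
                  pad(c(0, -1.2, 1.2, -1, 1)),
                  pad(c(0, 2, -1, 1, -2)),
                  pad(0), pad(0), pad(0))
  colnames(shifts) <- groups
  dplyr::bind_cols(specs, tibble::as_tibble(shifts))
}

#' Simulate a replicated Ct panel with planted stability structure
#'
#' Generates cycle-threshold values under the additive model the
#' delta-Ct family of methods assumes:
#' `Ct(g, s, rep) = baseline(g) + shift(g, group(s)) + b(s) + eps`,
#' with a per-sample loading effect `b(s) ~ N(0, sample_effect_sd^2)`
#' shared across genes (it cancels in every pairwise statistic) and
#' measurement noise `eps ~ N(0, noise_sd(g)^2)` independent per
#' replicate. Values go missing completely at random at `missing_rate`
#' (set `informative_dropout = TRUE` to make high-Ct measurements twice
#' as likely to drop out).
#'
#' @param gene_specs Gene-specification tibble (columns `gene`,
#'   `baseline_ct`, `noise_sd`, one shift column per group); default
#'   [default_ct_gene_specs()].
#' @param group_sizes Named integer vector of samples per group; default
#'   six per validation group.
#' @param n_replicates Replicates per (gene, sample); default 3.
#' @param sample_effect_sd SD (cycles) of the shared per-sample loading
#'   effect; default 0.5.
#' @param missing_rate Probability a measurement is missing; default 0.
#' @param informative_dropout Make dropout Ct-dependent (default off).
#' @param seed Integer seed (mandatory).
#' @return A list with `panel` (long tibble `gene`, `sample_id`,
#'   `group`, `replicate`, `ct`), `truth` (per-gene tibble with the
#'   shift spread, noise SD and the implied stability order) and
#'   `params`.
#' @export
simulate_ct <- function(gene_specs = default_ct_gene_specs(),
                        group_sizes = c(HC = 6, NSCLC = 6, CRC = 6,
                                        HBC = 6, BrCa = 6),
                        n_replicates = 3, sample_effect_sd = 0.5,
                        missing_rate = 0, informative_dropout = FALSE,
                        seed) {
  if (missing(seed)) stop("a seed is required")
  groups <- names(group_sizes)
  if (is.null(groups)) stop("group_sizes must be a named vector")
  stopifnot(all(group_sizes >= 2), n_replicates >= 1,
            missing_rate >= 0, missing_rate < 1)
  miss_cols <- setdiff(groups, names(gene_specs))
  if (length(miss_cols) > 0) {
    stop("gene_specs lacks shift column(s): ",
         paste(miss_cols, collapse = ", "))
  }
  if (any(gene_specs$baseline_ct < 10 | gene_specs$baseline_ct > 40)) {
    stop("baseline Ct outside the plausible 10-40 range")
  }
  set.seed(seed)

  sample_id <- sprintf("P%03d", seq_len(sum(group_sizes)))
  group <- rep(groups, group_sizes)
  b <- rnorm(length(sample_id), 0, sample_effect_sd)

  shifts <- as.matrix(gene_specs[groups])
  rownames(shifts) <- gene_specs$gene

  panel <- tidyr::crossing(gene = gene_specs$gene,
                           sample_id = sample_id,
                           replicate = seq_len(n_replicates))
  idx_g <- match(panel$gene, gene_specs$gene)
  idx_s <- match(panel$sample_id, sample_id)
  panel$group <- group[idx_s]
  mu <- gene_specs$baseline_ct[idx_g] +
    shifts[cbind(idx_g, match(panel$group, groups))] + b[idx_s]
  panel$ct <- rnorm(nrow(panel), mu, gene_specs$noise_sd[idx_g])
  if (missing_rate > 0) {
    p <- rep(missing_rate, nrow(panel))
    if (informative_dropout) {
      p <- pmin(ifelse(panel$ct > median(panel$ct), 2 * p, p), 0.99)
    }
    panel$ct[runif(nrow(panel)) < p] <- NA_real_
  }
  panel <- panel[c("gene", "sample_id", "group", "replicate", "ct")]

  # stability implied by the generating model: spread of the planted
  # group shifts (sample-size weighted) plus the per-gene noise
  w <- as.numeric(group_sizes) / sum(group_sizes)
  shift_spread <- apply(shifts, 1, function(sh) {
    mu_bar <- sum(w * sh)
    sqrt(sum(w * (sh - mu_bar)^2))
  })
  truth <- tibble::tibble(gene = gene_specs$gene,
                          baseline_ct = gene_specs$baseline_ct,
                          noise_sd = gene_specs$noise_sd,
                          shift_spread = unname(shift_spread),
                          instability = sqrt(shift_spread^2 +
                                               gene_specs$noise_sd^2))
  truth$stability_order <- rank(truth$instability,
                                ties.method = "average")

  list(panel = panel, truth = truth,
       params = list(seed = seed, group_sizes = as.list(group_sizes),
                     n_replicates = n_replicates,
                     sample_effect_sd = sample_effect_sd,
                     missing_rate = missing_rate))
}
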