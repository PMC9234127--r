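# In-code fixtures shared across test files.

# Long collapsed Ct panel from a gene x sample matrix.
panel_from_matrix <- function(ctm, groups = NULL) {
  if (is.null(colnames(ctm))) {
    colnames(ctm) <- paste0("s", seq_len(ncol(ctm)))
  }
  samples <- colnames(ctm)
  if (is.null(groups)) groups <- rep("g1", length(samples))
  tidyr::crossing(gene = rownames(ctm), sample_id = samples) |>
    dplyr::mutate(group = groups[match(sample_id, samples)],
                  ct = ctm[cbind(gene, sample_id)]) |>
    dplyr::select(gene, sample_id, group, ct)
}

# Random k x n Ct matrix (complete), two groups of samples.
random_ct_matrix <- function(k = 5, n = 8, seed) {
  set.seed(seed)
  ctm <- matrix(runif(k * n, 18, 30), k, n,
                dimnames = list(paste0("g", seq_len(k)),
                                paste0("s", seq_len(n))))
  ctm
}

two_group_labels <- function(n) {
  rep(c("case", "control"), length.out = n)[order(seq_len(n) %% 2)]
}

# Three-gene worked panel: A and B identical trajectories, C diverging.
abc_panel <- function() {
  ctm <- rbind(A = c(20, 21, 22, 23),
               B = c(20, 21, 22, 23),
               C = c(20, 22, 21, 25))
  colnames(ctm) <- paste0("s", 1:4)
  panel_from_matrix(ctm)
}

# Small count matrix + metadata with hand-set values.
toy_counts <- function(counts_mat, groups,
                       depth = rep(1e6, ncol(counts_mat))) {
  samples <- colnames(counts_mat)
  list(counts = dplyr::bind_cols(
         tibble::tibble(gene_id = rownames(counts_mat)),
         tibble::as_tibble(counts_mat)),
       metadata = tibble::tibble(sample_id = samples, group = groups,
                                 intron_spanning_reads = depth))
}
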