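make_stats <- function(mean_n, mean_t, cv_n, cv_t,
                       genes = sprintf("g%02d", seq_along(mean_n))) {
  dplyr::bind_rows(
    tibble::tibble(gene_id = genes, class = "normal", mean = mean_n,
                   sd = cv_n * mean_n, cv = ifelse(mean_n > 0, cv_n, NA),
                   cv_defined = mean_n > 0),
    tibble::tibble(gene_id = genes, class = "tumor", mean = mean_t,
                   sd = cv_t * mean_t, cv = ifelse(mean_t > 0, cv_t, NA),
                   cv_defined = mean_t > 0))
}

test_that("sample depth filter removes only samples strictly below threshold", {
  mat <- matrix(rep(5L, 8), nrow = 2,
                dimnames = list(c("a", "b"), paste0("s", 1:4)))
  dat <- toy_counts(mat, c("normal", "normal", "tumor", "tumor"),
                    depth = c(390000, 400000, 400001, 1e6))
  out <- filter_samples_by_depth(dat$counts, dat$metadata)
  expect_equal(out$removed, "s1")            # 390,000 < 4e5 removed
  expect_true(all(c("s2", "s3", "s4") %in% names(out$counts)))  # 4e5 kept

  # all samples at or above the threshold: identity
  dat2 <- toy_counts(mat, c("normal", "normal", "tumor", "tumor"),
                     depth = rep(4e5, 4))
  out2 <- filter_samples_by_depth(dat2$counts, dat2$metadata)
  expect_equal(out2$counts, dat2$counts)

  # missing depth: strict errors, lenient warns and keeps
  dat3 <- dat
  dat3$metadata$intron_spanning_reads[2] <- NA
  expect_error(filter_samples_by_depth(dat3$counts, dat3$metadata), "s2")
  expect_warning(
    out3 <- filter_samples_by_depth(dat3$counts, dat3$metadata,
                                    on_missing_depth = "keep"),
    "passing")
  expect_true("s2" %in% names(out3$counts))
})

test_that("zero-fraction filter uses a strict 'more than' rule", {
  n <- 100
  mat <- rbind(z71 = c(rep(0L, 71), rep(5L, n - 71)),
               z70 = c(rep(0L, 70), rep(5L, n - 70)),
               full = rep(5L, n))
  colnames(mat) <- paste0("s", seq_len(n))
  dat <- toy_counts(mat, rep(c("normal", "tumor"), 50))
  out <- filter_genes_by_zero_fraction(dat$counts)
  expect_equal(out$removed, "z71")
  expect_setequal(out$counts$gene_id, c("z70", "full"))
  expect_equal(out$report$n_in - out$report$n_out, out$report$n_removed)
})

test_that("group_stats computes mean, n-1 SD and CV per class", {
  expr <- tibble::tibble(gene_id = c("g1", "g2"),
                         a = c(20, 7), b = c(21, 7),
                         c = c(22, 7), d = c(23, 7),
                         e = c(5, 7), f = c(6, 7))
  md <- tibble::tibble(sample_id = letters[1:6],
                       group = c(rep("normal", 4), "NSCLC", "CRC"))
  gs <- group_stats(expr, md)
  g1n <- gs[gs$gene_id == "g1" & gs$class == "normal", ]
  expect_equal(g1n$mean, 21.5)
  expect_equal(g1n$sd, 1.290994, tolerance = 1e-6)
  expect_equal(g1n$cv, 0.0600462, tolerance = 1e-6)
  # constant gene: SD and CV are exactly zero
  g2n <- gs[gs$gene_id == "g2" & gs$class == "normal", ]
  expect_equal(g2n$sd, 0)
  expect_equal(g2n$cv, 0)
  # tumor class pools the non-normal labels
  g1t <- gs[gs$gene_id == "g1" & gs$class == "tumor", ]
  expect_equal(g1t$mean, 5.5)
})

test_that("group_stats flags undefined CV and rejects tiny classes", {
  expr <- tibble::tibble(gene_id = "g1", a = -1, b = 1, c = 2, d = 3)
  md <- tibble::tibble(sample_id = letters[1:4],
                       group = c("normal", "normal", "t", "t"))
  gs <- group_stats(expr, md)
  expect_false(gs$cv_defined[gs$class == "normal"])  # mean 0
  expect_true(is.na(gs$cv[gs$class == "normal"]))

  md1 <- md; md1$group <- c("normal", "t", "t", "t")
  expect_error(group_stats(expr, md1), "fewer than 2")
})

test_that("criterion 1 applies the two-sided mean-ratio bound", {
  st <- make_stats(mean_n = c(10, 10, 10), mean_t = c(11, 13, -2),
                   cv_n = rep(0.01, 3), cv_t = rep(0.01, 3))
  out <- stability_criteria_filter(st, top_frac = 1)  # isolate criterion 1
  expect_true(out$pass_fold[1])    # 1.1 and 1/1.1 both < 1.2
  expect_false(out$pass_fold[2])   # 1.3 >= 1.2
  expect_false(out$pass_fold[3])   # non-positive tumor mean fails
})

test_that("criterion 2 keeps the top decile by rank in both classes", {
  # 20-gene universe: means descending in normal, shuffled in tumor so
  # only genes ranked <= 2 in BOTH classes can pass
  mean_n <- seq(40, 2, length.out = 20)
  mean_t <- mean_n[c(2, 1, 3:20)] * 1.05  # swap top two, keep ratios ok
  st <- make_stats(mean_n, mean_t, cv_n = rep(0.001, 20),
                   cv_t = rep(0.001, 20))
  out <- stability_criteria_filter(st, fold_max = 10, cv_max = 1)
  expect_equal(sum(out$pass_top), 2)
  expect_setequal(out$gene_id[out$pass_top], c("g01", "g02"))
  # brute-force re-ranking agrees gene by gene
  cutoff <- ceiling(0.10 * 20)
  brute <- rank(-mean_n, ties.method = "min") <= cutoff &
    rank(-mean_t, ties.method = "min") <= cutoff
  expect_equal(out$pass_top, brute)
})

test_that("criterion 3 rejects high or undefined CV", {
  st <- make_stats(mean_n = c(10, 10, 0), mean_t = c(10, 10, 10),
                   cv_n = c(0.05, 0.15, 0.01), cv_t = c(0.09, 0.05, 0.01))
  out <- stability_criteria_filter(st, top_frac = 1, fold_max = 100)
  expect_equal(out$pass_cv, c(TRUE, FALSE, FALSE))
})

test_that("refine filter keeps exactly the genes designed to pass", {
  mean_n <- c(0.9, 8, 12, 9, 11, 10, 7, 13, 6, 14)
  mean_t <- mean_n
  cv <- c(0.005, 0.005, 0.02, 0.009, 0.011, 0.0099, 0.5, 0.001, 0.01,
          0.0001)
  st <- make_stats(mean_n, mean_t, cv, cv)
  out <- refine_filter(st)
  brute <- mean_n > 1 & mean_t > 1 & cv < 0.01 & cv < 0.01
  expect_equal(out$pass, brute)
  expect_equal(sum(out$pass), 5L)
  expect_false(out$pass[1])  # mean 0.9 fails mean_min
  expect_true(out$pass[2])   # mean 8, CV 0.005 passes both
})

test_that("known-list intersection preserves order and records provenance", {
  cand <- c("YWHAZ", "GNAS", "GAPDH", "OAZ1", "PTMA", "B2M", "ACTB",
            "XYZ1")
  known <- read_known_genes(system.file(
    "extdata", "known_reference_genes_synthetic.txt", package = "refstab"))
  expect_length(known, 73)
  out <- intersect_known(cand, known)
  expect_equal(out$gene_id,
               c("YWHAZ", "GNAS", "GAPDH", "OAZ1", "PTMA", "B2M", "ACTB"))
  expect_equal(attr(out, "provenance")$known_list_size, 73)

  expect_warning(empty <- intersect_known(c("NOPE1", "NOPE2"), known),
                 "no candidate")
  expect_equal(nrow(empty), 0)
  # idempotence
  expect_equal(intersect_known(cand, cand)$gene_id, cand)
  # normalization: whitespace, case, Ensembl versions
  expect_equal(normalize_gene_ids(c(" actb ", "ENSG00000111640.14")),
               c("ACTB", "ENSG00000111640"))
})

test_that("relaxing any criteria threshold never shrinks the survivor set", {
  set.seed(31)
  g <- 60
  st <- make_stats(mean_n = runif(g, 0.5, 20),
                   mean_t = runif(g, 0.5, 20),
                   cv_n = runif(g, 0, 0.3), cv_t = runif(g, 0, 0.3))
  base <- stability_criteria_filter(st, fold_max = 1.2, top_frac = 0.10,
                                    cv_max = 0.10)
  for (i in 1:8) {
    relaxed <- stability_criteria_filter(
      st, fold_max = 1.2 + runif(1, 0, 5),
      top_frac = 0.10 + runif(1, 0, 0.9),
      cv_max = 0.10 + runif(1, 0, 1))
    expect_true(all(relaxed$pass[base$pass]))
  }
})

test_that("criteria 1 and 3 are symmetric under class-label swap", {
  set.seed(32)
  g <- 40
  st <- make_stats(mean_n = runif(g, 0.5, 20),
                   mean_t = runif(g, 0.5, 20),
                   cv_n = runif(g, 0, 0.2), cv_t = runif(g, 0, 0.2))
  swapped <- st
  swapped$class <- ifelse(st$class == "normal", "tumor", "normal")
  a <- stability_criteria_filter(st)
  b <- stability_criteria_filter(swapped)
  expect_equal(a$pass_fold, b$pass_fold)
  expect_equal(a$pass_cv, b$pass_cv)
})

test_that("run_shortlist chains stages with conserved attrition", {
  cm <- simulate_counts(n_genes = 200, n_normal = 20, n_tumor = 20,
                        seed = 5)
  known <- c("GENE0001", "GENE0002", "NOT_PRESENT")
  res <- run_shortlist(cm$counts, cm$metadata, known = known)
  rep <- res$report
  expect_equal(rep$n_in - rep$n_out, rep$n_removed)
  gene_stages <- rep[rep$unit == "genes", ]
  # survivors of stage k enter stage k+1
  expect_equal(gene_stages$n_out[-nrow(gene_stages)],
               gene_stages$n_in[-1])
  expect_true(all(res$candidates$gene_id %in%
                    res$pre_intersection$gene_id))
  expect_s3_class(glance(res), "tbl_df")
  expect_equal(glance(res)$n_candidates_final, nrow(res$candidates))
  # empty known list is a config error before execution
  expect_error(run_shortlist(cm$counts, cm$metadata,
                             known = character(0)), "empty")
})
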