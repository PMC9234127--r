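test_that("log quantities calibrate per gene and scale with efficiency", {
  ctm <- rbind(g1 = c(20, 21, 23), g2 = c(25, 24, 26))
  colnames(ctm) <- paste0("s", 1:3)
  panel <- panel_from_matrix(ctm)
  a <- prepare_log_quantities(panel)
  expect_equal(unname(a["g1", ]), c(0, -1, -3))   # Ct {20,21,23}: a = min - Ct
  expect_equal(unname(a["g2", ]), c(-1, 0, -2))
  a21 <- prepare_log_quantities(panel, efficiency = 2.1)
  expect_equal(a21, a * log2(2.1))
  expect_equal(log2(2.1), 1.070389, tolerance = 1e-6)
  # shifting one gene's Cts leaves all pairwise SDs unchanged
  shifted <- panel
  shifted$ct[shifted$gene == "g1"] <- shifted$ct[shifted$gene == "g1"] + 3
  a2 <- prepare_log_quantities(shifted)
  expect_equal(sd(a2["g1", ] - a2["g2", ]), sd(a["g1", ] - a["g2", ]))
})

test_that("comparative delta-Ct reproduces the worked three-gene example", {
  res <- delta_ct_stability(abc_panel())
  s <- setNames(res$stability, res$gene)
  expect_equal(unname(s["A"]), 0.6454972, tolerance = 1e-6)
  expect_equal(unname(s["B"]), 0.6454972, tolerance = 1e-6)
  expect_equal(unname(s["C"]), 1.2909944, tolerance = 1e-6)
  expect_equal(res$rank[res$gene %in% c("A", "B")], c(1.5, 1.5))
  expect_equal(res$rank[res$gene == "C"], 3)
})

test_that("delta-Ct handles degenerate and incomplete panels", {
  ctm <- matrix(20, 3, 4, dimnames = list(c("a", "b", "c"),
                                          paste0("s", 1:4)))
  res <- delta_ct_stability(panel_from_matrix(ctm))
  expect_equal(res$stability, rep(0, 3))
  expect_equal(res$rank, rep(2, 3))  # all tied at the average rank

  ctm2 <- random_ct_matrix(3, 6, seed = 9)
  ctm2[1, 1:3] <- NA  # pair (g1, g2) keeps only 2 complete samples
  ctm2[2, 4] <- NA
  panel2 <- panel_from_matrix(ctm2)
  expect_error(delta_ct_stability(panel2), "g1, g2")
  expect_s3_class(delta_ct_stability(panel2, on_incomplete_pair = "drop"),
                  "delta_ct_stability")
})

test_that("geNorm reproduces the worked example and its tie conventions", {
  res <- genorm(abc_panel())
  first_step <- res$trace[res$trace$step == 1, ]
  expect_equal(first_step$M[first_step$gene == "A"], 0.6454972,
               tolerance = 1e-6)
  expect_equal(first_step$M[first_step$gene == "C"], 1.2909944,
               tolerance = 1e-6)
  expect_equal(first_step$gene[first_step$removed], "C")
  expect_equal(res$final_pair, c("A", "B"))
  expect_equal(res$ranks$rank[match(c("A", "B", "C"), res$ranks$gene)],
               c(1.5, 1.5, 3))
  expect_equal(nrow(res$v_series), 1)  # k - 2 entries
  expect_error(genorm(panel_from_matrix(rbind(a = c(1, 2, 3),
                                              b = c(2, 3, 4)) + 20)),
               "at least three")
})

test_that("an identical gene pair always survives to the geNorm final pair", {
  for (seed in 1:5) {
    ctm <- random_ct_matrix(6, 10, seed = seed)
    ctm[2, ] <- ctm[1, ] + 0.5  # identical trajectory, constant offset
    rownames(ctm)[1:2] <- c("twinA", "twinB")
    res <- genorm(panel_from_matrix(ctm))
    expect_setequal(res$final_pair, c("twinA", "twinB"))
  }
})

test_that("NormFinder scores zero-variance genes best and planted shifts worst", {
  # gene whose sample-centered values are constant: rho = 0, rank 1
  ctm <- random_ct_matrix(5, 8, seed = 21)
  groups <- rep(c("a", "b"), each = 4)
  common <- runif(8, 20, 24)
  ctm[1, ] <- common + 2  # tracks the sample mean exactly? no: make all
  # genes share loading, gene 1 has no extra noise
  for (i in 2:5) ctm[i, ] <- common + rnorm(8, 0, 1) + i
  rownames(ctm) <- paste0("g", 1:5)
  res <- normfinder(panel_from_matrix(ctm, groups))
  expect_equal(res$rank[res$gene == "g1"], 1)

  # a pure +2 group shift on an otherwise exchangeable gene maximizes rho
  set.seed(22)
  base <- matrix(rnorm(5 * 8, 0, 0.3), 5, 8) + runif(8, 20, 24)[col(matrix(0, 5, 8))]
  dimnames(base) <- list(paste0("g", 1:5), paste0("s", 1:8))
  base["g3", groups == "b"] <- base["g3", groups == "b"] + 2
  res2 <- normfinder(panel_from_matrix(base, groups))
  expect_equal(res2$gene[which.max(res2$stability)], "g3")

  # group with fewer than 2 samples errors
  bad_groups <- c("a", rep("b", 7))
  expect_error(normfinder(panel_from_matrix(ctm, bad_groups)),
               "fewer than 2")
})

test_that("BestKeeper descriptors match hand arithmetic", {
  ctm <- rbind(g1 = c(20, 21, 22, 23), g2 = c(25, 25, 25, 25))
  colnames(ctm) <- paste0("s", 1:4)
  res <- bestkeeper(panel_from_matrix(ctm))
  d1 <- res$descriptors[res$descriptors$gene == "g1", ]
  expect_equal(d1$ar_mean, 21.5)
  expect_equal(d1$sd, 1.0)                       # mean absolute deviation
  expect_equal(d1$cv_pct, 100 / 21.5, tolerance = 1e-9)
  expect_equal(d1$geo_mean, prod(c(20, 21, 22, 23))^(1 / 4),
               tolerance = 1e-9)
  expect_false(d1$inconsistent)                  # MAD at the cutoff, not above
  d2 <- res$descriptors[res$descriptors$gene == "g2", ]
  expect_equal(d2$sd, 0)
  expect_equal(d2$cv_pct, 0)
  expect_true(is.na(d2$r))                       # constant gene: r undefined
  expect_equal(d2$rank, 1)                       # ranked by dispersion alone

  # classic SD convention behind the flag
  res_sd <- bestkeeper(panel_from_matrix(ctm), sd_method = "sd")
  expect_equal(res_sd$descriptors$sd[res_sd$descriptors$gene == "g1"],
               sd(c(20, 21, 22, 23)))
})

test_that("BestKeeper index is the per-sample geometric mean of Ct", {
  ct1 <- c(20, 22, 24, 26)
  ctm <- rbind(g1 = ct1, g2 = ct1 + 1)
  colnames(ctm) <- paste0("s", 1:4)
  res <- bestkeeper(panel_from_matrix(ctm))
  expect_equal(res$index$bki, sqrt(ct1 * (ct1 + 1)))
  r1 <- res$descriptors$r[res$descriptors$gene == "g1"]
  expect_equal(r1, cor(ct1, sqrt(ct1 * (ct1 + 1))))
  expect_gt(r1, 0.999)
  expect_error(
    bestkeeper(panel_from_matrix(rbind(a = c(-1, 2, 3), b = c(1, 2, 3)))),
    "positive")
})

test_that("rank aggregation is the geometric mean with alphabetical ties", {
  ranks <- tibble::tibble(gene = c("GAPDH", "B2M", "ACTB"),
                          delta_ct = c(1, 2, 3),
                          bestkeeper = c(1, 3, 2),
                          normfinder = c(1, 2, 3),
                          genorm = c(1.5, 1.5, 3))
  agg <- aggregate_ranks(ranks)
  expect_equal(agg$gene, c("GAPDH", "B2M", "ACTB"))
  expect_equal(agg$aggregate_score,
               c((1 * 1 * 1 * 1.5)^0.25, (2 * 3 * 2 * 1.5)^0.25,
                 (3 * 2 * 3 * 3)^0.25))
  expect_equal(agg$comprehensive_rank, 1:3)

  # full agreement: comprehensive ranking equals the common ranking
  same <- tibble::tibble(gene = c("x", "y", "z"), m1 = 1:3, m2 = 1:3)
  expect_equal(aggregate_ranks(same)$comprehensive_rank, 1:3)
  # exact ties broken alphabetically
  tied <- tibble::tibble(gene = c("zz", "aa"), m1 = c(1, 2),
                         m2 = c(2, 1))
  expect_equal(aggregate_ranks(tied)$gene, c("aa", "zz"))
  # partial rankings refuse to aggregate
  holes <- tibble::tibble(gene = c("x", "y"), m1 = c(1, 2),
                          m2 = c(1, NA))
  expect_error(aggregate_ranks(holes), "y")
})

test_that("ct_stability assembles all four methods coherently", {
  sim <- simulate_ct(seed = 42)
  panel <- collapse_replicates(apply_ct_inclusion(sim$panel))
  fit <- ct_stability(panel)
  expect_setequal(fit$table$gene, unique(sim$panel$gene))
  expect_equal(sort(fit$table$comprehensive_rank), 1:7)
  # per-method ranks agree with the standalone functions
  dct <- delta_ct_stability(panel)
  expect_equal(fit$table$delta_ct[match(dct$gene, fit$table$gene)],
               dct$rank)
  long <- tidy(fit)
  expect_setequal(unique(long$method),
                  c("delta_ct", "genorm", "normfinder", "bestkeeper",
                    "comprehensive"))
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})
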