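# Brute-force oracles, written as plain double loops independently of the
# package's vectorized implementations. All take a gene x sample Ct matrix.

oracle_delta_ct <- function(ctm) {
  genes <- rownames(ctm)
  s_val <- numeric(length(genes))
  for (i in seq_along(genes)) {
    sds <- c()
    for (j in seq_along(genes)) {
      if (j == i) next
      d <- ctm[i, ] - ctm[j, ]
      d <- d[!is.na(d)]
      sds <- c(sds, sd(d))
    }
    s_val[i] <- mean(sds)
  }
  names(s_val) <- genes
  s_val
}

oracle_log_quantities <- function(ctm, efficiency = 2) {
  a <- ctm
  for (i in seq_len(nrow(ctm))) {
    a[i, ] <- (min(ctm[i, ], na.rm = TRUE) - ctm[i, ]) * log2(efficiency)
  }
  a
}

# Full stepwise geNorm: returns the per-step M values, removal order,
# final pair, ranks and the pairwise-variation series.
oracle_genorm <- function(ctm, efficiency = 2) {
  a <- oracle_log_quantities(ctm, efficiency)
  a <- a[, colSums(is.na(a)) == 0, drop = FALSE]
  m_values <- function(mat) {
    g <- rownames(mat)
    out <- numeric(length(g))
    for (i in seq_along(g)) {
      acc <- c()
      for (j in seq_along(g)) {
        if (j == i) next
        acc <- c(acc, sd(mat[i, ] - mat[j, ]))
      }
      out[i] <- mean(acc)
    }
    names(out) <- g
    out
  }
  steps <- list()
  removal <- character()
  removal_m <- numeric()
  cur <- a
  while (nrow(cur) > 2) {
    m <- m_values(cur)
    worst <- names(m)[m == max(m)]
    worst <- sort(worst)[length(worst)]  # lexicographically last on ties
    steps[[length(steps) + 1]] <- m
    removal <- c(removal, worst)
    removal_m <- c(removal_m, m[[worst]])
    cur <- cur[setdiff(rownames(cur), worst), , drop = FALSE]
  }
  final_m <- m_values(cur)
  steps[[length(steps) + 1]] <- final_m
  final_pair <- sort(rownames(cur))

  order_best_first <- c(final_pair, rev(removal))
  ranks <- c(1.5, 1.5, seq(3, nrow(a)))
  names(ranks) <- order_best_first

  # NF_n(s): geometric mean (via explicit product) of relative
  # quantities 2^a of the n top-ranked genes
  q <- 2^a
  nf <- function(n) {
    apply(q[order_best_first[1:n], , drop = FALSE], 2,
          function(col) prod(col)^(1 / length(col)))
  }
  v <- numeric(0)
  for (n in 2:(nrow(a) - 1)) {
    v <- c(v, sd(log2(nf(n) / nf(n + 1))))
  }
  list(steps = steps, removal = removal, removal_m = removal_m,
       final_pair = final_pair, ranks = ranks, v_series = v)
}

oracle_normfinder <- function(ctm, groups, efficiency = 2) {
  a <- oracle_log_quantities(ctm, efficiency)
  keep <- colSums(is.na(a)) == 0
  a <- a[, keep, drop = FALSE]
  groups <- groups[keep]
  x <- a
  for (s in seq_len(ncol(a))) x[, s] <- a[, s] - mean(a[, s])
  gl <- unique(groups)
  n_total <- ncol(x)
  rho <- numeric(nrow(x))
  names(rho) <- rownames(x)
  if (length(gl) == 1) {
    for (g in rownames(x)) rho[g] <- sd(x[g, ])
    return(rho)
  }
  for (g in rownames(x)) {
    m_overall <- 0
    m_g <- v_g <- n_g <- numeric(length(gl))
    for (k in seq_along(gl)) {
      vals <- x[g, groups == gl[k]]
      n_g[k] <- length(vals)
      m_g[k] <- mean(vals)
      v_g[k] <- var(vals)
      m_overall <- m_overall + n_g[k] * m_g[k]
    }
    m_overall <- m_overall / n_total
    acc <- 0
    for (k in seq_along(gl)) {
      d2 <- max((m_g[k] - m_overall)^2 - v_g[k] / n_g[k], 0)
      acc <- acc + (n_g[k] / n_total) * (sqrt(d2) + sqrt(v_g[k] / n_g[k]))
    }
    rho[g] <- acc
  }
  rho
}

oracle_bestkeeper <- function(ctm, sd_method = "mad") {
  genes <- rownames(ctm)
  desc <- data.frame(gene = genes, geo_mean = NA_real_,
                     ar_mean = NA_real_, sd = NA_real_, cv = NA_real_,
                     r = NA_real_, p = NA_real_)
  keep <- colSums(is.na(ctm)) == 0
  cc <- ctm[, keep, drop = FALSE]
  bki <- apply(cc, 2, function(col) prod(col)^(1 / length(col)))
  for (i in seq_along(genes)) {
    x <- ctm[i, ][!is.na(ctm[i, ])]
    am <- sum(x) / length(x)
    desc$ar_mean[i] <- am
    desc$geo_mean[i] <- prod(x)^(1 / length(x))
    desc$sd[i] <- if (sd_method == "mad") {
      sum(abs(x - am)) / length(x)
    } else sd(x)
    desc$cv[i] <- 100 * desc$sd[i] / am
    # Pearson r via the explicit sum formula, p via the t transform
    y <- cc[i, ]
    n <- length(y)
    sxy <- sum((y - mean(y)) * (bki - mean(bki)))
    sxx <- sum((y - mean(y))^2)
    syy <- sum((bki - mean(bki))^2)
    if (sxx > 0 && syy > 0) {
      r <- sxy / sqrt(sxx * syy)
      tt <- r * sqrt((n - 2) / (1 - r^2))
      desc$r[i] <- r
      desc$p[i] <- 2 * pt(-abs(tt), n - 2)
    }
  }
  desc
}
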