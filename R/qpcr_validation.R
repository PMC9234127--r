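#' Relative expression of a target gene against a reference gene
#'
#' Implements the delta-delta-Ct quantification used to validate a chosen
#' reference gene: per sample, `delta_ct = Ct(target) - Ct(reference)`;
#' fold change `2^-(delta_ct - mean(delta_ct in control group))`, so the
#' control group's fold changes have geometric mean 1 by construction.
#' Group means are compared by a two-sided two-sample t-test on the
#' delta-Ct values (classical equal-variance test by default; set
#' `var_equal = FALSE` for the Welch variant).
#'
#' @param panel Collapsed long Ct tibble (`gene`, `sample_id`, `group`,
#'   `ct`); run [apply_ct_inclusion()] and [collapse_replicates()] first.
#' @param target,reference Gene ids of the target and reference genes.
#' @param case_group,control_group Group labels of the two compared
#'   classes.
#' @param var_equal Use the classical pooled-variance t-test (default
#'   `TRUE`).
#' @return An object of class `relative_expression`: list with `samples`
#'   (per-sample tibble: `sample_id`, `group`, `delta_ct`,
#'   `fold_change`), `summary` (per-group delta-Ct means/SDs and
#'   fold-change geometric means) and `test` (t statistic, df, two-sided
#'   p-value; `NA` when the pooled variance is zero).
#' @examples
#' panel <- simulate_ct(seed = 7)$panel |>
#'   apply_ct_inclusion() |>
#'   collapse_replicates()
#' relative_expression(panel, target = "NOISY1", reference = "STAB1",
#'                     case_group = "NSCLC", control_group = "HC")
#' @export
relative_expression <- function(panel, target, reference,
                                case_group, control_group,
                                var_equal = TRUE) {
  sub <- panel[panel$group %in% c(case_group, control_group), ]
  wide <- tidyr::pivot_wider(sub[sub$gene %in% c(target, reference),
                                 c("gene", "sample_id", "group", "ct")],
                             names_from = "gene", values_from = "ct")
  for (g in c(target, reference)) {
    if (!g %in% names(wide)) stop("gene not present in panel: ", g)
  }
  ref_missing <- is.na(wide[[reference]])
  if (any(ref_missing)) {
    warning("dropping ", sum(ref_missing),
            " sample(s) with missing reference Ct")
  }
  wide <- wide[!ref_missing & !is.na(wide[[target]]), ]
  for (g in c(case_group, control_group)) {
    if (sum(wide$group == g) < 3) {
      stop("group '", g, "' has fewer than 3 usable samples")
    }
  }
  delta_ct <- wide[[target]] - wide[[reference]]
  ctrl_mean <- mean(delta_ct[wide$group == control_group])
  samples <- tibble::tibble(sample_id = wide$sample_id,
                            group = wide$group,
                            delta_ct = delta_ct,
                            fold_change = 2^-(delta_ct - ctrl_mean))

  smry <- dplyr::summarise(
    dplyr::group_by(samples, .data$group),
    n = dplyr::n(),
    delta_ct_mean = mean(.data$delta_ct),
    delta_ct_sd = sd(.data$delta_ct),
    fold_change_geomean = geomean(.data$fold_change),
    .groups = "drop")

  x <- delta_ct[wide$group == case_group]
  y <- delta_ct[wide$group == control_group]
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate zero-variance comparison (e.g. target == reference)
    test <- tibble::tibble(statistic = NA_real_, df = NA_real_,
                           p_value = NA_real_, method = "degenerate")
  } else {
    tt <- t.test(x, y, var.equal = var_equal)
    test <- tibble::tibble(statistic = unname(tt$statistic),
                           df = unname(tt$parameter),
                           p_value = tt$p.value,
                           method = tt$method)
  }

  structure(list(samples = samples, summary = smry, test = test,
                 target = target, reference = reference,
                 case_group = case_group, control_group = control_group,
                 alpha = 0.05),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("Relative expression of %s vs reference %s\n",
              x$target, x$reference))
  print(as.data.frame(x$summary), row.names = FALSE)
  if (is.na(x$test$p_value)) {
    cat("t-test: degenerate (zero variance in both groups)\n")
  } else {
    cat(sprintf("%s: t = %.4g, df = %.4g, two-sided p = %.4g\n",
                x$test$method, x$test$statistic, x$test$df,
                x$test$p_value))
  }
  invisible(x)
}

#' Per-sample table of a relative-expression analysis
#'
#' @param x A `relative_expression` object.
#' @param ... Unused.
#' @return Tibble with one row per sample: `sample_id`, `group`,
#'   `delta_ct`, `fold_change`.
#' @export
tidy.relative_expression <- function(x, ...) x$samples

#' One-row summary of a relative-expression analysis
#'
#' @param x A `relative_expression` object.
#' @param ... Unused.
#' @return Tibble with the case/control delta-Ct means, the case-group
#'   fold-change geometric mean, and the test statistic and p-value.
#' @export
glance.relative_expression <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    delta_ct_mean_case = s$delta_ct_mean[s$group == x$case_group],
    delta_ct_mean_control = s$delta_ct_mean[s$group == x$control_group],
    fold_change_geomean_case = s$fold_change_geomean[s$group ==
                                                       x$case_group],
    statistic = x$test$statistic,
    p_value = x$test$p_value)
}

#' Fold-change plot for a relative-expression analysis
#'
#' Boxplot of per-sample fold changes by group on a log2 y axis.
#'
#' @param object A `relative_expression` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relative_expression <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$group, y = .data$fold_change)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "fold change (vs control geometric mean)",
                  title = sprintf("%s relative to %s", object$target,
                                  object$reference)) +
    ggplot2::theme_minimal()
}
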