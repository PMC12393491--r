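#' Pooled-variance independent two-sample t-test
#'
#' Student's t with pooled variance, `df = n_a + n_b - 2`, two-sided p-value.
#' The mean difference is reported as `mean(group_a) - mean(group_b)`.
#'
#' @param group_a,group_b numeric vectors (each at least 2 finite values).
#' @return List of class `test_result`: `statistic`, `df`, `p_value`,
#'   `mean_difference`, `method`.
#' @export
independent_ttest <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("zero pooled variance: t statistic undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_difference = mean(group_a) - mean(group_b),
                 method = "independent t-test (pooled variance)"),
            class = "test_result")
}

#' Paired t-test
#'
#' t-test on within-pair differences, `df = n - 1`.
#'
#' @param values_a,values_b numeric vectors of equal length (at least 2).
#' @return A `test_result` as in [independent_ttest()].
#' @export
paired_ttest <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2L)
  d <- values_a - values_b
  if (stats::var(d) == 0) {
    stop("zero variance of paired differences: t statistic undefined")
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_difference = mean(d),
                 method = "paired t-test"), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result>", x$method, "- mean diff", signif(x$mean_difference, 4),
      ", t =", signif(x$statistic, 4), ", df =", x$df,
      ", p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Covariate-adjusted OLS of a dynamics/energy metric on a clinical score
#'
#' Fits `Q = b0 + b_cx * cx + b_s * sex + b_a * age + b_m * medication + e`
#' by ordinary least squares, where `Q` is a computed statistic (dwell time,
#' fractional occupancy, transition probability, energy) and `cx` a clinical
#' score. Sex and medication enter as 0/1 indicators, age in years,
#' uncentered. Optionally restricted to one group, or fitted pooled with a
#' group-by-score interaction.
#'
#' @param outcome numeric vector `Q`, one value per clinical-table row.
#' @param clinical_score name of the score column in `clinical` (e.g.
#'   `"QIDS"`).
#' @param clinical a clinical table (see [clinical_table()]).
#' @param group restrict to `"HC"` or `"MDD"`; `NULL` (default) uses all.
#' @param interaction logical; add a `group * score` interaction (pooled fit
#'   only).
#' @return List of class `regression_result`: `coefficients`, `t_values`,
#'   `p_values` (named), `r_squared`, `n`, `score_coefficient`,
#'   `score_t`, `score_p`, `fit` (the `lm` object).
#' @export
ols_with_covariates <- function(outcome, clinical_score, clinical,
                                group = NULL, interaction = FALSE) {
  stopifnot(clinical_score %in% names(clinical),
            length(outcome) == nrow(clinical))
  df <- data.frame(Q = outcome,
                   cx = clinical[[clinical_score]],
                   sex = as.numeric(clinical$sex),
                   age = as.numeric(clinical$age),
                   medication = as.numeric(clinical$medication),
                   group = as.character(clinical$group))
  if (!is.null(group)) {
    df <- df[df$group == group, ]
  }
  df <- df[stats::complete.cases(df[c("Q", "cx", "sex", "age", "medication")]), ]
  n_par <- 5L + 2L * isTRUE(interaction)
  if (nrow(df) <= n_par) stop("need more rows (", nrow(df),
                              ") than parameters (", n_par, ")")
  form <- if (interaction && is.null(group)) {
    Q ~ cx * group + sex + age + medication
  } else {
    Q ~ cx + sex + age + medication
  }
  fit <- stats::lm(form, data = df)
  if (fit$rank < length(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(coefficients = co[, "Estimate"],
                 t_values = co[, "t value"],
                 p_values = co[, "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 n = nrow(df),
                 score_coefficient = co["cx", "Estimate"],
                 score_t = co["cx", "t value"],
                 score_p = co["cx", "Pr(>|t|)"],
                 fit = fit), class = "regression_result")
}

#' Multiple-comparison adjustment of p-values
#'
#' Benjamini-Hochberg FDR step-up (with the usual monotonicity enforcement)
#' or Bonferroni (`min(m * p, 1)`), delegated to [stats::p.adjust()].
#'
#' @param p_list numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p_list, method = c("bh", "bonferroni")) {
  if (length(method) != 1L || !method %in% c("bh", "bonferroni")) {
    stop("method must be one of 'bh', 'bonferroni'")
  }
  stopifnot(all(p_list >= 0 & p_list <= 1, na.rm = TRUE))
  stats::p.adjust(p_list, method = if (method == "bh") "BH" else "bonferroni")
}

#' Group comparison of every dynamics metric
#'
#' Runs a pooled-variance independent t-test (HC vs MDD) for each
#' metric/state combination of a cohort dynamics table and adjusts the
#' p-values within each metric family.
#'
#' @param dynamics long-format table from [cohort_dynamics()].
#' @param clinical a clinical table with `subject` and `group` columns.
#' @param adjust `"bh"` or `"bonferroni"`.
#' @return data.frame: `metric`, `from_state`, `to_state`, `mean_difference`
#'   (HC minus MDD), `t`, `df`, `p`, `adjusted_p`.
#' @export
compare_groups <- function(dynamics, clinical, adjust = "bh") {
  grp <- stats::setNames(as.character(clinical$group), clinical$subject)
  keys <- unique(dynamics[c("metric", "from_state", "to_state")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- dynamics$metric == keys$metric[i] &
      dynamics$from_state == keys$from_state[i] &
      (is.na(keys$to_state[i]) | (!is.na(dynamics$to_state) &
                                    dynamics$to_state == keys$to_state[i]))
    if (is.na(keys$to_state[i])) sel <- sel & is.na(dynamics$to_state)
    v <- dynamics$value[sel]
    g <- grp[dynamics$subject[sel]]
    res <- tryCatch(independent_ttest(v[g == "HC"], v[g == "MDD"]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(metric = keys$metric[i], from_state = keys$from_state[i],
               to_state = keys$to_state[i],
               mean_difference = res$mean_difference, t = res$statistic,
               df = res$df, p = res$p_value)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  for (m in unique(out$metric)) {
    sel <- out$metric == m
    out$adjusted_p[sel] <- adjust_pvalues(out$p[sel], method = adjust)
  }
  rownames(out) <- NULL
  out
}
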