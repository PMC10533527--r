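#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum comparison. The U statistic counts `a`-over-`b` wins
#' with ties counted 1/2. The p-value is the exact permutation p-value when
#' `n1 * n2 <= 400` and the pooled sample is tie-free, and the normal
#' approximation with tie and continuity correction otherwise (both via
#' [stats::wilcox.test()]); the branch taken is recorded in `method`.
#'
#' @param group_a,group_b nonempty numeric vectors.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`, default) the
#'   exact branch.
#' @return a `group_comparison`: `u_statistic`, `n1`, `n2`, `p_value`,
#'   `p_adjusted` (`NA` until adjusted), `method`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact = NULL) {
  if (!length(group_a) || !length(group_b)) {
    abort("both groups must be nonempty", class = "svbn_validation_error")
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  if (is.null(exact)) exact <- (n1 * n2 <= 400L) && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            exact = exact, correct = TRUE))
  structure(list(u_statistic = unname(wt$statistic),
                 n1 = n1, n2 = n2,
                 p_value = unname(wt$p.value),
                 p_adjusted = NA_real_,
                 method = if (exact && !has_ties) "exact"
                          else "normal-approximation"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> U = %g (n1 = %d, n2 = %d), p = %.4g%s [%s]\n",
              x$u_statistic, x$n1, x$n2, x$p_value,
              if (is.na(x$p_adjusted)) "" else
                sprintf(", adj. p = %.4g", x$p_adjusted),
              x$method))
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size (the vector length) and caps
#' at 1; order is preserved.
#'
#' @param p_values numeric vector with entries in (0, 1].
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1 | !is.finite(p_values))) {
    abort("p-values must lie in (0, 1]", class = "svbn_validation_error")
  }
  pmin(1, length(p_values) * p_values)
}

#' Compare a continuous outcome across a binary grouping flag
#'
#' Splits `value` by the `TRUE`/`FALSE` states of `by` (missing cells in
#' either column are dropped pairwise) and runs [mann_whitney_u()].
#'
#' @param table a [cohort_table()].
#' @param by binary column name (`TRUE` rows form group a).
#' @param value continuous column name.
#' @inheritParams mann_whitney_u
#' @return a `group_comparison`.
#' @export
compare_groups <- function(table, by, value, exact = NULL) {
  kinds <- cohort_kinds(table)
  if (is.null(kinds[[by]]) || kinds[[by]] != "binary") {
    abort("'", by, "' must be a binary column", class = "svbn_validation_error")
  }
  if (is.null(kinds[[value]]) || kinds[[value]] != "continuous") {
    abort("'", value, "' must be a continuous column",
          class = "svbn_validation_error")
  }
  keep <- !is.na(table[[by]]) & !is.na(table[[value]])
  g <- table[[by]][keep]
  v <- table[[value]][keep]
  mann_whitney_u(v[g], v[!g], exact = exact)
}
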