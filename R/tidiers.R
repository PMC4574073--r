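# broom-style accessors and print methods for test objects.

#' Tidy a cohort test
#'
#' @param x A `cohort_test` from [rank_sum_test()] or [signed_rank_test()].
#' @param ... Unused.
#' @return One-row tibble with the test name, statistic, group sizes, raw
#'   and adjusted p-values and (for signed-rank tests) the direction.
#' @export
tidy.cohort_test <- function(x, ...) {
  tibble(
    comparison = x$comparison %||% NA_character_,
    test = x$test,
    statistic = x$statistic,
    n_a = x$n_a,
    n_b = x$n_b,
    p_raw = x$p_raw,
    p_adjusted = x$p_adjusted,
    correction = x$correction,
    exact = x$exact,
    direction = x$direction %||% NA_character_,
    median_a = x$median_a %||% NA_real_,
    median_b = x$median_b %||% NA_real_
  )
}

#' @rdname tidy.cohort_test
#' @export
glance.cohort_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_raw, method = x$test,
         exact = x$exact)
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("%s test%s\n", x$test,
              if (!is.null(x$comparison)) paste0(": ", x$comparison) else ""))
  cat(sprintf("  statistic = %.6g, n = %d vs %d, p = %.4g (%s branch)\n",
              x$statistic, x$n_a, x$n_b, x$p_raw,
              if (x$exact) "exact" else "approximate"))
  if (!is.null(x$median_a)) {
    cat(sprintf("  group medians: %.6g vs %.6g\n", x$median_a, x$median_b))
  }
  if (!is.null(x$direction)) cat(sprintf("  direction: %s\n", x$direction))
  invisible(x)
}

#' Tidy an association result
#'
#' @param x An `assoc_result` from [expression_association()] or
#'   [methylation_association()].
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.assoc_result <- function(x, ...) {
  tibble(scope = x$scope, omics = x$omics, n_genes = x$n_genes,
         test = x$test, statistic = x$statistic, p_raw = x$p_raw,
         p_adjusted = x$p_adjusted, correction = x$correction,
         direction = x$direction)
}

#' @rdname tidy.assoc_result
#' @export
glance.assoc_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_raw, method = x$test,
         direction = x$direction)
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("Repeat instability ~ %s association (%s)\n", x$omics, x$scope))
  cat(sprintf("  WSR over %d genes: statistic = %.6g, p = %.4g, direction = %s\n",
              x$n_genes, x$statistic, x$p_raw, x$direction))
  invisible(x)
}
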