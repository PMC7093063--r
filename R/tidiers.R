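#' Tidy a statistical test result
#'
#' @param x A `vanco_test` object.
#' @param ... Unused.
#'
#' @return A one-row tibble with `statistic`, `df`, `p.value`, `method` and
#'   `continuity_corrected`.
#' @examples
#' tidy(chisq_independence(rbind(c(10, 5), c(3, 12))))
#' @exportS3Method generics::tidy
tidy.vanco_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic %||% NA_real_,
    df = as.integer(x$df %||% NA_integer_),
    p.value = x$p_value,
    method = x$method,
    continuity_corrected = isTRUE(x$continuity_corrected)
  )
}

#' @rdname tidy.vanco_test
#' @exportS3Method generics::glance
glance.vanco_test <- function(x, ...) tidy(x, ...)

#' Tidy a cohort comparison
#'
#' @param x A `trough_comparison` from [compare_cohorts()].
#' @param ... Unused.
#'
#' @return The per-category test table: one row per trough category with the
#'   test used, its statistic, degrees of freedom and p-value.
#' @exportS3Method generics::tidy
tidy.trough_comparison <- function(x, ...) x$tests

#' @rdname tidy.trough_comparison
#' @exportS3Method generics::glance
glance.trough_comparison <- function(x, ...) {
  tibble::tibble(
    n_groups = length(x$groups),
    n_total = sum(x$summary$n[!duplicated(x$summary$group)]),
    min_p = min(x$tests$p.value)
  )
}
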