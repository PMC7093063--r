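#' Classify a steady-state trough against the 10--20 mcg/ml window
#'
#' The protocol's therapeutic range for first steady-state troughs is
#' 10--20 mcg/ml: below 10 is subtherapeutic (the under-dosing the nomogram
#' exists to prevent, and a resistance-selection risk), above 20 is
#' supratherapeutic. The boundaries follow the range definition: exactly 10
#' and exactly 20 are therapeutic, since subtherapeutic is strictly
#' `< 10` and supratherapeutic strictly `> 20`.
#'
#' @param concentration Trough concentration(s) in mcg/ml; non-negative.
#'
#' @return Factor with levels `subtherapeutic`, `therapeutic`,
#'   `supratherapeutic` -- a partition of `[0, Inf)`.
#' @examples
#' classify_trough(c(8, 10, 14.8, 20, 20.1))
#' @export
classify_trough <- function(concentration) {
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    abort("`concentration` must be finite and >= 0 (mcg/ml).")
  }
  out <- dplyr::case_when(
    concentration < 10 ~ "subtherapeutic",
    concentration <= 20 ~ "therapeutic",
    TRUE ~ "supratherapeutic"
  )
  factor(out, levels = TROUGH_LEVELS)
}

#' Summarize a trough cohort
#'
#' Counts and proportions per trough category, with the median and
#' interquartile range of the concentrations (quartiles by linear
#' interpolation between order statistics, the default `quantile()` type 7).
#'
#' @param data A data frame with a `trough_mcg_ml` column and, optionally, a
#'   `group` column to summarize by.
#' @param trough Column of trough concentrations (tidy-eval); default
#'   `trough_mcg_ml`.
#' @param group Optional grouping column (tidy-eval); default `group` if
#'   present.
#'
#' @return A tibble with one row per group (or one row total): `n`, counts
#'   `n_subtherapeutic` / `n_therapeutic` / `n_supratherapeutic`, matching
#'   proportions, `median`, `q25`, `q75`.
#' @examples
#' troughs <- tibble::tibble(trough_mcg_ml = c(8, 12, 15, 22))
#' summarize_cohort(troughs)
#' @export
summarize_cohort <- function(data, trough = trough_mcg_ml, group = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort("Cannot summarize an empty cohort.")
  gq <- rlang::enquo(group)
  if (rlang::quo_is_null(gq) && "group" %in% names(data)) {
    gq <- rlang::quo(group)
  }
  conc <- dplyr::pull(data, {{ trough }})
  data$.category <- classify_trough(conc)
  data$.conc <- conc
  grouped <- if (!rlang::quo_is_null(gq)) {
    dplyr::group_by(data, !!gq)
  } else {
    data
  }
  dplyr::summarise(
    grouped,
    n = dplyr::n(),
    n_subtherapeutic = sum(.data$.category == "subtherapeutic"),
    n_therapeutic = sum(.data$.category == "therapeutic"),
    n_supratherapeutic = sum(.data$.category == "supratherapeutic"),
    prop_subtherapeutic = .data$n_subtherapeutic / .data$n,
    prop_therapeutic = .data$n_therapeutic / .data$n,
    prop_supratherapeutic = .data$n_supratherapeutic / .data$n,
    median = median(.data$.conc),
    q25 = unname(quantile(.data$.conc, 0.25)),
    q75 = unname(quantile(.data$.conc, 0.75)),
    .groups = "drop"
  )
}

#' Per-comparison test configuration
#'
#' Names the test applied to each trough category's group-by-in/out-of-
#' category table when exactly two groups are compared. The defaults are the
#' variants that reproduce the protocol evaluation's printed p-values: the
#' continuity-corrected chi-square for the primary (subtherapeutic) outcome
#' and the uncorrected Pearson chi-square for the secondary outcomes.
#' Comparisons of three or more groups always use the uncorrected Pearson
#' chi-square on the k x 2 table.
#'
#' @param subtherapeutic,therapeutic,supratherapeutic One of `"chisq"`,
#'   `"chisq_corrected"`, `"fisher"`.
#'
#' @return A named list consumed by [compare_cohorts()].
#' @export
comparison_config <- function(subtherapeutic = "chisq_corrected",
                              therapeutic = "chisq",
                              supratherapeutic = "chisq") {
  cfg <- list(
    subtherapeutic = subtherapeutic,
    therapeutic = therapeutic,
    supratherapeutic = supratherapeutic
  )
  ok <- c("chisq", "chisq_corrected", "fisher")
  bad <- setdiff(unlist(cfg), ok)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown test '%s'; use one of %s.",
      bad[1], paste(ok, collapse = ", ")
    ))
  }
  cfg
}

run_named_test <- function(name, counts) {
  switch(name,
    chisq = chisq_independence(counts, correct = FALSE),
    chisq_corrected = chisq_independence(counts, correct = TRUE),
    fisher = fisher_exact(counts)
  )
}

#' Compare trough-category attainment between cohorts
#'
#' For each trough category, builds the groups-by-(in category / not) count
#' table and tests for independence with the configured test
#' ([comparison_config()]). Two-group comparisons use the per-category test
#' from `config`; comparisons of three or more groups use the uncorrected
#' Pearson chi-square. With `pairwise = TRUE` all two-group sub-comparisons
#' are additionally run with the configured per-category tests.
#'
#' @param data A data frame with `group` and `trough_mcg_ml` columns (the
#'   trough CSV schema, see [read_troughs()]).
#' @param config A [comparison_config()].
#' @param pairwise Also run every pairwise two-group comparison.
#'
#' @return A `trough_comparison` object: `summary` (per-group
#'   [summarize_cohort()] output), `tables` (per-category count matrices),
#'   `tests` (per-category tidy test results), and `pairwise` (if
#'   requested). [tidy()] returns `tests`; [autoplot()] draws the grouped
#'   category-proportion bar chart.
#' @examples
#' troughs <- tibble::tibble(
#'   group = rep(c("control", "intervention"), c(6, 6)),
#'   trough_mcg_ml = c(5, 7, 12, 14, 16, 25, 11, 12, 13, 15, 18, 22)
#' )
#' compare_cohorts(troughs)
#' @export
compare_cohorts <- function(data, config = comparison_config(),
                            pairwise = FALSE) {
  data <- tibble::as_tibble(data)
  require_columns(data, c("group", "trough_mcg_ml"))
  groups <- if (is.factor(data$group)) {
    levels(droplevels(data$group))
  } else {
    unique(as.character(data$group))
  }
  if (length(groups) < 2) abort("Need at least two groups to compare.")
  category <- classify_trough(data$trough_mcg_ml)
  grp <- factor(as.character(data$group), levels = groups)

  tables <- lapply(setNames(TROUGH_LEVELS, TROUGH_LEVELS), function(cat) {
    m <- vapply(
      groups,
      function(g) {
        inside <- sum(grp == g & category == cat)
        c(inside, sum(grp == g) - inside)
      },
      numeric(2)
    )
    m <- t(m)
    dimnames(m) <- list(groups, c("in_category", "out_of_category"))
    m
  })

  tests <- purrr::map_dfr(TROUGH_LEVELS, function(cat) {
    test_name <- if (length(groups) == 2) config[[cat]] else "chisq"
    res <- run_named_test(test_name, tables[[cat]])
    dplyr::mutate(tidy(res), category = cat, .before = 1)
  })

  pairwise_tests <- NULL
  if (pairwise && length(groups) > 2) {
    pairs <- combn(groups, 2, simplify = FALSE)
    pairwise_tests <- purrr::map_dfr(TROUGH_LEVELS, function(cat) {
      purrr::map_dfr(pairs, function(pr) {
        res <- run_named_test(config[[cat]], tables[[cat]][pr, ])
        dplyr::mutate(
          tidy(res),
          category = cat, group1 = pr[1], group2 = pr[2], .before = 1
        )
      })
    })
  }

  structure(
    list(
      summary = summarize_cohort(data),
      tables = tables,
      tests = tests,
      pairwise = pairwise_tests,
      groups = groups
    ),
    class = "trough_comparison"
  )
}

#' @export
print.trough_comparison <- function(x, ...) {
  cat("Trough-category comparison across", length(x$groups), "groups\n\n")
  print(
    dplyr::mutate(
      x$summary,
      dplyr::across(dplyr::starts_with("prop_"), ~ round(.x * 100, 1))
    )
  )
  cat("\nPer-category tests:\n")
  print(dplyr::mutate(x$tests, p.value = signif(.data$p.value, 2)))
  invisible(x)
}

#' Therapeutic-attainment subgroup analysis at the extremes of weight and
#' renal function
#'
#' Within each actual-body-weight stratum and/or renal (eGFR) stratum,
#' builds the groups-by-(therapeutic / not) table and tests it with the
#' uncorrected Pearson chi-square (df = groups - 1). Strata whose table is
#' degenerate (no observations, a single group, or an empty margin) are
#' excluded with a warning.
#'
#' @param data A data frame with `group`, `trough_mcg_ml` and, per stratifier
#'   requested, `weight_kg` and/or `egfr` (plus optional `renal_modality`,
#'   which forces the `lt15_or_rrt` stratum).
#' @param by Stratifiers to use: any of `"weight"`, `"egfr"`.
#'
#' @return A `subgroup_report`: a tibble with one row per (stratifier,
#'   stratum) holding the therapeutic counts per group (`counts`, a list
#'   column), the chi-square `statistic`, `df` and `p.value`, plus a
#'   `detail` attribute with the per-group long form.
#' @examples
#' set.seed(1)
#' troughs <- tibble::tibble(
#'   group = rep(c("a", "b"), each = 40),
#'   weight_kg = runif(80, 50, 120),
#'   trough_mcg_ml = runif(80, 5, 25)
#' )
#' subgroup_analysis(troughs, by = "weight")
#' @export
subgroup_analysis <- function(data, by = c("weight", "egfr")) {
  data <- tibble::as_tibble(data)
  by <- match.arg(by, several.ok = TRUE)
  require_columns(data, c("group", "trough_mcg_ml"))
  groups <- unique(as.character(data$group))
  therapeutic <- classify_trough(data$trough_mcg_ml) == "therapeutic"

  one_stratifier <- function(which) {
    strata <- switch(which,
      weight = {
        require_columns(data, "weight_kg")
        weight_stratum(data$weight_kg)
      },
      egfr = {
        require_columns(data, "egfr")
        renal_stratum(
          data$egfr,
          if ("renal_modality" %in% names(data)) data$renal_modality else "none"
        )
      }
    )
    purrr::map_dfr(levels(strata), function(s) {
      sel <- strata == s
      counts <- t(vapply(
        groups,
        function(g) {
          k <- sum(sel & data$group == g & therapeutic)
          c(therapeutic = k, other = sum(sel & data$group == g) - k)
        },
        numeric(2)
      ))
      res <- tryCatch(
        chisq_independence(counts, correct = FALSE),
        error = function(e) NULL
      )
      if (is.null(res)) {
        warn(sprintf(
          "Excluding %s stratum '%s': degenerate table (empty group or margin).",
          which, s
        ))
        return(tibble::tibble())
      }
      dplyr::mutate(
        tidy(res),
        stratifier = which, stratum = s, counts = list(counts), .before = 1
      )
    })
  }

  out <- purrr::map_dfr(by, one_stratifier)
  detail <- tidyr::unnest_longer(
    dplyr::mutate(
      out,
      per_group = purrr::map(.data$counts, function(m) {
        tibble::tibble(
          group = rownames(m),
          n_therapeutic = m[, "therapeutic"],
          n_total = rowSums(m),
          prop_therapeutic = m[, "therapeutic"] / rowSums(m)
        )
      })
    )[c("stratifier", "stratum", "per_group")],
    "per_group"
  )
  structure(out, class = c("subgroup_report", class(out)), detail = detail)
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat("Therapeutic-range attainment by subgroup\n")
  show <- dplyr::mutate(
    tibble::as_tibble(x)[c("stratifier", "stratum", "statistic", "df", "p.value")],
    statistic = round(.data$statistic, 2),
    p.value = signif(.data$p.value, 2)
  )
  print(show)
  invisible(x)
}
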