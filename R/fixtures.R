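#' Packaged fixtures from the published protocol evaluation
#'
#' The integer inputs needed to regenerate the published evaluation of the
#' nomogram: the 4 x 4 dosing grid, the three cohorts' trough-category
#' compositions, the weight/eGFR subgroup therapeutic counts, and the power
#' computation's planning constants.
#'
#' Cohort category counts are reconstructed from the printed percentages and
#' group sizes; each triple is the unique set of integers summing to n
#' within 0.5 percentage points of the printed proportions:
#' * historical controls, n = 75: 32.0% / 50.7% / 17.3% -> 24 / 38 / 13
#' * protocol non-users, n = 70: 27.1% / 51.4% / 21.4% -> 19 / 36 / 15
#' * nomogram intervention, n = 108: 13.0% / 69.4% / 17.6% -> 14 / 75 / 19
#'
#' @return A list of class `paper_fixtures`:
#' \describe{
#'   \item{nomogram_grid}{16-row tibble: `renal_stratum`, `weight_stratum`,
#'     `dose_mg`, `interval`.}
#'   \item{cohort_composition}{Tibble: `group`, `n`, `n_subtherapeutic`,
#'     `n_therapeutic`, `n_supratherapeutic`.}
#'   \item{subgroup_counts}{Tibble: `stratifier`, `stratum`, `group`,
#'     `n_therapeutic`, `n_total` (all eight published subgroup rows).}
#'   \item{power_spec}{List: `p1` = 0.34, `p2` = 0.14, `alpha` = 0.05,
#'     `power` = 0.80.}
#' }
#' @examples
#' paper_fixtures()$power_spec
#' @export
paper_fixtures <- function() {
  grid <- tidyr::expand_grid(
    renal_stratum = factor(RENAL_LEVELS, levels = RENAL_LEVELS),
    weight_stratum = factor(WEIGHT_LEVELS, levels = WEIGHT_LEVELS)
  )
  grid$dose_mg <- unname(DOSE_BY_WEIGHT[as.character(grid$weight_stratum)])
  grid$interval <- factor(
    unname(INTERVAL_BY_RENAL[as.character(grid$renal_stratum)]),
    levels = INTERVAL_LEVELS
  )

  composition <- tibble::tibble(
    group = c("control", "non_user", "intervention"),
    n = c(75, 70, 108),
    # 24/75 = 32.0%, 38/75 = 50.7%, 13/75 = 17.3%
    # 19/70 = 27.1%, 36/70 = 51.4%, 15/70 = 21.4%
    # 14/108 = 13.0%, 75/108 = 69.4%, 19/108 = 17.6%
    n_subtherapeutic = c(24, 19, 14),
    n_therapeutic = c(38, 36, 75),
    n_supratherapeutic = c(13, 15, 19)
  )

  groups <- composition$group
  subgroups <- tibble::tibble(
    stratifier = rep(c("weight", "egfr"), each = 12),
    stratum = rep(
      c(WEIGHT_LEVELS, RENAL_LEVELS[c(4, 3, 2, 1)]),
      each = 3
    ),
    group = rep(groups, 8),
    n_therapeutic = c(
      4, 5, 9,      # weight < 60 kg
      6, 7, 36,     # 60 - 80 kg
      18, 10, 14,   # 81 - 100 kg
      10, 14, 16,   # > 100 kg
      5, 9, 12,     # eGFR < 15 or RRT
      8, 6, 14,     # eGFR 15 - 49
      12, 9, 28,    # eGFR 50 - 90
      13, 12, 21    # eGFR > 90
    ),
    n_total = c(
      10, 14, 11,
      19, 14, 50,
      30, 20, 23,
      16, 22, 24,
      9, 17, 16,
      14, 8, 20,
      24, 17, 42,
      28, 28, 30
    )
  )

  structure(
    list(
      nomogram_grid = grid,
      cohort_composition = composition,
      subgroup_counts = subgroups,
      power_spec = list(p1 = 0.34, p2 = 0.14, alpha = 0.05, power = 0.80)
    ),
    class = "paper_fixtures"
  )
}

#' Regenerate the published evaluation from the packaged fixtures
#'
#' Recomputes, from the stored integer counts alone, every headline
#' statistic of the protocol evaluation: the three-cohort trough-category
#' proportions; the control-versus-intervention tests per category (the
#' primary, subtherapeutic, outcome with the continuity-corrected 2 x 2
#' chi-square; the secondary outcomes with the uncorrected Pearson
#' chi-square); the per-stratum therapeutic-attainment chi-square tests for
#' all eight weight/eGFR subgroups; and the planning sample size per group.
#' Deterministic, runs in well under a second.
#'
#' @param fixtures A [paper_fixtures()] list (override to re-analyse
#'   modified counts).
#'
#' @return A list of class `paper_report`: `proportions` (long tibble,
#'   group x category), `outcome_tests` (per-category control vs
#'   intervention), `subgroup_tests` (per stratifier/stratum), and
#'   `n_per_group`.
#' @examples
#' run_paper_report()
#' @export
run_paper_report <- function(fixtures = paper_fixtures()) {
  if (is.null(fixtures) || length(fixtures) == 0) {
    abort("Empty fixture set: nothing to report.")
  }
  required <- c(
    "cohort_composition", "subgroup_counts", "power_spec"
  )
  missing <- setdiff(required, names(fixtures))
  if (length(missing) > 0) {
    abort(sprintf("Fixtures missing: %s.", paste(missing, collapse = ", ")))
  }
  comp <- fixtures$cohort_composition
  count_cols <- paste0("n_", TROUGH_LEVELS)
  if (!all(rowSums(comp[count_cols]) == comp$n)) {
    abort("Fixture category counts must sum to the group sizes.")
  }

  proportions <- tidyr::pivot_longer(
    comp, dplyr::all_of(count_cols),
    names_to = "category", names_prefix = "n_", values_to = "count"
  )
  proportions$category <- factor(proportions$category, levels = TROUGH_LEVELS)
  proportions$proportion <- proportions$count / proportions$n
  proportions$percent <- round(100 * proportions$proportion, 1)

  cfg <- comparison_config()
  two_group <- comp[comp$group %in% c("control", "intervention"), ]
  outcome_tests <- purrr::map_dfr(TROUGH_LEVELS, function(cat) {
    inside <- two_group[[paste0("n_", cat)]]
    counts <- cbind(in_category = inside, out_of_category = two_group$n - inside)
    rownames(counts) <- two_group$group
    dplyr::mutate(
      tidy(run_named_test(cfg[[cat]], counts)),
      category = cat, .before = 1
    )
  })

  subgroup_tests <- fixtures$subgroup_counts |>
    dplyr::group_by(.data$stratifier, .data$stratum) |>
    dplyr::group_modify(function(d, key) {
      counts <- cbind(
        therapeutic = d$n_therapeutic,
        other = d$n_total - d$n_therapeutic
      )
      rownames(counts) <- d$group
      tidy(chisq_independence(counts, correct = FALSE))
    }) |>
    dplyr::ungroup()

  n_per_group <- two_proportion_sample_size(
    fixtures$power_spec$p1, fixtures$power_spec$p2,
    fixtures$power_spec$alpha, fixtures$power_spec$power
  )$n_per_group

  structure(
    list(
      proportions = proportions,
      outcome_tests = outcome_tests,
      subgroup_tests = subgroup_tests,
      n_per_group = n_per_group
    ),
    class = "paper_report"
  )
}

#' @export
print.paper_report <- function(x, ...) {
  cat("Protocol evaluation, regenerated from packaged counts\n\n")
  cat("Trough-category distribution (%):\n")
  wide <- tidyr::pivot_wider(
    x$proportions[c("group", "category", "percent")],
    names_from = "category", values_from = "percent"
  )
  print(wide)
  cat("\nControl vs intervention, per category:\n")
  print(dplyr::mutate(x$outcome_tests, p.value = signif(.data$p.value, 2)))
  cat("\nSubgroup therapeutic-attainment tests:\n")
  print(
    dplyr::mutate(
      x$subgroup_tests[c("stratifier", "stratum", "statistic", "df", "p.value")],
      statistic = round(.data$statistic, 2),
      p.value = signif(.data$p.value, 2)
    ),
    n = 24
  )
  cat(sprintf("\nPlanning sample size: %d per group\n", x$n_per_group))
  invisible(x)
}
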