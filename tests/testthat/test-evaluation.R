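test_that("trough classification respects the 10-20 mcg/ml window", {
  expect_equal(as.character(classify_trough(9.99)), "subtherapeutic")
  expect_equal(as.character(classify_trough(10)), "therapeutic")
  expect_equal(as.character(classify_trough(14.8)), "therapeutic")
  expect_equal(as.character(classify_trough(20.0)), "therapeutic")
  expect_equal(as.character(classify_trough(20.01)), "supratherapeutic")
  expect_error(classify_trough(-0.1), "concentration")
})

test_that("classification partitions the non-negative reals", {
  set.seed(9)
  conc <- c(0, runif(500, 0, 40), 10, 20)
  cat <- classify_trough(conc)
  expect_false(anyNA(cat))
  expect_equal(
    sum(table(cat)), length(conc)
  )
})

test_that("cohort summaries count, proportion and interpolate correctly", {
  s <- summarize_cohort(tibble::tibble(trough_mcg_ml = c(8, 12, 15, 22)))
  expect_equal(s$n, 4)
  expect_equal(
    c(s$n_subtherapeutic, s$n_therapeutic, s$n_supratherapeutic), c(1, 2, 1)
  )
  expect_equal(
    c(s$prop_subtherapeutic, s$prop_therapeutic, s$prop_supratherapeutic),
    c(0.25, 0.5, 0.25)
  )
  expect_equal(s$median, 13.5)

  s1 <- summarize_cohort(tibble::tibble(trough_mcg_ml = 14.8))
  expect_equal(s1$prop_therapeutic, 1)
  expect_equal(s1$median, 14.8)
  expect_error(summarize_cohort(tibble::tibble(trough_mcg_ml = numeric(0))),
               "empty")
})

test_that("a 24-subtherapeutic cohort of 75 reports 32.0%", {
  obs <- troughs_from_counts(24, 38, 13, "control")
  s <- summarize_cohort(obs)
  expect_equal(s$prop_subtherapeutic, 0.32)
})

test_that("the published cohort compositions reproduce the printed percentages", {
  comp <- paper_fixtures()$cohort_composition
  pct <- function(k, n) round(100 * k / n, 1)
  expect_equal(pct(comp$n_subtherapeutic, comp$n), c(32.0, 27.1, 13.0))
  expect_equal(pct(comp$n_therapeutic, comp$n), c(50.7, 51.4, 69.4))
  expect_equal(pct(comp$n_supratherapeutic, comp$n), c(17.3, 21.4, 17.6))
  expect_equal(rowSums(comp[paste0("n_", c(
    "subtherapeutic", "therapeutic", "supratherapeutic"
  ))]), comp$n, ignore_attr = TRUE)
})

control_vs_intervention <- function() {
  dplyr::bind_rows(
    troughs_from_counts(24, 38, 13, "control"),
    troughs_from_counts(14, 75, 19, "intervention")
  )
}

test_that("two-cohort comparison reproduces the published p-values", {
  cmpn <- compare_cohorts(control_vs_intervention())
  tests <- cmpn$tests
  expect_equal(
    tests$p.value[tests$category == "subtherapeutic"], 0.003313,
    tolerance = 1e-3
  )
  expect_true(tests$continuity_corrected[tests$category == "subtherapeutic"])
  expect_equal(
    round(tests$p.value[tests$category == "therapeutic"], 2), 0.01
  )
  expect_equal(
    round(tests$p.value[tests$category == "supratherapeutic"], 2), 0.96
  )
  # margins of every per-category table equal the cohort sizes
  for (tab in cmpn$tables) {
    expect_equal(unname(rowSums(tab)), c(75, 108))
  }
})

test_that("comparisons are invariant to group label order", {
  data <- control_vs_intervention()
  flipped <- data[order(data$group, decreasing = TRUE), ]
  p1 <- compare_cohorts(data)$tests$p.value
  p2 <- compare_cohorts(flipped)$tests$p.value
  expect_equal(sort(p1), sort(p2))
})

test_that("identical cohorts give p = 1 under Fisher", {
  data <- dplyr::bind_rows(
    troughs_from_counts(5, 10, 5, "a"),
    troughs_from_counts(5, 10, 5, "b")
  )
  cfg <- comparison_config("fisher", "fisher", "fisher")
  expect_equal(compare_cohorts(data, config = cfg)$tests$p.value, rep(1, 3))
  expect_error(compare_cohorts(troughs_from_counts(1, 1, 1, "only")), "two groups")
  expect_error(comparison_config("bogus"), "Unknown test")
})

test_that("weight subgroup analysis reproduces the published subgroup p-values", {
  # therapeutic k/n per group inside one weight stratum, troughs placed at
  # representative concentrations and weights
  make_stratum <- function(weight, k, n, group) {
    tibble::tibble(
      patient_id = paste0(group, "-", weight, "-", seq_len(n)),
      group = group,
      weight_kg = weight,
      trough_mcg_ml = c(rep(15, k), rep(5, n - k))
    )
  }
  data <- dplyr::bind_rows(
    make_stratum(70, 6, 19, "control"),
    make_stratum(70, 7, 14, "non_user"),
    make_stratum(70, 36, 50, "intervention"),
    make_stratum(55, 4, 10, "control"),
    make_stratum(55, 5, 14, "non_user"),
    make_stratum(55, 9, 11, "intervention")
  )
  rep <- suppressWarnings(subgroup_analysis(data, by = "weight"))
  tb <- tibble::as_tibble(rep)
  expect_equal(round(tb$p.value[tb$stratum == "s60_80"], 2), 0.01)
  expect_equal(round(tb$p.value[tb$stratum == "lt60"], 2), 0.05)
  expect_equal(tb$df, rep(2L, nrow(tb)))
})

test_that("degenerate subgroup strata are excluded with a warning", {
  data <- tibble::tibble(
    patient_id = as.character(1:8),
    group = rep(c("a", "b"), 4),
    weight_kg = 70,           # every patient in one stratum
    trough_mcg_ml = c(5, 15, 15, 5, 15, 15, 5, 15)
  )
  w <- capture_warnings(out <- subgroup_analysis(data, by = "weight"))
  expect_match(w, "Excluding", all = TRUE)
  expect_length(w, 3)
  expect_equal(nrow(out), 1)
  expect_equal(out$stratum, "s60_80")
})

test_that("three-group comparison uses the k x 2 Pearson chi-square", {
  data <- dplyr::bind_rows(
    troughs_from_counts(24, 38, 13, "control"),
    troughs_from_counts(19, 36, 15, "non_user"),
    troughs_from_counts(14, 75, 19, "intervention")
  )
  cmpn <- compare_cohorts(data, pairwise = TRUE)
  expect_equal(cmpn$tests$df, rep(2L, 3))
  expect_false(any(cmpn$tests$continuity_corrected))
  expect_equal(nrow(cmpn$pairwise), 9)  # 3 categories x 3 pairs
  expect_s3_class(autoplot(cmpn), "ggplot")
  expect_s3_class(plot_trough_distribution(data), "ggplot")
})

test_that("the packaged report regenerates the published statistics", {
  rep <- run_paper_report()
  outcome <- rep$outcome_tests
  expect_equal(
    round(outcome$p.value[outcome$category == "subtherapeutic"], 3), 0.003
  )
  expect_equal(
    round(outcome$p.value[outcome$category == "therapeutic"], 2), 0.01
  )
  expect_equal(
    round(outcome$p.value[outcome$category == "supratherapeutic"], 2), 0.96
  )
  sub <- rep$subgroup_tests
  get_p <- function(strat, s) {
    sub$p.value[sub$stratifier == strat & sub$stratum == s]
  }
  expect_equal(round(get_p("weight", "s60_80"), 2), 0.01)
  expect_equal(round(get_p("weight", "lt60"), 2), 0.05)
  expect_equal(round(get_p("egfr", "gt90"), 2), 0.08)
  expect_equal(rep$n_per_group, 70L)
  expect_error(run_paper_report(list()), "Empty fixture")
})
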