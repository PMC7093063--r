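#' Actual-body-weight strata of the dosing grid
#'
#' Weight is rounded to the nearest integer kilogram (ties away from zero,
#' matching the grid's integer column labels) and binned: \eqn{\le 59 \to}
#' `lt60`, 60--80 \eqn{\to} `s60_80`, 81--100 \eqn{\to} `s81_100`,
#' \eqn{\ge 101 \to} `gt100`. Actual (not ideal or adjusted) body weight is
#' used throughout, including in obese patients.
#'
#' @param weight_kg Actual body weight in kg; strictly positive.
#'
#' @return Factor with levels `lt60`, `s60_80`, `s81_100`, `gt100`.
#' @examples
#' weight_stratum(c(55, 78, 80.4, 101))
#' @export
weight_stratum <- function(weight_kg) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    abort("`weight_kg` must be finite and > 0.")
  }
  w <- round_half_up(weight_kg)
  out <- dplyr::case_when(
    w <= 59 ~ "lt60",
    w <= 80 ~ "s60_80",
    w <= 100 ~ "s81_100",
    TRUE ~ "gt100"
  )
  factor(out, levels = WEIGHT_LEVELS)
}

# The 4 x 4 dosing grid: dose depends only on the weight stratum, interval
# only on the renal stratum. 1500 mg q8 = 4500 mg/day is the protocol cap.
DOSE_BY_WEIGHT <- c(lt60 = 750, s60_80 = 1000, s81_100 = 1250, gt100 = 1500)
INTERVAL_BY_RENAL <- c(
  gt90 = "q8", s50_90 = "q12", s15_49 = "q24", lt15_or_rrt = "single_dose"
)
DOSES_PER_DAY <- c(q8 = 3, q12 = 2, q24 = 1, single_dose = NA_real_)
INTERVAL_HOURS <- c(q8 = 8, q12 = 12, q24 = 24, single_dose = NA_real_)

#' Select the initial vancomycin regimen for each patient
#'
#' Looks each patient up in the dosing grid: the per-administration dose is
#' set by the actual-body-weight stratum (750 / 1000 / 1250 / 1500 mg) and
#' the interval by the renal stratum (q8 / q12 / q24, or a single dose with
#' level-guided redosing when eGFR < 15, the patient is on renal replacement,
#' or renal function is unstable). All doses are multiples of 250 mg and no
#' recurring regimen exceeds 4500 mg/day (1500 mg q8). The protocol targets
#' steady-state troughs of 10--20 mcg/ml.
#'
#' `data` must contain `weight_kg` plus either a precomputed `egfr` column or
#' the covariates [estimate_gfr()] needs; `renal_modality` defaults to
#' `"none"` when absent.
#'
#' @param data A data frame of patient covariates.
#'
#' @return `data` as a tibble with columns added: `weight_stratum`,
#'   `renal_stratum`, `dose_mg`, `interval` (`q8`/`q12`/`q24`/`single_dose`),
#'   `tdd_mg` (total daily dose; `NA` for single-dose regimens, whose
#'   redosing is level-driven), `specimen` and `monitoring` (the attached
#'   monitoring plan).
#' @examples
#' tibble::tibble(weight_kg = 78, egfr = 70) |> recommend_dose()
#' @seealso [monitoring_plan()], [random_level_decision()]
#' @export
recommend_dose <- function(data) {
  require_columns(data, "weight_kg")
  data <- tibble::as_tibble(data)
  if (!"egfr" %in% names(data)) {
    data <- estimate_gfr(data)
  }
  if (!"renal_modality" %in% names(data)) {
    data$renal_modality <- "none"
  }
  data$renal_modality <- parse_modality(data$renal_modality)
  data$weight_stratum <- weight_stratum(data$weight_kg)
  data$renal_stratum <- renal_stratum(data$egfr, data$renal_modality)
  data$dose_mg <- unname(DOSE_BY_WEIGHT[as.character(data$weight_stratum)])
  data$interval <- factor(
    unname(INTERVAL_BY_RENAL[as.character(data$renal_stratum)]),
    levels = INTERVAL_LEVELS
  )
  data$tdd_mg <- data$dose_mg *
    unname(DOSES_PER_DAY[as.character(data$interval)])
  plan <- monitoring_plan(data$interval, data$renal_modality)
  data$specimen <- plan$specimen
  data$monitoring <- plan$timing
  data
}

#' Therapeutic-drug-monitoring plan for a regimen
#'
#' Encodes when the confirmatory level is drawn: regimens dosed every 8 or
#' 12 hours get a steady-state trough 30 minutes before the 4th dose; every
#' 24 hours, before the 3rd dose. Single-dose regimens are followed with a
#' random level instead -- 24 hours after the dose (eGFR < 15, continuous
#' renal replacement, or unstable renal function) or 2 hours after the next
#' hemodialysis session (intermittent hemodialysis) -- interpreted with
#' [random_level_decision()].
#'
#' @param interval `q8`, `q12`, `q24` or `single_dose` (vectorized).
#' @param modality Renal modality as in [renal_stratum()]; only used for
#'   single-dose regimens.
#'
#' @return Tibble with columns `interval`, `specimen`
#'   (`steady_state_trough` or `random_level`) and `timing`.
#' @examples
#' monitoring_plan(c("q12", "q24", "single_dose"), c("none", "none", "ihd"))
#' @export
monitoring_plan <- function(interval, modality = "none") {
  interval <- as.character(interval)
  bad <- !interval %in% INTERVAL_LEVELS
  if (any(bad)) {
    abort(sprintf(
      "`interval` must be one of %s.", paste(INTERVAL_LEVELS, collapse = ", ")
    ))
  }
  modality <- parse_modality(modality)
  n <- max(length(interval), length(modality))
  interval <- rep_len(interval, n)
  modality <- rep_len(modality, n)
  single <- interval == "single_dose"
  tibble::tibble(
    interval = factor(interval, levels = INTERVAL_LEVELS),
    specimen = ifelse(single, "random_level", "steady_state_trough"),
    timing = dplyr::case_when(
      interval %in% c("q8", "q12") ~ "trough 30 min before 4th dose",
      interval == "q24" ~ "trough 30 min before 3rd dose",
      single & modality == "ihd" ~ "random level 2 h after hemodialysis",
      TRUE ~ "random level 24 h after dose"
    )
  )
}

#' Redosing decision from a random vancomycin level
#'
#' Single-dose regimens (eGFR < 15, renal replacement, unstable renal
#' function) are redosed from a random level against a 20 mcg/ml threshold:
#' below 20 the dose is repeated; at or above 20 the dose is held and the
#' level rechecked -- in 12 hours, or after the next dialysis session for
#' intermittent hemodialysis. A level of exactly 20 is assigned to the hold
#' arm (the conservative choice; the protocol text covers only strict
#' inequalities).
#'
#' @param level Measured random vancomycin level, mcg/ml; non-negative.
#' @param modality Renal modality as in [renal_stratum()].
#'
#' @return Tibble with columns `level`, `action` (`repeat_dose` or `hold`)
#'   and `recheck` (`NA`, `"random level in 12 h"`, or
#'   `"random level after next dialysis"`).
#' @examples
#' random_level_decision(c(15, 25), "crrt")
#' random_level_decision(22, "ihd")
#' @export
random_level_decision <- function(level, modality = "crrt") {
  if (any(!is.finite(level)) || any(level < 0)) {
    abort("`level` must be finite and >= 0 (mcg/ml).")
  }
  modality <- parse_modality(modality)
  n <- max(length(level), length(modality))
  level <- rep_len(level, n)
  modality <- rep_len(modality, n)
  hold <- level >= 20
  tibble::tibble(
    level = level,
    action = ifelse(hold, "hold", "repeat_dose"),
    recheck = dplyr::case_when(
      !hold ~ NA_character_,
      modality == "ihd" ~ "random level after next dialysis",
      TRUE ~ "random level in 12 h"
    )
  )
}
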