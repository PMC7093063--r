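#' Estimate glomerular filtration rate with the four-variable MDRD equation
#'
#' Computes eGFR (ml/min/1.73 m\eqn{^2}) from serum creatinine, age, sex and
#' race:
#' \deqn{186 \times SCr^{-1.154} \times Age^{-0.203} \times 0.742^{[female]}
#'   \times 1.210^{[Black]}}
#' The result is already indexed to 1.73 m\eqn{^2} body surface area, so no
#' further body-size normalisation is applied. Creatinine is accepted only in
#' mg/dL; no automatic unit conversion is attempted, to avoid silent
#' \eqn{\mu}mol/L errors.
#'
#' @param scr_mg_dl Serum creatinine in mg/dL. Must be strictly positive.
#' @param age_years Age in years. Must be strictly positive.
#' @param sex `"M"` or `"F"` (case insensitive).
#' @param black_race Logical (or 0/1): Black / African American race
#'   indicator for the 1.210 multiplier.
#'
#' @return Numeric vector of eGFR values in ml/min/1.73 m\eqn{^2}.
#' @examples
#' mdrd4(1.0, 50, "M", FALSE)
#' mdrd4(c(0.8, 2.4), c(40, 70), c("F", "M"), c(FALSE, TRUE))
#' @export
mdrd4 <- function(scr_mg_dl, age_years, sex, black_race = FALSE) {
  if (any(!is.finite(scr_mg_dl)) || any(scr_mg_dl <= 0)) {
    abort("`scr_mg_dl` must be finite and > 0 (mg/dL).")
  }
  if (any(!is.finite(age_years)) || any(age_years <= 0)) {
    abort("`age_years` must be finite and > 0.")
  }
  female <- parse_sex(sex) == "F"
  black <- parse_binary_flag(black_race, "black_race")
  186 * scr_mg_dl^-1.154 * age_years^-0.203 *
    ifelse(female, 0.742, 1) * ifelse(black, 1.210, 1)
}

#' Map eGFR and renal-replacement status to the nomogram's renal strata
#'
#' The dosing grid distinguishes four renal strata. Any renal-replacement or
#' unstable-renal-function modality forces the `lt15_or_rrt` stratum
#' regardless of the computed eGFR (a dialysis patient's creatinine does not
#' reflect native clearance). Otherwise eGFR is rounded to the nearest
#' integer (ties away from zero, matching the grid's integer labels) and
#' binned: \eqn{\ge 91 \to} `gt90`, 50--90 \eqn{\to} `s50_90`, 15--49
#' \eqn{\to} `s15_49`, \eqn{\le 14 \to} `lt15_or_rrt`.
#'
#' @param egfr eGFR in ml/min/1.73 m\eqn{^2}; strictly positive.
#' @param modality One of `"none"`, `"ihd"` (intermittent hemodialysis),
#'   `"crrt"` (continuous renal replacement), `"unstable"` (unstable renal
#'   function). Recycled against `egfr`.
#'
#' @return Factor with levels `gt90`, `s50_90`, `s15_49`, `lt15_or_rrt`.
#' @examples
#' renal_stratum(70, "none")
#' renal_stratum(120, "crrt")
#' renal_stratum(c(90, 90.5), "none")
#' @export
renal_stratum <- function(egfr, modality = "none") {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    abort("`egfr` must be finite and > 0.")
  }
  modality <- parse_modality(modality)
  n <- max(length(egfr), length(modality))
  egfr <- rep_len(egfr, n)
  modality <- rep_len(modality, n)
  g <- round_half_up(egfr)
  out <- dplyr::case_when(
    modality != "none" ~ "lt15_or_rrt",
    g >= 91 ~ "gt90",
    g >= 50 ~ "s50_90",
    g >= 15 ~ "s15_49",
    TRUE ~ "lt15_or_rrt"
  )
  factor(out, levels = RENAL_LEVELS)
}

#' Add eGFR and renal stratum columns to a patient table
#'
#' Data-frame-first wrapper around [mdrd4()] and [renal_stratum()]. Expects
#' the patient CSV schema columns `age_years`, `sex`, `black_race`,
#' `scr_mg_dl` and (optionally) `renal_modality`; a missing
#' `renal_modality` column is treated as `"none"` for every row.
#'
#' @param data A data frame of patient covariates (see [read_patients()]).
#'
#' @return `data` as a tibble with `egfr` and `renal_stratum` columns added.
#' @examples
#' pts <- tibble::tibble(
#'   age_years = c(50, 64), sex = c("M", "F"),
#'   black_race = c(0, 1), scr_mg_dl = c(1.0, 2.2),
#'   weight_kg = c(78, 55), renal_modality = c("none", "crrt")
#' )
#' estimate_gfr(pts)
#' @export
estimate_gfr <- function(data) {
  require_columns(data, c("age_years", "sex", "black_race", "scr_mg_dl"))
  data <- tibble::as_tibble(data)
  modality <- if ("renal_modality" %in% names(data)) {
    data$renal_modality
  } else {
    "none"
  }
  data$egfr <- mdrd4(data$scr_mg_dl, data$age_years, data$sex, data$black_race)
  data$renal_stratum <- renal_stratum(data$egfr, modality)
  data
}

# --- internal helpers -------------------------------------------------------

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

parse_sex <- function(sex) {
  s <- toupper(as.character(sex))
  bad <- !s %in% c("M", "F")
  if (any(bad)) {
    abort(sprintf(
      "`sex` must be 'M' or 'F'; got %s.",
      paste(unique(s[bad]), collapse = ", ")
    ))
  }
  s
}

parse_binary_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)) || any(!v %in% c(0, 1))) {
    abort(sprintf("`%s` must be logical or 0/1.", name))
  }
  v == 1
}

parse_modality <- function(modality) {
  m <- tolower(as.character(modality))
  bad <- !m %in% MODALITY_LEVELS
  if (any(bad)) {
    abort(sprintf(
      "`modality` must be one of %s; got %s.",
      paste(MODALITY_LEVELS, collapse = ", "),
      paste(unique(m[bad]), collapse = ", ")
    ))
  }
  m
}

require_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "Missing required column(s): %s.",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
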