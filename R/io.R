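#' Read and validate a patient covariate CSV
#'
#' Reads the patient schema used throughout the package -- exact header
#' `patient_id, age_years, sex, black_race, scr_mg_dl, weight_kg,
#' renal_modality` with `sex` in `{M, F}`, `black_race` in `{0, 1}` and
#' `renal_modality` in `{none, ihd, crrt, unstable}` -- and validates every
#' row, collecting all problems (with their row numbers) into a single
#' error rather than stopping at the first.
#'
#' @param path Path to a CSV file.
#'
#' @return A tibble of validated patient records.
#' @seealso [write_patients()], [read_troughs()]
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      age_years = readr::col_double(),
      sex = readr::col_character(),
      black_race = readr::col_double(),
      scr_mg_dl = readr::col_double(),
      weight_kg = readr::col_double(),
      renal_modality = readr::col_character()
    )
  )
  require_columns(data, c(
    "patient_id", "age_years", "sex", "black_race", "scr_mg_dl",
    "weight_kg", "renal_modality"
  ))
  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      rows <- which(bad | is.na(bad))
      problems <<- c(
        problems,
        sprintf("row %d: %s", rows, msg)
      )
    }
  }
  flag(!(data$age_years > 0), "age_years must be > 0")
  flag(!data$sex %in% c("M", "F"), "sex must be 'M' or 'F'")
  flag(!data$black_race %in% c(0, 1), "black_race must be 0 or 1")
  flag(!(data$scr_mg_dl > 0), "scr_mg_dl must be > 0")
  flag(!(data$weight_kg > 0), "weight_kg must be > 0")
  flag(
    !data$renal_modality %in% MODALITY_LEVELS,
    sprintf("renal_modality must be one of %s",
            paste(MODALITY_LEVELS, collapse = "/"))
  )
  if (length(problems) > 0) {
    abort(c(
      sprintf("Invalid patient file '%s':", path),
      utils::head(problems, 20)
    ))
  }
  data
}

#' @rdname read_patients
#' @param data A patient tibble in the schema above.
#' @export
write_patients <- function(data, path) {
  require_columns(data, c(
    "patient_id", "age_years", "sex", "black_race", "scr_mg_dl",
    "weight_kg", "renal_modality"
  ))
  readr::write_csv(data, path)
  invisible(path)
}

#' Read and validate a trough observation CSV
#'
#' Reads the trough schema `patient_id, group, trough_mcg_ml, weight_kg,
#' egfr` (the last two optional columns may be empty for observations
#' without subgroup covariates). Concentrations must be non-negative.
#'
#' @param path Path to a CSV file.
#'
#' @return A tibble of trough observations ready for [summarize_cohort()],
#'   [compare_cohorts()] and [subgroup_analysis()].
#' @export
read_troughs <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      group = readr::col_character(),
      trough_mcg_ml = readr::col_double(),
      .default = readr::col_guess()
    )
  )
  require_columns(data, c("patient_id", "group", "trough_mcg_ml"))
  for (col in intersect(c("weight_kg", "egfr"), names(data))) {
    data[[col]] <- as.double(data[[col]])
  }
  bad <- which(is.na(data$trough_mcg_ml) | data$trough_mcg_ml < 0)
  if (length(bad) > 0) {
    abort(c(
      sprintf("Invalid trough file '%s':", path),
      sprintf("row %d: trough_mcg_ml must be >= 0", utils::head(bad, 20))
    ))
  }
  data
}

#' @rdname read_troughs
#' @param data A trough tibble.
#' @export
write_troughs <- function(data, path) {
  require_columns(data, c("patient_id", "group", "trough_mcg_ml"))
  readr::write_csv(data, path)
  invisible(path)
}
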