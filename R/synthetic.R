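#' Configuration for the synthetic ICU cohort simulator
#'
#' Collects every constant the synthetic-cohort and pharmacokinetic layers
#' use, so a simulation is fully specified by one object. The covariate
#' defaults emulate the marginal summaries of an adult medical-ICU
#' vancomycin population: median age near 53 with IQR roughly 42--64
#' (normal, truncated at 18), 56% male, actual body weight with median near
#' 78 kg and IQR roughly 67--96 kg (lognormal), and an eGFR mix of 28% above
#' 90, 39% at 50--90, 19% at 15--49 and 15% with eGFR < 15 or on renal
#' replacement. Serum creatinine is back-solved from each patient's sampled
#' eGFR through the MDRD4 equation, so the stratum mix matches the
#' configured targets up to multinomial sampling noise.
#'
#' The pharmacokinetic block is invented test scaffolding -- plausible
#' population constants for a one-compartment model, not estimates from any
#' clinical dataset: clearance
#' \eqn{(\theta_0 + \theta_1 \cdot eGFR) (W/70)^{0.75} e^{\eta}} in L/h with
#' \eqn{\eta \sim N(0, \omega^2)} (linear in renal function, allometric in
#' body weight, the shape population vancomycin models typically take),
#' volume \eqn{v_{kg} \cdot weight \cdot e^{\eta'}} in L, a fixed low
#' clearance for renal-replacement/unstable patients, and 1-hour infusions.
#'
#' @param n_per_group Patients per simulated arm.
#' @param age_mean,age_sd,age_min Age distribution (years), truncated below.
#' @param male_frac,black_frac Bernoulli fractions for sex and race.
#' @param weight_median,weight_iqr_hi Body-weight lognormal: median, and
#'   75th percentile used to set the log-scale spread.
#' @param egfr_mix Named probabilities over the four renal strata
#'   (`gt90`, `s50_90`, `s15_49`, `lt15_or_rrt`); must sum to 1.
#' @param modality_mix Named probabilities over `ihd`, `crrt`, `unstable`
#'   for patients in the `lt15_or_rrt` stratum.
#' @param cl_intercept,cl_slope Clearance model: L/h at eGFR 0 and L/h per
#'   ml/min/1.73 m\eqn{^2}, for a 70 kg reference patient.
#' @param cl_wt_exp Allometric exponent scaling clearance by
#'   `(weight/70)^cl_wt_exp`.
#' @param rrt_clearance Fixed typical clearance (L/h) for renal-replacement
#'   or unstable patients; dialysis-session kinetics are not modelled.
#' @param v_per_kg Volume of distribution, L per kg actual body weight.
#' @param omega_cl,omega_v Lognormal between-patient SDs for clearance and
#'   volume (0 disables variability).
#' @param t_inf Infusion duration, hours.
#' @param comparator The non-nomogram strategy simulated alongside: a list
#'   with `dose_mg` and `interval` (`q8`/`q12`/`q24`), default a flat
#'   1000 mg q12 for every patient.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 108,
                       age_mean = 53, age_sd = 16, age_min = 18,
                       male_frac = 0.56, black_frac = 0.12,
                       weight_median = 78, weight_iqr_hi = 96,
                       egfr_mix = c(
                         gt90 = 0.28, s50_90 = 0.39,
                         s15_49 = 0.19, lt15_or_rrt = 0.15
                       ),
                       modality_mix = c(ihd = 0.5, crrt = 0.3, unstable = 0.2),
                       cl_intercept = 0.22, cl_slope = 0.041,
                       cl_wt_exp = 0.75,
                       rrt_clearance = 0.75,
                       v_per_kg = 0.7,
                       omega_cl = 0.3, omega_v = 0.2,
                       t_inf = 1,
                       comparator = list(dose_mg = 1000, interval = "q12")) {
  cfg <- as.list(environment())
  if (cfg$n_per_group < 1) abort("`n_per_group` must be >= 1.")
  if (cfg$omega_cl < 0 || cfg$omega_v < 0) {
    abort("Variability SDs must be >= 0.")
  }
  # published stratum percentages carry rounding (the default mix sums to
  # 101%); accept mixes within 5 points of 1 and renormalize
  if (!setequal(names(cfg$egfr_mix), RENAL_LEVELS) ||
      abs(sum(cfg$egfr_mix) - 1) > 0.05 || any(cfg$egfr_mix < 0)) {
    abort("`egfr_mix` must be non-negative probabilities over the four renal strata summing to 1.")
  }
  cfg$egfr_mix <- cfg$egfr_mix / sum(cfg$egfr_mix)
  if (abs(sum(cfg$modality_mix) - 1) > 0.05 || any(cfg$modality_mix < 0)) {
    abort("`modality_mix` must be non-negative probabilities summing to 1.")
  }
  cfg$modality_mix <- cfg$modality_mix / sum(cfg$modality_mix)
  if (!cfg$comparator$interval %in% c("q8", "q12", "q24")) {
    abort("`comparator$interval` must be a recurring interval (q8/q12/q24).")
  }
  structure(cfg, class = "sim_config")
}

# eGFR sampling windows per stratum, kept clear of the .5 rounding
# boundaries so the realised (rounded) stratum always matches the draw
EGFR_WINDOWS <- list(
  gt90 = c(91, 150), s50_90 = c(50, 90.4),
  s15_49 = c(15, 49.4), lt15_or_rrt = c(5, 14.4)
)

# invert MDRD4: the creatinine that yields a target eGFR for given covariates
scr_for_egfr <- function(egfr, age_years, sex, black_race) {
  f <- ifelse(parse_sex(sex) == "F", 0.742, 1) *
    ifelse(parse_binary_flag(black_race, "black_race"), 1.210, 1)
  (186 * age_years^-0.203 * f / egfr)^(1 / 1.154)
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` patients from the covariate distributions in `config` (see
#' [sim_config()]). Each patient's renal stratum is sampled from the
#' configured mix, a target eGFR is drawn within the stratum, and serum
#' creatinine is back-solved through the MDRD4 equation so that
#' re-estimating eGFR from the emitted covariates reproduces the intended
#' stratum. Reproducible under a fixed RNG seed.
#'
#' @param config A [sim_config()].
#' @param n Number of patients; defaults to `config$n_per_group`.
#' @param seed Optional integer seed (`set.seed()` applied when given).
#'
#' @return A tibble in the patient CSV schema: `patient_id`, `age_years`,
#'   `sex`, `black_race`, `scr_mg_dl`, `weight_kg`, `renal_modality`.
#' @examples
#' generate_cohort(sim_config(), n = 5, seed = 1)
#' @export
generate_cohort <- function(config = sim_config(), n = config$n_per_group,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  age <- pmax(config$age_min, rnorm(n, config$age_mean, config$age_sd))
  sex <- ifelse(rbinom(n, 1, config$male_frac) == 1, "M", "F")
  black <- rbinom(n, 1, config$black_frac)
  # lognormal weight: sdlog from the median -> upper-quartile ratio
  sdlog <- log(config$weight_iqr_hi / config$weight_median) / qnorm(0.75)
  weight <- rlnorm(n, log(config$weight_median), sdlog)
  stratum <- sample(
    names(config$egfr_mix), n,
    replace = TRUE, prob = config$egfr_mix
  )
  egfr_target <- unname(vapply(
    stratum,
    function(s) runif(1, EGFR_WINDOWS[[s]][1], EGFR_WINDOWS[[s]][2]),
    numeric(1)
  ))
  modality <- ifelse(
    stratum == "lt15_or_rrt",
    sample(
      names(config$modality_mix), n,
      replace = TRUE, prob = config$modality_mix
    ),
    "none"
  )
  tibble::tibble(
    patient_id = sprintf("synth-%04d", seq_len(n)),
    age_years = age,
    sex = sex,
    black_race = black,
    scr_mg_dl = scr_for_egfr(egfr_target, age, sex, black),
    weight_kg = weight,
    renal_modality = modality
  )
}

#' Assign individual one-compartment pharmacokinetic parameters
#'
#' Adds `clearance` (L/h), `volume` (L) and the elimination rate constant
#' `k` (1/h, = clearance/volume) to a patient table. Clearance scales
#' linearly with eGFR for patients with native renal function and is a fixed
#' low typical value for renal-replacement or unstable patients; both
#' clearance and volume carry lognormal between-patient variability.
#'
#' @param data A patient table; `egfr` is computed via [estimate_gfr()] if
#'   absent.
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#'
#' @return `data` with `clearance`, `volume`, `k` and `t_inf` columns added.
#' @export
assign_pk <- function(data, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (!"egfr" %in% names(data)) data <- estimate_gfr(data)
  n <- nrow(data)
  modality <- if ("renal_modality" %in% names(data)) {
    parse_modality(data$renal_modality)
  } else {
    rep("none", n)
  }
  cl_typ <- ifelse(
    modality == "none",
    (config$cl_intercept + config$cl_slope * data$egfr) *
      (data$weight_kg / 70)^config$cl_wt_exp,
    config$rrt_clearance
  )
  data$clearance <- cl_typ * exp(rnorm(n, 0, config$omega_cl))
  data$volume <- config$v_per_kg * data$weight_kg *
    exp(rnorm(n, 0, config$omega_v))
  data$k <- data$clearance / data$volume
  data$t_inf <- config$t_inf
  data
}

#' Steady-state trough of an intermittent intravenous infusion
#'
#' Closed-form one-compartment steady-state concentrations for a dose
#' infused over `t_inf` hours every `interval_h` hours. The end-of-infusion
#' peak is
#' \deqn{C_{max} = \frac{dose/t_{inf}}{CL} \cdot
#'   \frac{1 - e^{-k t_{inf}}}{1 - e^{-k \tau}}}
#' and the trough, sampled just before the next dose, is
#' \eqn{C_{max} e^{-k(\tau - t_{inf})}}. Units: mg and L/h give mg/L, which
#' is numerically identical to mcg/ml.
#'
#' @param dose_mg Dose per administration, mg (> 0).
#' @param interval_h Dosing interval \eqn{\tau}, hours; must exceed `t_inf`.
#' @param clearance Clearance, L/h (> 0).
#' @param volume Volume of distribution, L (> 0).
#' @param t_inf Infusion duration, hours (> 0).
#'
#' @return Steady-state trough concentration(s), mcg/ml.
#' @examples
#' steady_state_trough(1000, 12, clearance = 5, volume = 50)
#' @export
steady_state_trough <- function(dose_mg, interval_h, clearance, volume,
                                t_inf = 1) {
  if (any(dose_mg <= 0) || any(clearance <= 0) || any(volume <= 0) ||
      any(t_inf <= 0)) {
    abort("Dose, clearance, volume and infusion duration must be > 0.")
  }
  if (any(interval_h <= t_inf)) {
    abort("Invalid regimen: the dosing interval must exceed the infusion duration.")
  }
  k <- clearance / volume
  cmax <- (dose_mg / t_inf) / clearance *
    (1 - exp(-k * t_inf)) / (1 - exp(-k * interval_h))
  cmax * exp(-k * (interval_h - t_inf))
}

#' Concentration after a single intravenous infusion
#'
#' One-compartment concentration at `t_h` hours after the start of a single
#' infusion (for `t_h` past the end of the infusion). Used for the random
#' level drawn 24 h after a one-time dose in renal-replacement patients.
#'
#' @inheritParams steady_state_trough
#' @param t_h Sampling time, hours after the start of the infusion; must be
#'   at least `t_inf`.
#'
#' @return Concentration(s), mcg/ml.
#' @export
single_dose_level <- function(dose_mg, t_h, clearance, volume, t_inf = 1) {
  if (any(dose_mg <= 0) || any(clearance <= 0) || any(volume <= 0) ||
      any(t_inf <= 0)) {
    abort("Dose, clearance, volume and infusion duration must be > 0.")
  }
  if (any(t_h < t_inf)) {
    abort("`t_h` must be at or after the end of the infusion.")
  }
  k <- clearance / volume
  (dose_mg / t_inf) / clearance * (1 - exp(-k * t_inf)) *
    exp(-k * (t_h - t_inf))
}

#' Simulate a two-strategy dosing trial
#'
#' Generates a synthetic cohort, doses every patient twice -- once with the
#' nomogram ([recommend_dose()]) and once with the comparator strategy from
#' `config` (default: a flat 1000 mg q12 regardless of weight or renal
#' function) -- and simulates each patient's first measured level with the
#' one-compartment model: the steady-state trough for recurring regimens,
#' or the 24-h post-dose level for the nomogram's single-dose
#' renal-replacement path. The same patients (and the same individual PK
#' parameters) appear in both arms, so strategy differences are purely due
#' to dosing.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed controlling the whole pipeline.
#'
#' @return A tibble in the trough CSV schema, two rows per patient:
#'   `patient_id`, `group` (`"nomogram"` or `"flat_<dose>_<interval>"`),
#'   `trough_mcg_ml`, `weight_kg`, `egfr`, `renal_modality`.
#' @examples
#' trial <- simulate_trial(sim_config(n_per_group = 50), seed = 42)
#' summarize_cohort(trial)
#' @export
simulate_trial <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(config)
  dosed <- assign_pk(recommend_dose(cohort), config)

  recurring <- dosed$interval != "single_dose"
  nomogram_level <- numeric(nrow(dosed))
  nomogram_level[recurring] <- steady_state_trough(
    dosed$dose_mg[recurring],
    unname(INTERVAL_HOURS[as.character(dosed$interval[recurring])]),
    dosed$clearance[recurring], dosed$volume[recurring], config$t_inf
  )
  if (any(!recurring)) {
    nomogram_level[!recurring] <- single_dose_level(
      dosed$dose_mg[!recurring], 24,
      dosed$clearance[!recurring], dosed$volume[!recurring], config$t_inf
    )
  }
  flat <- config$comparator
  flat_level <- steady_state_trough(
    flat$dose_mg, unname(INTERVAL_HOURS[flat$interval]),
    dosed$clearance, dosed$volume, config$t_inf
  )

  base <- dosed[c("patient_id", "weight_kg", "egfr", "renal_modality")]
  dplyr::bind_rows(
    dplyr::mutate(
      base, group = "nomogram", trough_mcg_ml = nomogram_level
    ),
    dplyr::mutate(
      base,
      group = sprintf("flat_%d_%s", flat$dose_mg, flat$interval),
      trough_mcg_ml = flat_level
    )
  )[
    ,
    c(
      "patient_id", "group", "trough_mcg_ml", "weight_kg", "egfr",
      "renal_modality"
    )
  ]
}
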