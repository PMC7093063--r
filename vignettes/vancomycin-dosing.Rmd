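---
title: "Nomogram-based vancomycin dosing: models, conventions, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nomogram-based vancomycin dosing: models, conventions, and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancodose)
```

## The clinical problem

Vancomycin takes roughly 36–48 hours of repeated intravenous dosing to reach
steady state. An initial regimen chosen poorly therefore leaves a critically
ill patient under- or over-exposed for one to two days: troughs below
10 mcg/ml risk treatment failure and selection of intermediate-resistance
*Staphylococcus aureus*, while troughs above 20 mcg/ml add toxicity without
established benefit. `vancodose` implements a protocolised answer: a lookup
nomogram that maps actual body weight and renal function to an initial
regimen, the therapeutic-drug-monitoring (TDM) rules attached to each
regimen, the statistics used to evaluate trough-attainment cohorts, and a
synthetic cohort/pharmacokinetic simulator so the whole pipeline can be
exercised end to end without patient data.

## The dosing engine

### Renal function

Renal function is estimated with the four-variable MDRD equation,

$$\mathrm{eGFR} = 186 \times SCr^{-1.154} \times \mathrm{Age}^{-0.203}
  \times 0.742^{[\mathrm{female}]} \times 1.210^{[\mathrm{Black}]},$$

in ml/min/1.73 m². The formula is already indexed to body surface area, so
no renormalisation is applied. Creatinine is accepted **only** in mg/dL;
a µmol/L value passed accidentally would be ~88-fold too large, and we
prefer a loud unit discipline to a silent heuristic conversion.

Two conventions close gaps the integer-labelled grid leaves open:

* **Rounding.** eGFR and weight are rounded to the nearest integer with
  ties away from zero before binning, so the bins `>90`, `50–90`, `15–49`,
  `<15` (and `<60`, `60–80`, `81–100`, `>100` kg) partition the positive
  reals with no gaps: an eGFR of 90.4 is `50–90`, 90.5 is `>90`.
* **Renal replacement dominates.** Intermittent hemodialysis, continuous
  renal replacement, or a caller-supplied "unstable renal function" flag
  force the lowest renal stratum regardless of the computed eGFR, because
  creatinine under renal replacement does not reflect native clearance.
  Instability is an input flag, not something detected from the data: the
  engine computes a point estimate and does not track creatinine trends.

### The regimen grid

The per-administration dose depends only on the weight stratum
(750 / 1000 / 1250 / 1500 mg for `<60` / `60–80` / `81–100` / `>100` kg, i.e.
roughly 15–20 mg/kg on a convenient 250 mg grid) and the interval only on
the renal stratum (q8 / q12 / q24 / single dose). The heaviest, fastest
cell — 1500 mg q8 — is exactly the protocol's safety cap of 4500 mg/day;
no recurring regimen can exceed it by construction, which the test suite
verifies by exhaustive enumeration and randomized probing.

### Monitoring and the random-level rule

q8/q12 regimens draw a steady-state trough 30 minutes before the 4th dose;
q24 regimens before the 3rd dose (slower elimination means fewer doses to
steady state within the same wall-clock window). Single-dose regimens are
followed by a *random* level — 24 h after the dose, or 2 h after the next
hemodialysis session — interpreted against a 20 mcg/ml threshold: below 20
the dose is repeated, at or above 20 the dose is held and the level
rechecked (12 h later, or after the next dialysis). A level of exactly
20 mcg/ml is assigned to the **hold** arm: the protocol text covers only
strict inequalities, and holding is the conservative resolution of the tie.

## Trough classification and cohort evaluation

Troughs partition as `< 10` subtherapeutic, `10–20` therapeutic (closed on
both ends), `> 20` supratherapeutic. Cohort summaries report per-category
counts and proportions plus the median and IQR (quartiles by linear
interpolation between order statistics — the convention is stated because
quantile definitions differ and the choice is otherwise invisible).

`compare_cohorts()` builds, for each category, the group × (in/out of
category) table and tests independence. For two-group comparisons the
defaults are pinned per category: the **continuity-corrected** 2×2
chi-square for the subtherapeutic (primary) outcome and the uncorrected
Pearson chi-square for the two secondary outcomes. These are the variants
that reproduce the protocol evaluation's published p-values from its
integer counts (0.003, 0.01, 0.96), and `run_paper_report()` regenerates
exactly those numbers from the fixtures shipped in `paper_fixtures()`;
naming the variant per comparison was preferred over guessing a single
software default for all of them. All defaults are overridable through
`comparison_config()`. Subgroup analyses (by weight or eGFR stratum) use
the uncorrected k×2 Pearson chi-square throughout.

The packaged cohort-composition fixtures are reconstructed from published
percentages and group sizes; each count triple is the unique set of
integers summing to the group size within 0.5 percentage points of the
printed proportions (the arithmetic is recorded beside the numbers in
`paper_fixtures()`'s source).

## The statistical battery

The tests are implemented from first principles (the standard library
implementations serve as independent cross-checks in the test suite):

* **Pearson chi-square**: $X^2=\sum (O-E)^2/E$, expected counts from the
  margins; Yates correction shrinks $|O-E|$ by 0.5 (never past zero) for
  2×2 tables; p from the $\chi^2_{(r-1)(c-1)}$ upper tail.
* **Fisher's exact test** (2×2): two-sided p as the total hypergeometric
  probability of all tables with the observed margins whose probability
  does not exceed the observed table's, with a $1+10^{-7}$ relative
  tolerance when comparing probabilities so floating-point noise cannot
  break ties.
* **Mann-Whitney U** from midranks; exact by enumerating all
  $\binom{n_1+n_2}{n_1}$ splits when $n_1+n_2 \le 10$ (a permutation
  enumeration, so it stays valid under ties), otherwise a normal
  approximation with tie-corrected variance and 0.5 continuity correction.
  The cutoff of 10 keeps the enumeration at ≤252 splits and is overridable.
* **Kruskal-Wallis** with tie correction; when every observation is
  identical the correction denominator vanishes and H is *defined* as 0
  with p = 1 — there is no rank variation to explain.
* **Two-proportion sample size**: pooled null / unpooled alternative
  normal approximation,
  $n = \left(z_{1-\alpha/2}\sqrt{2\bar p\bar q} +
  z_{1-\beta}\sqrt{p_1q_1+p_2q_2}\right)^2/(p_1-p_2)^2$, rounded to the
  *nearest* integer. Nearest (rather than ceiling) rounding is what makes
  the protocol's own planning case — 34% to 14% subtherapeutic, 80% power,
  two-sided α = 0.05 — come out at its stated 70 per group (the raw value
  is 70.39).

All p-values are two-sided and kept at full precision; rounding to the
two decimals seen in reports happens only at display time.

## The synthetic test bed

`sim_config()` / `generate_cohort()` / `assign_pk()` / `simulate_trial()`
exist so the dosing engine and evaluation pipeline can be tested end to
end. The covariate generator emulates the *marginal* summaries of an adult
medical-ICU vancomycin population: median age ≈ 53 (normal, SD 16,
truncated at 18), 56% male, lognormal weight with median 78 kg and upper
quartile 96 kg, and a renal mix of roughly 28/39/19/15% across the
`>90` / `50–90` / `15–49` / `<15-or-RRT` strata. Published stratum
percentages carry rounding (the default mix sums to 101%), so mixes within
five points of 1 are accepted and renormalised. Each patient's stratum is
sampled first, a target eGFR drawn inside it (windows stop short of the .5
rounding boundaries so the realised stratum always matches), and serum
creatinine back-solved through the MDRD equation — so the generated CSV
columns are ordinary covariates, yet the stratum mix hits the configured
targets by construction, up to multinomial noise.

What it deliberately does **not** emulate: the joint covariate
distribution (weight, age and renal function are sampled independently),
within-patient creatinine dynamics, dialysis-session kinetics (renal
replacement is reduced to a fixed low clearance and the single-dose path),
or any real trough dataset. Passing tests therefore demonstrate that the
pipeline is internally consistent and directionally sensible — not that
the simulator predicts clinical trough distributions.

The PK layer is a one-compartment intermittent-infusion model. At steady
state the end-of-infusion peak and the trough are

$$C_{\max} = \frac{D/t_{inf}}{CL}\,
  \frac{1-e^{-k t_{inf}}}{1-e^{-k\tau}}, \qquad
  C_{trough} = C_{\max}\, e^{-k(\tau - t_{inf})},$$

with $k = CL/V$; mg and L/h give mg/L ≡ mcg/ml. The closed form is checked
against an independent superposition-of-doses oracle to <0.1% in the test
suite. Individual parameters follow the shape population vancomycin models
typically take — clearance linear in renal function and allometric in body
size, $CL = (0.22 + 0.041\,\mathrm{eGFR})\,(W/70)^{0.75} e^{\eta}$ L/h
(about 0.7 × creatinine clearance for a 70 kg reference patient), volume
$0.7\,\mathrm{L/kg} \times W\, e^{\eta'}$, lognormal variabilities
$\omega = 0.3$ and $\omega' = 0.2$, one-hour infusions, and a fixed
0.75 L/h for renal-replacement or unstable patients. These constants are
plausible population values chosen for the simulator, not estimates from
any dataset, and no published number is asserted from them. The allometric
weight term matters: without it, clearance per kilogram is higher in small
patients and a flat comparator dose spuriously beats weight-scaled dosing
at the low-weight extreme.

`simulate_trial()` doses the *same* simulated patients (same individual PK)
once with the nomogram and once with a comparator strategy — by default a
flat 1000 mg q12 for everyone — so arm differences are attributable to the
dosing rule alone. Single-dose patients contribute their 24-h post-dose
level in place of a steady-state trough.

## Numerical choices and problem sizes

* Rounding is half-away-from-zero everywhere a grid label is matched
  (base `round()`'s banker's rounding would map 90.5 to 90).
* Degenerate contingency tables (an empty margin) are errors, not NaNs;
  degenerate subgroup strata are dropped with a warning naming the stratum.
* Determinism: every stochastic entry point takes an optional seed, and
  the trial pipeline is byte-reproducible under a fixed seed.
* The test suite sizes its simulations for seconds-scale runs chosen to
  make sampling error negligible relative to the tolerances tested:
  cohort-marginal checks at n = 5000 (binomial SE ≈ 0.7 points against
  3–5-point tolerances), variability recovery at 10,000 draws, oracle
  agreement over 100–1000 randomized cases.

## Known limitations

The engine stops at the initial regimen plus the first-level decision; no
adjustment nomogram is encoded because the protocol defines none. AUC:MIC
targets are the pharmacodynamic rationale for the 10–20 mcg/ml window but
are not computed. Continuous-infusion dosing, doses above 4500 mg/day,
alternative eGFR equations (CKD-EPI, Cockcroft-Gault) and pediatric
dosing are out of scope. The evaluation layer reproduces count-based
statistics exactly, but cohort medians/IQRs of real trough data require
patient-level concentrations that integer fixtures cannot reconstruct.
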