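# Independent oracles used to check the package's implementations.
# Each is written as a direct, naive evaluation of the defining formula or a
# brute-force enumeration, sharing no code with the implementation under test.

# MDRD4 with the coefficients parsed from a string, evaluated term by term
oracle_mdrd4 <- function(scr, age, female, black) {
  k <- as.numeric(strsplit("186 -1.154 -0.203 0.742 1.210", " ")[[1]])
  out <- numeric(length(scr))
  for (i in seq_along(scr)) {
    v <- k[1]
    v <- v * exp(k[2] * log(scr[i]))
    v <- v * exp(k[3] * log(age[i]))
    if (female[i]) v <- v * k[4]
    if (black[i]) v <- v * k[5]
    out[i] <- v
  }
  out
}

# chi-square by explicit double loop over cells
oracle_chisq_stat <- function(m, correct = FALSE) {
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      e <- sum(m[i, ]) * sum(m[, j]) / n
      d <- abs(m[i, j] - e)
      if (correct) d <- max(d - 0.5, 0)
      stat <- stat + d^2 / e
    }
  }
  stat
}

# Fisher 2x2 by enumerating every table compatible with the margins
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); n <- sum(m)
  tbl_prob <- function(a) {
    # hypergeometric probability of table with top-left cell a
    b <- r1 - a; c_ <- c1 - a; d <- r2 - c_
    if (b < 0 || c_ < 0 || d < 0) return(0)
    exp(
      lchoose(c1, a) + lchoose(n - c1, b) - lchoose(n, r1)
    )
  }
  p_obs <- tbl_prob(m[1, 1])
  total <- 0
  for (a in 0:min(r1, c1)) {
    p <- tbl_prob(a)
    if (p > 0 && p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  total
}

# Mann-Whitney U by pair counting; exact p by enumerating rank splits
oracle_mwu_u <- function(x, y) {
  u <- 0
  for (xi in x) {
    for (yi in y) {
      if (xi > yi) u <- u + 1 else if (xi == yi) u <- u + 0.5
    }
  }
  u
}

oracle_mwu_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- oracle_mwu_u(x, y)
  splits <- utils::combn(length(pooled), n1)
  hits <- 0
  for (j in seq_len(ncol(splits))) {
    xs <- pooled[splits[, j]]
    ys <- pooled[-splits[, j]]
    if (abs(oracle_mwu_u(xs, ys) - mu) >= abs(u_obs - mu) - 1e-9) {
      hits <- hits + 1
    }
  }
  hits / ncol(splits)
}

# Kruskal-Wallis H by direct evaluation of the rank-variance formula
oracle_kw_h <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- rank(pooled)
  offsets <- c(0, cumsum(lengths(groups)))
  rbar_all <- (n + 1) / 2
  h <- 0
  for (i in seq_along(groups)) {
    ri <- r[(offsets[i] + 1):offsets[i + 1]]
    h <- h + length(ri) * (mean(ri) - rbar_all)^2
  }
  h <- 12 / (n * (n + 1)) * h
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# steady-state trough by superposing many single-dose curves
oracle_superposition_trough <- function(dose_mg, interval_h, clearance,
                                        volume, t_inf = 1, n_doses = 400) {
  k <- clearance / volume
  total <- 0
  for (j in seq_len(n_doses)) {
    t_since_start <- j * interval_h          # time from dose start to sample
    total <- total +
      (dose_mg / t_inf) / clearance * (1 - exp(-k * t_inf)) *
        exp(-k * (t_since_start - t_inf))
  }
  total
}

# expand a (subtherapeutic, therapeutic, supratherapeutic) count triple into
# a trough vector with representative concentrations in each band
troughs_from_counts <- function(n_sub, n_ther, n_supra, group) {
  tibble::tibble(
    patient_id = sprintf("%s-%03d", group, seq_len(n_sub + n_ther + n_supra)),
    group = group,
    trough_mcg_ml = c(rep(5, n_sub), rep(15, n_ther), rep(25, n_supra))
  )
}
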