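#' @title The cohort-comparison statistical battery
#' @description
#' The evaluation layer rests on five procedures implemented here from first
#' principles: the Pearson chi-square test for independence (with optional
#' Yates continuity correction for 2 x 2 tables), Fisher's exact test for
#' 2 x 2 tables, the Mann-Whitney U test, the Kruskal-Wallis one-way
#' analysis of variance by ranks, and a two-proportion sample-size
#' calculation. All p-values are two-sided and returned at full precision;
#' any display rounding belongs to the report layer.
#' @name stats-battery
NULL

new_vanco_test <- function(statistic, df, p_value, method,
                           continuity_corrected = FALSE, ...) {
  structure(
    list(
      statistic = statistic, df = df,
      p_value = min(max(p_value, 0), 1),
      method = method, continuity_corrected = continuity_corrected,
      ...
    ),
    class = "vanco_test"
  )
}

#' @export
print.vanco_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic) && !is.na(x$statistic)) {
    cat(sprintf("statistic = %.4f", x$statistic))
    if (!is.null(x$df) && !is.na(x$df)) cat(sprintf(", df = %d", x$df))
    cat(", ")
  }
  cat(sprintf("p-value = %.4g\n", x$p_value))
  invisible(x)
}

as_count_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("Counts must be a numeric matrix or data frame.")
  }
  if (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    abort("Counts must be finite non-negative integers.")
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort("A contingency table needs at least 2 rows and 2 columns.")
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort("Degenerate table: every row and column margin must be positive.")
  }
  x
}

#' Pearson chi-square test for independence
#'
#' Computes \eqn{X^2 = \sum (O - E)^2 / E} with expected counts
#' \eqn{E_{ij} = n_{i.} n_{.j} / N} from the margins, and the p-value from
#' the upper tail of the chi-square distribution with
#' \eqn{(r-1)(c-1)} degrees of freedom. For 2 x 2 tables
#' `correct = TRUE` applies the Yates continuity correction, shrinking each
#' \eqn{|O - E|} by 0.5 (never past zero) before squaring.
#'
#' @param x An r x c matrix (or data frame) of non-negative integer counts
#'   with positive margins.
#' @param correct Apply the continuity correction (2 x 2 tables only).
#'
#' @return A `vanco_test` object: `statistic`, `df`, `p_value`, `method`,
#'   `continuity_corrected`. Use [tidy()] for a one-row tibble.
#' @examples
#' chisq_independence(rbind(c(6, 13), c(7, 7), c(36, 14)))
#' chisq_independence(rbind(c(24, 51), c(14, 94)), correct = TRUE)
#' @export
chisq_independence <- function(x, correct = FALSE) {
  x <- as_count_matrix(x)
  if (correct && !all(dim(x) == c(2, 2))) {
    abort("The continuity correction applies to 2 x 2 tables only.")
  }
  n <- sum(x)
  expected <- outer(rowSums(x), colSums(x)) / n
  dev <- abs(x - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  new_vanco_test(
    statistic = stat, df = df,
    p_value = pchisq(stat, df, lower.tail = FALSE),
    method = if (correct) {
      "Pearson chi-square test (continuity corrected)"
    } else {
      "Pearson chi-square test"
    },
    continuity_corrected = correct,
    expected = expected
  )
}

#' Fisher's exact test for a 2 x 2 table
#'
#' With all margins fixed, the count in cell (1,1) follows a hypergeometric
#' distribution. The two-sided p-value is the total probability of every
#' table (with those margins) whose probability does not exceed that of the
#' observed table, the usual small-sample definition.
#'
#' @param x A 2 x 2 matrix (or data frame) of non-negative integer counts
#'   with positive margins.
#'
#' @return A `vanco_test` object with `p_value` (no asymptotic statistic or
#'   degrees of freedom; `estimate` holds the sample odds ratio).
#' @examples
#' fisher_exact(rbind(c(2, 0), c(0, 2)))
#' @export
fisher_exact <- function(x) {
  x <- as_count_matrix(x)
  if (!all(dim(x) == c(2, 2))) {
    abort("Fisher's exact test is implemented for 2 x 2 tables.")
  }
  r1 <- sum(x[1, ]); c1 <- sum(x[, 1]); n <- sum(x)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(x[1, 1], c1, n - c1, r1)
  # relative tolerance guards against ties broken by floating-point noise
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_vanco_test(
    statistic = NA_real_, df = NA_integer_, p_value = p,
    method = "Fisher's exact test",
    estimate = (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  )
}

midranks <- function(v) rank(v, ties.method = "average")

tie_counts <- function(v) as.numeric(table(v))

#' Mann-Whitney U test
#'
#' Ranks the pooled samples with midranks and computes
#' \eqn{U = R_x - n_1(n_1+1)/2}, the number of (x, y) pairs with x ahead of
#' y (ties counting one half). With 10 or fewer total observations
#' (overridable via `exact`) the two-sided p-value is computed exactly by
#' enumerating all \eqn{\binom{n_1+n_2}{n_1}} assignments of the pooled
#' values to the first sample and counting those at least as far from the
#' null mean \eqn{n_1 n_2 / 2} as observed -- a permutation enumeration that
#' remains valid under ties. Otherwise a normal approximation is used with
#' the tie-corrected variance
#' \eqn{\sigma^2 = \frac{n_1 n_2}{12}\left(N + 1 - \frac{\sum (t^3 - t)}{N(N-1)}\right)}
#' and a 0.5 continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact enumeration;
#'   default `NULL` enumerates when \eqn{n_1 + n_2 \le 10}.
#'
#' @return A `vanco_test` object; `statistic` is U for the first sample.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' mann_whitney(rnorm(20), rnorm(20, 1))
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0 || anyNA(c(x, y))) {
    abort("Both samples must be non-empty with no missing values.")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  u_of <- function(idx) {
    sum(midranks(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  exact <- exact %||% (n <= 10)
  if (exact) {
    splits <- combn(n, n1)
    us <- apply(splits, 2, u_of)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    ties <- tie_counts(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(abs(u - mu) - 0.5, 0) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "Mann-Whitney U test (normal approximation, tie corrected)"
  }
  new_vanco_test(
    statistic = u, df = NA_integer_, p_value = p, method = method,
    n = c(n1 = n1, n2 = n2)
  )
}

#' Kruskal-Wallis rank analysis of variance
#'
#' Computes
#' \eqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar r_i - \bar r)^2}
#' from midranks of the pooled data, divided by the tie correction
#' \eqn{C = 1 - \sum (t^3 - t) / (N^3 - N)}, with the p-value from the
#' chi-square upper tail on \eqn{k - 1} degrees of freedom. When every
#' observation is identical the tie-correction denominator vanishes; H is
#' then defined as 0 with p = 1 (no rank variation to explain).
#'
#' @param x A list of non-empty numeric samples, or a numeric vector
#'   accompanied by `g`.
#' @param g Optional grouping vector parallel to a numeric `x`.
#'
#' @return A `vanco_test` object.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
#' @export
kruskal_wallis <- function(x, g = NULL) {
  if (!is.list(x)) {
    if (is.null(g)) abort("Provide a list of samples, or `x` with `g`.")
    x <- split(as.numeric(x), g)
  }
  x <- lapply(x, as.numeric)
  if (length(x) < 2 || any(lengths(x) == 0) || anyNA(unlist(x))) {
    abort("Need >= 2 non-empty groups with no missing values.")
  }
  k <- length(x)
  pooled <- unlist(x, use.names = FALSE)
  n <- length(pooled)
  r <- midranks(pooled)
  grp <- rep(seq_len(k), lengths(x))
  rbar <- tapply(r, grp, mean)
  h <- 12 / (n * (n + 1)) * sum(lengths(x) * (rbar - (n + 1) / 2)^2)
  ties <- tie_counts(pooled)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction <= 0) {
    h <- 0
    p <- 1
  } else {
    h <- h / correction
    p <- pchisq(h, k - 1L, lower.tail = FALSE)
  }
  new_vanco_test(
    statistic = h, df = k - 1L, p_value = p,
    method = "Kruskal-Wallis rank sum test"
  )
}

#' Sample size for comparing two independent proportions
#'
#' Normal-approximation per-group sample size for a two-sided test of
#' \eqn{H_0: p_1 = p_2}, with the null standard deviation pooled at
#' \eqn{\bar p = (p_1 + p_2)/2} and the alternative unpooled:
#' \deqn{n = \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_{1-\beta}\sqrt{p_1 q_1 + p_2 q_2}\right)^2}{(p_1 - p_2)^2}}
#' rounded to the nearest integer. The protocol's own power computation --
#' a drop from 34% to 14% subtherapeutic troughs, 80% power, two-sided
#' \eqn{\alpha} = 0.05 -- gives 70 patients per group.
#'
#' @param p1,p2 The two proportions, in (0, 1) and unequal.
#' @param alpha Two-sided significance level; default 0.05.
#' @param power Target power; default 0.80.
#'
#' @return A one-row tibble: `n_per_group` (integer), `n_raw` (unrounded),
#'   `p1`, `p2`, `alpha`, `power`.
#' @examples
#' two_proportion_sample_size(0.34, 0.14)
#' @export
two_proportion_sample_size <- function(p1, p2, alpha = 0.05, power = 0.80) {
  vals <- c(p1 = p1, p2 = p2, alpha = alpha, power = power)
  if (any(vals <= 0) || any(vals >= 1)) {
    abort("p1, p2, alpha and power must all lie strictly in (0, 1).")
  }
  if (p1 == p2) {
    abort("p1 and p2 must differ: the required sample size diverges.")
  }
  pbar <- (p1 + p2) / 2
  n <- (qnorm(1 - alpha / 2) * sqrt(2 * pbar * (1 - pbar)) +
    qnorm(power) * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  tibble::tibble(
    n_per_group = as.integer(round_half_up(n)), n_raw = n,
    p1 = p1, p2 = p2, alpha = alpha, power = power
  )
}
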