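test_that("Pearson chi-square reproduces hand-checked tables", {
  # 3 x 2 therapeutic-attainment table, mid-weight stratum
  res <- chisq_independence(rbind(c(6, 13), c(7, 7), c(36, 14)))
  expect_equal(res$statistic, oracle_chisq_stat(rbind(c(6, 13), c(7, 7), c(36, 14))))
  expect_equal(res$statistic, 9.8705, tolerance = 1e-4)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, 0.007189, tolerance = 1e-3)

  # supratherapeutic 2 x 2: no difference
  res <- chisq_independence(rbind(c(13, 62), c(19, 89)))
  expect_equal(round(res$p_value, 2), 0.96)

  # continuity-corrected primary-outcome 2 x 2
  res <- chisq_independence(rbind(c(24, 51), c(14, 94)), correct = TRUE)
  expect_true(res$continuity_corrected)
  expect_equal(res$p_value, 0.003313, tolerance = 1e-3)
})

test_that("chi-square is zero with p = 1 on proportional rows", {
  res <- chisq_independence(rbind(c(10, 20, 30), c(5, 10, 15)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("chi-square matches the reference implementation on random tables", {
  set.seed(21)
  for (i in 1:25) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    m <- matrix(rpois(r * c, 8) + 1, r, c)
    got <- chisq_independence(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    if (r == 2 && c == 2) {
      got_c <- chisq_independence(m, correct = TRUE)
      ref_c <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
      expect_equal(got_c$p_value, ref_c$p.value, tolerance = 1e-12)
    }
    # invariance under row/column permutation
    perm <- m[sample(r), sample(c)]
    expect_equal(chisq_independence(perm)$statistic, got$statistic,
                 tolerance = 1e-12)
  }
})

test_that("degenerate tables are rejected", {
  expect_error(chisq_independence(rbind(c(0, 0), c(3, 4))), "margin")
  expect_error(chisq_independence(rbind(c(1, 0), c(2, 0))), "margin")
  expect_error(chisq_independence(rbind(c(-1, 2), c(3, 4))), "non-negative")
  expect_error(chisq_independence(matrix(1:3, 1)), "2 rows")
  expect_error(
    chisq_independence(rbind(c(1, 2, 3), c(4, 5, 6)), correct = TRUE),
    "2 x 2"
  )
})

test_that("Fisher's exact test matches small-table enumeration", {
  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1)))$p_value, 1.0)
  expect_equal(fisher_exact(rbind(c(2, 0), c(0, 2)))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5)))$p_value, 1.0)
})

test_that("Fisher's exact p equals brute-force enumeration for N <= 40", {
  set.seed(31)
  for (i in 1:40) {
    repeat {
      m <- matrix(rpois(4, 4), 2, 2)
      if (sum(m) <= 40 && all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    expect_equal(fisher_exact(m)$p_value, oracle_fisher_p(m),
                 tolerance = 1e-10)
    expect_equal(fisher_exact(m)$p_value,
                 stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("Mann-Whitney U reproduces enumerated exact p-values", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  # identical multisets: U at its null mean, p = 1
  x <- c(3, 1, 4, 1)
  res <- mann_whitney(x, x)
  expect_equal(res$statistic, length(x)^2 / 2)
  expect_equal(res$p_value, 1)
})

test_that("exact Mann-Whitney equals rank-split enumeration with ties", {
  set.seed(41)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)  # replacement forces ties
    y <- sample(1:6, n2, replace = TRUE)
    res <- mann_whitney(x, y)
    expect_equal(res$statistic, oracle_mwu_u(x, y))
    expect_equal(res$p_value, oracle_mwu_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney matches the reference approximation", {
  set.seed(51)
  for (i in 1:10) {
    x <- round(rnorm(15, 10, 3), 1)
    y <- round(rnorm(20, 12, 3), 1)
    got <- mann_whitney(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    )
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis H matches the direct rank formula and reference", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(groups)
  expect_equal(res$statistic, oracle_kw_h(groups), tolerance = 1e-12)
  expect_equal(res$df, 2L)

  set.seed(61)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) sample(1:8, sample(3:8, 1), replace = TRUE))
    got <- kruskal_wallis(g)
    ref <- stats::kruskal.test(unlist(g), rep(1:3, lengths(g)))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z (no ties)", {
  set.seed(71)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  h <- kruskal_wallis(list(x, y))$statistic
  u <- mann_whitney(x, y)$statistic
  n1 <- 12; n2 <- 15; n <- n1 + n2
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(h, z^2, tolerance = 1e-12)
})

test_that("Kruskal-Wallis on all-identical data is defined as H = 0, p = 1", {
  res <- kruskal_wallis(list(rep(4, 3), rep(4, 5), rep(4, 2)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
})

test_that("all tests return two-sided p-values in [0, 1]", {
  set.seed(81)
  ps <- c(
    chisq_independence(matrix(rpois(4, 5) + 1, 2))$p_value,
    fisher_exact(matrix(rpois(4, 5) + 1, 2))$p_value,
    mann_whitney(rnorm(8), rnorm(8))$p_value,
    mann_whitney(rnorm(30), rnorm(30, 3))$p_value,
    kruskal_wallis(list(rnorm(5), rnorm(5), rnorm(5)))$p_value
  )
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("the planning sample-size formula gives 70 per group for the protocol", {
  res <- two_proportion_sample_size(0.34, 0.14, alpha = 0.05, power = 0.80)
  expect_equal(res$n_per_group, 70L)
  expect_equal(res$n_raw, 70.3912, tolerance = 1e-4)
  # frozen from direct evaluation of the formula (19.3808 unrounded)
  expect_equal(two_proportion_sample_size(0.50, 0.10)$n_per_group, 19L)
})

test_that("required sample size increases with target power", {
  n <- vapply(
    c(0.5, 0.7, 0.8, 0.9, 0.99),
    function(p) two_proportion_sample_size(0.34, 0.14, power = p)$n_raw,
    numeric(1)
  )
  expect_true(all(diff(n) > 0))
  expect_error(two_proportion_sample_size(0.3, 0.3), "diverge")
  expect_error(two_proportion_sample_size(0, 0.3), "strictly")
})

test_that("tidy and glance return one-row test summaries", {
  res <- chisq_independence(rbind(c(24, 51), c(14, 94)), correct = TRUE)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(
    td, c("statistic", "df", "p.value", "method", "continuity_corrected")
  )
  expect_true(td$continuity_corrected)
  expect_equal(glance(res)$p.value, res$p_value)
})
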