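test_that("summaries reproduce the packaged per-participant tables", {
  t1 <- load_rmse_table("scannability")
  expect_equal(nrow(t1), 5L)
  expect_identical(mean_range_label(t1$rmse_sphere), "0.24 (0.23-0.28)")
  s <- summarize_values(t1$rmse_sphere)
  expect_equal(s$mean, mean(c(0.23, 0.28, 0.23, 0.24, 0.24)))
  # cross column: arithmetic mean is 0.354 -> rounds 0.35, not the printed 0.36
  expect_identical(mean_range_label(t1$rmse_cross), "0.35 (0.33-0.40)")

  t2 <- load_rmse_table("in_face")
  expect_equal(nrow(t2), 10L)
  expect_identical(mean_range_label(t2$rmse_sphere), "0.32 (0.19-0.41)")
  expect_identical(mean_range_label(t2$rmse_cross), "0.36 (0.25-0.46)")

  cst <- summarize_values(c(0.3, 0.3, 0.3))
  expect_equal(cst$sd, 0)
  expect_equal(cst$variance, 0)
  expect_error(summarize_values(numeric(0)), "empty")
})

test_that("signed-rank statistic and exact p match enumeration", {
  t2 <- load_rmse_table("in_face")
  res <- wilcoxon_signed_rank(paired_samples(t2$rmse_sphere, t2$rmse_cross))
  expect_equal(res$W_plus, 13)          # zeros dropped, tied |d|=0.02 averaged
  expect_equal(res$n_effective, 8L)
  expect_equal(res$p_two_sided,
               enum_signed_rank_p(t2$rmse_sphere - t2$rmse_cross),
               tolerance = 1e-12)
  # tie-free n = 6 against the 2^6 enumeration oracle
  set.seed(5)
  for (rep in 1:5) {
    d <- round(rnorm(6, 0.1, 1), 3)
    if (any(d == 0) || any(duplicated(abs(d)))) next
    got <- wilcoxon_signed_rank(d, rep(0, 6), mode = "exact")
    expect_equal(got$p_two_sided, enum_signed_rank_p(d), tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)),
               class = "fiducialign_undefined_test")
})

test_that("zero policies and approximation modes behave as documented", {
  a <- c(0.5, 0.4, 0.3, 0.2, 0.9, 0.8)
  b <- c(0.5, 0.1, 0.5, 0.1, 0.2, 0.9)   # one zero difference
  drop <- wilcoxon_signed_rank(a, b, zero_policy = "drop")
  pratt <- wilcoxon_signed_rank(a, b, zero_policy = "pratt")
  expect_equal(drop$n_effective, 5L)
  expect_equal(pratt$n_effective, 5L)
  expect_gte(pratt$W_plus, drop$W_plus)  # zero takes the lowest rank in pratt
  # normal approximation is close to exact at moderate n
  set.seed(8)
  d <- rnorm(15, 0.3, 1)
  pe <- wilcoxon_signed_rank(d, rep(0, 15), mode = "exact")$p_two_sided
  pn <- wilcoxon_signed_rank(d, rep(0, 15), mode = "normal_approx")$p_two_sided
  expect_lt(abs(pe - pn), 0.02)
})

test_that("exact rank-sum test matches enumeration and edge conventions", {
  t1 <- load_rmse_table("scannability")
  res <- mann_whitney_exact(t1$rmse_sphere, t1$rmse_cross)
  expect_equal(res$U, 0)                       # complete separation
  expect_equal(res$p_two_sided, 2 / 252, tolerance = 1e-12)
  expect_lt(res$p_two_sided, 0.008)
  # identical multisets: U = n^2/2 and p capped at 1
  same <- mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 9 / 2)
  expect_equal(same$p_two_sided, 1.0)
  # any 3-vs-3 input matches the 20-assignment enumeration
  set.seed(12)
  for (rep in 1:5) {
    a <- round(runif(3), 2); b <- round(runif(3), 2)
    expect_equal(mann_whitney_exact(a, b)$p_two_sided, enum_rank_sum_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_exact(numeric(0), 1), "non-empty")
  expect_error(mann_whitney_exact(rnorm(15), rnorm(15)), "<= 20")
})

test_that("repetition analysis reports consistent variance", {
  expect_error(repetition_analysis(0.3), "at least 2")
  r <- repetition_analysis(c(0.2, 0.2, 0.2))
  expect_equal(r$variance, 0)
  set.seed(3)
  x <- rnorm(10, 0.27, 0.078)
  s <- repetition_analysis(x)
  expect_equal(s$variance, s$sd^2, tolerance = 1e-12)
  expect_true(s$min <= s$mean && s$mean <= s$max)
  # the published sd of 0.078 implies a variance that prints as 0.006
  expect_equal(round_half_up(0.078^2, 3), 0.006)
  # permutation invariance
  expect_equal(unclass(summarize_values(rev(x))), unclass(summarize_values(x)))
})
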