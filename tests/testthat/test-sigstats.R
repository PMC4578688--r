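# Significance machinery: tails, permutation, tables, FDR, hybrid.

test_that("tail_prob matches the frozen reference values and limits", {
  expect_equal(tail_prob(2.0), 0.1815, tolerance = 1e-3)
  expect_equal(tail_prob(3.0), 0.0108, tolerance = 1e-2)
  # large x: vanishing tail; small x: clamped into [0, 1]
  expect_lt(tail_prob(50), 1e-300)
  expect_gte(tail_prob(0.05), 0)
  expect_lte(tail_prob(0.05), 1)
  expect_error(tail_prob(0), "x")
  expect_error(tail_prob(-2), "x")
})

test_that("theta and resummed representations agree where both are accurate", {
  for (x in seq(0.8, 4, by = 0.2)) {
    expect_equal(tail_prob(x, method = "theta"),
                 tail_prob(x, method = "resummed"), tolerance = 1e-11)
  }
})

test_that("delay adjustment is the independence power identity", {
  for (x in c(1.5, 2, 2.5, 3)) {
    L <- tail_prob(x)
    for (D in 0:3) {
      expect_equal(tail_prob_delay(x, D), 1 - (1 - L)^(2 * D + 1),
                   tolerance = 1e-12)
    }
  }
  expect_identical(tail_prob_delay(2, 0), tail_prob(2))
})

test_that("tails are decreasing and bounded on the useful range", {
  xs <- seq(0.6, 6, by = 0.1)
  for (D in c(0L, 2L)) {
    p <- vapply(xs, tail_prob_delay, 0, D = D)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(diff(p[xs >= 1]) < 0))
  }
})

test_that("approx_pvalue scales the score and handles edge cases", {
  # score chosen so the scaled statistic is exactly 2.0
  m <- 80L
  s <- round(2 * sqrt(1.25 * m))
  expect_equal(approx_pvalue(s, m, 1.25, D = 0),
               tail_prob(s / sqrt(1.25 * m)))
  expect_identical(approx_pvalue(0L, 50L, 1.25), 1)
  expect_error(approx_pvalue(5, 4, 1.25), "exceed")
  expect_error(approx_pvalue(3, 10, -1), "sigma2")
})

test_that("perm_pvalue: bounds, ties, and power on a perfect match", {
  # constant series: every permutation ties the zero observed score
  p <- perm_pvalue(rep(1, 10), rnorm(10), t = 0, D = 0, B = 50, seed = 1)
  expect_equal(p, 1)
  # identical strictly monotone series: observed score is maximal
  x <- seq_len(20) + 0
  expect_lte(perm_pvalue(x, x, t = 0, D = 0, B = 999, seed = 2), 0.05)
  # add-one bound and determinism
  set.seed(99); a <- rnorm(15); b <- rnorm(15)
  p1 <- perm_pvalue(a, b, B = 200, seed = 7)
  expect_gte(p1, 1 / 201)
  expect_lte(p1, 1)
  expect_identical(p1, perm_pvalue(a, b, B = 200, seed = 7))
  expect_error(perm_pvalue(a, b, B = 0), "B")
})

test_that("p-value table lookups are bit-identical to direct evaluation", {
  m <- 40L
  tab <- build_pvalue_table(m, 1.25, D = 1)
  expect_identical(lookup_pvalue(tab, 0L), 1)
  direct <- vapply(0:m, approx_pvalue, 0, m = m, sigma2 = 1.25, D = 1L)
  expect_identical(lookup_pvalue(tab, 0:m), direct)
  expect_true(all(diff(tab$p) <= 0))
  expect_error(lookup_pvalue(tab, m + 1L), "range")
})

test_that("bh_qvalues implements the step-up adjustment", {
  expect_equal(bh_qvalues(0.01), 0.01)
  # frozen hand computation of the BH step-up with monotone adjustment
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 1.0)),
               c(0.04, 0.04, 0.04, 1.0))
  set.seed(5)
  p <- runif(50)
  q <- bh_qvalues(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_qvalues(numeric(0)), "non-empty")
})

test_that("hybrid screening refines only the screened pairs", {
  mat <- gen_null_matrix(8, 30, seed = 17)
  cfg <- lta_config(sig_mode = "theo")
  res <- run_lta(mat, cfg)
  hyb <- hybrid_pvalues(res[, c("factor_x", "factor_y", "p")],
                        t(apply(mat, 1, normal_score_transform)),
                        t = 0, D = 0, B = 100, alpha_screen = 1.0, seed = 3)
  expect_true(all(hyb$p_source == "perm"))   # degenerate screen: all permuted
  expect_error(hybrid_pvalues(res, mat, alpha_screen = 0), "alpha_screen")

  # under the null with a 0.05 screen, only a small fraction is permuted
  mat2 <- gen_null_matrix(12, 40, seed = 23)
  res2 <- run_lta(mat2, lta_config(sig_mode = "hybrid", B = 100,
                                   alpha_screen = 0.05, seed = 5))
  expect_lte(mean(res2$p_source == "perm"), 0.20)
})

test_that("validity region flags small-sample approximate calls", {
  expect_true(lta_validity(25L, 0L, 0.01))
  expect_false(lta_validity(10L, 0L, 0.01))
  expect_false(lta_validity(25L, 2L, 0.01))
  expect_true(lta_validity(35L, 2L, 0.01))
  expect_true(lta_validity(10L, 0L, 0.01, p_source = "perm"))
  expect_false(lta_validity(100L, 0L, 0.5))   # large p: outside trusted region
})
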