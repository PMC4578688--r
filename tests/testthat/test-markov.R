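# Null transition models for trend symbol chains.

test_that("two-letter model: transition matrix, stationarity, sigma2", {
  m <- two_letter_model()
  expect_equal(m$T, matrix(c(1, 2, 2, 1) / 3, 2, 2, byrow = TRUE,
                           dimnames = dimnames(m$T)))
  expect_equal(unname(m$phi), c(0.5, 0.5))
  expect_true(m$sigma2 == 1.25)
  # lagged product probabilities follow the closed form of T^k
  for (k in 1:5) {
    Tk <- matpow(m$T, k)
    p_same <- unname(0.5 * (Tk[1, 1] + Tk[2, 2]))
    expect_equal(p_same, (1 + (-1)^k / 3^k) / 2, tolerance = 1e-14)
    expect_equal(unname(Tk), two_letter_power_closed(k), tolerance = 1e-14)
  }
})

test_that("Monte-Carlo estimation recovers the transition parameters", {
  e <- estimate_transition_params(0, N = 200000, seed = 3)
  expect_equal(e$b, 1 / 3, tolerance = 0.01)
  expect_equal(e$c, 2 / 3, tolerance = 0.01)
  expect_true(is.na(e$d))   # no-change state unreachable at t = 0

  e <- estimate_transition_params(0.5, N = 200000, seed = 3)
  expect_equal(e$b, 0.2311, tolerance = 0.01)
  expect_equal(e$c, 0.6088, tolerance = 0.01)
  expect_equal(e$d, 0.4043, tolerance = 0.01)

  # huge threshold: nearly everything is no-change
  e <- estimate_transition_params(50, N = 100000, seed = 9)
  expect_lt(e$b, 0.05)
  expect_lt(e$d, 0.05)
  expect_error(estimate_transition_params(0.5, N = 10), "N")
})

test_that("quadrature reproduces the t = 0.5 parameters and matches Monte Carlo", {
  q <- transition_params_quadrature(0.5)
  expect_equal(round(q$b, 4), 0.2311)
  expect_equal(round(q$c, 4), 0.6088)
  expect_equal(round(q$d, 4), 0.4043)
  expect_error(transition_params_quadrature(0), "t")
})

test_that("stationary distribution satisfies phi T = phi and symmetry", {
  phi <- stationary_distribution(0.2311, 0.6088, 0.4043)
  expect_equal(unname(phi), c(0.4174, 0.1653, 0.4174), tolerance = 1e-4)
  expect_equal(sum(phi), 1)
  set.seed(12)
  for (i in 1:25) {
    b <- runif(1, 0, 0.6); c <- runif(1, 0, 1 - b); d <- runif(1, 0.05, 0.5)
    mod <- build_transition_matrix(b, c, d)
    expect_equal(unname(rowSums(mod$T)), rep(1, 3), tolerance = 1e-12)
    expect_equal(as.vector(mod$phi %*% mod$T), unname(mod$phi),
                 tolerance = 1e-12)
    expect_identical(mod$phi[["1"]], mod$phi[["-1"]])
    # invariance under exchanging the up and down states
    expect_equal(unname(mod$T), unname(mod$T[3:1, 3:1]))
  }
  # b + c = 1: no-change state vanishes in stationarity
  expect_equal(unname(stationary_distribution(0.4, 0.6, 0.3)),
               c(0.5, 0, 0.5))
  expect_error(stationary_distribution(0.6, 0.4, 0), "degenerate")
  expect_error(build_transition_matrix(0.5, 0.6, 0.1), "b \\+ c")
  expect_error(build_transition_matrix(0.2, 0.3, 0.7), "2d")
})

test_that("closed-form T^k matches repeated multiplication", {
  # k = 1 reproduces T itself
  mod <- build_transition_matrix(0.2311, 0.6088, 0.4043)
  expect_equal(matrix_power_closed_form(0.2311, 0.6088, 0.4043, 1), mod$T,
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    b <- runif(1, 0, 0.6); c <- runif(1, 0, 1 - b); d <- runif(1, 0.05, 0.45)
    mod <- build_transition_matrix(b, c, d)
    k <- sample(1:20, 1)
    expect_equal(matrix_power_closed_form(b, c, d, k),
                 matpow(mod$T, k), ignore_attr = TRUE, tolerance = 1e-12)
  }
  # ergodic limit: every row converges to phi
  big <- matrix_power_closed_form(0.2311, 0.6088, 0.4043, 500)
  phi <- stationary_distribution(0.2311, 0.6088, 0.4043)
  for (r in 1:3) expect_equal(unname(big[r, ]), unname(phi), tolerance = 1e-12)
})

test_that("sigma2 closed form equals direct series summation", {
  # two-letter reduction: b = 1/3, c = 2/3 recovers 1.25 for any valid d
  for (d in c(0.2, 0.4, 0.5)) {
    expect_equal(sigma2_three_letter(1 / 3, 2 / 3, d) /
                   (4 * stationary_distribution(1 / 3, 2 / 3, d)[["1"]]^2),
                 1.25, tolerance = 1e-12)
  }
  # b = c: correlation terms vanish
  expect_equal(sigma2_three_letter(0.3, 0.3, 0.25),
               4 * stationary_distribution(0.3, 0.3, 0.25)[["1"]]^2)
  # closed form vs truncated series oracle
  expect_equal(sigma2_three_letter(0.2311, 0.6088, 0.4043),
               sigma2_series_oracle(0.2311, 0.6088, 0.4043),
               tolerance = 1e-10)
  set.seed(31)
  for (i in 1:20) {
    b <- runif(1, 0, 0.6); c <- runif(1, 0, 1 - b); d <- runif(1, 0.05, 0.45)
    s2 <- sigma2_three_letter(b, c, d)
    expect_gt(s2, 0)
    expect_equal(s2, sigma2_series_oracle(b, c, d), tolerance = 1e-9)
    # and against the from-first-principles matrix-power route
    mod <- build_transition_matrix(b, c, d)
    expect_equal(mod$sigma2,
                 trendsig:::sigma2_from_powers(mod$T, mod$phi)$sigma2,
                 tolerance = 1e-9)
  }
})

test_that("trend_null_model dispatches on the threshold", {
  expect_identical(trend_null_model(0)$alphabet_size, 2L)
  mod <- trend_null_model(0.5)
  expect_identical(mod$alphabet_size, 3L)
  expect_equal(mod$b, 0.2311, tolerance = 1e-4)
  mc <- trend_null_model(0.5, params = "montecarlo", N = 50000, seed = 4)
  expect_equal(mc$b, mod$b, tolerance = 0.02)
})
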