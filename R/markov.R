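# Null models for trend symbol sequences.
#
# Under exchangeability of the original values, the trend symbols are
# approximated by a first-order Markov chain, and the product of two
# independent trend chains by another Markov chain whose long-run
# variance constant sigma^2 feeds the tail approximation of the LT
# score.  State order is fixed as (1, 0, -1) everywhere; symmetry of the
# up and down states makes three parameters (b, c, d) sufficient:
#   T[1,1] = T[-1,-1] = b,  T[1,-1] = T[-1,1] = c,
#   T[0,1] = T[0,-1] = d,   rows sum to 1.

new_transition_model <- function(alphabet_size, threshold_t, b, c, d,
                                 T, phi, sigma2, sigma2_nterms = NA_integer_) {
  structure(list(alphabet_size = alphabet_size, threshold_t = threshold_t,
                 b = b, c = c, d = d, T = T, phi = phi, sigma2 = sigma2,
                 sigma2_nterms = sigma2_nterms),
            class = "transition_model")
}

# Long-run variance of the product chain computed directly from matrix
# powers: sigma2 = E(Z_1^2) + 2 * sum_k E(Z_1 Z_{k+1}) where
# Z_i = d_i^X d_i^Y and, by independence of the two chains,
# E(Z_1 Z_{k+1}) = E(d_1 d_{k+1})^2 with
# E(d_1 d_{k+1}) = sum_a phi_a * (P(up at k | a) - P(down at k | a)) * a.
# Serves as the from-first-principles route; the closed forms below must
# agree with it.
sigma2_from_powers <- function(T, phi, max_terms = 400L, tol = 1e-17) {
  states <- if (nrow(T) == 2L) c(1, -1) else c(1, 0, -1)
  ez2 <- sum(phi * states^2)
  Tk <- T
  acc <- 0
  nterms <- 0L
  for (k in seq_len(max_terms)) {
    e <- sum(phi * states * as.vector(Tk %*% states))
    acc <- acc + e^2
    nterms <- k
    if (e^2 < tol) break
    Tk <- Tk %*% T
  }
  list(sigma2 = ez2^2 + 2 * acc, nterms = nterms)
}

#' Two-letter (t = 0) trend null model
#'
#' For continuous exchangeable data at threshold `t = 0` the trend
#' alphabet is effectively \{-1, 1\} and order statistics give the
#' transition matrix exactly: staying in the same trend state has
#' probability 1/3, switching 2/3.  The stationary distribution is
#' (1/2, 1/2) and the variance constant of the product chain is
#' `sigma2 = 1 + 2 * sum_k (1/9)^k = 1.25`, computed here by summing the
#' lagged autocovariance series over actual matrix powers.
#'
#' @return an object of class `"transition_model"` with fields
#'   `alphabet_size = 2`, `b = 1/3`, `c = 2/3`, `T`, `phi`, `sigma2`.
#' @examples
#' two_letter_model()$sigma2   # 1.25
#' @export
two_letter_model <- function() {
  T <- matrix(c(1, 2, 2, 1) / 3, 2L, 2L, byrow = TRUE,
              dimnames = list(c("1", "-1"), c("1", "-1")))
  phi <- c("1" = 0.5, "-1" = 0.5)
  s2 <- sigma2_from_powers(T, phi)
  new_transition_model(2L, 0, b = 1 / 3, c = 2 / 3, d = NA_real_,
                       T = T, phi = phi, sigma2 = s2$sigma2,
                       sigma2_nterms = s2$nterms)
}

#' Monte-Carlo estimation of the trend transition parameters
#'
#' Generates `N` i.i.d. standard normal values, discretizes them at
#' threshold `t`, and estimates the transition probabilities by counting
#' consecutive symbol pairs, `T[a, b] = C[a, b] / C[a]`.  Counts for
#' symmetric transitions -- (1,1) with (-1,-1), (1,-1) with (-1,1),
#' (0,1) with (0,-1) -- are pooled, enforcing the up/down symmetry of
#' the model exactly and halving the estimator variance.
#'
#' @param t trend threshold, >= 0.
#' @param N number of simulated values (>= 1000).
#' @param seed RNG seed.
#' @return list with `b`, `c`, `d` (and the inputs `t`, `N`).  `d` is
#'   `NA` when the no-change state was never visited (always at `t = 0`).
#' @export
estimate_transition_params <- function(t, N = 10000L, seed = 1L) {
  t <- check_scalar_number(t, "t", min = 0)
  N <- check_count(N, "N", min = 1000L)
  x <- with_seed(seed, rnorm(N))
  d <- as.integer(discretize(x, t))
  from <- d[-length(d)]
  to <- d[-1]
  cnt <- function(a, b) sum(from == a & to == b)
  n_ud <- sum(from == 1L) + sum(from == -1L)
  n_0 <- sum(from == 0L)
  list(b = (cnt(1L, 1L) + cnt(-1L, -1L)) / n_ud,
       c = (cnt(1L, -1L) + cnt(-1L, 1L)) / n_ud,
       d = if (n_0 == 0L) NA_real_ else (cnt(0L, 1L) + cnt(0L, -1L)) / (2 * n_0),
       t = t, N = N)
}

#' Transition parameters by deterministic numerical integration
#'
#' For three consecutive i.i.d. standard normal values `(X1, X2, X3)`
#' the conditional transition probabilities of the induced trend symbols
#' are two- and three-fold Gaussian integrals over the regions defined
#' by the discretization rule.  They are evaluated here by nested
#' adaptive quadrature:
#' `b = P(d2 = 1 | d1 = 1)`, `c = P(d2 = -1 | d1 = 1)`,
#' `d = P(d2 = 1 | d1 = 0)`.  This is the deterministic, reproducible
#' source of `(b, c, d)` used by default when `t > 0`.
#'
#' @param t trend threshold, strictly positive.
#' @param rel_tol relative tolerance passed to the quadrature.
#' @return list with `b`, `c`, `d` and the input `t`.
#' @export
transition_params_quadrature <- function(t, rel_tol = 1e-9) {
  t <- check_scalar_number(t, "t")
  if (t <= 0) stop_input("`t` must be > 0 (use two_letter_model() for t = 0)")
  # P(next symbol is up / down | current value x): the band edges are
  # x + t|x| and x - t|x|.
  p_up <- function(x) pnorm(x + t * abs(x), lower.tail = FALSE)
  p_dn <- function(x) pnorm(x - t * abs(x))
  quad <- function(f, lower, upper) {
    r <- tryCatch(integrate(f, lower, upper, rel.tol = rel_tol,
                            abs.tol = 0, subdivisions = 400L),
                  error = function(e) stop_input("quadrature failed: ",
                                                 conditionMessage(e)))
    r$value
  }
  p1 <- quad(function(x) dnorm(x) * p_up(x), -Inf, Inf)
  p0 <- quad(function(x) dnorm(x) * (pnorm(x + t * abs(x)) - pnorm(x - t * abs(x))),
             -Inf, Inf)
  inner_tail <- function(lo, g) quad(function(x2) dnorm(x2) * g(x2), lo, Inf)
  inner_band <- function(lo, hi) quad(function(x2) dnorm(x2) * p_up(x2), lo, hi)
  p11 <- quad(function(x1) dnorm(x1) *
                vapply(x1 + t * abs(x1), inner_tail, 0, g = p_up), -Inf, Inf)
  p1m1 <- quad(function(x1) dnorm(x1) *
                 vapply(x1 + t * abs(x1), inner_tail, 0, g = p_dn), -Inf, Inf)
  p01 <- quad(function(x1) dnorm(x1) *
                mapply(inner_band, x1 - t * abs(x1), x1 + t * abs(x1)),
              -Inf, Inf)
  list(b = p11 / p1, c = p1m1 / p1, d = p01 / p0, t = t)
}

#' Stationary distribution of the three-letter trend chain
#'
#' `phi = (d, 1 - b - c, d) / (1 - b - c + 2d)` over states (1, 0, -1).
#' Symmetry of the up and down states forces `phi[1] == phi[3]`.
#'
#' @param b,c,d transition parameters.
#' @return named numeric vector of length 3 summing to 1.
#' @export
stationary_distribution <- function(b, c, d) {
  denom <- 1 - b - c + 2 * d
  if (!is.finite(denom) || denom <= 0) {
    stop_input("degenerate model: 1 - b - c + 2d must be positive")
  }
  c("1" = d, "0" = 1 - b - c, "-1" = d) / denom
}

#' Variance constant of the three-letter product chain
#'
#' The long-run variance of the product of two independent stationary
#' trend chains:
#' `sigma2 = 4 * (d / (1 - b - c + 2d))^2 * (1 + 2 (b - c)^2 / (1 - (b - c)^2))`,
#' i.e. `4 phi_1^2 * (1 + 2 * sum_k (b - c)^(2k))`.  With
#' `(b, c) = (1/3, 2/3)` and the two-letter stationary weight 1/2 this
#' reduces to the two-letter constant 1.25.
#'
#' @inheritParams stationary_distribution
#' @return positive scalar.
#' @export
sigma2_three_letter <- function(b, c, d) {
  if (abs(b - c) >= 1) stop_input("divergent series: |b - c| must be < 1")
  phi1 <- stationary_distribution(b, c, d)[["1"]]
  4 * phi1^2 * (1 + 2 * (b - c)^2 / (1 - (b - c)^2))
}

#' Assemble a three-letter transition model
#'
#' Builds the row-stochastic matrix over states (1, 0, -1) with rows
#' `(b, 1-b-c, c)`, `(d, 1-2d, d)`, `(c, 1-b-c, b)`, together with its
#' stationary distribution and the product-chain variance constant.
#'
#' @inheritParams stationary_distribution
#' @param threshold_t the trend threshold the parameters correspond to
#'   (metadata only).
#' @return an object of class `"transition_model"`.
#' @export
build_transition_matrix <- function(b, c, d, threshold_t = NA_real_) {
  b <- check_scalar_number(b, "b", 0, 1)
  c <- check_scalar_number(c, "c", 0, 1)
  d <- check_scalar_number(d, "d", 0, 1)
  if (b + c > 1) stop_input("invalid parameters: b + c must be <= 1")
  if (2 * d > 1) stop_input("invalid parameters: 2d must be <= 1")
  st <- c("1", "0", "-1")
  T <- matrix(c(b, 1 - b - c, c,
                d, 1 - 2 * d, d,
                c, 1 - b - c, b),
              3L, 3L, byrow = TRUE, dimnames = list(st, st))
  phi <- stationary_distribution(b, c, d)
  new_transition_model(3L, threshold_t, b, c, d, T, phi,
                       sigma2_three_letter(b, c, d))
}

#' Closed-form k-th power of the three-letter transition matrix
#'
#' Evaluates the spectral expansion of `T^k` entrywise.  The three
#' eigenvalues are 1, `b - c` and `b + c - 2d`; the expansion is exact
#' for every `k >= 1` and converges rowwise to the stationary
#' distribution as `k` grows.
#'
#' @inheritParams stationary_distribution
#' @param k power, integer >= 1.
#' @return 3 x 3 matrix over states (1, 0, -1).
#' @export
matrix_power_closed_form <- function(b, c, d, k) {
  k <- check_count(k, "k", min = 1L)
  e <- -1 + b + c - 2 * d
  if (e == 0) stop_input("degenerate model: -1 + b + c - 2d must be nonzero")
  if (1 - b - c == 0 && d == 0) stop_input("degenerate model: isolated no-change state")
  A <- (b + c - 2 * d)^k
  B <- (b - c)^k
  t11 <- B / 2 + (-1 + b + c) * A / (2 * e) - d / e
  t12 <- (-1 + b + c) / e + (1 - b - c) * A / e
  t13 <- -B / 2 + (-1 + b + c) * A / (2 * e) - d / e
  t21 <- -d / e + A * d / e
  # middle-row centre entry has an extra (-1 + b + c) denominator; when
  # b + c = 1 the no-change state is transient and the entry is (1-2d)^k
  t22 <- if (b + c == 1) (1 - 2 * d)^k
         else (-1 + b + c) / e + 2 * (1 - b - c) * A * d / ((-1 + b + c) * e)
  st <- c("1", "0", "-1")
  matrix(c(t11, t12, t13,
           t21, t22, t21,
           t13, t12, t11),
         3L, 3L, byrow = TRUE, dimnames = list(st, st))
}

#' Null transition model for a given trend threshold
#'
#' Convenience dispatcher: the exact two-letter model when `t = 0`,
#' otherwise a three-letter model with `(b, c, d)` from deterministic
#' quadrature (default) or Monte-Carlo estimation.
#'
#' @param t trend threshold, >= 0.
#' @param params source of `(b, c, d)` when `t > 0`.
#' @param N,seed Monte-Carlo settings (used only for `params = "montecarlo"`).
#' @return an object of class `"transition_model"`.
#' @export
trend_null_model <- function(t = 0, params = c("quadrature", "montecarlo"),
                             N = 10000L, seed = 1L) {
  t <- check_scalar_number(t, "t", min = 0)
  if (t == 0) return(two_letter_model())
  params <- match.arg(params)
  p <- if (params == "quadrature") transition_params_quadrature(t)
       else estimate_transition_params(t, N, seed)
  if (is.na(p$d)) stop_input("no-change state never observed; cannot build a three-letter model")
  build_transition_matrix(p$b, p$c, p$d, threshold_t = t)
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Trend null model: %d-letter alphabet (t = %g)\n",
              x$alphabet_size, x$threshold_t))
  cat(sprintf("  b = %.6f, c = %.6f, d = %s\n", x$b, x$c,
              if (is.na(x$d)) "NA" else sprintf("%.6f", x$d)))
  cat("  transition matrix:\n")
  print(round(x$T, 6))
  cat("  stationary distribution:", paste(sprintf("%.6f", x$phi), collapse = " "), "\n")
  cat(sprintf("  sigma2 = %.6f\n", x$sigma2))
  invisible(x)
}
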