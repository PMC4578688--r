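# Statistical significance of LT scores: closed-form tail approximation,
# permutation, hybrid screening, score -> p lookup tables, and FDR.

# Theta-series form of the limiting tail of the scaled range of partial
# sums: 1 - 8 * sum_k (1/x^2 + 1/((2k-1)^2 pi^2)) exp(-(2k-1)^2 pi^2 / (2 x^2)).
# Terms decay super-exponentially; truncate when the next term is below
# 1e-16, hard cap K.
tail_theta <- function(x, K) {
  acc <- 0
  for (k in seq_len(K)) {
    odd <- 2 * k - 1
    term <- (1 / x^2 + 1 / (odd^2 * pi^2)) * exp(-odd^2 * pi^2 / (2 * x^2))
    acc <- acc + term
    if (8 * term < 1e-16) break
  }
  1 - 8 * acc
}

# Poisson-resummed (complementary) form of the same tail:
#   L(x) = 8 * sum_j (-1)^(j+1) j * pnorm(-j x).
# Mathematically identical to the theta series, but free of the
# 1 - (sum ~ 1) cancellation, so it resolves the far tail (L below
# ~1e-12) where the theta form returns only rounding noise.
tail_resummed <- function(x) {
  acc <- 0
  for (j in 1:200) {
    term <- (-1)^(j + 1) * j * pnorm(-j * x)
    acc <- acc + term
    if (j * pnorm(-j * x) < .Machine$double.xmin || abs(term) < 1e-18 * max(acc, 1e-300)) break
  }
  8 * acc
}

#' Tail probability of the scaled range of partial sums
#'
#' The limiting probability that the range of partial sums of `n`
#' zero-mean Markov variables, scaled by `sigma * sqrt(n)`, is at least
#' `x`.  This is the null distribution of the LT score at delay 0.  The
#' default evaluation uses the theta series for moderate `x` and an
#' exactly equivalent Gaussian resummation for large `x`, where the
#' theta form loses all precision to cancellation; the two agree to
#' better than 1e-12 on the crossover region.
#'
#' The asymptotic series can exceed 1 for small `x`; the result is
#' clamped to `[0, 1]`.  The approximation is only trusted where the
#' tail is small (roughly p < 0.05) and the series is long enough; see
#' [lta_validity()].
#'
#' @param x positive scalar, the scaled score.
#' @param K series truncation cap (theta form; terms are also cut
#'   adaptively once below 1e-16).
#' @param method `"auto"` (default), `"theta"`, or `"resummed"`.
#' @return tail probability in `[0, 1]`.
#' @examples
#' tail_prob(2.0)   # 0.1815
#' tail_prob(3.0)   # 0.0108
#' @export
tail_prob <- function(x, K = 500L, method = c("auto", "theta", "resummed")) {
  x <- check_scalar_number(x, "x")
  if (x <= 0) stop_input("`x` must be > 0")
  K <- check_count(K, "K", min = 1L)
  method <- match.arg(method)
  p <- switch(method,
              theta = tail_theta(x, K),
              resummed = tail_resummed(x),
              auto = if (x < 4) tail_theta(x, K) else tail_resummed(x))
  min(max(p, 0), 1)
}

#' Tail probability with bounded time delay
#'
#' Treating the score maxima at the `2D + 1` admissible delays as
#' independent, the tail with delay limit `D` is
#' `L_D(x) = 1 - (1 - L(x))^(2D + 1)`.  `D = 0` reduces exactly to
#' [tail_prob()].
#'
#' @inheritParams tail_prob
#' @param D delay limit, integer >= 0.
#' @return tail probability in `[0, 1]`.
#' @examples
#' tail_prob_delay(2.0, D = 1)   # 0.4516
#' @export
tail_prob_delay <- function(x, D = 0L, K = 500L,
                            method = c("auto", "theta", "resummed")) {
  D <- check_count(D, "D")
  L <- tail_prob(x, K, method)
  if (L >= 1) return(1)
  # -expm1((2D+1) * log1p(-L)) keeps precision when L is tiny
  min(max(-expm1((2 * D + 1) * log1p(-L)), 0), 1)
}

#' Approximate p-value of an LT score
#'
#' Scales the un-normalized integer score by `sqrt(sigma2 * m)` and
#' evaluates the delay-adjusted tail: `p = L_D(score / sqrt(sigma2 * m))`.
#' `m` is conventionally the trend-series length `n - 1` (the number of
#' terms the partial sums actually run over); callers preferring the
#' raw number of time points can simply pass `n`.
#'
#' @param score_S un-normalized LT score, integer in `[0, m]`.
#' @param m number of product terms (trend-series length).
#' @param sigma2 variance constant of the product chain (1.25 at t = 0).
#' @param D delay limit used when scoring.
#' @param K series truncation cap.
#' @return p-value in `[0, 1]`; `score_S = 0` gives 1.
#' @export
approx_pvalue <- function(score_S, m, sigma2, D = 0L, K = 500L) {
  score_S <- check_count(score_S, "score_S")
  m <- check_count(m, "m", min = 1L)
  if (score_S > m) stop_input("`score_S` cannot exceed `m`")
  sigma2 <- check_scalar_number(sigma2, "sigma2")
  if (sigma2 <= 0) stop_input("`sigma2` must be > 0")
  if (score_S == 0L) return(1)
  tail_prob_delay(score_S / sqrt(sigma2 * m), D, K)
}

#' Permutation p-value of an LT score
#'
#' The observed score is computed from the discretized series; each of
#' `B` iterations uniformly permutes the original values of `x` (not
#' the trend symbols), re-discretizes, and re-scores with the same `t`
#' and `D`.  The default estimator is the add-one fraction
#' `(#{permuted >= observed} + 1) / (B + 1)`, which never reports 0;
#' `add_one = FALSE` restores the raw fraction.
#'
#' @param x,y numeric series of equal length (raw values, length >= 2).
#' @param t trend threshold.
#' @param D delay limit.
#' @param B number of permutations, >= 1.
#' @param seed RNG seed.
#' @param add_one use the add-one estimator (default TRUE).
#' @return p-value in `[1/(B+1), 1]` (or `[0, 1]` when `add_one = FALSE`).
#' @export
perm_pvalue <- function(x, y, t = 0, D = 0L, B = 1000L, seed = 1L,
                        add_one = TRUE) {
  B <- check_count(B, "B", min = 1L)
  D <- check_count(D, "D")
  dx <- as.integer(discretize(x, t))
  dy <- as.integer(discretize(y, t))
  obs <- lt_score_only(dx, dy, D)
  xv <- as.numeric(x)
  hits <- with_seed(seed, {
    h <- 0L
    for (i in seq_len(B)) {
      dp <- as.integer(discretize(sample(xv), t))
      if (lt_score_only(dp, dy, D) >= obs) h <- h + 1L
    }
    h
  })
  if (add_one) (hits + 1) / (B + 1) else hits / B
}

#' Precomputed score-to-p-value lookup table
#'
#' Tabulates [approx_pvalue()] for every integer score in `[0, m]` so
#' that all-vs-all pipelines pay the series evaluation once and each
#' pair costs a constant-time lookup, bit-identical to direct
#' evaluation.
#'
#' @inheritParams approx_pvalue
#' @return object of class `"pvalue_table"`.
#' @seealso [lookup_pvalue()]
#' @export
build_pvalue_table <- function(m, sigma2, D = 0L, K = 500L) {
  m <- check_count(m, "m", min = 1L)
  p <- vapply(0:m, approx_pvalue, 0, m = m, sigma2 = sigma2, D = D, K = K)
  structure(list(m = m, sigma2 = sigma2, D = D, p = p),
            class = "pvalue_table")
}

#' Constant-time lookup in a p-value table
#'
#' @param table a [build_pvalue_table()] object.
#' @param score_S integer score(s) in `[0, m]`.
#' @return p-value(s).
#' @export
lookup_pvalue <- function(table, score_S) {
  if (!inherits(table, "pvalue_table")) stop_input("`table` must be a pvalue_table")
  if (any(score_S < 0 | score_S > table$m)) stop_input("score out of table range")
  table$p[score_S + 1L]
}

#' @export
print.pvalue_table <- function(x, ...) {
  cat(sprintf("LT score p-value table: m = %d, sigma2 = %.4f, D = %d\n",
              x$m, x$sigma2, x$D))
  show <- unique(pmin(x$m, c(0L, 1L, seq(0L, x$m, length.out = 6L))))
  print(data.frame(score = show, p = x$p[show + 1L]), row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (monotone), returned in the
#' input order.
#'
#' @param pvals p-values in `[0, 1]`, non-empty.
#' @return q-values, same length and order.
#' @export
bh_qvalues <- function(pvals) {
  if (!length(pvals)) stop_input("`pvals` must be non-empty")
  if (!is.numeric(pvals) || any(!is.finite(pvals)) ||
      any(pvals < 0 | pvals > 1)) {
    stop_input("`pvals` must be numeric in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Hybrid approximation + permutation p-values
#'
#' The screening strategy for all-vs-all analysis: the conservative
#' closed-form p-value is computed for every pair, and only pairs at or
#' below the loose screen `alpha_screen` are refined by permutation.
#' Refined pairs report the permutation p-value (`p_source = "perm"`),
#' all others keep the approximation (`p_source = "theo"`).  The final
#' `p` column is what feeds [bh_qvalues()].
#'
#' @param results data frame with columns `factor_x`, `factor_y`, `p`
#'   (approximate p-values), as produced by [run_lta()] in `"theo"` mode.
#' @param data numeric matrix of the (preprocessed) profiles, factor IDs
#'   as row names.
#' @param t,D scoring parameters, matching those used for `results`.
#' @param B permutations per refined pair.
#' @param alpha_screen screening threshold in (0, 1].
#' @param seed master RNG seed; each refined pair gets a derived stream.
#' @param add_one passed to [perm_pvalue()].
#' @return `results` with updated `p` and `p_source` columns.
#' @export
hybrid_pvalues <- function(results, data, t = 0, D = 0L, B = 1000L,
                           alpha_screen = 0.05, seed = 1L, add_one = TRUE) {
  alpha_screen <- check_scalar_number(alpha_screen, "alpha_screen")
  if (alpha_screen <= 0 || alpha_screen > 1) {
    stop_input("`alpha_screen` must be in (0, 1]")
  }
  if (!all(c("factor_x", "factor_y", "p") %in% names(results))) {
    stop_input("`results` must have factor_x, factor_y and p columns")
  }
  results$p_source <- rep("theo", nrow(results))
  todo <- which(results$p <= alpha_screen)
  if (length(todo)) {
    seeds <- derive_seeds(seed, length(todo))
    for (i in seq_along(todo)) {
      r <- todo[i]
      results$p[r] <- perm_pvalue(data[results$factor_x[r], ],
                                  data[results$factor_y[r], ],
                                  t = t, D = D, B = B, seed = seeds[i],
                                  add_one = add_one)
      results$p_source[r] <- "perm"
    }
  }
  results
}

#' Validity region of the closed-form approximation
#'
#' The tail approximation is asymptotic; empirically it tracks
#' permutation p-values once the approximate p-value is below 0.05 and
#' the series has at least 20 time points with no delay, or 30 with a
#' delay limit up to three steps.  Returns `TRUE` where a reported
#' approximate p-value lies inside that trusted region (permutation
#' p-values are always considered valid); `FALSE` rows carry a warning
#' flag in [run_lta()] output.
#'
#' @param n number of time points of the analyzed series.
#' @param D delay limit.
#' @param p the p-value.
#' @param p_source `"theo"` or `"perm"`.
#' @return logical vector.
#' @export
lta_validity <- function(n, D, p, p_source = "theo") {
  n_ok <- if (D == 0L) n >= 20L else n >= 30L
  p_source == "perm" | (n_ok & p < 0.05)
}
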