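# Local trend score: banded Smith-Waterman alignment of two trend series.
#
# For a fixed offset delta = j - i, every admissible interval pair lies on
# one diagonal of the alignment matrix, and the classical two-table
# recursion P = max(0, P + u*v), N = max(0, N - u*v) along that diagonal
# is equivalent to taking the range (max - min) of the prefix sums of the
# symbol products on the diagonal.  We exploit that equivalence: per
# diagonal we take cumulative sums once, which is both faster in R and
# exactly equal to the cellwise DP (verified against the brute-force
# oracle in the test suite).

# Deterministic tie-breaking among equal-score optima: larger score,
# then smaller |delay|, then positive sign, then smaller start_x, then
# positive delay.
better_candidate <- function(cand, best) {
  if (is.null(best)) return(cand$score > 0L)
  if (cand$score != best$score) return(cand$score > best$score)
  if (abs(cand$delay) != abs(best$delay)) return(abs(cand$delay) < abs(best$delay))
  if (cand$sign != best$sign) return(cand$sign > best$sign)
  if (cand$start_x != best$start_x) return(cand$start_x < best$start_x)
  cand$delay > best$delay
}

# Best-scoring interval on one diagonal, with traceback.
# z: products along the diagonal; delta: delay j - i of the diagonal.
diag_candidate <- function(z, delta) {
  pref <- c(0L, cumsum(z))            # prefix sums, positions 0..len
  mx <- max(pref)
  mn <- min(pref)
  if (mx == mn) return(NULL)          # all-zero diagonal, score 0
  imax <- which(pref == mx) - 1L
  imin <- which(pref == mn) - 1L
  # positive run: prefix positions a < b with pref[b] - pref[a] = range
  a_pos <- imin[imin < max(imax)]
  if (length(a_pos)) {
    a <- min(a_pos)
    b <- min(imax[imax > a])
    sgn <- 1L
  } else {
    a <- min(imax[imax < max(imin)])
    b <- min(imin[imin > a])
    sgn <- -1L
  }
  start <- a + 1L                     # 1-based along the diagonal
  list(score = mx - mn,
       sign = sgn,
       delay = delta,
       start_x = if (delta >= 0L) start else start - delta,
       start_y = if (delta >= 0L) start + delta else start,
       length = b - a)
}

zero_candidate <- function() {
  list(score = 0L, sign = 1L, delay = 0L, start_x = 1L, start_y = 1L,
       length = 0L)
}

new_lt_result <- function(cand, m, D) {
  structure(list(score_S = as.integer(cand$score),
                 lt_norm = cand$score / m,
                 sign = as.integer(cand$sign),
                 delay = as.integer(cand$delay),
                 start_x = as.integer(cand$start_x),
                 start_y = as.integer(cand$start_y),
                 length_l = as.integer(cand$length),
                 m = as.integer(m),
                 D = as.integer(D)),
            class = "lt_result")
}

check_pair <- function(u, v, D) {
  u <- as_trend(u, "u")
  v <- as_trend(v, "v")
  if (length(u) != length(v)) stop_input("trend series lengths differ")
  m <- length(u)
  if (m < 1L) stop_input("trend series must be non-empty")
  D <- check_count(D, "D")
  if (D > m - 1L) stop_input("delay limit D must be at most m - 1")
  list(u = u, v = v, m = m, D = D)
}

#' Local trend (LT) score of a pair of trend series
#'
#' Finds, over all equal-length interval pairs `I = [i, i+l-1]`,
#' `J = [j, j+l-1]` with `|i - j| <= D`, the maximum of the absolute sum
#' of symbol products `|sum(u[I] * v[J])|` -- the LT score with maximum
#' time delay `D` -- by a banded Smith-Waterman dynamic program, and
#' recovers the optimal intervals by traceback.  The empty alignment
#' (`l = 0`, score 0) is admissible.
#'
#' Ties among equal-score optima are broken deterministically: smaller
#' `|delay|`, then positive sign, then smaller `start_x`, then positive
#' delay.
#'
#' @param u,v trend series ([discretize()] output, or plain vectors over
#'   \{-1, 0, 1\}) of equal length `m`.
#' @param D maximum allowed offset `|i - j|`, an integer in `[0, m - 1]`.
#' @return an object of class `"lt_result"`: a list with `score_S` (the
#'   un-normalized integer score), `lt_norm = score_S / m`, `sign`
#'   (+1 co-trending, -1 anti-trending), `delay = j - i`, `start_x`,
#'   `start_y`, `length_l`, and the inputs `m`, `D`.
#' @examples
#' lt_score(c(1, 1, -1), c(1, 1, -1), D = 0)
#' @seealso [lt_score_bruteforce()] for the exhaustive-enumeration oracle.
#' @export
lt_score <- function(u, v, D = 0L) {
  p <- check_pair(u, v, D)
  best <- NULL
  for (delta in 0:p$D) {
    for (s in if (delta == 0L) 1L else c(1L, -1L)) {
      dl <- delta * s
      if (dl >= 0L) {
        idx <- seq_len(p$m - dl)
        z <- p$u[idx] * p$v[idx + dl]
      } else {
        idx <- seq_len(p$m + dl)
        z <- p$u[idx - dl] * p$v[idx]
      }
      cand <- diag_candidate(z, dl)
      if (!is.null(cand) && better_candidate(cand, best)) best <- cand
    }
  }
  if (is.null(best)) best <- zero_candidate()
  new_lt_result(best, p$m, p$D)
}

# Score-only fast path (no traceback); used by permutation loops and
# null simulations.  u, v must already be integer trend vectors.
lt_score_only <- function(u, v, D) {
  m <- length(u)
  best <- 0L
  for (dl in (-D):D) {
    if (dl >= 0L) {
      idx <- seq_len(m - dl)
      z <- u[idx] * v[idx + dl]
    } else {
      idx <- seq_len(m + dl)
      z <- u[idx - dl] * v[idx]
    }
    pref <- cumsum(z)
    rng <- max(pref, 0L) - min(pref, 0L)
    if (rng > best) best <- rng
  }
  best
}

#' Brute-force LT score (testing oracle)
#'
#' Identical contract to [lt_score()], computed by exhaustive
#' enumeration over all interval pairs `(i, j, l)` with `|i - j| <= D`,
#' applying the same tie-breaking rules.  Refuses series longer than
#' `cap` symbols; this function exists to validate the dynamic program,
#' not for production use.
#'
#' @inheritParams lt_score
#' @param cap maximum admissible `m` (default 50).
#' @return an object of class `"lt_result"`.
#' @export
lt_score_bruteforce <- function(u, v, D = 0L, cap = 50L) {
  p <- check_pair(u, v, D)
  if (p$m > cap) stop_input("brute-force oracle refuses m > ", cap)
  best <- NULL
  for (i in seq_len(p$m)) {
    for (j in seq_len(p$m)) {
      if (abs(i - j) > p$D) next
      lmax <- min(p$m - i, p$m - j) + 1L
      s <- 0L
      for (l in seq_len(lmax)) {
        s <- s + p$u[i + l - 1L] * p$v[j + l - 1L]
        if (s == 0L) next
        cand <- list(score = abs(s), sign = if (s > 0L) 1L else -1L,
                     delay = j - i, start_x = i, start_y = j, length = l)
        if (better_candidate(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best)) best <- zero_candidate()
  new_lt_result(best, p$m, p$D)
}

#' @export
print.lt_result <- function(x, ...) {
  cat(sprintf("LT score: %d (normalized %.6f, sign %+d)\n",
              x$score_S, x$lt_norm, x$sign))
  cat(sprintf("  intervals: x[%d..%d] ~ y[%d..%d]  (length %d, delay %d, D = %d)\n",
              x$start_x, x$start_x + max(x$length_l - 1L, 0L),
              x$start_y, x$start_y + max(x$length_l - 1L, 0L),
              x$length_l, x$delay, x$D))
  for (f in c("p_theo", "p_perm", "q")) {
    if (!is.null(x[[f]])) cat(sprintf("  %s = %.6g\n", f, x[[f]]))
  }
  invisible(x)
}
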