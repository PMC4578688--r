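# Preprocessing and discretization of factor profiles into trend alphabets.

# Validate a raw profile: numeric, finite, minimum length.
check_series <- function(x, name = "series", min_len = 2L) {
  if (!is.numeric(x)) stop_input(sprintf("`%s` must be numeric", name))
  if (length(x) < min_len) {
    stop_input(sprintf("`%s` must have at least %d time points", name, min_len))
  }
  if (!all(is.finite(x))) {
    stop_input(sprintf("`%s` contains non-finite values (missing values are not supported)", name))
  }
  as.numeric(x)
}

#' Rank-based normal-score transform
#'
#' Replaces each value by the standard normal quantile of its fractional
#' rank, `qnorm((rank - 0.5) / n)`, with ties receiving average ranks.
#' This is the usual percentile + Z-score normalization applied to
#' sequencing-derived abundance profiles before pairwise comparison: it
#' removes scale and heavy tails while preserving order.
#'
#' @param x numeric vector, length >= 2, all values finite.
#' @return numeric vector of the same length (names preserved).
#' @examples
#' normal_score_transform(c(3, 1, 2))
#' @export
normal_score_transform <- function(x) {
  v <- check_series(x, "x")
  n <- length(v)
  r <- rank(v, ties.method = "average")
  out <- qnorm((r - 0.5) / n)
  names(out) <- names(x)
  out
}

#' Lag-one autoregressive detrending
#'
#' Regresses the value at time `i + 1` on the value at time `i`
#' (ordinary least squares, with intercept) and returns the `n - 1`
#' residuals.  This is an optional preprocessing step for series whose
#' consecutive values are dependent: the residuals are closer to the
#' exchangeability assumption underlying both the permutation null and
#' the Markov-chain approximation.  Off by default in [run_lta()].
#'
#' @param x numeric vector, length >= 3, all values finite.
#' @return numeric vector of `length(x) - 1` residuals.
#' @examples
#' ar1_detrend(c(1, 2, 3, 4))   # exact AR fit, residuals all zero
#' @export
ar1_detrend <- function(x) {
  v <- check_series(x, "x", min_len = 3L)
  n <- length(v)
  lagged <- v[-n]
  if (var(lagged) == 0) {
    stop_input("degenerate input: series is constant, lag-one regression is undefined")
  }
  unname(residuals(lm(v[-1] ~ lagged)))
}

#' Discretize a profile into a trend series
#'
#' Converts a length-`n` profile into `n - 1` trend symbols.  When
#' `x[i] != 0` the relative change `(x[i+1] - x[i]) / |x[i]|` is
#' compared against the threshold `t`: at or above `t` gives `1`
#' (trend-up), at or below `-t` gives `-1` (trend-down), strictly inside
#' the band gives `0` (no change).  When `x[i] == 0` the symbol is the
#' sign of `x[i+1]`.  With `t = 0` the no-change band is empty for
#' nonzero `x[i]`, giving an effectively two-letter alphabet on
#' continuous data.
#'
#' @param x numeric vector, length >= 2, all values finite.
#' @param t relative-change threshold, a single finite number >= 0.
#' @return an integer vector of class `"trend_series"` over \{-1, 0, 1\}
#'   with attributes `threshold_t` and `alphabet_size` (2 when `t = 0`,
#'   3 otherwise).
#' @examples
#' discretize(c(1, 2, 3), t = 0)
#' discretize(c(2, 2.5, 1), t = 0.5)
#' @export
discretize <- function(x, t = 0) {
  v <- check_series(x, "x")
  t <- check_scalar_number(t, "t", min = 0)
  n <- length(v)
  cur <- v[-n]
  nxt <- v[-1]
  d <- integer(n - 1L)
  nz <- cur != 0
  if (any(nz)) {
    ratio <- (nxt[nz] - cur[nz]) / abs(cur[nz])
    d[nz] <- ifelse(ratio >= t, 1L, ifelse(ratio <= -t, -1L, 0L))
  }
  d[!nz] <- as.integer(sign(nxt[!nz]))
  structure(d,
            threshold_t = t,
            alphabet_size = if (t == 0) 2L else 3L,
            class = "trend_series")
}

# Accept either a trend_series or a plain vector of -1/0/1 symbols.
as_trend <- function(u, name = "u") {
  if (inherits(u, "trend_series")) return(as.integer(u))
  if (!is.numeric(u) || !all(u %in% c(-1, 0, 1))) {
    stop_input(sprintf("`%s` must be a trend series with symbols in {-1, 0, 1}", name))
  }
  as.integer(u)
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("Trend series of length %d (t = %g, %d-letter alphabet)\n",
              length(x), attr(x, "threshold_t"), attr(x, "alphabet_size")))
  print(as.integer(x))
  invisible(x)
}

#' Read a factor-by-time matrix
#'
#' Reads a tab-delimited matrix: header row, first column = factor ID,
#' remaining columns = ordered time points.  Ragged rows, non-numeric
#' cells and duplicate factor IDs are rejected with the offending row
#' named.
#'
#' @param path path to a tab-delimited text file.
#' @return numeric matrix with factor IDs as row names.
#' @export
read_lta_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 3L) stop_input("matrix must have a factor-ID column and at least 2 time points")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop_input("duplicate factor ID(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(apply(!is.finite(num), 1L, any))
  if (length(bad)) {
    stop_input("non-numeric or missing cell(s) in row(s): ",
               paste(ids[bad], collapse = ", "))
  }
  rownames(num) <- ids
  colnames(num) <- colnames(df)[-1]
  num
}

#' Write a factor-by-time matrix
#'
#' Emits the same tab-delimited dialect that [read_lta_matrix()] reads.
#'
#' @param m numeric matrix with factor IDs as row names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lta_matrix <- function(m, path) {
  if (is.null(rownames(m))) stop_input("`m` must have factor IDs as row names")
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("t", seq_len(ncol(m)))
  df <- data.frame(factor = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("factor", cn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
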