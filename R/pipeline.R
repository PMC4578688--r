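# All-vs-all local trend analysis pipeline: configuration, the pairwise
# driver, and flat-file output.

#' Pipeline configuration
#'
#' Collects every tunable of [run_lta()] with validation.  Defaults: two
#' -letter analysis (`t = 0`), no delay, fast closed-form significance,
#' normal-score normalization on, AR(1) detrending off, score scaling
#' by the trend length `m = n - 1`.
#'
#' @param t trend threshold, >= 0.
#' @param D delay limit, >= 0.
#' @param sig_mode `"theo"` (closed form only), `"perm"` (permutation
#'   for every pair), or `"hybrid"` (screen with the closed form at
#'   `alpha_screen`, refine survivors by permutation).
#' @param B permutations per pair (perm / hybrid modes).
#' @param alpha_screen screening threshold for hybrid mode, in (0, 1].
#' @param seed master RNG seed (ignored by `"theo"` mode, which draws
#'   no random numbers).
#' @param normal_score apply [normal_score_transform()] to each row.
#' @param detrend apply [ar1_detrend()] to each row (before the
#'   normal-score step; shortens the series by one point).
#' @param sqrt_length_convention `"m"` (trend length, default) or `"n"`
#'   (raw time points) in the score scaling of the approximation.
#' @param add_one add-one permutation estimator (see [perm_pvalue()]).
#' @return object of class `"lta_config"`.
#' @export
lta_config <- function(t = 0, D = 0L, sig_mode = c("theo", "perm", "hybrid"),
                       B = 1000L, alpha_screen = 0.05, seed = 1L,
                       normal_score = TRUE, detrend = FALSE,
                       sqrt_length_convention = c("m", "n"),
                       add_one = TRUE) {
  cfg <- list(t = check_scalar_number(t, "t", min = 0),
              D = check_count(D, "D"),
              sig_mode = match.arg(sig_mode),
              B = check_count(B, "B", min = 1L),
              alpha_screen = check_scalar_number(alpha_screen, "alpha_screen"),
              seed = check_count(seed, "seed"),
              normal_score = isTRUE(normal_score),
              detrend = isTRUE(detrend),
              sqrt_length_convention = match.arg(sqrt_length_convention),
              add_one = isTRUE(add_one))
  if (cfg$alpha_screen <= 0 || cfg$alpha_screen > 1) {
    stop_input("`alpha_screen` must be in (0, 1]")
  }
  structure(cfg, class = "lta_config")
}

#' @export
print.lta_config <- function(x, ...) {
  cat("LTA configuration:\n")
  for (f in names(x)) cat(sprintf("  %s: %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Write a configuration to a key-value text file
#'
#' Debian-control-style `key: value` lines; [read_lta_config()] restores
#' an identical object.
#'
#' @param config an [lta_config()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lta_config <- function(config, path) {
  if (!inherits(config, "lta_config")) stop_input("`config` must be an lta_config")
  fields <- lapply(config, function(v) format(v, digits = 17))
  write.dcf(as.data.frame(fields, stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read a configuration from a key-value text file
#'
#' @param path a file written by [write_lta_config()].
#' @return an [lta_config()] object.
#' @export
read_lta_config <- function(path) {
  rec <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  num <- function(f) as.numeric(rec[[f]])
  lta_config(t = num("t"), D = num("D"), sig_mode = rec$sig_mode,
             B = num("B"), alpha_screen = num("alpha_screen"),
             seed = num("seed"),
             normal_score = as.logical(rec$normal_score),
             detrend = as.logical(rec$detrend),
             sqrt_length_convention = rec$sqrt_length_convention,
             add_one = as.logical(rec$add_one))
}

#' All-vs-all local trend analysis
#'
#' Runs the full pipeline on a factor-by-time matrix: per-row
#' preprocessing (optional AR(1) detrending, then normal-score
#' normalization), discretization at threshold `t`, banded LT scoring of
#' every unordered factor pair with delay limit `D`, significance per
#' `sig_mode`, and Benjamini-Hochberg q-values across all pairs.
#'
#' In `"theo"` mode the significance of all pairs is served from one
#' precomputed score-to-p lookup table and no random numbers are drawn;
#' runtime per pair is the `O(n * D)` dynamic program plus an O(1)
#' lookup.  Pairs are oriented with the lexicographically smaller
#' factor as `factor_x`; `delay` is `start_y - start_x` at the optimum
#' in that orientation.
#'
#' @param x numeric matrix (factor IDs as row names) or path to a
#'   tab-delimited matrix file (see [read_lta_matrix()]).
#' @param config an [lta_config()] object.
#' @return data frame, one row per unordered factor pair, with columns
#'   `factor_x`, `factor_y`, `score_S`, `lt_norm`, `sign`, `delay`,
#'   `start_x`, `start_y`, `length`, `p`, `p_source`, `q`,
#'   `validity_flag`.  The resolved null-model parameters are attached
#'   as attribute `"model"`; the effective series length as `"n"`.
#' @export
run_lta <- function(x, config = lta_config()) {
  if (!inherits(config, "lta_config")) stop_input("`config` must be an lta_config")
  mat <- if (is.character(x)) read_lta_matrix(x) else x
  if (!is.matrix(mat) || !is.numeric(mat)) stop_input("`x` must be a numeric matrix or a file path")
  if (is.null(rownames(mat))) stop_input("`x` must have factor IDs as row names")
  if (anyDuplicated(rownames(mat))) stop_input("duplicate factor IDs")
  if (nrow(mat) < 2L) stop_input("need at least 2 factors")
  bad <- which(apply(!is.finite(mat), 1L, any))
  if (length(bad)) {
    stop_input("non-finite value(s) in row(s): ",
               paste(rownames(mat)[bad], collapse = ", "))
  }

  # preprocessing: detrend shortens each series by one point
  if (config$detrend) mat <- t(apply(mat, 1L, ar1_detrend))
  if (config$normal_score) mat <- t(apply(mat, 1L, normal_score_transform))
  n <- ncol(mat)
  if (n < 2L) stop_input("too few time points after preprocessing")
  if (config$D > n - 2L) stop_input("delay limit D must be at most n - 2")
  m <- n - 1L

  ids <- sort(rownames(mat))
  mat <- mat[ids, , drop = FALSE]
  trends <- lapply(seq_len(nrow(mat)),
                   function(i) as.integer(discretize(mat[i, ], config$t)))
  names(trends) <- ids

  model <- trend_null_model(config$t)
  len <- if (config$sqrt_length_convention == "n") n else m
  ptab <- build_pvalue_table(len, model$sigma2, config$D)

  pairs <- combn(ids, 2L)
  np <- ncol(pairs)
  res <- vector("list", np)
  for (k in seq_len(np)) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    r <- lt_score(trends[[a]], trends[[b]], config$D)
    res[[k]] <- data.frame(factor_x = a, factor_y = b,
                           score_S = r$score_S, lt_norm = r$lt_norm,
                           sign = r$sign, delay = r$delay,
                           start_x = r$start_x, start_y = r$start_y,
                           length = r$length_l,
                           p = lookup_pvalue(ptab, r$score_S),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  res$p_source <- rep("theo", np)

  if (config$sig_mode == "perm") {
    seeds <- derive_seeds(config$seed, np)
    for (k in seq_len(np)) {
      res$p[k] <- perm_pvalue(mat[res$factor_x[k], ], mat[res$factor_y[k], ],
                              t = config$t, D = config$D, B = config$B,
                              seed = seeds[k], add_one = config$add_one)
      res$p_source[k] <- "perm"
    }
  } else if (config$sig_mode == "hybrid") {
    res <- hybrid_pvalues(res, mat, t = config$t, D = config$D,
                          B = config$B, alpha_screen = config$alpha_screen,
                          seed = config$seed, add_one = config$add_one)
  }

  res$q <- bh_qvalues(res$p)
  res$validity_flag <- lta_validity(n, config$D, res$p, res$p_source)
  attr(res, "model") <- list(t = config$t, b = model$b, c = model$c,
                             d = model$d, sigma2 = model$sigma2)
  attr(res, "n") <- n
  res
}

#' Write pipeline results as a flat TSV
#'
#' One pair per row, tab-delimited, deterministic formatting.
#'
#' @param results a [run_lta()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lta_results <- function(results, path) {
  out <- results
  for (col in c("lt_norm", "p", "q")) out[[col]] <- sprintf("%.6g", out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export significant pairs as a network edge list
#'
#' Writes `source, target, sign, delay, q` rows for pairs with
#' `q <= q_max`, a format directly loadable by network tools.
#'
#' @param results a [run_lta()] data frame.
#' @param path output path.
#' @param q_max FDR cutoff for inclusion.
#' @return number of edges written, invisibly.
#' @export
export_edges <- function(results, path, q_max = 0.05) {
  keep <- results$q <= q_max
  edges <- data.frame(source = results$factor_x[keep],
                      target = results$factor_y[keep],
                      sign = results$sign[keep],
                      delay = results$delay[keep],
                      q = sprintf("%.6g", results$q[keep]),
                      stringsAsFactors = FALSE)
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sum(keep))
}
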