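Package: trendsig
Title: Local Trend Analysis of Biological Time Series with Fast
    Markov-Chain Significance Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Local trend analysis (LTA) for time series of biological
    factors (OTU abundances, gene expression, environmental variables).
    Series are discretized into up/no-change/down trend alphabets, pairs
    are scored by a banded Smith-Waterman local alignment of trend
    symbols with a bounded time delay, and statistical significance is
    assigned either by a closed-form tail approximation for the range of
    partial sums of a Markov product chain, by permutation, or by a
    hybrid of both, with Benjamini-Hochberg false discovery rate control
    across all factor pairs.  Includes a synthetic-data generator and
    simulation experiments that validate the approximation against
    empirical null tails, plus a command-line pipeline for all-vs-all
    analysis of tab-delimited factor-by-time matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
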