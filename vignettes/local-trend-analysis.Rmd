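---
title: "Local trend analysis: model, significance approximation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local trend analysis: model, significance approximation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendsig)
```

## The problem

Time-resolved omics studies — monthly 16S surveys of a marine microbial
community, daily human-microbiome sampling, synchronized cell-cycle
expression courses — produce a matrix of factors (OTUs, genes,
environmental variables) by ordered time points.  Two factors can be
strongly coupled while showing no global correlation: the coupling may
hold only on a subinterval, may lag by a few sampling steps, or may
concern the *direction* of change rather than the level.  Local trend
analysis targets exactly that: it asks whether the up/down *shapes* of
two series align locally, possibly with a bounded delay.

## The statistic

Each profile $X_1,\dots,X_n$ is discretized into a trend series
$d^X_1,\dots,d^X_{n-1}$ over $\{-1,0,1\}$.  For $X_i \neq 0$ the symbol
compares the relative change $(X_{i+1}-X_i)/|X_i|$ to a threshold
$t \ge 0$: at least $t$ is an up-trend, at most $-t$ a down-trend,
strictly inside the band no-change.  For $X_i = 0$ the symbol is the
sign of $X_{i+1}$.  With $t = 0$ the band is empty and continuous data
yield a two-letter alphabet.

For a pair of trend series $u, v$ of length $m = n - 1$ and a delay
limit $D$, the local trend (LT) score is

$$ S \;=\; \max_{\substack{i,j,l \;:\; |i-j|\le D}}
   \Bigl|\sum_{k=0}^{l-1} u_{i+k}\,v_{j+k}\Bigr| , $$

found by a Smith–Waterman-style dynamic program restricted to the band
$|i-j| \le D$ (`lt_score()`).  The package reports the integer score,
the normalized score $S/m$, the alignment sign, the optimal intervals
and their delay $j - i$.  A note on implementation: for a fixed offset
$j-i$ every admissible interval lies on one diagonal of the alignment
matrix, where the two-table recursion
$P \leftarrow \max(0, P + u v)$, $N \leftarrow \max(0, N - u v)$
is algebraically the range (max minus min) of the prefix sums of the
symbol products.  `lt_score()` therefore processes the band diagonal by
diagonal with cumulative sums; the test suite enforces exact agreement
— scores, signs, delays and intervals — with an independent
brute-force enumeration (`lt_score_bruteforce()`) over thousands of
random instances.

Ties among equal-score optima are broken deterministically (smaller
$|delay|$, then positive sign, then smaller `start_x`, then positive
delay) so that repeated runs are byte-identical.

## The null model and the closed-form p-value

The null hypothesis is that the two series are unrelated and each is
*exchangeable* (every ordering equally likely).  Permutation testing
follows directly (`perm_pvalue()`), but costs $O(B)$ alignments per
pair and its resolution is limited by $B$ — prohibitive for
all-vs-all analysis of thousands of factors.

The fast route models the trend symbols as a first-order Markov chain.
This is a deliberate simplification — consecutive trend symbols share a
source value and are not Markov of any order — but it brings the tail
theory for ranges of partial sums of Markov variables to bear, and its
accuracy is then checked empirically (below).  At $D = 0$ the LT score
is exactly the range of partial sums of the product sequence
$Z_i = u_i v_i$, so

$$ P\!\left(S \ge s\right) \;\approx\;
   \mathcal{L}\!\left(\frac{s}{\sigma\sqrt{m}}\right), \qquad
   \mathcal{L}(x) = 1 - 8\sum_{k=1}^{\infty}
   \Bigl(\tfrac{1}{x^2} + \tfrac{1}{(2k-1)^2\pi^2}\Bigr)
   \exp\!\Bigl(-\tfrac{(2k-1)^2\pi^2}{2x^2}\Bigr), $$

where $\sigma^2$ is the long-run variance of the product chain
(stationary variance plus twice the summed lagged autocovariances).
With a delay limit $D$, the maxima at the $2D+1$ offsets are treated as
independent, giving
$\mathcal{L}_D(x) = 1-(1-\mathcal{L}(x))^{2D+1}$ (`tail_prob_delay()`).
The independence is again an approximation (all offsets reuse the same
data); it is part of what the simulation experiments check.

**Two-letter case ($t=0$).**  Order statistics of exchangeable
continuous values give the transition matrix exactly: staying in the
same trend state has probability $1/3$, switching $2/3$.  The lagged
autocorrelations are $(-1)^k/3^k$ and
$\sigma^2 = 1 + 2\sum_k 9^{-k} = 1.25$.  `two_letter_model()` computes
this sum over actual matrix powers (18 terms to machine precision)
rather than assigning the constant.

**Three-letter case ($t>0$).**  No closed form exists for the
transition parameters; by the up/down symmetry three numbers suffice
($b$ = stay up, $c$ = up to down, $d$ = leave no-change upward).  The
package estimates them either by Monte Carlo on a long simulated
i.i.d. standard normal series (`estimate_transition_params()`, with
symmetric transition counts pooled so the model's symmetry holds
exactly), or — the default, because it is deterministic — by nested
adaptive Gaussian quadrature over the discretization regions of three
consecutive normals (`transition_params_quadrature()`).  The stationary
distribution, the closed-form spectral expansion of $T^k$ (eigenvalues
$1$, $b-c$, $b+c-2d$) and
$\sigma^2(t) = 4\varphi_1^2\,(1 + 2(b-c)^2/(1-(b-c)^2))$
follow analytically; each is tested against an independent oracle
(repeated matrix multiplication, direct series summation).

## Numerical choices

* **Far-tail evaluation.**  The theta-type series for $\mathcal{L}$
  computes $1 - (\text{sum} \approx 1)$: in double precision everything
  below about $10^{-13}$ is cancellation noise.  `tail_prob()` therefore
  switches, at $x \ge 4$, to the exactly equivalent Poisson resummation
  $\mathcal{L}(x) = 8\sum_{j\ge1} (-1)^{j+1}\, j\, \Phi(-jx)$,
  which is cancellation-free and resolves arbitrarily small tails.  The
  two representations agree to better than $10^{-11}$ across the
  overlap region (tested), and both reproduce the frozen reference
  values at $x = 2$ and $x = 3$.
* **Truncation.**  The theta series is cut when a term falls below
  $10^{-16}$, with a hard cap of 500 terms; the resummation needs only
  a handful of terms anywhere it is used.
* **Clamping.**  The asymptotic series can exceed 1 for small $x$; the
  result is clamped to $[0,1]$ rather than erroring, since only the
  small-$p$ region is of inferential interest.
* **Scaling length.**  The partial sums run over $m = n-1$ product
  terms, so the score is scaled by $\sqrt{\sigma^2 m}$ by default;
  `sqrt_length_convention = "n"` restores scaling by the raw number of
  time points.  The difference is immaterial at the recommended sample
  sizes but is pinned down explicitly.  `simulate_null_tail()` defaults
  to the $n$ convention, matching the usual presentation of simulated
  null tables.
* **Permutation estimator.**  `perm_pvalue()` defaults to the add-one
  estimator $(c+1)/(B+1)$, which never reports 0 and is the proper
  p-value of the permutation test that includes the observed ordering;
  `add_one = FALSE` restores the raw fraction.
* **Degenerate inputs.**  Missing values are rejected, not imputed;
  constant series fail AR(1) detrending with a clear error; all-zero
  trend pairs score 0 and report $p = 1$.

## Validity region and the hybrid strategy

The tail law is asymptotic.  Empirically the approximate p-value
tracks permutation p-values once $p < 0.05$ and the series has at
least 20 time points at $D = 0$, or 30 with $D \le 3$; within that
region it sits slightly *above* the permutation value, i.e. the test
is conservative.  `run_lta()` flags rows outside the trusted region
(`validity_flag = FALSE`), and `simulate_null_tail()` /
`compare_theo_perm()` let users reproduce the calibration for their own
$(n, D, t)$.

Conservativeness costs power.  The hybrid mode restores it cheaply:
compute the approximation for all pairs, then refine only pairs with
$p \le \alpha_{screen}$ (default 0.05) by permutation.  Under the null
only about $\alpha_{screen}$ of the pairs are permuted, so the expensive
route runs on a small fraction of a large pair set.

In `"theo"` mode the pipeline precomputes a score→p lookup table
(`build_pvalue_table()`) once per run — lookups are O(1) and
bit-identical to direct evaluation — and draws no random numbers at
all.

## What the synthetic generator does and does not establish

`gen_null_pair()` / `gen_null_matrix()` draw i.i.d. standard normal
series: the stated null world, and the world in which the transition
parameters are defined, since profiles are assumed rank-normalized
(`normal_score_transform()`) before comparison.  Green simulation tests
therefore establish that the approximation is calibrated and
conservative *under exchangeable, continuous, independent nulls*.  They
do not establish calibration for sparse zero-inflated counts (many
identical values break the continuity behind the two-letter transition
probabilities), for strongly autocorrelated series (use
`ar1_detrend()` and/or permutation mode), or for the dependence among
the $2D+1$ delay offsets beyond what the $D \le 3$ experiments cover.
On real sparse data the approximation has been observed to be markedly
more conservative than permutations; the hybrid mode is the pragmatic
answer.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `t` | relative-change band half-width (dimensionless) | 0 | two-letter analysis; the exact $\sigma^2=1.25$ applies |
| `D` | delay limit (sampling steps) | 0 | delays multiply the effective tests; keep $\le 3$ |
| `B` | permutations per refined pair | 1000 | p-resolution $\approx 10^{-3}$ |
| `alpha_screen` | hybrid screening level | 0.05 | loose enough to protect power, tight enough to spare compute |
| `normal_score` | rank-normalize rows | TRUE | makes the i.i.d. normal null model applicable |
| `detrend` | AR(1) residuals first | FALSE | only when consecutive dependence is evident; shortens series by 1 |
| `sqrt_length_convention` | $m$ or $n$ in the score scaling | "m" | the sums run over $m = n-1$ terms |

## Known limitations

* The Markov and delay-independence assumptions are heuristic; the
  p-values are approximations validated empirically, not rigorous
  bounds.  The conservative direction of the error is the saving grace.
* Short series ($n < 20$) should use permutation mode only.
* No replicate handling, bootstrap confidence intervals, or
  missing-data imputation; profiles must be complete and one-per-factor.
* Scoring raw levels (local similarity of values rather than trends) is
  out of scope.
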