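---
title: "Plasmode benchmarking of DE methods for low-count transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasmode benchmarking of DE methods for low-count transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmodeDE)
```

## The problem

Differential expression (DE) inference on RNA-seq counts is hardest where
the data are thinnest: *low-count transcripts* — here, the bottom 60th
percentile of total read abundance, which in typical datasets holds only a
few percent of all reads — carry little information per transcript, and
methods differ most in how they borrow strength across transcripts to
stabilize inference there. Two widely used strategies are

* **LFC shrinkage** (`run_shrink_engine()`): a negative-binomial (NB) GLM
  with empirical-Bayes moderation of both the dispersion (toward a
  mean-dependent trend) and the log2 fold change (toward a zero-centered
  normal prior), tested by a Wald statistic on the shrunken LFC;
* **robust observation weights** (`run_robust_engine()`): an NB GLM with
  dispersions moderated toward a common value by a *prior degrees of
  freedom* (prior DF) parameter, Huber weights on Pearson residuals to
  damp outlying observations, and a likelihood-ratio test. The `classic`
  variant is the same pipeline without the weights.

A *plasmode* study evaluates such methods on reshuffled real (or
realistically simulated) data: samples of a single condition are
repartitioned into two arbitrary groups, so any DE call is a false
positive (**null plasmode**); known log2 fold changes drawn from a pool of
previously estimated effect sizes are then multiplied into one group for a
fraction π of transcripts (**DE plasmode**), providing ground truth for
power, precision, NPV and accuracy while preserving the data's
distributional quirks.

## The model

Counts are modeled as `K_ij ~ NB(mean = mu_ij, dispersion = alpha_i)` with
`Var = mu + alpha * mu^2` and a log link. The two engines differ in the
mean decomposition:

* shrinkage engine: `mu_ij = s_j * q_ij`, `log q_ij = x_j' beta_i`, with
  `s_j` the **median-of-ratios size factor** entering as offset `log s_j`;
* robust/classic engines: `log mu_ij = x_j' beta_i + log N_j`, with `N_j`
  the raw library size (column sum).

Coefficients are estimated by IRLS (Fisher scoring) on the natural-log
scale and reported as log2. For the saturated two-group design the IRLS
update has a closed per-iteration form (weighted working-response means
per group), which the package exploits to fit all transcripts at once;
the scalar `fit_nb_glm()` implements the general design with
step-halving and is cross-checked against the vectorized path in the
tests.

### Dispersion estimation

* *Genewise*: Cox-Reid adjusted profile likelihood — the NB log-likelihood
  at the IRLS-fitted means minus `0.5 * log det(X'WX)` — maximized over
  `alpha` in `[1e-8, 10]`.
* *Trend*: a Gamma-family GLM fit of the genewise estimates to
  `a0 + a1 / mu`, with a second pass excluding gross outliers
  (ratio outside `[1e-4, 15]`), coefficients constrained non-negative.
* *MAP*: the Cox-Reid objective plus a log-normal prior centered at the
  trend with variance
  `max(var(log genewise - log trend) - trigamma((n-p)/2), 0.25)`.
* *Common* (robust path): the maximizer of the average per-transcript
  **conditional log-likelihood**, computed on counts rescaled
  (mean-preservingly, then rounded) to the geometric-mean library size.
  This rescaling is a deliberate simplification of quantile adjustment:
  it keeps the equal-library-size conditioning argument valid to first
  order and is the documented surrogate for the exact qCML algorithm.
* *Moderated tagwise*: per transcript, maximize
  `l_g(alpha) + (prior_df / df_res) * lbar(alpha)`, where `lbar` is the
  average conditional log-likelihood curve. `prior_df` is thereby
  interpretable as prior residual-df worth of shared information:
  `prior_df = 0` gives the tagwise MLE, `prior_df -> Inf` the common
  value. The data-driven `estimate_prior_df()` moment-matches
  `var(log alpha_hat) = trigamma(df_res/2) + trigamma(d0/2)` and solves
  for `d0` (capped at 1e6 when the observed spread does not exceed the
  sampling variance).

All dispersion optimizations use a coarse log-spaced grid, a local fine
grid, and two quadratic-vertex refinements; tests compare this machinery
against dense grid searches and scalar `optimize()` oracles.

### LFC shrinkage and testing

The LFC prior standard deviation is set globally so the prior's 0.95
quantile of `|LFC|` matches the observed 0.95 quantile of the finite-SE
maximum-likelihood LFCs (floor 0.1 log2 units) — a concrete stand-in for
"shrinkage inversely proportional to information". Under the quadratic
approximation the MAP estimate is the ridge form
`lfc * psd^2 / (psd^2 + se^2)`. Wald p-values are
`2 * (1 - Phi(|lfc/se|))`; LRTs compare full vs intercept-only fits at
the final dispersions against a chi-square with 1 df. Transcripts at the
zero-count boundary keep their row in the output with `SE = Inf`, Wald
p = 1 and the sign of the clamped LFC (the LRT remains computable).
Benjamini-Hochberg step-up adjustment (`bh_adjust()`, hand-implemented
and oracle-tested) yields calls at the configured FDR.

## The synthetic world

`sim_config()` defaults state the world the tests and the acceptance
study run in; they were chosen once, to match the qualitative structure
the analysis assumes, and are not tuned:

| parameter | default | why |
|---|---|---|
| `n_transcripts` | 2000 | desk-scale stand-in for a 25k-transcript dataset |
| `n_per_group` | 4 | the motivating 4 + 4 design |
| `logmean_location` | `log(5)` | median baseline expectation of 5 counts/sample |
| `logmean_scale` | 2.13 | makes the bottom 60% of transcripts hold ~3% of reads and the top 3% hold ~60% (the log-normal share identity `Phi(Phi^-1(p) - sigma)`) |
| `disp_a0`, `disp_a1` | 0.1, 1 | BCV ~0.32 at high counts, rising as the mean falls |
| `libsize_factors` | range 0.5–2, log-uniform | unequal library sizes |
| `frac_group_only` | 0 | "group-only" transcripts opt-in |

Counts are gamma-Poisson draws; group-only transcripts are zeroed
post-draw (reproducing the all-zero-in-one-group pattern exactly rather
than via `delta = -Inf`). One top-level seed expands into named
substreams (transcript parameters, structure, counts), so enlarging the
matrix never perturbs earlier transcripts' draws.

What the generator does *not* emulate: transcript-to-transcript
correlation, positional/GC bias, and the exact mean-dispersion relation
of any real dataset. A green test therefore establishes that the
machinery behaves as specified on data with the assumed marginal
structure — not that any particular real dataset will show the same
orderings between methods.

The default benchmark source (`benchmark_config()`) gives 40% of
transcripts a true log2 fold change of magnitude `1 + Exp(rate = 2/3)`
with random sign. This is deliberately generous so that the pool of
harvested effect sizes (classic-engine calls at FDR 0.05 on the source)
comfortably exceeds the `round(0.2 * G)` effects each DE plasmode draws
without replacement — mirroring how the original study harvested its
pool from a preliminary analysis of real two-condition data.

## Plasmode construction choices

* Effects are log2 fold changes applied multiplicatively,
  `y -> round(y * 2^delta)` with half-away-from-zero rounding: this
  avoids a pseudo-count choice and keeps counts integral. Zero counts
  stay zero; spiked-but-unexpressed transcripts remain in the truth with
  `delta != 0`, uniformly depressing measured power for every method.
* Spikes always go into group B of the partition; the sign of `delta`
  supplies directionality.
* Stratum membership (low/mid/high) is frozen from the source data so
  spiking cannot migrate transcripts between strata.
* Filters (reads-present; CPM) are applied to the source data before
  plasmode construction, and CPM always uses the raw unfiltered library
  sizes.

## Numerical and design notes

* IRLS: relative-change tolerance 1e-8, at most 100 iterations
  (60 in the vectorized path), step clamping, means clamped to
  `[1e-10, 1e14]`; the scalar fitter adds step-halving on likelihood
  decrease.
* Huber tuning constant `k = 1.345` (the standard 95%-efficiency
  choice); the robust cycle iterates fit → weights → dispersions three
  times or to a 1e-4 weight change. The shared likelihood curve `lbar`
  stays unweighted so all transcripts are moderated toward the same
  reference; weights scale each observation's contribution to its own
  transcript's conditional likelihood (fractional observations).
* With a pure-null dataset the estimated LFC prior SD collapses toward
  the sampling noise of the MLEs, making the shrunken-LFC Wald test
  conservative relative to the LRT; with realistic signal present the
  two approximate tests agree closely at high counts.
* The robust engine's raw `log(N_j)` offsets are kept as stated even
  though multiplicative spiking shifts group-B library sizes
  (`E[2^delta] > 1` for sign-symmetric effects): on some spiked worlds
  this makes the robust engine anticonservative *on DE plasmodes*
  (null-plasmode error control is unaffected). Normalizations robust to
  a minority of DE transcripts (median-of-ratios, TMM) absorb this; TMM
  is deliberately out of scope. This is a known limitation to keep in
  mind when reading DE-plasmode FPR/PPV columns.
* Directional orderings between engines (robust power above shrinkage
  power on low counts; shrinkage precision above robust; FPR rising
  with prior DF) are reported as soft pass/warn checks: they summarize
  what was observed on the original real-data study, and a synthetic
  world need not reproduce all of them. On the shipped defaults, the
  power ordering holds clearly; the precision ordering and the
  FPR-vs-prior-DF monotonicity vary with the world's seed.

## Known limitations

* Two-group designs only; no blocking, no quasi-likelihood F-tests.
* The prior-DF estimator is a moment-matching surrogate for the exact
  quantile-adjusted conditional ML estimator; its values are comparable
  in spirit (small single-digit estimates on heterogeneous data, large
  cap on homogeneous data) but not numerically interchangeable.
* Aggregation across plasmodes is descriptive (mean ± SEM); the original
  mixed-model/Tukey-Kramer comparison machinery is out of scope.
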