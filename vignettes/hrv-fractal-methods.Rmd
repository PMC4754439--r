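---
title: "Multifractal and visibility-graph characterisation of heart-rate series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal and visibility-graph characterisation of heart-rate series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvfractal)
```

## The problem

Instantaneous heart rate (beats/minute, derived from inter-beat intervals)
is a non-stationary, nonlinear signal. Classical spectral summaries assume
stationarity and linear superposition, so comparisons between physiological
states — here, pre-meditation versus meditation recordings of subjects
practising Chi meditation (C1–C8) and Kundalini Yoga (Y1–Y4), in the
PhysioNet meditation database — are better served by scale-based
complexity measures. This package implements two complementary ones and a
pipeline for comparing states subject by subject:

* **MF-DFA** (multifractal detrended fluctuation analysis): the width
  $\Delta\alpha$ of the singularity spectrum $f(\alpha)$, a measure of
  *multifractality* — how broad the range of local scaling exponents is.
* **Natural visibility graph**: the exponent $\lambda_p$ of the power-law
  degree distribution $P(k) \propto k^{-\lambda_p}$ of the graph whose
  nodes are time samples and whose edges are unobstructed lines of sight —
  a measure of *complexity / fractal dimension* that remains usable on
  series as short as a few hundred samples, where MF-DFA is starved of
  scales.

Running both on the same pair of recordings is a double-check: if both
rank the meditation state above the pre-meditation state, the conclusion
does not hinge on either method's assumptions.

## MF-DFA

For a series $x(i)$, $i = 1 \dots N$, the chain is:

1. profile $Y(i) = \sum_{k \le i} (x(k) - \bar x)$;
2. cut the profile into $N_s = \lfloor N/s \rfloor$ non-overlapping
   windows of length $s$ and compute the mean squared residual
   $F^2(s, v)$ of each window about its least-squares polynomial of order
   $m$;
3. form the $q$-order average
   $F_q(s) = \{ \tfrac{1}{N_s}\sum_v [F^2(s,v)]^{q/2} \}^{1/q}$, with the
   logarithmic limit $F_0(s) = \exp\{\tfrac{1}{2N_s}\sum_v \ln F^2(s,v)\}$
   at $q = 0$;
4. the slope of $\log_2 F_q(s)$ on $\log_2 s$ is the generalized Hurst
   exponent $h(q)$;
5. $\tau(q) = q\,h(q) - 1$, then the Legendre transform
   $\alpha = h(q) + q h'(q)$, $f(\alpha) = q[\alpha - h(q)] + 1$, and the
   headline statistic $\Delta\alpha = \max\alpha - \min\alpha$.

Negative $q$ emphasises the quietest windows, positive $q$ the most
volatile ones; a monofractal has constant $h(q)$ and $\Delta\alpha \approx 0$.

### Parameters

* `q_grid`: 100 equidistant values on $[-5, 5]$, endpoints included. The
  grid does not contain $q = 0$ exactly, but the $q \to 0$ branch is
  implemented (and tested) for grids that do. Beyond $|q| = 5$ the moments
  of short physiological series are dominated by single windows.
* `scale_grid`: 16 window sizes equispaced in $\log_2$ between 16 and 256
  samples, rounded and deduplicated. The lower end keeps $\ge m + 2$
  points per fit with headroom; the upper end keeps $N_s \ge N/256$
  windows in the moment average. Both ends and the count are
  configurable; `run_mfdfa` requires $N \ge 4 \max(s)$ and warns below
  $N \approx 1024$, where the regression has too few independent windows.
* `order` ($m$): 1 (linear detrending). Heart-rate records carry slow
  drifts rather than high-order polynomial trends; higher orders mainly
  eat degrees of freedom in 16-sample windows, but the order is
  configurable.
* `bidirectional`: off by default — windows are taken forward only and the
  tail remainder $N - N_s s$ is discarded, following the displayed
  definition of $F_q(s)$; the doubled-window variant (forward plus
  backward) is available behind the flag.

### Numerical choices

* Windows are detrended jointly per scale: the profile is reshaped to an
  $s \times N_s$ matrix and one QR factorisation of the shared polynomial
  design is applied to all columns. A dedicated `local_rms` reproduces
  single windows for inspection; tests pin it to an independently coded
  normal-equations fit at $10^{-10}$ relative tolerance.
* A window with exactly zero residual (a constant segment) makes negative
  moments infinite. That raises an error naming the scale, with the
  remediation hint (lower `order`, or drop the scale) — not a silent
  `Inf`.
* $h'(q)$ uses central differences on the $q$ grid, one-sided at the two
  endpoints. The endpoint derivative is the noisiest ingredient of
  $\Delta\alpha$; see the reliability note below.
* The width is taken over the computed $q$ range, not extrapolated to
  $q \to \pm\infty$: it is the width of the arc the procedure actually
  produces.
* Non-monotone $\alpha(q)$ (possible for noisy $h(q)$) is kept, flagged
  via the `monotone_alpha` attribute, and the width is still
  $\max - \min$.

### Validation against ground truth

Two analytic oracles back the chain (both run in the test suite):

* **Fractional Gaussian noise** with Hurst exponent $H$, synthesised by
  Davies–Harte circulant embedding, which is exact in distribution — the
  sample autocovariance matches
  $\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})$ within
  three standard errors over 20 seeds, using the known-zero-mean
  autocovariance estimator (the mean-subtracted estimator is biased
  downward for long-range-dependent data). MF-DFA recovers
  $h(2) \approx H$ within 0.1 for $H \in \{0.3, 0.5, 0.7\}$ at $N = 2^{13}$.
* **The binomial multifractal cascade** with multiplier $a$, whose
  exponents are known in closed form,
  $h(q) = 1/q - \ln(a^q + (1-a)^q)/(q \ln 2)$. Validation uses dyadic
  scales ($s = 16, 32, \dots, 256$, i.e. `n_scales = 5`): the cascade is
  built on a dyadic grid, and only dyadic windows align with its
  construction cells. With the default 16-point rounded scale grid,
  misaligned windows mix adjacent cells and bias $h(q > 0)$ low by up to
  0.12 at $N = 2^{13}$; on dyadic scales the error is a uniform
  $-0.033$, within the 0.05 the tests require for
  $q \in \{-5, -2, 2, 5\}$.

## Visibility graphs

Samples $X_m$ and $X_n$ ($m < n$) are joined iff every intermediate sample
lies *strictly* below the chord between them. The implementation evaluates
the criterion in slope form — $X_t$ blocks the pair iff
$(X_t - X_m)/(t - m) \ge (X_n - X_m)/(n - m)$ — which is algebraically the
same inequality but, unlike the chord-anchored form, classifies exactly
collinear points exactly in floating point, so ties always break toward
fewer edges. The construction is an $O(n^2)$ running-maximum-slope sweep
in C++; the test suite pins it to an exhaustive $O(n^3)$ triple-loop
oracle on random series, including heavily tied integer-valued ones.

The criterion compares slopes only, so the graph is invariant under adding
any constant to the series. The conventional preliminary shift of the
series into the positive half-plane is therefore a no-op; it is available
as an explicit `shift_positive` flag, and a test proves it never changes
the graph.

$\lambda_p$ is the least-squares gradient of $\log_2 P(k)$ against
$\log_2(1/k)$, so an exact power law $P(k) = c\,k^{-\lambda}$ returns
$+\lambda$ with $R^2 = 1$. The fit window matters and is an explicit,
reported choice (`fit_range` in the result):

* **default**: all observed degrees — nothing is hidden;
* **`auto_range`**: degrees $k \ge 4$ up to the largest degree observed at
  least twice. The two boundary nodes and the guaranteed sequential path
  make $k \le 3$ geometry- rather than fractality-dominated, and the
  singleton tail (many distinct large degrees, each at $P(k) = 1/n$)
  flattens the regression. On fractional Brownian motion the all-degree
  fit is biased low by roughly 0.35 across $H$; with `auto_range` the
  estimator tracks the Lacasa relation $\lambda_p = 3 - 2H$ within 0.3
  for $H \in \{0.3, 0.5, 0.8\}$ at $n = 4096$ (10 seeds), which is the
  configuration the recovery tests use.

## The synthetic generators

`generate_fgn` / `generate_fbm` (exact-covariance monofractals, the Hurst
oracles), `generate_binomial_cascade` (deterministic multifractal with
closed-form $h(q)$), `generate_bpm_like` (baseline + slow sinusoid +
correlated noise, defaults chosen to resemble resting human BPM traces of
roughly 55–105 beats/minute), and `shuffle_series` (seeded Fisher–Yates
surrogate preserving the value multiset exactly). All seeded generators
are bit-reproducible and leave the caller's RNG state untouched. The
BPM-like generator's noise is centred in-sample so that `baseline` is the
realised mean.

What these stand-ins do *not* emulate: uneven sampling of instantaneous
heart rate (both analyses here deliberately treat the series as an ordered
sample sequence; time stamps are metadata), respiratory sinus arrhythmia,
ectopic beats, and any physiological coupling between states of one
subject. Passing tests demonstrate that the estimators recover known
exponents and orderings on controlled signals — not that any particular
physiological conclusion holds.

Two empirical facts about these generators shaped the test design:

* Along every single generator axis the two markers move in *opposite*
  directions (more noise: $\lambda_p$ up, width down; more persistence or
  oscillation: width up, $\lambda_p$ down). A synthetic pair in which the
  "meditation" state raises both markers — as the published heart-rate
  comparisons show — therefore needs two axes at once. The concordance
  test uses pre = fBm($H = 0.65$) versus med = a multifractal random walk
  (cascade-modulated, anti-persistent increments, integrated): rougher
  *and* more multifractal. With that construction both methods rank
  med > pre in $\ge 8$ of 10 paired seeds.
* For *monofractal* correlated noise (fGn, $H = 0.9$), shuffling removes
  only a small finite-size width excess ($\approx 0.02$–0.04), which is
  the same order as the width's own seed-to-seed noise (sd $\approx
  0.03$; the endpoint derivatives of $h(q)$ dominate). Replicated
  measurements at $N = 2^{13}$ through $2^{17}$, with five-shuffle
  averaged surrogates and with bidirectional binning, put the probability
  that a single shuffled width is below its original at roughly 0.6–0.85
  — the *mean* paired difference is reliably positive, and that is the
  property the MF-DFA suite asserts. A 9-in-10 per-seed ordering is at
  the edge of what the statistic supports for monofractal input; one
  acceptance check states that stricter ordering and is expected to fail
  for some seed sets. On genuinely multifractal signals (cascades, and
  the published heart-rate widths of 0.2–0.7) the shuffle contrast is far
  larger.

## The comparison pipeline

`analyze_subject` runs PSVG on both states, and MF-DFA plus
shuffled-surrogate MF-DFA unless suppressed. Suppression defaults to a
length rule (either series shorter than 1024 samples) rather than a
silent judgment call: the Kundalini recordings are too short for a
reliable width, so their width columns are absent while $\lambda_p$ is
retained. Surrogate widths may be averaged over `shuffle_reps`
permutations (default 1, matching one-surrogate-per-subject reporting;
the tests use 5 where stability matters).

`build_table` aggregates subjects into the published table layout and
computes the summaries the package reports: per-group minimum and maximum
percent increases ($100\,(\mathrm{med} - \mathrm{pre})/\mathrm{pre}$,
reported at one decimal place), per-state group means of $\lambda_p$, and
the three cross-method Pearson correlations between $\lambda$ and width
(pooled, meditation-only, pre-only) over subjects with MF-DFA present.
Correlations use the table-level summary values, as the published
analysis does; `stats::cor` does the arithmetic.

The packaged `published_meditation_values()` table carries the published
per-subject exponents, from which the package reproduces the study-level
summaries (maximum Chi PSVG increase 70.5%, maximum Chi width increase
175%, Kundalini PSVG range ≈ 46.9–265.1%, correlations ≈ 0.64 pooled /
0.40 meditation / 0.015 pre). The underlying heart-rate recordings are
not redistributed; `read_bpm_series` ingests them in the PhysioNet
two-column text dialect for users who download them.

## Problem sizes

The test suite and the acceptance script use: $N = 2^{13}$ for fGn-based
MF-DFA properties (10–20 seeds), $2^{13}$ points for the cascade oracle,
$n = 4096$ with 10 seeds for the $\lambda$–$H$ recovery, $n \le 64$ for
the exhaustive visibility oracle (50 instances), and $N = 2^{13}$–$2^{14}$
with five-shuffle surrogates for the shuffle contrasts. These sizes put
every estimator in its documented operating regime while keeping a full
run in tens of seconds.

## Known limitations

* MF-DFA below $N \approx 1024$ is reported with a warning and suppressed
  by default in the subject pipeline; the visibility route is the
  short-series instrument.
* $\lambda_p$ is sensitive to the fit window; both the window and the fit
  diagnostics ($R^2$, standard error) are always reported, and the two
  built-in window policies are described above.
* The spectrum width over a finite $q$ grid underestimates the asymptotic
  $q \to \pm\infty$ width of strongly multifractal signals.
* Percent-increase summaries require a positive baseline; a zero-width
  baseline yields an undefined (absent) increase rather than an infinity.
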