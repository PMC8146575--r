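---
title: "Finite-time corrections for Kramers–Moyal coefficient estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-time corrections for Kramers–Moyal coefficient estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmfinite)
```

## The model and its assumptions

`kmfinite` reconstructs one-dimensional Markovian stochastic dynamics of
the jump-diffusion form

$$\mathrm{d}X_t = a(X_t)\,\mathrm{d}t + b(X_t)\,\mathrm{d}W(t)
  + \xi\,\mathrm{d}J(t),$$

with Brownian motion $W$, a Poisson process $J$ of rate $\lambda$, and
i.i.d. Gaussian jump amplitudes $\xi \sim N(0, s)$ ($s$ is the amplitude
*variance*). The conditional density of such a process obeys the
Kramers–Moyal equation, whose coefficients
$D_n(x)$ — drift $D_1$, diffusion $D_2$, and the higher orders that vanish
for continuous paths and encode jumps otherwise — are the estimation
targets. Two assumptions are essential and are *not* checked by the
package: the process is Markovian at the sampling resolution (memory of
increments has decayed within one sampling step), and it is stationary,
so that $D_n(x,t) = D_n(x)$. Chapman–Kolmogorov-style Markov testing is
out of scope.

## Why finite sampling biases the naive estimator

With data sampled at interval $\Delta t$, the accessible quantities are
the finite-lag conditional moments $M_n(x, \tau)$,
$\tau = \Delta t$. The limit definition
$D_n = \lim_{\tau \to 0} M_n/(n!\,\tau)$ degrades into the biased plug-in
rule $D_n \approx M_n/(n!\,\Delta t)$. Expanding the exponential of the
Kramers–Moyal operator applied to a delta initial condition gives the
exact finite-$\tau$ relation

$$M_n(x, \tau) = n! \sum_{k=1}^{n} \frac{\tau^k}{k!}
  \hat B_{n,k}(D_1, \dots, D_{n-k+1}) + \Phi_n,$$

where $\hat B_{n,k}$ are partial ordinary Bell polynomials and $\Phi_n$
collects every term containing spatial derivatives $D_p^{(d)}$ of the
coefficients. Dropping $\Phi$ (exactly the approximation under which the
closed-form inversion below exists) and rewriting through partial
*exponential* Bell polynomials, the relation inverts term by term:

$$D_n = \frac{1}{n!\,\tau} \sum_{k=1}^{n} (-1)^{k-1}(k-1)!\,
  B_{n,k}(M_1, \dots, M_{n-k+1}).$$

This is precisely the classical map from raw moments to cumulants:
$n!\,\tau\,D_n$ is the $n$-th cumulant of the increment distribution at
lag $\tau$. The package verifies this equivalence against the standard
moment–cumulant recursion in its test suite.

`moments_from_km()` and `km_from_moments()` build both expansions at any
order; `invert_numeric()` applies the inversion to measured moments at a
chosen truncation order (order 1 reproduces the naive estimator, order 2
subtracts the $\hat B_{n,2}$ group, and order $n$ is the complete
correction — for $D_2$ order 2 and full order coincide, and $D_1$ receives
no correction at all). `expand_with_derivatives()` produces the neglected
$\Phi$ terms by formal application of the truncated operator with
symbolic integration by parts; it exists for verification and
diagnostics, never inside the estimation path.

## Exact arithmetic and canonical form

All symbolic coefficients are combinatorial integers (or small
rationals), so the expansion engine uses exact rational arithmetic on
integer-valued doubles with gcd reduction — no floating point enters a
Bell evaluation, and coefficients up to the supported orders stay far
below the 2^53 exact-integer limit. Monomials are kept in a canonical
order (graded by the power of $\tau$, then by total degree, then
lexicographically on symbol indices), so rendered expansions are
deterministic, and the plain format round-trips through `parse_km()`.

A note on one printed third-order reference expression: the corrective
terms for the first conditional moment under a Fokker–Planck truncation
contain a final term that, as commonly typeset, violates the bookkeeping
rule that the sum of coefficient orders minus the sum of derivative
orders must equal the moment order. Our operator expansion yields
$D_1^{(4)} D_2 D_2$ in that position, which satisfies the rule; the test
suite asserts the bookkeeping invariant and the closed-form
$\Phi_n^{[2]}$ rather than any hard-coded term list for that case.

## The synthetic-data generator

`simulate_jd()` integrates the constant-coefficient mean-reverting case
$\mathrm{d}X = -aX\,\mathrm{d}t + b\,\mathrm{d}W + \xi\,\mathrm{d}J$ with
an Euler–Maruyama scheme at the sampling step (a `refine` argument
integrates at $\Delta t/\text{refine}$ and down-samples when the
integrator bias itself is under study). Per step the compound-Poisson
increment is drawn exactly: $K \sim \text{Pois}(\lambda \Delta t)$ jumps
contribute $\sqrt{K s}\,Z$, $Z \sim N(0,1)$, which is the exact law of a
sum of $K$ independent $N(0, s)$ amplitudes — valid at any
$\lambda \Delta t$, not a single-jump approximation. Gaussian increments,
jump counts and jump amplitudes are drawn in fixed blocks from one seed,
so a trajectory is reproducible regardless of how many jumps occur.

The default parameters are the two study conditions exercised throughout
the tests: an Ornstein–Uhlenbeck process with $a = 1.0$, $b = 0.5$
($\lambda = s = 0$) and its jump-augmented counterpart with $a = 0.5$,
$b = 0.5$, $s = 0.75$, $\lambda = 0.6$; coarse sampling
($\Delta t = 0.1$) exposes the finite-time artefacts, fine sampling
($\Delta t = 0.01$) is used for quantitative parameter recovery. What the
generator deliberately does *not* emulate: state-dependent or
time-dependent coefficients, non-Gaussian jump laws, measurement noise,
and non-Markovian memory — so green tests say nothing about those
features of real data.

## Estimator defaults

`conditional_moments()` uses histogram binning by default: 30 equal-width
half-open bins spanning the sample mean ± 4 standard deviations. Bins
with fewer than 100 transitions are flagged excluded (reported, never
dropped) because sixth-moment estimates in sparse bins are noise-
dominated; the threshold is configurable. A Nadaraya–Watson alternative
with an Epanechnikov kernel and Silverman's-rule bandwidth is available.
The lag defaults to 1 sample — the smallest accessible temporal
difference is the best-case regime for the correction — and each bin also
records its occupancy-weighted mean state, which is the right abscissa
when comparing against closed-form transition moments. Negative corrected
$D_2$ or $D_4$ values (possible for diffusive data, where the true value
is zero and the estimate fluctuates around it) are reported as-is with a
warning flag; clipping would bias the downstream averages.

## Parameter recovery and classification

For the constant-jump model the corrected coefficients are constants in
$x$:

$$D_2 = \tfrac12\left(b^2 + s\lambda\right), \qquad
  D_{2n} = \frac{s^n \lambda}{2^n\, n!},$$

consistent with the Gaussian moment identity
$\langle \xi^{2n} \rangle = \frac{(2n)!}{2^n n!} s^n$. `recover_jump()`
therefore averages $D_2$, $D_4$, $D_6$ over a central state range
(default mean ± 2 sd, occupancy-weighted — ratios of noisy per-bin values
are unstable) and inverts: $\hat s = 6\bar D_6/\bar D_4$,
$\hat\lambda = 8 \bar D_4/\hat s^2$,
$\hat b^2 = 2\bar D_2 - \hat s \hat\lambda$ (the last identity holds
exactly by construction). Non-positive $\bar D_4$ or $\bar D_6$ suppresses
jump inference with a flag. The drift slope comes from a least-squares
fit of $D_1(x)$ over the included bins in the same range.

`classify_process()` calls the dynamics jump-diffusion when $\bar D_4$
exceeds `factor` (default 3) times its standard error. Uncertainty is
estimated by batch means: the series is split into 20 contiguous blocks,
the bin-averaged coefficients are recomputed per block with the pooled
bin edges held fixed, and the standard error of the pooled average is
$\mathrm{sd}(\text{blocks})/\sqrt{20}$. Batch means was chosen over a
moving-block bootstrap because it costs one extra pass over the data
rather than hundreds while estimating the same weak-dependence
variability; 20 blocks keeps each block long relative to the correlation
time $1/a$ in both study conditions.

## Numerical choices and degenerate inputs

* Truncation: the operator expansion truncates the coefficient sum at
  `truncation_N` and derivative orders at `max_deriv`, both explicit;
  terms whose $(x - x')$ power can no longer reach zero within the
  remaining operator applications are pruned exactly.
* The negative-value flag ignores cancellation residue below
  $10^{-10}$ of the naive estimate's magnitude, so exact cancellations
  are not spuriously flagged.
* A constant series degenerates to a single occupied bin with all
  moments zero; the binning range collapses to a narrow interval around
  the constant.
* Non-finite moments propagate to non-finite coefficients rather than
  being silently dropped.
* Table and series files store all values at 17 significant digits, so a
  write–read–write cycle is byte-identical.

## Problem sizes used in the tests

The quantitative recovery checks simulate $5\times10^6$ steps at
$\Delta t = 0.01$ (the two study conditions above), matching the data
volume of the coarse-sampling illustrations; consistency and
classification property tests use shorter runs ($10^5$–$10^6$ steps) with
errors averaged over three fixed seeds per condition, sizes chosen so the
statistical error dominates discretisation effects while the whole suite
runs in well under a minute. The estimator-consistency test integrates
with `refine = 10` so that the exact Ornstein–Uhlenbeck transition
moments are a valid oracle above the integrator bias.

## Known limitations

* The inversion neglects the $\Phi$ derivative terms; for strongly
  state-dependent coefficients at coarse sampling this residual bias is
  not removed (it vanishes for the constant-coefficient study conditions
  up to the orders that matter).
* At coarse sampling of jump-diffusion data, even full-order corrected
  coefficients retain a bias relative to the jump-parameter relations;
  quantitative jump recovery is therefore specified at fine sampling
  only, while the coarse regime is assessed by the ordering property
  (full-order closer to theory than lower orders).
* Jumps are assumed state-independent with Gaussian amplitudes; the
  $D_4/D_6$ ratios are specific to that law.
* One-dimensional processes only.
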