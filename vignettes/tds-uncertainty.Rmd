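---
title: "Bootstrap uncertainty bands for TDS curves: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap uncertainty bands for TDS curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdsboot)
```

## The data model

A temporal dominance of sensations (TDS) task records which one of $p$
descriptors an assessor judges dominant at each moment between a start and a
stop press. Because exactly one descriptor can be selected at a time and a
selection persists until the next press, task $i$ induces right-continuous
binary step functions $b_{ij}(t) \in \{0,1\}$, at most one of them equal to 1
at any instant. `tdsboot` adopts the **right-open interval convention**: a
descriptor becomes dominant at the exact instant of its selection and stays
dominant up to (not including) the next selection; the last selection
persists through the stop instant. A selection exactly at the stop instant is
legal — it is how a state change landing on the final grid point of a
simulated trajectory is stored — and is the dominant descriptor at $t'=1$.

Tasks are compared on the normalized timeline: the elapsed time between the
start and stop presses is rescaled to 1 (`normalize_task()`, affine, stored
in double precision with a $10^{-12}$ tolerance for detecting an
already-normalized record). The TDS curves of $n$ tasks are the dominance
proportions
$$d_j(t') = \frac{1}{n}\sum_{i=1}^{n} b_{ij}(t'),$$
evaluated on a grid of normalized times. Panel tasks may begin with a gap
before the first selection; proportions are nevertheless divided by the full
$n$ (not by the number of responding tasks), so curve columns may sum to less
than 1 early in the timeline. Re-selecting the already-dominant descriptor is
accepted as a no-op. Default grids: 101 evenly spaced points for real panel
data, where selection times are continuous; 21 points for tasks simulated
from the built-in models, whose trajectories live natively on that grid.

## Bootstrap bands

The resampling unit is the **whole task**. From $m$ observed tasks, $m$ are
drawn uniformly with replacement and the curve set recomputed; repeating $q$
times (default 1000) gives replicate curve sets whose pointwise spread
estimates the uncertainty of the observed curves. This is *not* a block
bootstrap: time structure within a task is never broken, so no stationarity
assumption about the time series is needed — the exchangeable unit is the
assessor-task.

At each descriptor and grid point the replicate values are sorted and

* the 95% confidence band spans the $k$-th smallest to $k$-th largest value
  with $k = \mathrm{round}(0.025\,q)$ (25 and 976 of 1000);
* the standard-error band uses $k = \mathrm{round}(0.1587\,q)$ (159 and 842
  of 1000), $0.1587 = 1 - \Phi(1)$, i.e. a central $\approx 68.3\%$
  percentile interval — the percentile analogue of $\pm 1$ standard error,
  implemented as order statistics rather than as a parametric
  $\pm\hat\sigma$ interval.

Ties among replicate values are left as they are (ranks index the sorted
multiset; no interpolation), which keeps the "$k$-th largest value"
definition literal. If $\mathrm{round}(\alpha q) < 1$ the ensemble cannot
support the requested rank and the package raises an error asking for a
larger $q$ instead of silently substituting the sample range.

For comparison, `normal_bands()` implements the proportion approximation
$d \pm z\sqrt{d(1-d)/m}$ with $z = 1.96$ (CI95) or $1$ (SE). These bands are
clipped to $[0,1]$ (clipping is recorded in the result) and flagged wherever
$md < 5$ or $m(1-d) < 5$, the usual rule of thumb for when the normal
approximation to a proportion is unreliable.

Implementation note: `bootstrap_curves()` does not materialize resampled
task lists. It draws multinomial task counts (`rmultinom(q, m, 1/m)`) and
forms every replicate curve set in one weighted cross-product against the
per-task indicator matrix. The two procedures are identical in
distribution; the counting form is what makes $200 \times 1000$ resamples
in the coverage study cheap.

## The Markov task simulator

`builtin_model(1)` and `builtin_model(2)` are reference populations for
validation: descriptors are Markov states; a task draws its initial state
(Case 1: $(0.5, 0.25, 0.25, 0)$ over 4 descriptors; Case 2:
$(1/6, 1/3, 1/3, 1/6, 0, 0)$ over 6, stored as double-precision quotients,
not decimals) and then makes 20 transitions of width $\Delta t' = 1/20$. The
transition table switches across three phases — initial, middle, last — so
the simulated curves rise and fall the way real consumption episodes do
(early descriptors fade, late descriptors take over).

Two conventions had to be fixed where a discrete phase schedule meets a
discrete grid:

* **Phase attribution at boundaries.** The transition leaving grid point
  $k/20$ uses the table of the phase containing that *source* time: the
  initial-phase table governs transitions leaving steps 0–6, the middle
  7–13, the last 14–19. The simulator and the analytic oracle share this
  single definition (`step_matrix()`), so they cannot drift apart; choosing
  the destination-time convention instead would shift curves by at most one
  grid step.
* **Draw order.** One seeded generator per experiment: all initial states
  first, then the population's transitions step by step along the timeline.
  Populations are therefore bit-reproducible given a seed.

One entry of the built-in Case 2 model required attention: the last-phase
row leaving D3 is not row-stochastic as commonly printed (its entries sum to
1.1). The package ships the minimal correction (the D3$\to$D4 entry lowered
from 0.4 to 0.3, making the row equal the last-phase D1 row) so the chain is
well defined; validation uses Case 1, which is unaffected.

`exact_marginals()` propagates the initial distribution through the product
of per-step matrices and returns the *exact* population curves, with columns
summing to 1 by construction. It is the simulator's oracle twice over: the
test suite checks it against exhaustive path enumeration on a truncated
model ($p = 4$, 4 steps, $4^5$ paths, agreement to $10^{-12}$), and checks
empirical curves from 10,000 simulated tasks against it everywhere within
$4\sqrt{0.25/n}$.

## The coverage study

`run_inclusion_study()` measures calibration: simulate a population of
$n$ tasks, and repeatedly (a) draw $m$ tasks from it **without**
replacement — the sample is a set of distinct tasks, with replacement
entering only inside the bootstrap, mirroring standard survey-then-bootstrap
practice — (b) build bootstrap and/or normal bands, and (c) record per
descriptor and grid point whether the population proportion lies inside
(endpoints included). The per-point inclusion probability across repetitions
is the empirical coverage; a calibrated 95% band should sit near 0.95 and
the SE band near 0.683.

Headline numbers average the per-point probabilities over descriptors and
grid points whose reference proportion lies in $[0.1, 0.9]$: proportions
near 0 or 1 produce degenerate bands (often exactly zero-width at reference
0), are conventionally regarded as below chance level and ignored in
practice, and would otherwise drag the mean in ways that say nothing about
the method. The per-point table always retains every point, so other
summaries can be formed after the fact.

**Problem sizes.** The package's standard validation — what
`scripts/acceptance.R` reruns — uses one Case 1 population of $n = 10{,}000$
tasks, sample size $m = 500$, $q = 1000$ bootstrap replicates and 200 Monte
Carlo repetitions. 200 repetitions put the Monte Carlo standard error of a
coverage estimate near $\sqrt{0.95 \times 0.05/200} \approx 0.015$, tight
enough to separate 0.95 from miscalibration while keeping the full study
under a minute on one CPU; a full sweep over
$m \in \{15, \dots, 500\}$ with 1000 repetitions is available by passing
those values explicitly.

```{r coverage, eval = FALSE}
st <- run_inclusion_study(builtin_model(1), sample_sizes = c(15, 500),
                          n = 10000, q = 1000, outer_reps = 200, seed = 2021)
summary(st)
```

Expected behavior, which the test suite asserts: at $m = 500$ the bootstrap
CI covers with probability in $[0.90, 0.97]$ and the SE band in
$[0.62, 0.73]$; bootstrap and normal coverages differ by less than 0.03; at
$m = 15$ coverage falls clearly below nominal — with tiny samples both the
percentile and the normal bands underestimate the uncertainty, which is the
practical reason to treat $m \lesssim 50$ TDS panels with caution.

## What the simulator does and does not emulate

The generator reproduces the features that matter for validating proportion
bands: sequential single dominance, a task-level exchangeable unit, phase
structure over the timeline, and descriptors that are genuinely absent early
or late. It does **not** emulate assessor heterogeneity (every task is
i.i.d. from one chain), continuous selection times (events sit on the
21-point grid), pre-selection gaps (simulated tasks always start selected,
so simulated curve columns sum to exactly 1), or serial dependence between a
panelist's repeated tasks. Passing coverage checks on this population shows
the resampling machinery is calibrated for i.i.d. tasks; it does not by
itself license ignoring panel structure in real data, where tasks from the
same assessor may be correlated and the effective sample size smaller than
$m$.

## Numerical and degenerate-input choices

* Times are doubles; normalization uses a $10^{-12}$ tolerance; stochastic
  vectors and matrix rows are validated to $10^{-9}$.
* Zero-duration tasks, empty task lists, empty files, unsorted or
  out-of-range events all raise immediate errors naming the offending task.
* Cumulative transition rows are forced to end exactly at 1 before inverse
  sampling, so accumulated float error cannot produce an out-of-range state.
* Bootstrap bands need no clipping (replicate values are proportions);
  normal bands are clipped and say so.
* `exact_marginals()` reports `n_tasks = Inf`, marking curves that are not
  an $n$-task average.

## Known limitations

Only the TDS design (single dominant descriptor) is covered — check-all-
that-apply variants produce curves that are not dominance proportions and
need different machinery. Transition matrices are not estimated from data;
the simulator is a validation instrument, not a fitted model. Coverage
conclusions transfer to real panels only to the extent the i.i.d.-task
assumption does, and small-$m$ undercoverage means uncertainty bands from
panels of a few dozen tasks should be read as optimistic.
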