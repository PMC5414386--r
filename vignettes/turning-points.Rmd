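---
title: "Detecting turning points in intra-individual emotion trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting turning points in intra-individual emotion trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(emoturn)
```

## The question

People's emotions during a multi-week learning experience do not evolve
smoothly. A participant who reports growing enthusiasm for five sessions may
abruptly reverse after a discouraging week. emoturn implements a two-step
procedure for locating such *turning points* inside individual emotion
trajectories — short ordinal time series (typically 8 occasions, scores 1–5)
of one participant's intensity ratings for one emotion — and for asking
whether turning points co-occur with how complex the participant perceived
the training to be at that moment.

## Step 1: the control band and exceptional points

Each trajectory is summarized by an ordinary least-squares line over the
occasions $t = 1, \dots, T$. Around the fitted line we draw a constant-width
control band

$$\mathrm{UCL}(t) = \hat y(t) + 1.65\,\sigma, \qquad
  \mathrm{LCL}(t) = \hat y(t) - 1.65\,\sigma,$$

where $\sigma = \sqrt{\tfrac1T \sum_t r_t^2}$ is the residual standard
deviation computed with denominator $T$ (a population-style estimate, chosen
to reproduce the reference worked example exactly; `fit_trend()` documents
this). A score strictly above the UCL is a *high exceptional point*; strictly
below the LCL, a *low* one. Strict inequality means a degenerate band
(perfectly linear series, $\sigma = 0$) flags nothing.

```{r}
distress <- c(2, 1, 1, 2, 3, 2, 2, 1)
fit <- fit_trend(distress)
control_limits(fit)
find_exceptional_points(distress)
```

## Step 2: the slope-change permutation test

An exceptional point at occasion $k$ is promoted to a turning point when the
trajectory's slope before $k$ differs from its slope after $k$ more than
chance reshuffling would allow. The statistic is
$|b_{\text{after}} - b_{\text{before}}|$, the absolute difference of the OLS
slopes of the two segments. Its null distribution is approximated by Monte
Carlo: the whole score vector is randomly reordered (by default 10,000
times), the statistic recomputed each time, and

$$p = \frac{\#\{\text{resamples with statistic} \ge \text{observed}\}}
           {\text{number of resamples}}.$$

Ties within $10^{-9}$ count as extreme, so a constant or perfectly linear
series always yields $p = 1$. Promotion requires $p < \alpha$ (default
0.05). A promoted high point is a *pre-decrease* turning point (the rise
ends there); a promoted low point is *pre-increase*.

### Segment membership at the candidate point

Where does occasion $k$ itself belong? `segment_rule` offers two
conventions:

* `"include"` (default): the candidate point anchors **both** segments
  (before = $1..k$, after = $k..T$). Every interior occasion
  ($2 \le k \le T-1$) is testable, and the observed peak contributes to
  both slopes — this is the reading under which the method's worked
  examples behave as described, with first and last occasions untestable.
* `"exclude"`: the candidate point is dropped (before = $1..k-1$, after =
  $k+1..T$), so only $3 \le k \le T-2$ is testable.

The choice matters a great deal. Because an exceptional point is by
construction an extreme score, excluding it removes exactly the observation
that generated the candidate, and with $T = 8$ the remaining two- to
five-point segments are so short that, in our simulations, the exclude rule
promoted essentially nothing — neither on null series nor on series with
large injected reversals. The include rule has real power but is
anti-conservative at data-selected candidate points (see *Calibration*
below). Both are available; the default is `"include"`.

### Calibration: a known limitation

The permutation test reshuffles the full series, but the candidate occasion
was itself *selected* by the control band as the most extreme point. Testing
a data-selected hypothesis against an unconditional null inflates the
type-I rate: on iid-uniform Likert null trajectories we measure a
per-tested-point promotion rate of roughly 0.11–0.16 at $\alpha = 0.05$,
not 0.05. Conversely, sensitivity to genuinely injected reversals depends
strongly on where they sit: reversals at occasions 4–5 are found nearly
always, while reversals at occasions 3 or 6 leave one segment with little
leverage and are found only 30–40% of the time, capping overall sensitivity
near 0.7 under the strong-effect generator preset. Neither number can be
moved without changing the method itself, so the package reports them
honestly rather than tuning around them. Detected turning points should be
read as descriptive flags, not as calibrated hypothesis tests.

## The complexity association

Perceived training complexity at each occasion is the mean of two 1–5 items
(conceptual and performative), so it lives on a half-integer grid. The
participant-by-occasion cells are split into those *with* a turning point
and those *without* (`group_cells()`; by default a cell belongs to the
with-group only for the specific participant who turned there —
`grouping = "occasion"` instead flags the whole occasion for everyone). The
statistic is the difference of group means, and significance comes from a
one-sided permutation test that by default reshuffles each participant's
complexity series *within* that participant (`reshuffle = "within"`), so
between-person differences in complexity level cannot masquerade as an
effect. Group SDs are population-style (denominator $n$), matching the band
convention. Unlike the turning-point test, this test is well calibrated in
our simulations (null rejection rate ≈ 0.05) because the partition is fixed
before the complexity values are permuted.

```{r}
g <- generate_cohort(synthetic_spec(n_participants = 6, p_inject = 0.3),
                     seed = 1)
det <- detect_cohort(g$dataset, n_permutations = 1000, seed = 2)
part <- group_cells(det, g$dataset)
association_pvalue(g$dataset, part, n_permutations = 1000, seed = 3)
```

## The synthetic cohort generator

`synthetic_spec()` describes a cohort of piecewise-linear latent
trajectories plus Gaussian noise, discretized to the 1–5 Likert grid
(rounding then clipping; `discretize = FALSE` keeps the continuous values
for calibration studies). With probability `p_inject` a trajectory receives
a slope reversal at a random occasion in `inject_occasions`, with an
`overshoot` spike at the change occasion so the reversal also crosses the
control band. Polarity follows valence by default — positive emotions get
pre-increase reversals, negative ones pre-decrease — and injected cells
receive a `complexity_bump` on both complexity items. The generator logs
every injection, so `recovery_report()` can score a detection run
(sensitivity with type matching, false-positive rate, type-confusion
table). The defaults mirror the reference study's shape: 17 participants,
16 emotions (6 positive, 10 negative), 8 occasions.

Limits worth knowing: the latent model is piecewise linear with homoskedastic
noise, discretization is a hard round-and-clip (so extreme latent values
saturate at 1 or 5), and at most one reversal is injected per trajectory.

## Numerical conventions

* Residual SD uses denominator $T$; group SDs use denominator $n$.
* Band crossing is strict (`>` / `<`), with no clipping of the band to the
  1–5 range.
* Permutation ties count as extreme within an absolute tolerance of
  $10^{-9}$, and $p$ is the plain ratio `n_extreme / n_permutations` with
  no +1 correction.
* All Monte Carlo functions accept a `seed` and are bit-reproducible given
  one; `run_pipeline()` threads a single seed through the whole analysis.

## Problem sizes used by the test suite

Exact oracles (full enumeration of all $n!$ orderings) are feasible only up
to $n = 7$, so oracle-equivalence tests use series of length 5–7 with
10,000 Monte Carlo resamples and a three-standard-error band. Calibration
audits use 2,000 null trajectories and 1,000 association replicates at a
reduced 1,000 permutations per test — enough for binomial error bars of
about ±0.01 around 0.05 — and recovery audits run the strong-effect preset
(272 trajectories) at 1,000 permutations. Full-scale runs (10,000
permutations) behave identically up to Monte Carlo error.
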