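---
title: "Divergence point analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence point analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many experimental manipulations lengthen mean response latencies —
fixation durations in reading, reaction times in recognition tasks — but a
mean difference says nothing about *when* the manipulated variable first
takes hold. A 20-ms mean effect could come from a small shift of every
response or from a large shift of a few late ones. Divergence point
analysis (DPA) answers the timing question distributionally: plot, for each
of two conditions, the *survival curve* — the percentage of latencies
strictly exceeding each 1-ms time bin `t` — and estimate the earliest bin at
which the "slow" condition's curve reliably rises above the "fast"
condition's. That bin is the divergence point: the onset of the earliest
discernible influence of the manipulation.

Because no parametric form is assumed for latency distributions, inference
rests on bootstrap resampling: observations are resampled with replacement
within each participant × condition cell, the statistic of interest is
recomputed per iteration, and the iteration distribution substitutes for an
analytic sampling distribution.

## The three procedures

**Group procedure (`original_dpa`).** Per iteration, each cell is resampled
to its observed size, per-participant survival curves are computed on bins
0..`t_max` (default 600 ms) and averaged — unweighted — across participants
within condition, and the fast group curve is subtracted from the slow.
Across the 10,000 iterations the per-bin differences are sorted; the value
at rank 5 (of 10,000) is the lower bound of a 99.9% interval for that bin.
A bin is *significant* when that bound exceeds zero, and the divergence
point is the first bin opening a run of five consecutive significant bins.
The deliberately strict settings (α ≈ 0.001 per bin, run of five) guard
against declaring onset too early; the price, demonstrated by the
subsampling study below, is a late-shifted estimate when power is low. The
procedure returns one number and no interval around it.

**Confidence-Interval procedure (`ci_dpa`).** Same resampling, but the
divergence point is located *within* each of 1,000 iterations: the first
bin of a run of five consecutive bins where the slow survival percent is at
least 1.5 points above the fast ("at least" = `>=`). Sorting the 1,000
per-iteration onsets gives a median (the estimate) and the 25th/975th
values (a 95% percentile interval). Two conditions whose intervals do not
overlap have significantly different onsets. The 1.5% threshold means
effects smaller than 1.5 survival points are undetectable by construction;
lowering it is safe only for very large samples.

**Individual-Participant procedure (`ip_dpa_group`).** Group curves hide
individual variation, and single-participant curves are too noisy for the
group machinery. The individual procedure therefore works on paired order
statistics: per iteration, 1,200 latencies are drawn with replacement from
the participant's slow pool and 1,200 from the fast pool — 1,200 regardless
of how many observations exist, so every "death" steps survival down by the
fixed minimum 1/1200 × 100 ≈ 0.083% — each resample is sorted ascending and
the two are paired index-wise. The iteration's divergence value is the
average of the first pair opening a run of 100 consecutive *strictly*
positive differences (`s_i > f_i`; a tie breaks the run). The participant's
estimate is the median over the iterations that detected anything;
participants detecting in fewer than 50% of iterations are flagged
unreliable and excluded from group summaries (exactly 50% counts as
reliable). Group mean and SD are computed over reliable participants only.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `t_max` | 600 ms | last evaluated 1-ms bin; raise for slow RT tasks |
| `n_iterations` | 10,000 / 1,000 / 1,000 | bootstrap iterations (original / CI / IP) |
| `run_length` | 5 / 5 / 100 | consecutive qualifying bins required |
| `difference_threshold` | 1.5% | CI-DPA per-bin qualification |
| `ci_lower_index`, `ci_upper_index` | 5 & 9,995 / 25 & 975 | 1-based ranks into the sorted iteration values |
| `resample_n` | 1,200 | IP resample size per pool |

When `n_iterations` is rescaled the ranks rescale proportionally
(`round(0.0005 n)` / `round(0.9995 n)`, resp. `round(0.025 n)` /
`round(0.975 n)`, floored at 1). The IP `run_length` of 100 (out of 1,200)
is a strictness dial: more lenient values raise sensitivity and the false
alarm rate together, and are defensible only with many observations per
cell.

## Numerical and convention choices

These were the genuinely open design points; each is fixed as follows.

* **Strict exceedance.** Survival at `t` counts latencies `> t`; a latency
  equal to `t` has died at `t`. Raw latencies may be non-integer and are
  never rounded — only the evaluation grid is integer.
* **Resample sizes.** Group procedures resample each cell to its observed
  size (standard bootstrap convention; the method's description is silent).
  Participants are fixed, never resampled — the bootstrap unit is the
  observation within a cell.
* **Non-detecting CI-DPA iterations.** Iterations with no qualifying run
  are dropped before sorting; with `m` retained values the interval ranks
  become `round(0.025 m)` / `round(0.975 m)` (floored at 1) and the
  detection rate `m/n` is reported so users can judge reliability. No
  published rule exists for this case; dropping plus rank rescaling keeps
  the interval a percentile interval of the detected-onset distribution.
* **Medians with even counts** are the mean of the two central values.
* **Interval overlap** uses closed intervals; a shared endpoint counts as
  overlap (conservative when claiming condition differences).
* **Ties in the IP rule** break the run (strict `s_i > f_i`). With
  continuous data ties are measure-zero; with shared or integer-valued
  pools they are the mechanism that keeps the null false-alarm rate down —
  see the null analysis below.
* **Truncated runs** (hitting the end of the grid or of the 1,200 pairs
  before reaching full length) never qualify.
* **Per-participant RNG substreams** are derived from (master seed, hash of
  participant id), so IP results are invariant to input row order.
* **Degenerate paired t test.** With constant pairwise differences the
  usual statistic is 0/0; `compare_individual_estimates` returns t = 0
  (all-zero differences) or ±Inf, rather than NaN.
* **Latencies above `t_max`** are retained in the data; curves are simply
  not evaluated past `t_max`.

## The synthetic world

`generate_simulation2_population()` builds the validation population: 104
participants split at random into 26 groups of four, each group assigned an
injected divergence point from 110 to 210 ms in 4-ms steps (truth-map mean
exactly 160 ms). A participant's fast cell is 60 ex-Gaussian draws; the
slow cell copies every draw below the participant's divergence value `d`
and lengthens a random 50% of the draws at or above `d` by 50 ms. Below
`min(d)` the two conditions are therefore *identical by construction*, so
no procedure should systematically report divergence far below the smallest
injected value.

The ex-Gaussian base defaults to `mu = 176, sigma = 24, tau = 27`: mean
≈ 203 ms, rightward skew, and left-tail support down to roughly 110–120 ms.
Its SD (≈ 36 ms) is wider than the ≈ 27 ms a comparably centred empirical
fixation sample prints. The two cannot be matched simultaneously with an
ex-Gaussian: forcing SD ≈ 27 around a 203-ms mean truncates the Gaussian
body's left tail near 140 ms, whereas real fixation-duration distributions
with that SD still reach ≈ 100 ms. Since onset recovery depends on there
being data around the injected divergence values, support fidelity was
chosen over SD fidelity. Even so, mass below ≈ 135 ms is scarcer than in
real data, which compresses estimates for the lowest injected divergence
levels; full-scale recovery correlations here run ≈ 0.92–0.94, a little
under the ≈ 0.96 reported for the semi-empirical analogue of this design.
The generator emulates the *shape* of fixation-duration data; it does not
reproduce participant heterogeneity in means or any empirical dataset, so a
green recovery test establishes that the estimator tracks injected onsets
in a realistic latency world — not that it reproduces any particular
empirical figure.

`generate_null_population()` draws slow and fast cells independently from
one ex-Gaussian; no divergence exists. Note a subtlety uncovered during
calibration: on such *independent-draw* nulls the group procedure is
appropriately silent (≈ 0–5% false detections), but the IP procedure's
reliability filter is nearly toothless — independent continuous order
statistics wander in long same-sign runs, so most participants "detect" in
over half their iterations. The filter's real mechanism is ties: on a
*shared-pool* null (slow and fast cells holding the same draws — the
relevant null when asking whether two conditions differ on identical data),
exact ties break the strict-inequality runs and essentially all
participants are flagged unreliable. Users should read IP detection rates
as tie-sensitive: a high detection rate on continuous data is not by itself
evidence of a real effect; the estimate's spread and the group design carry
that burden.

## Test scaling

The shipped tests scale the published settings down to fit a CI budget,
never by weakening a bound: the recovery criterion runs the
Individual-Participant procedure at 200 of its 1,000 iterations (the
full-scale run is `scripts/acceptance.R`); subsampling sweeps use 20
replicates instead of 100; the null-specificity suite runs the original
procedure at 2,000 iterations with lower rank 1, which preserves the
published 5/10,000 = 0.05% per-bin rank quantile exactly; the
interval-consistency property compares 60 against 600 observations per
cell (3 replicates) rather than sweeping to 6,000. Stochastic expectations
(oracle tolerances, the S1-style window [130, 160] ms for a 140-ms injected
onset) were frozen from independent naive-oracle pilot runs —
`sample()`-and-`sort()` re-implementations in
`tests/testthat/helper-oracles.R` that share no code with the package.

## Known limitations

* Exactly two conditions; no omnibus comparison across three or more
  curves.
* No censoring machinery: every latency is assumed fully observed.
* No analytic (non-bootstrap) onset estimator; estimates are discrete at
  1-ms (group) or pair-value (IP) resolution.
* The detected onset is the earliest *statistically discernible*
  difference, necessarily later than the true causal onset for weak or
  gradual effects; cross-method convergence is the appropriate remedy.
* Group IP summaries average over reliable participants only and are
  typically somewhat later than group-curve estimates on heterogeneous
  samples — the two views are complementary, not interchangeable.
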