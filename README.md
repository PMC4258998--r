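# divpoint

Divergence point analysis (DPA) for response-latency distributions:
bootstrap estimation of the earliest discernible onset of an experimental
effect on fixation durations, reaction times, or any positive latency
measure.

## What it does

Given latencies from two conditions — a "slow" condition expected to yield
longer latencies and a "fast" one — each condition's *survival curve*
S(t) = 100 × P(latency > t) is evaluated on 1-ms bins. A real effect makes
the slow curve rise above the fast one from some time onward; the
*divergence point* is the earliest bin at which that separation is
statistically reliable, and is read as the onset of the variable's
influence. Three bootstrap procedures are implemented:

* **Original group DPA** (`original_dpa`): 10,000 iterations of resampling
  within each participant × condition cell; per bin, the slow−fast
  difference of the group-average curves is collected across iterations and
  a bin is significant when the rank-5 (of 10,000) value — the lower bound
  of a 99.9% interval — exceeds zero. Onset = first bin of five consecutive
  significant bins. Conservative; no CI on the estimate itself.
* **Confidence-Interval DPA** (`ci_dpa`): the onset is found *within* each
  of 1,000 iterations (first run of five bins with the slow survival
  percent ≥ 1.5 points above the fast); the median of the per-iteration
  onsets is the estimate and their 25th/975th sorted values form a 95% CI,
  so onsets can be compared across conditions (`compare_ci_overlap`).
* **Individual-Participant DPA** (`ip_dpa_participant`, `ip_dpa_group`):
  per participant and iteration, 1,200 draws from each condition's pool are
  sorted and paired; the iteration's divergence value is the mean of the
  first pair opening a run of 100 consecutive strictly positive paired
  differences s_i − f_i. Median over detecting iterations per participant;
  participants detecting in < 50% of iterations are flagged unreliable and
  excluded from group summaries (`compare_individual_estimates` runs the
  paired t test between conditions).

Synthetic-data generators with injectable, known divergence points
(`generate_simulation2_population`, `generate_null_population`) and a
simulation harness (`simulation1`, `simulation2`) reproduce the standard
validation designs: participant subsampling (bias under low power) and
observation subsampling (parameter recovery for individual differences).

## Worked example

```r
library(divpoint)

# a population with a known 140-ms divergence point injected into every
# participant: fast = 60 skewed draws/cell, slow = fast with a random half
# of the values >= 140 ms lengthened by 50 ms
pop <- generate_simulation2_population(
  n_participants = 104, per_cell = 60,
  effect_spec = artificial_effect_spec(divergence_values = 140),
  seed = 1)

ci <- ci_dpa(pop$table, dpa_config("ci", seed = 3))
ci
#> <divergence_result> ci DPA: estimate 151 ms, 95% CI [147, 154] ms (detection rate 1.000, 1000 iterations)

orig <- original_dpa(pop$table, dpa_config("original", n_iterations = 2000, seed = 2))
orig$estimate
#> [1] 148
```

Both group procedures place the onset a few ms after the injected 140 ms —
the earliest *detectable* separation sits where the survival difference
first clears the evidence threshold, slightly beyond the true onset. The
narrow CI (width 7 ms) reflects the strong, consistent injected effect; on
a null population `original_dpa` returns no estimate and `ci_dpa` reports a
low detection rate instead.

Recovery of individual differences (the acceptance-target quantity):

```r
pop <- generate_simulation2_population(104, 60, seed = 1009 %% 2147483629 + 1)
res <- ip_dpa_group(pop$table, dpa_config("ip", seed = 2003 %% 2147483629 + 1))
est <- setNames(res$participants$estimate_ms, res$participants$participant)
recovery_correlation(pop$truth, est)
#> [1] 0.934294
res$group_mean
#> [1] 174.2503
```

With 26 injected divergence levels (110–210 ms, truth mean 160 ms) the
individual estimates correlate with the truth at r ≈ 0.93, and the group
mean sits near 173 ms — later than 160 because group IP summaries track
where each participant's effect becomes individually detectable.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dpa.R", package = "divpoint"))')" \
  run --procedure ci --input table.csv --slow-label low --fast-label high \
  --iterations 1000 --seed 7 --out result.json
```

Subcommands: `run`, `synth` (generate sim2/null CSVs plus a truth map),
`simulate` (designs 1 and 2), `compare` (CI overlap + paired t test).
Input CSVs are long format with header `participant,condition,latency_ms`;
the slow/fast role assignment always comes from the labels you pass, never
from the data.

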