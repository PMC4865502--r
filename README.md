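# vstmbind

Analysis tools for the **'What was where?'** delayed-reproduction task, a
visual short-term memory (VSTM) paradigm that separates *what* a person
remembers from *where* they remember it. Participants study 1 or 3 fractal
objects at random screen positions, wait 1 or 4 seconds, pick the studied
object from a two-alternative test array, and drag it back to its
remembered location on a touch screen. Because the report is continuous,
errors can be decomposed into distinct sources — and one of them,
**object-location misbinding** ("swap errors"), is a candidate early
cognitive marker of hippocampal dysfunction in familial Alzheimer's disease
(FAD).

The package is written for behavioural researchers who want a tested,
reproducible version of this analysis: a constrained trial-design
generator, a generative simulator of participant reports, the error
metrics, and the group-level inference — all as pipe-friendly functions on
tibbles.

## The outcome measures

For each trial with target location $\mathbf{t}$, non-target locations
$\mathbf{n}_j$, and reported location $\mathbf{r}$ (degrees of visual
angle):

* **Identification** — proportion of trials where the target, not the
  foil, is chosen in the two-alternative test array.
* **Gross localization error** — $\lVert \mathbf{r}-\mathbf{t} \rVert$,
  on correctly identified trials only.
* **Nearest-neighbour error** —
  $\min_k \lVert \mathbf{r}-\mathbf{x}_k \rVert$ over *all* array items
  regardless of identity: a precision measure insensitive to swaps.
* **Swap error** — a correctly identified object placed within 4.5° of a
  non-target's original location (boundary inclusive). Items are never
  closer than 9°, so a report can qualify for at most one partner.
* **Chance-corrected swap rate** — the observed swap rate minus the rate
  expected under a geometric null in which non-target positions are
  redrawn by the same constrained sampler conditional on the realized
  target position (Monte-Carlo, with its standard error).

Group contrasts use covariate-adjusted (generalized) linear models on
subject summaries — Gaussian for continuous outcomes (t statistics),
binomial for identification counts (z statistics, odds ratios) — with
bias-corrected accelerated (BCa) bootstrap confidence intervals from 2000
stratified replications, repeated-measures interaction tests
(group × block × load), and hippocampal-volume association models
(log-scale for localization error, square-root scale for swap rates,
adjusted for age, sex and total intracranial volume).

## Worked example

```r
library(vstmbind)
library(dplyr)

cohort <- simulate_cohort(
  n_per_group = c(control = 30, asymptomatic = 12, symptomatic = 8),
  seed = 2026
)
outcomes  <- score_trials(cohort$responses, cohort$sessions)
summaries <- summarize_subjects(outcomes) |>
  left_join(select(cohort$subjects, -params), by = "participant_id")

summaries |>
  group_by(group) |>
  summarise(ident = mean(ident_pct), gross = mean(gross_err_deg),
            nn = mean(nn_err_deg), swap = mean(swap_pct))
#> # A tibble: 3 × 5
#>   group        ident gross    nn  swap
#>   <chr>        <dbl> <dbl> <dbl> <dbl>
#> 1 asymptomatic  89.6  7.87  3.76  15.5
#> 2 control       91    6.44  3.78  10.6
#> 3 symptomatic   81.2 10.3   5.27  18.1
```

Identification falls and errors grow from controls through asymptomatic to
symptomatic carriers; the asymptomatic group's deficit is concentrated in
the swap rate (15.5% vs 10.6%) while its nearest-neighbour precision is
control-like (3.76° vs 3.78°) — the misbinding signature the task is
designed to expose.

```r
cmp <- adjusted_group_comparison(
  filter(summaries, included), "swap_pct",
  groups = c("control", "symptomatic"),
  n_boot = 2000, seed = 99
)
cmp
#> Adjusted comparison of swap_pct: symptomatic vs control (n = 8/30)
#>   estimate 7.422 (SE 1.58), t = 4.696 (df = 34), p = 4.241e-05
#>   BCa 95% CI [3.571, 11.23] (B = 2000)
#>   adjusted for: nart, sex ; p-values are raw (no multiplicity correction)
```

Symptomatic carriers make an estimated 7.4 percentage points more swap
errors than controls after adjusting for premorbid IQ (NART) and sex.
`tidy()` and `glance()` return the same results as tibbles;
`autoplot(cmp)` draws the estimate with its interval. The all-in-one
driver `run_pipeline(pipeline_config(...), out_dir)` writes every stage's
table as CSV plus a manifest with the seed and configuration hash.

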