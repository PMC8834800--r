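---
title: "Modelling street-tree turnover, PM absorption and diversity with treedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling street-tree turnover, PM absorption and diversity with treedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treedyn)
```

## The model

`treedyn` treats a street-tree site as a system-dynamics stock-flow model.
The stocks are continuous per-species tree counts $N_i(t)$ (fractional trees
are deliberate: the model's flows are fractions of a tree per month, and
rounding happens only in reports). Two flows act on every stock each month:

* **Retirement.** Trees are removed at the end of a replacement cycle of
  $T$ months ($T = 240$, a 20-year cycle, by default). The site's initial
  age distribution is unknown, so the default scheduling is *first-order
  turnover*: each species loses $N_i / T$ trees per month, giving the stock
  a mean residence time of $T$. An alternative *cohort* scheduling (the
  initial stock retires linearly over exactly one period, i.e. a uniform
  initial age spread) is available via
  `turnover_settings(scheme = "cohort")` for sensitivity analysis.
* **Planting.** Every retired tree is replaced, so the site total is an
  invariant of the dynamics. The replacement flow is allocated by a
  `planting_policy()`:
  * `status_quo` — in proportion to the current composition, which makes
    any composition a fixed point;
  * `single_priority` — a designated species receives a fixed fraction $r$
    (the *intensive planting ratio*) of all plantings, and the remaining
    $1-r$ is split over the other species in proportion to their current
    counts with the priority species excluded from the proportions,
    recomputed every step;
  * `fixed_mix` — plantings follow a fixed distribution (the study's mixed
    scenarios use 30/30/30/10 across *Zelkova serrata*, *Prunus yedoensis*,
    *Pinus densiflora* and the pooled remainder).

Integration is explicit Euler with $\Delta t = 1$ month, the convention of
stock-flow simulation tools. There is no randomness anywhere in the
dynamics; runs are bit-reproducible.

Under a single-priority policy the priority stock obeys the linear ODE
$dB/dt = (rN - B)/T$ with the closed form

$$B(t) = rN + (B_0 - rN)\,e^{-t/T},$$

implemented as `closed_form_priority_share()` and used as an independent
oracle for the integrator. At $\Delta t / T = 1/240$ the first-order Euler
error stays below 1% of the site total over a 360-month horizon (the
acceptance sweep observes well under 0.1%); the synthetic-data property
tests draw $T \ge 24$ months, the range over which that bound continues to
hold.

## Ecosystem metrics

**PM absorption.** Monthly particulate-matter absorption of the site is
$\mathrm{MPA}(t) = \sum_i N_i(t)\, a_i\, w_{i,m(t)}$, where $a_i$ is the
species' annual absorption (g/tree/year), $m(t)$ the calendar month and
$w_{i,m}$ its monthly weight. In **flat** mode $w_{i,m} = 1/12$; in
**seasonal** mode the weights follow leaf phenology (below). Because every
weight vector sums to 1, the two modes agree on any whole-year total.

The reference rates are the published Seoul leaf-sampling estimates:
66.6 g/tree/year for *Zelkova serrata*, 45.3 for *Prunus yedoensis*, 24.2
for the evergreen *Pinus densiflora*, and the Korean national per-tree
estimate of 35.7 g/tree/year for the pooled "other" category, which the
model carries as a single deciduous pseudo-species (its phenology is not
published; `reference_species(other_phenology =)` makes the assumption
explicit and overridable). Leaf-level mechanism — leaf area index, stomatal
uptake, DBH scaling — is outside the model; species enter only through
$a_i$ and $w_{i,\cdot}$.

**Seasonal weights.** Species-level monthly absorption patterns are not
published numerically, so `seasonal_profile()` parameterizes their shape:

* deciduous — a leaf-on plateau from April to November with 1-month linear
  ramps on each side and zero weight in deep winter;
* evergreen — a year-round plateau with December–February damped to
  `evergreen_winter_fraction` (default 0.6) of the plateau level.

Defaults are chosen as a plausible temperate-Korea phenology; every
parameter is config-overridable, and no headline result depends on the
exact values — only on the structural properties that weights are
distributions and that evergreens keep strictly more of their mass in
winter than deciduous species do. Winter is fixed as meteorological
December–February.

**Diversity.** `shannon_index()` computes $H = -\sum_i p_i \ln p_i$ over
the categories with positive count, with $0 \ln 0 := 0$; the categories are
the three named species plus pooled "other" as one category, and the log
base is configurable. Natural log is the standard ecological convention.
The published study reports Shannon magnitudes (baseline 0.7) that cannot
be reconciled with any log base applied to its printed composition
($-\sum p \ln p = 0.96$ for counts 112/70/26), so the package treats
absolute published Shannon values as non-reproducible and reproduces
*orderings* instead (which it does: the diversity ranking matches the
published assessment table exactly).

## The nine reference scenarios

`reference_scenarios()` builds the published scenario set: a 208-tree
baseline (112/70/0/26) with status-quo replacement; four Replace-only
scenarios keeping the 208 total while replacing intensively toward Zelkova,
Prunus, Pinus (single-priority at ratio $r$) or the 30/30/30/10 mix; and
four Additional Tree Planting scenarios starting from expanded 388-tree
compositions — (292,70,0,26), (112,250,0,26), (112,70,180,26),
(172,130,60,26) — with the matching policies. The extra 180 trees are
planted instantaneously at simulation start: the published initial
compositions already include them, so no mid-run planting event exists.
All scenarios run monthly from January 2021 for 360 months.

The study states the intensive ratio as 70%, raised to 90% as a
sensitivity setting, without tying either value to specific result curves;
`target_ratio` is therefore a scalar scenario parameter, default 0.7, and
the analysis scripts run both.

Summaries use arithmetic means over simulated months 1–360; the month-0
snapshot enters only the reported initial value. `rank_scenarios()` orders
scenarios by mean absorption, by final-month Shannon index (the long-term
quantity the study emphasises; the mean is also reported), by joint
improvement over the baseline, and by winter-mean absorption, breaking ties
lexicographically.

## What reproduces, and a documented divergence

Exactly reproducible desk-scale quantities — the five published initial
absorption values (963, 1962, 1643, 1326, 1644 g/month) and the constant
baseline mean (963 g/month) — are reproduced to the printed integer by the
test suite and the acceptance script. Published *trajectory averages* for
the other scenarios and absolute Shannon levels are not reproducible from
published information: they depend on the original model's undisclosed
turnover scheduling (its curves converge faster than any
first-order turnover can) and on its unresolved Shannon categorization.
For these, the package reproduces the published orderings: PM ranking,
diversity ranking, winter ranking, and the Replace-only/Additional
dominance patterns all match.

One ordering claim diverges, knowingly. With first-order turnover at
$r = 0.7$, `Plant_more_Pinus` still sits above the baseline on final
Shannon after 360 months (1.5 time constants leave the fourth abundant
species only partially converged), so it joins `Plant_more_Mix` on the
joint both-improved criterion, whereas the published table lists
`Plant_more_Mix` alone. The package keeps the faithful first-order model
rather than tuning toward the published table; `analysis/03_rankings.R`
shows that faster conversion — $r = 0.9$, or cohort scheduling — leaves
`Plant_more_Mix` alone on the joint criterion, consistent with the
published claim being an artefact of the original model's faster turnover.

## Synthetic data for property testing

The `synthetic_spec()` generators exist so that every pipeline stage is
testable without external data. They emulate the statistical shape the
analysis assumes — a site total split across $k$ species by a symmetric
Dirichlet draw; annual absorption rates log-normal with median pinned to
the 35.7 g/year national estimate (strictly positive, right-skewed;
sd 0.4 on the log scale); evergreen phenology as a Bernoulli draw;
uniformly chosen valid policies. These are declared testing conventions,
not fitted distributions, and they do not emulate real-world features such
as spatial arrangement, age structure, mortality or measurement error —
passing property tests therefore demonstrates internal consistency of the
model, not predictive skill on real inventories. Each generator takes an
explicit seed and restores the global RNG state, so property sweeps are
reproducible seed-by-seed.

## Numerical choices and degenerate inputs

* Allocations are built to sum exactly to the retirement flow;
  conservation is asserted to $10^{-9}$ relative throughout the tests.
* Stocks that dip below zero by floating error are clipped to zero (with a
  warning beyond $-10^{-8}$); this cannot occur with $\Delta t \le T$ under
  first-order turnover but protects the cohort scheme.
* An empty composition has absorption 0; its Shannon index is an error, as
  are proportional allocations from an empty site.
* If a single-priority policy finds no non-priority stock to share the
  remainder, the priority species receives the whole flow.
* Trajectory CSVs print floats at 6 significant digits; YAML configs are
  written at 17 significant digits so parameter tables round-trip
  bit-identically.

Problem sizes throughout (360-month horizons, 100-configuration oracle
sweeps, 1000-composition fuzzing) were chosen so the full study re-runs in
seconds while exercising every code path at the study's own scale.

## Limitations

Tree mortality, growth, pests, climate feedbacks, PM concentration fields,
deposition physics and costs are all outside the model; absorption is
strictly per-tree rate times stock. Results are scenario projections of a
deliberately small mechanistic model, suited to comparing planting policies
at one site, not to forecasting air quality.
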