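---
title: "Multistate life tables for long-term-care states: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate life tables for long-term-care states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carestates)
```

This vignette is the package's own account of its statistical methods: the
multistate model and its conventions, the smoothing and standardization
machinery, the decomposition, the bootstrap, what the synthetic-cohort
generator does and does not emulate, and the design decisions taken where
several defensible choices existed.

## The model

Older adults (ages 70–105) occupy one of three transient long-term-care
(LTC) states — `no_care` (0), `home_care` (1), `care_home` (2) — or the
absorbing state `dead` (3). All transitions among the transient states are
allowed, including recovery to lower care levels. Time is discrete: the age
axis is divided into 3-month intervals from age 70 to the terminal age
$\omega = 105$, and for each interval starting at age $a$ a $4\times4$
row-stochastic matrix $P(a)$ gives the probability of each state at
$a + 0.25$ given the state at $a$. Narrow intervals capture short care-home
stays that annual models miss. This is an *incidence-based* health-expectancy
model: everything is built from observed transitions, not prevalence
snapshots.

### Counting transitions

`count_transitions()` maps each person's monthly state history onto the
grid. A person is at risk in the interval starting at $a$ if they are alive
and under observation at the moment they reach exact age $a$; the origin
state is the state recorded for the calendar month containing that moment
(state histories have monthly resolution, so the state is constant within a
month). The destination is the state in the month containing age $a + 0.25$,
or death if the death date falls inside the interval. A person whose
observation ends inside the interval for any other reason (emigration,
administrative end of follow-up) is removed from both numerator and
denominator of that interval — the standard discrete-time treatment of
mid-interval censoring.

### Smoothing

Raw probabilities `count / at-risk` are noisy at old ages where few remain
at risk. `smooth_probabilities()` fits, for each origin state and each
off-diagonal destination, a binomial generalized additive model on the logit
scale with a penalized B-spline (P-spline) basis in age, weighted by the
at-risk counts. Defaults (all configurable via `mslt_control()`): cubic
B-splines, 15 basis functions across the grid, second-order difference
penalty, smoothing parameter by REML. These are standard P-spline practice;
there is no published reference setting for this problem, so the defaults
are declared rather than inherited. Choices worth knowing:

* **Per-transition binomial fits, not a joint multinomial smoother.** Each
  of the nine exit curves is fitted independently and the stay probability
  is set to one minus the fitted exits. If the fitted exits ever sum above
  one (possible only in pathologically sparse strata) they are rescaled
  proportionally and a warning is raised. This keeps every curve testable in
  isolation; the cost is that the row constraint is imposed post hoc rather
  than by the likelihood.
* **Smoothing scale.** Fitting is on the logit scale, which keeps fitted
  probabilities in $(0, 1)$ and makes the heavy-penalty limit a log-odds
  line in age (a Gompertz-like baseline) — a sensible null for mortality.
* **Ages without data** are predicted from the fit. With baseline ages 75+
  this concerns ages 70–75, which stabilize the spline but are never
  reported: life expectancies are computed from 75 onward.
* **Frozen smoothing parameters.** A fitted surface carries its selected
  smoothing parameters as attribute `"sp"`; passing them back through
  `mslt_control(sp = ...)` reproduces the fit without re-running REML. The
  bootstrap-coverage study in the test suite selects the parameters once per
  simulated dataset and holds them fixed across that dataset's bootstrap
  replicates — re-selection per replicate mostly adds selection noise to the
  interval at substantial cost.

### Life-table conventions

`occupancy()` iterates $\pi(a + \Delta) = \pi(a) P(a)$; `state_expectancies()`
accumulates $\Delta \sum_a \Pr(\text{in } s \text{ at } a)$. Three
conventions are fixed so that results are reproducible bit for bit:

1. **Full-interval credit.** A person present at an interval start is
   credited the whole interval. With zero mortality this forces a remaining
   life expectancy at 75 of exactly $120 \times 0.25 = 30$ years, and with
   certain death in the first interval exactly 0.25 years. A trapezoidal
   (half-interval) correction is available via `half_interval = TRUE`; at
   3-month resolution it shifts totals by at most $\Delta/2 = 0.125$ years.
2. **Closure at $\omega$.** At age 105 all remaining probability mass moves
   to death. Survivorship beyond 105 is negligible in the populations the
   model targets, but the convention must be fixed for exact testability.
3. **Initial distribution.** By default the life expectancy is
   population-based: the initial state mixture is the observed composition
   of the at-risk cohort at the index age, matching a whole-population
   reading of care-state expectancy bars. `conditional = TRUE` instead
   conditions on starting without care. Both modes are first-class because
   registry publications rarely state which one a figure uses.

State expectancies sum to the total *exactly* (same summation), which the
test suite asserts as an identity, not within a tolerance.

## Rates, standardization, comparisons

The second analysis track works on the person level. The **baseline state**
is the state occupied in the calendar month immediately preceding the
baseline month; when care use changes mid-month the highest care level
occupied at any time in that month wins (this choice avoids undercounting
short care-home stays and is stated openly because register conventions
differ). Persons not under observation in that reference month are excluded
rather than errored.

Death **rates** are deaths divided by person-years over a 3-year follow-up
window (5 years as a sensitivity setting), accumulated within
population × sex × 5-year age group × *baseline* state — intention-to-treat
style: a death after a later care-state change still counts in the baseline
state's cell. CIs are Wald with Bernoulli variance for proportions and
Poisson variance for rates; rate differences are compared on the natural
scale (variance sum) and rate ratios on the log scale
($\mathrm{var}(\log \mathrm{RR}) = 1/D_A + 1/D_B$). The comparison order
(A − B) is an explicit argument echoed in every output row; no sign
convention is hard-coded.

**Age standardization** uses the combined two-population cohort as the
standard, with weight sets per sex and per baseline state (plus an `all`
set). Standardizing a population with weights proportional to its own
denominators returns its crude value exactly — an identity used as a test.
At desk scale, rare cells (care home at 100+) can be empty in one
population; the pipeline then restricts the weight set to the common
support and renormalizes. With registry-scale data every cell is populated
and this is a no-op.

## Decomposition

`decompose_rates()` splits the total-population rate difference
$M_A - M_B$, where $M = \sum_s \pi_s m_s$, into

$$\underbrace{\sum_s \frac{m_{sA}+m_{sB}}{2}\,(\pi_{sA}-\pi_{sB})}_{\text{composition}}
\;+\; \sum_s \underbrace{\frac{\pi_{sA}+\pi_{sB}}{2}\,(m_{sA}-m_{sB})}_{\text{rate component for } s}.$$

This averaged two-factor (Kitagawa-type) decomposition is exactly additive
and antisymmetric under population swap; both properties are tested on 1000
random fixtures at $10^{-9}$. A stepwise-replacement variant
(`method = "stepwise"` — the average of the two pure replacement orders) is
provided for sensitivity; for two factors it is algebraically identical to
the averaged form, which the tests confirm numerically. The standardized
decomposition is the weight-average of the age-specific ones and inherits
exact additivity by linearity. Components are reported per 1000
person-years, the same scale as the rates.

## Bootstrap

`ltc_bootstrap()` implements the percentile bootstrap (default 1000
replicates, 2.5th/97.5th percentiles). The resampling unit is the whole
individual trajectory, stratified by population × sex, so per-stratum sample
sizes are preserved exactly and within-person serial dependence is never
broken — the conservative choice when the resampling unit is not dictated by
the design. Replicates come from a single seeded RNG stream drawn
sequentially; the same seed reproduces the same intervals byte for byte.
Replicate failures (e.g. an empty cell in a tiny resample) are excluded with
a warning when below 1% of replicates and are an error otherwise.

## The synthetic-cohort generator

Because individual-level registry data of this kind cannot be shared, the
package ships `ltc_scenario()` / `simulate_cohort()`: a generator whose
*exact implied estimands* are computable, so parameter recovery can be
tested honestly.

**What it emulates.** Two populations ("A", Japan-like; "B", Sweden-like),
both sexes, baseline 2017-04-01 with 3-year follow-up (5-year
configurable), baseline ages 75+ drawn from 5-year-group mixtures, initial
states from state-given-age mixtures, all inter-state transitions including
recovery, mortality increasing log-linearly with age and sharply with care
level, emigration censoring (exponential, state-independent), and
observation starting one month before baseline so the baseline-state rule is
exercised. The default age and state-given-age mixtures are taken from
published census-style cohort tables; the default hazards were calibrated
once against the package's analytic life-table oracle so the implied life
expectancies sit at realistic register magnitudes (total LE at 75 of roughly
12.5 vs 11.9 years for men and 15.0 vs 13.2 for women, population B with
higher in-LTC mortality and more care-home use, and population A's no-care
mortality overtaking B's around age 80). No published transition
probabilities exist to match exactly, and nothing in the test suite compares
against these magnitudes.

**The monthly clock.** Trajectories are simulated month by month while the
parameters are specified per 3-month interval; the monthly exit probability
is $1-(1-p)^{1/3}$ of the total exit mass, allocated across destinations
proportionally (competing-risks-proportional). The generator's clock is
therefore deliberately *not* the estimation grid, so interval handling in
the estimator is genuinely tested rather than mirrored.
`true_transition_surface()` returns the composition of the three monthly
kernels inside each grid interval — the exact law of the generator on the
grid and hence the quantity empirical frequencies converge to. (The nominal
3-month parameters differ from this law at second order when several exits
compete; defining the oracle as the composed kernel keeps the recovery tests
unbiased.) Deaths and censorings are dated mid-month.

**Seeding.** One master seed (`set.seed`) drives the whole cohort through
vectorized month-stepping in a fixed stratum order; the same configuration
and seed reproduce the panel byte for byte. Per-person RNG substreams were
considered and rejected: they would force a per-person loop in R for a
parallelism the package does not use.

**What it does not emulate** — and therefore what passing tests do *not*
show about real registers: no informal care (so no blurring of the no-care
boundary), no household structure, no seasonal or period effects (hazards
depend on age only), no measurement error or linkage error in state
histories, no state-dependent emigration, and exact monthly state
resolution rather than episodic records with reporting gaps. Recovery tests
demonstrate that the estimator inverts the generator's data law, not that
the model is correct for any particular country's registers.

## Problem sizes and numerical tolerances

The test suite runs at desk scale, chosen as the package's own balance of
power against runtime: parameter recovery uses 10,000 persons per
population × sex (raw transition probabilities within 3 SE of the true
surface pointwise, read statistically: at least 99% of informative cells
inside 3 SE — with thousands of cells, a literal all-cells assertion at 3 SE
would fail by chance — and none beyond 6 SE). The life-table algebra is
checked against 200,000 Monte-Carlo trajectories at 3 SE and against the
geometric closed form of the constant-hazard two-state chain at $10^{-9}$.
The bootstrap-coverage study uses 20 independently simulated datasets of
1,500 persons with 100 bootstrap replicates each and requires the 95%
percentile interval to cover the true life expectancy in at least 90% of
replications; percentile-interval coverage does not depend on the cohort
size, so the smaller-than-registry $n$ tests the same property at a
fraction of the cost. A null scenario with two identical populations
verifies that standardized rate differences sit within 3 SE of zero and
that bootstrap intervals for every decomposition component cover zero.

Row-stochasticity is enforced at $10^{-9}$; the dead row is exact;
decomposition additivity and the own-weights standardization identity are
exact to floating point ($10^{-9}$ and $10^{-12}$ in the assertions).

## Known limitations

* The discrete-time model has no continuous-time generator; probabilities
  are tied to the 3-month grid and cannot be rescaled to other interval
  widths without refitting.
* Post-hoc row renormalization (rare, warned) slightly distorts the
  individual fitted curves where it triggers.
* The Wald intervals for rates and proportions are the conventional
  register-epidemiology choice but degenerate in zero-death cells (flagged
  `low_information`); the bootstrap is the fallback there.
* P-spline extrapolation into the unobserved 70–75 range is a linear
  log-odds extension; those ages must not be interpreted, only integrated
  over (and the reported quantities never use them).
* `baseline_states()` classifies from monthly panels; the highest-level
  rule is applied when converting episodic records via
  `episodes_to_panel()`, so a panel built elsewhere with a different
  mid-month rule will carry that rule through.
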