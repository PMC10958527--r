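---
title: "Model structure, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campcea)
```

This vignette is the package's own account of the science: the cohort
model and its assumptions, the parameters that matter, what the
synthetic-data generators emulate, and the choices made where the model's
published description left the design genuinely open.

## The decision problem

Chronic diabetic foot ulcers (DFUs) — ulcers not halving in size after four
weeks of good wound care — heal slowly under standard of care (SoC:
debridement, infection control, off-loading, moist wound environment) and
carry material risks of infection, amputation and death. Skin substitutes
(CAMPs) applied adjunctively raise healing rates at a substantial product
cost. The package ranks six human-origin CAMPs and SoC by cost-effectiveness
from a US payer perspective, using each CAMP's randomized evidence against
SoC to compare the CAMPs indirectly with SoC as the anchor.

## Cohort model

Eight health states on a weekly cycle: `UNHEALED`, `POST_UNHEALED`,
`HEALED`, `POST_HEALED`, `INFECTED`, `AMPUTATION`, `POST_AMPUTATION`,
`DEAD` (absorbing). The paired "post" states honour the stated model
structure: the unpaired member is a one-cycle entry state (newly unhealed,
newly healed, the amputation event itself) whose occupants move to the
persistent post state after one cycle. In the base case a post state carries
the same exit probabilities, weekly cost and utility as its parent, so the
pairing is behaviourally neutral but leaves room for state-specific
overrides (for example an elevated perioperative cost on `AMPUTATION`
only).

The whole cohort starts unhealed. Weekly exits from the unhealed pool are
healing, infection, amputation and death; the infected state resolves,
progresses to amputation, or dies; healed states and the post-amputation
state face only (background or state-specific) mortality. The trace records
state occupancy per cycle and the cumulative first-passage incidence of
healing — once healed a wound cannot reopen in this model (no recurrence),
so inflow into `HEALED` from non-healed states is exactly the probability
of having ever healed, the published "healed wounds" outcome.

```{r}
M <- build_matrix(camp_strategies()$SoC)
round(M["UNHEALED", ], 4)
```

## Parameters

**Baseline transitions.** Published as cumulative probabilities with 95%
CIs over a source period — 12 weeks for trial-derived rows (healing,
infection, direct amputation), 52 weeks for annual rows (post-infection
amputation, mortalities, background mortality); the periods were inferred by
reproducing each published weekly value. The conversion is *linear division
by the period length*: it reproduces every published weekly figure, which is
why it is the default rather than the actuarial constant-rate form
`1 - (1 - p)^(1/n)` (available via `model_options(conversion =
"constant_rate")`). Linear conversion slightly understates early-cycle
hazard relative to the exponential form; at these magnitudes the difference
is under one part in ten.

**Treatment effects.** Product-specific wound-closure risk ratios (vCPM
2.91, HAMA 2.62, HSAM 1.64, dHACM 1.63, BLCC 1.55, hFDS 1.31) and
class-wide infection (0.49) and amputation (0.27) risk ratios, applied
multiplicatively on the weekly probability scale with a cap at 1, for as
long as the cohort occupies the unhealed states. Not truncating the
12-week trial effect is deliberate: the published 52-week healed-wound
magnitudes are only reachable with a persistent effect.

**Costs.** Product cost = cost per application × applications, charged
upfront in the first cycle (applications are not dated in the source; with
no discounting the timing is immaterial). Base case: 4 applications for
every CAMP; the sensitivity fixture uses the trial-reported means (5 BLCC,
6 vCPM, 7.1 hFDS, 3.5 dHACM). The dHACM cost row is internally inconsistent
in the source ($933 × 4 ≠ $3,264.45); the fixture stores the printed
per-treatment total as authoritative and records the discrepancy. Weekly
state costs (unhealed $600, infected $900, healed $0, post-amputation $150)
and the one-off amputation event cost ($35,000, hospitalization plus a year
of subsequent care) are **assumption-level placeholders**: the source cites
them from literature without printing values. They were chosen once at the
scale of that literature and are flagged in the fixture file. QALYs use
annual utility weights (unhealed 0.75, healed 0.84, infected 0.71,
post-amputation 0.63, dead 0), equally placeholder.

Consequence: the healed-wound surface and everything derived from it is a
reproduction of the published analysis; absolute costs and QALYs are
scale-correct but assumption-dependent, and the ranking stages are
therefore also validated against the published results tables used directly
as stage inputs.

**Accrual.** Costs and utilities accrue on the occupancy reached after each
weekly transition, without half-cycle correction; QALYs divide by 52. The
amputation event cost is charged on each cycle's inflow into `AMPUTATION`.

## Structural choices (and why)

* **Infection resolution routes back to `UNHEALED`** (default). The stated
  structure has infected ulcers returning to the unhealed state rather than
  counting directly as closures, and the numbers agree: with
  return-to-unhealed the model yields 0.612 cumulative healed wounds for
  SoC and 0.931 for vCPM at 52 weeks, against the published 0.601 and
  0.914; routing resolution directly to `HEALED` pushes SoC to 0.705.
  The direct routing remains available
  (`model_options(infection_healing_to = "healed")`).
* **Both amputation pathways are active**: direct from the unhealed state
  and from the infected state, because both published transition rows exist;
  either can be zeroed in configuration.
* **Mortality is not double-counted**: the state-specific mortalities are
  treated as already inclusive of background mortality; healed states use
  the flat all-ages weekly background rate (0.09%), with age-band overrides
  (`model_options(age_band = ...)`) and additive stacking
  (`add_background_mortality = TRUE`) available as switches.
* **ICER as a ratio**: incremental cost divided by incremental effect; the
  frontier sorts by cost (ties broken by descending effect, keeping the more
  effective strategy eligible), removes simple dominance, then iteratively
  removes extended dominance until surviving ICERs strictly increase
  (equal slopes, up to relative rounding noise of 1e-9, count as extended
  dominance). ICERs are kept unrounded internally.
* **Tornado metric**: net monetary benefit at $100,000 per healed wound by
  default; ICER tornadoes are unstable when increments cross zero, so the
  ICER is optional.

## A note on the published tables

The published results table transposes the hFDS and BLCC rows relative to
its own risk ratios: cumulative healing is strictly monotone in the healing
risk ratio in any model of this structure, and the published
anchored-comparison table (increments −$1,432 / 0.216 and −$364 / 0.174)
matches the swapped assignment, not the printed one. The acceptance tests
therefore compare against the published ordering and increments with that
single adjacent transposition corrected, and verify it is the only
difference.

## Probabilistic sensitivity analysis

Distribution assignment follows the conventional families: beta for
probabilities (sampled on the cumulative source-period scale, where the CIs
live, then converted weekly per draw) and utilities, gamma for costs,
lognormal for risk ratios. Moment matching uses the normal-theory standard
error `(upper − lower)/3.92` where only a CI is published and a ±20%
SE-equivalent spread where nothing is. The lognormal is *median-centred* on
the reported ratio (`meanlog = log RR`), matching the log-scale symmetry of
the published intervals; its arithmetic mean therefore exceeds the reported
ratio by `exp(sdlog²/2)` (≈4.7% for vCPM), which is a property of the
centring choice, not a sampling bias — the sampled-moment tests check means
for beta/gamma and the median for lognormal.

Each of the 5,000 draws samples one shared baseline, shared class effects
and shared state values for every strategy (common random numbers mirror
the shared evidence base) plus per-CAMP healing ratios and product costs;
draws that momentarily violate row feasibility are rescaled to the boundary
and counted in diagnostics (none occur at the base-case spread). CEACs
report, per willingness-to-pay threshold, the fraction of draws in which
each strategy attains the maximal net monetary benefit, ties split equally.
At 5,000 draws the acceptability estimates carry Monte Carlo noise of about
±0.01; doubling the draws halves little of substance, and the published
60%/40% figures depend on the unprinted cost/utility inputs, so the package
treats the PSA ranking (vCPM first, HAMA second) as the reproducible
quantity.

```{r, eval = FALSE}
psa <- run_psa(camp_strategies(), n_draws = 5000, seed = 1)
ceac(psa, thresholds = seq(0, 2e5, by = 5e3))
```

## Synthetic data

The generators produce every input the pipeline needs without downloads,
and are pure functions of their seed:

* `generate_trials()` emulates the evidence base behind the pooled class
  effects: a handful of two-arm trials (default 5 studies, 50–150 patients
  per arm, control event risk 0.20) with a study-level log risk ratio drawn
  from `Normal(log RR, tau)` (default RR 0.49, tau 0.2) and binomial event
  counts. It emulates between-study heterogeneity and binomial sampling
  noise; it does **not** emulate publication bias, differential follow-up
  or non-compliance, so recovery tests certify the estimator, not the
  robustness of the published pooling to those threats.
* `generate_random_parameter_set()` draws a full, row-feasible parameter
  set around the published means using the PSA distributions
  (rejection-resampled, capped at 1,000 attempts).
* `generate_strategy_cloud()` draws random cost/effect pairs spanning all
  dominance geometries for frontier stress tests against a convex-hull
  oracle.

Passing tests on these generators show the machinery is correct under the
stated uncertainty structure; they cannot show that the placeholder state
values match the unpublished originals, which is why costs and QALYs stay
labelled assumption-level throughout.

## Numerical conventions and problem sizes

Row sums are validated to 1e-12 and occupancy conservation to 1e-9; the
path-enumeration oracle agrees with the trace to 1e-10 at a 6-cycle
horizon. The test suite exercises 1,000 random frontier clouds, 1,000
random cohort models, 500 replicate meta-analyses and a 100,000-patient
microsimulation (agreement within 3 standard errors); these sizes give
comfortable statistical resolution for every property tested while keeping
a full run in well under a minute for the unit suite.

## Known limitations

* No ulcer recurrence after healing, no individual-level heterogeneity in
  wound size or age (beyond the age-band mortality override), no half-cycle
  correction.
* Absolute costs and QALYs depend on placeholder state values (above).
* The class-wide infection and amputation effects assume no differences
  between CAMPs on those outcomes; products with stronger healing effects
  may be penalized by this assumption.
* The study-level 2×2 tables behind the published pooled class effects are
  not published; the pooled ratios are fixture constants, and the
  meta-analysis stage is validated on synthetic trials instead.
* Indirect comparison through a common SoC anchor inherits the usual
  caveats of unanchored cross-trial differences.
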