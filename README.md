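# campcea

Cost-effectiveness modelling of human-origin skin substitutes — cellular,
acellular and matrix-like products (CAMPs) — used adjunctively with standard
of care (SoC) for chronic diabetic foot ulcers (DFUs). The package is aimed
at health-economic modellers and reimbursement analysts who want a tested,
scriptable re-implementation of this published decision model: six CAMPs
(vCPM, HAMA, dHACM, hFDS, BLCC, HSAM) compared indirectly against each other
with SoC as the common anchor, from a US payer perspective.

## The model

The core is an eight-state Markov cohort model with a weekly cycle over a
52-week horizon (12- and 26-week scenarios): *unhealed ulcer*,
*post-unhealed ulcer*, *healed ulcer*, *post-healed ulcer*, *infected*,
*amputation*, *post-amputation*, and absorbing *death*. The cohort starts
100% unhealed; each week it can heal, become infected, progress to
amputation, or die. Writing `p` for a weekly transition probability, the
treatment effect of a CAMP enters multiplicatively,

    p_heal   = p_heal_SoC  x RR_healing   (product-specific)
    p_infect = p_infect_0  x RR_infection (class effect, 0.49)
    p_amp    = p_amp_0     x RR_amputation (class effect, 0.27)

with weekly baselines obtained from published cumulative probabilities by
linear division by the source period (12-week trial or 52-week annual
values), the convention that reproduces every published weekly figure.
Outcomes per patient are cumulative healed wounds (first-passage incidence
into the healed state), QALYs (utility-weighted state occupancy / 52) and
total cost (upfront product cost = cost per application x applications,
weekly state costs, a one-off amputation event cost). Nothing is discounted
at these horizons.

Around the engine sit the standard decision-analytic layers:

* **Evidence synthesis** — DerSimonian–Laird random-effects pooling of
  two-arm event tables on the log risk-ratio scale
  (`pool_dersimonian_laird()`), with `tau^2 = max(0, (Q - (k-1))/(S1 - S2/S1))`.
* **Ranking** — SoC-anchored incremental comparison (`anchor_to_soc()`) and
  an ICER frontier with simple and extended dominance (`build_frontier()`);
  `ICER = delta cost / delta effect` between surviving neighbours, strictly
  increasing along the frontier.
* **Sensitivity** — one-way (tornado) analysis over 95% CIs or ±20% ranges
  (`run_owsa()`), horizon scenarios (`run_scenario()`).
* **Uncertainty** — probabilistic sensitivity analysis with 5,000 Monte
  Carlo draws (`run_psa()`: beta for probabilities/utilities, gamma for
  costs, lognormal for risk ratios) and cost-effectiveness acceptability
  curves (`ceac()`).

Every published input ships as a structured-text fixture
(`inst/extdata/tables_1_2_3.json`). Health-state costs and utilities are
*not* published and are assumption-level placeholders
(`placeholder_costs_utilities.json`); the healed-wound surface does not
depend on them, but absolute costs and QALYs do.

## Worked example

```r
library(campcea)
strategies <- camp_strategies()          # SoC + six CAMPs, 52-week horizon
out <- run_strategies(strategies)
print(out, digits = 4)
#>   strategy  cost  qalys healed_wounds horizon_weeks
#> 1      SoC 21725 0.7467        0.6120            52
#> 2     vCPM 11104 0.7928        0.9307            52
#> 3     HAMA 11687 0.7903        0.9200            52
#> 4    dHACM 16186 0.7771        0.8430            52
#> 5     hFDS 19876 0.7705        0.7896            52
#> 6     BLCC 18766 0.7756        0.8317            52
#> 7     HSAM 24536 0.7773        0.8444            52
```

Healed wounds land on the published surface (SoC 0.601, vCPM 0.914, both
within ±0.05); costs and QALYs are on the published scale but depend on the
placeholder state values. Anchoring to SoC reproduces the published
decision structure — every CAMP except HSAM is cost-saving and dominant,
HSAM buys extra healing at a positive ICER:

```r
anchor_to_soc(out)
#>   strategy inc_cost inc_healed_wounds ... cost_per_healed  quadrant
#>   SoC             0            0.0000                  NA    anchor
#>   vCPM       -10621            0.3187                  NA  dominant
#>   ...
#>   HSAM         2810            0.2324               12092 trade-off

psa <- run_psa(strategies, n_draws = 5000, seed = 1)
ceac(psa, thresholds = 1e5)   # vCPM highest, HAMA second
```

A YAML-configured pipeline (`load_config()` + `run_pipeline()`) writes the
outcome, anchored, frontier, OWSA, scenario and PSA/CEAC tables plus a run
manifest, byte-reproducibly for a fixed seed.

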