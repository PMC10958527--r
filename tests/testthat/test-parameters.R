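test_that("period-to-weekly conversion reproduces the published weekly column", {
  tab <- cea_tables()$baseline_transitions
  weekly <- period_to_weekly(tab$mean, tab$period_weeks)
  # every published weekly value, to the printed 2 decimals on the % scale
  expect_equal(round(100 * weekly, 2), 100 * tab$weekly_printed)
  expect_equal(period_to_weekly(0, 12), 0)
  expect_equal(round(period_to_weekly(0.3829, 12), 4), 0.0319)
  expect_equal(round(period_to_weekly(0.174, 52), 4), 0.0033)
})

test_that("constant-rate conversion is available behind the convention switch", {
  expect_equal(period_to_weekly(0.3829, 12, "constant_rate"),
               1 - (1 - 0.3829)^(1 / 12))
  expect_equal(round(period_to_weekly(0.3829, 12, "constant_rate"), 4), 0.0394)
  # the constant-rate weekly value always exceeds the linear one for p in (0,1)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(period_to_weekly(p, 12, "constant_rate") >
                    period_to_weekly(p, 12, "linear")))
})

test_that("conversion is monotone in probability and period, and validates input", {
  p <- seq(0, 1, by = 0.1)
  expect_true(all(diff(period_to_weekly(p, 12)) > 0))
  for (pp in c(0.1, 0.5, 0.9)) {
    expect_true(period_to_weekly(pp, 12) > period_to_weekly(pp, 52))
  }
  expect_error(period_to_weekly(-0.1, 12), "0, 1")
  expect_error(period_to_weekly(1.1, 12), "0, 1")
  expect_error(period_to_weekly(0.5, 0), ">= 1")
})

test_that("risk-ratio application is multiplicative, capped, and validated", {
  expect_equal(apply_risk_ratio(0.0319, 2.91), 0.0319 * 2.91)
  expect_equal(round(apply_risk_ratio(0.0319, 2.91), 4), 0.0928)
  expect_equal(apply_risk_ratio(0.0319, 1), 0.0319)
  expect_equal(apply_risk_ratio(0.6, 2), 1)
  # never outside [0, 1] over a random grid
  set.seed(42)
  p <- runif(200); rr <- exp(runif(200, -3, 3))
  out <- apply_risk_ratio(p, rr)
  expect_true(all(out >= 0 & out <= 1))
  expect_error(apply_risk_ratio(-0.1, 1), "0, 1")
  expect_error(apply_risk_ratio(0.1, -1), "positive")
})

test_that("product-cost arithmetic matches the published per-treatment totals", {
  expect_equal(product_cost_per_treatment(1201.125, 4), 4804.50)
  expect_equal(product_cost_per_treatment(2918.35, 4), 11673.40)
  expect_equal(product_cost_per_treatment(500, 0), 0)
  expect_error(product_cost_per_treatment(-1, 4), ">= 0")
})

test_that("the SoC fixture is the null strategy", {
  soc <- camp_strategies()$SoC
  expect_equal(soc$effect$rr_healing, 1)
  expect_equal(soc$effect$rr_infection, 1)
  expect_equal(soc$effect$rr_amputation, 1)
  expect_equal(total_product_cost(soc$costs), 0)
  expect_equal(soc$costs$weekly_cost_healed, 0)
})

test_that("strategy fixtures carry the published costs and effects", {
  strat <- camp_strategies()
  expect_named(strat, c("SoC", "vCPM", "HAMA", "dHACM", "hFDS", "BLCC", "HSAM"))
  expect_equal(strat$vCPM$effect$rr_healing, 2.91)
  expect_equal(strat$HAMA$effect$rr_healing, 2.62)
  # shared class effects on infection and amputation
  for (lab in setdiff(names(strat), "SoC")) {
    expect_equal(strat[[lab]]$effect$rr_infection, 0.49)
    expect_equal(strat[[lab]]$effect$rr_amputation, 0.27)
  }
  # the dHACM per-treatment total is the published (internally inconsistent)
  # figure, not cost-per-application x 4
  expect_equal(total_product_cost(strat$dHACM$costs), 3264.45)
  expect_false(isTRUE(all.equal(3264.45, 933 * 4)))
  # trial-reported application counts enter the sensitivity fixture
  trial <- camp_strategies(applications = "trial")
  expect_equal(trial$vCPM$costs$n_applications, 6)
  expect_equal(trial$hFDS$costs$n_applications, 7.1)
  expect_equal(total_product_cost(trial$vCPM$costs), 802.44 * 6)
  # HAMA and HSAM keep the base case
  expect_equal(total_product_cost(trial$HSAM$costs), 11673.40)
})

test_that("constructors reject out-of-range inputs", {
  expect_error(utility_inputs(1.2, 0.8, 0.7, 0.6), "0, 1")
  expect_error(
    treatment_effect("x", rr_healing = 2,
                     ci = list(rr_healing = c(2.5, 3))),
    "bracketing"
  )
  expect_error(cost_inputs(weekly_cost_unhealed = -5), "non-negative")
  expect_error(
    toy_parameter_set(p_heal = 1.5),
    "0, 1"
  )
})

test_that("the placeholder state values are flagged as assumptions", {
  sv <- placeholder_state_values()
  expect_true(sv$assumption_level)
  expect_equal(sv$state_costs_weekly$healed, 0)
  expect_equal(sv$utilities_annual$dead, 0)
  expect_true(all(unlist(sv$utilities_annual) >= 0 &
                    unlist(sv$utilities_annual) <= 1))
})
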