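test_that("the SoC unhealed row matches the published weekly probabilities", {
  M <- build_matrix(camp_strategies()$SoC)
  row <- M["UNHEALED", ]
  expect_equal(round(row[["HEALED"]], 4), 0.0319)
  expect_equal(round(row[["INFECTED"]], 4), 0.0163)
  expect_equal(round(row[["AMPUTATION"]], 4), 0.0057)
  expect_equal(round(row[["DEAD"]], 4), 0.0012)
  expect_equal(round(row[["POST_UNHEALED"]], 4), 0.9449)
  expect_equal(sum(row), 1)
})

test_that("the matrix honours the stated state structure", {
  M <- build_matrix(camp_strategies()$vCPM)
  expect_equal(rowSums(M), setNames(rep(1, 8), health_states()))
  # death is absorbing
  expect_equal(M["DEAD", ], setNames(c(rep(0, 7), 1), health_states()))
  # post-amputation exits only to itself or death
  expect_equal(sum(M["POST_AMPUTATION", c("POST_AMPUTATION", "DEAD")]), 1)
  # healed states exit only to death (background mortality)
  expect_equal(sum(M["HEALED", c("POST_HEALED", "DEAD")]), 1)
  expect_equal(M["HEALED", "DEAD"], 0.0487 / 52, tolerance = 1e-12)
  # amputation is a one-cycle event state
  expect_equal(M["AMPUTATION", "AMPUTATION"], 0)
})

test_that("infection-resolution routing is switchable", {
  base <- camp_strategies()$SoC
  M_unhealed <- build_matrix(base)
  expect_gt(M_unhealed["INFECTED", "UNHEALED"], 0)
  expect_equal(M_unhealed["INFECTED", "HEALED"], 0)
  direct <- camp_strategies(options = model_options(infection_healing_to = "healed"))$SoC
  M_healed <- build_matrix(direct)
  expect_equal(M_healed["INFECTED", "UNHEALED"], 0)
  expect_equal(M_healed["INFECTED", "HEALED"],
               M_unhealed["INFECTED", "UNHEALED"])
})

test_that("infeasible rows error by name unless capping is requested", {
  ps <- toy_parameter_set(p_heal = 0.9, p_infect = 0.9)
  expect_error(build_matrix(ps), "UNHEALED")
  M <- build_matrix(ps, cap_rows = TRUE)
  expect_equal(rowSums(M), setNames(rep(1, 8), health_states()))
  expect_true("UNHEALED" %in% attr(M, "capped_rows"))
})

test_that("a cohort with no exits stays in the unhealed pool", {
  M <- build_matrix(toy_parameter_set())
  trace <- run_cohort(M, 10)
  pool <- rowSums(trace$occupancy[, c("UNHEALED", "POST_UNHEALED")])
  expect_equal(unname(pool), rep(1, 11))
  expect_equal(trace$cum_healed, rep(0, 11))
})

test_that("certain healing empties the cohort into the healed state in one cycle", {
  M <- build_matrix(toy_parameter_set(p_heal = 1))
  trace <- run_cohort(M, 3)
  expect_equal(trace$cum_healed[2], 1)
  expect_equal(unname(trace$occupancy[2, "HEALED"]), 1)
})

test_that("occupancy is conserved and death/healing accumulate monotonically", {
  set.seed(101)
  for (i in 1:200) {
    M <- random_valid_matrix()
    trace <- run_cohort(M, 30)
    expect_true(all(abs(rowSums(trace$occupancy) - 1) < 1e-9))
    expect_true(all(diff(trace$cum_healed) >= -1e-12))
    expect_true(all(diff(trace$occupancy[, "DEAD"]) >= -1e-12))
    expect_true(all(trace$occupancy >= -1e-12 & trace$occupancy <= 1 + 1e-12))
  }
})

test_that("cumulative healing is monotone in the healing risk ratio", {
  strat <- camp_strategies()
  rr_grid <- c(0.5, 1, 1.5, 2, 2.5, 3)
  hw <- vapply(rr_grid, function(rr) {
    ps <- strat$SoC
    ps$effect$rr_healing <- rr
    run_strategy(ps)$healed_wounds
  }, numeric(1))
  expect_true(all(diff(hw) > 0))
})

test_that("the cohort trace equals exhaustive path enumeration at short horizons", {
  for (opts in list(model_options(), model_options(infection_healing_to = "healed"))) {
    ps <- camp_strategies(options = opts)$vCPM
    M <- build_matrix(ps)
    trace <- run_cohort(M, 6)
    oracle <- enumerate_paths(M, 6)
    expect_equal(trace$occupancy, oracle$occupancy, tolerance = 1e-10)
    expect_equal(trace$cum_healed, oracle$cum_healed, tolerance = 1e-10)
  }
})

test_that("accumulation matches the hand-propagated two-cycle toy", {
  ps <- toy_parameter_set(
    p_heal = 0.5, horizon = 2,
    utilities = c(unhealed = 0.5, healed = 1, infected = 0, post_amputation = 0)
  )
  out <- run_strategy(ps)
  # after one cycle utility is 0.5*1 + 0.5*0.5 = 0.75; after two, 0.875
  expect_equal(out$qalys, (0.75 + 0.875) / 52)
})

test_that("degenerate accumulations isolate each cost and utility channel", {
  # all utilities zero -> zero QALYs
  ps <- camp_strategies()$SoC
  ps$utilities <- utility_inputs(0, 0, 0, 0)
  expect_equal(run_strategy(ps)$qalys, 0)
  # all state costs zero, product cost C -> total cost C
  ps2 <- toy_parameter_set(p_heal = 0.1, horizon = 20,
                           costs = list(product_cost_per_application = 250,
                                        n_applications = 4))
  expect_equal(run_strategy(ps2)$total_cost, 1000)
  # amputation event cost is charged once per entry: certain amputation from
  # the whole cohort in cycle 1 charges exactly one event cost
  ps3 <- toy_parameter_set(p_amp_dfu = 1, horizon = 10,
                           costs = list(amputation_event_cost = 35000))
  expect_equal(run_strategy(ps3)$total_cost, 35000)
})

test_that("mismatched horizons are rejected", {
  ps <- camp_strategies()$SoC
  M <- build_matrix(ps)
  trace <- run_cohort(M, 10)
  expect_error(accumulate(trace, ps), "does not match")
})

test_that("the microsimulation agrees with the cohort trace", {
  ps <- camp_strategies()$SoC
  M <- build_matrix(ps)
  det <- run_cohort(M, 52)$cum_healed[53]
  sim <- simulate_patients(M, 52, n_patients = 2e4, seed = 99)
  expect_lt(abs(sim$cum_healed - det), 3 * sim$se)
})

test_that("strategy outcomes satisfy their range invariants", {
  out <- run_strategies(camp_strategies())
  expect_true(all(out$healed_wounds >= 0 & out$healed_wounds <= 1))
  expect_true(all(out$qalys >= 0 & out$qalys <= 52 / 52))
  expect_true(all(out$cost >= 0))
  expect_equal(out$strategy, names(camp_strategies()))
})
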