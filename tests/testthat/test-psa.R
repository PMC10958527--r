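strategies <- camp_strategies()

test_that("distribution resolution matches the closed forms", {
  ln <- resolve_distribution(dist_spec("lognormal", 2.91, 1.61, 5.26))
  expect_equal(ln$params$meanlog, log(2.91))
  expect_equal(ln$params$sdlog, 0.3020, tolerance = 1e-4)
  g <- resolve_distribution(dist_spec("gamma", mean = 100, se = 10))
  expect_equal(g$params$shape, 100)
  expect_equal(g$params$rate, 1)
  b <- resolve_distribution(dist_spec("beta", mean = 0.5, se = 0.05))
  expect_equal(b$params$shape1, b$params$shape2)
  # moment matching reproduces the source mean and SE
  expect_equal(b$params$shape1 / (b$params$shape1 + b$params$shape2), 0.5)
  v <- with(b$params, shape1 * shape2 / ((shape1 + shape2)^2 * (shape1 + shape2 + 1)))
  expect_equal(sqrt(v), 0.05)
})

test_that("invalid distribution inputs are rejected", {
  expect_error(dist_spec("lognormal", 2, ci_lower = 2.5, ci_upper = 3),
               "bracket")
  expect_error(resolve_distribution(dist_spec("beta", mean = 1.5, se = 0.1)),
               "0, 1")
  expect_error(resolve_distribution(dist_spec("beta", mean = 0.5, se = 0.6)),
               "infeasible")
  expect_error(resolve_distribution(dist_spec("gamma", mean = 5)),
               "needs a CI or a standard error")
})

test_that("sampled distributions reproduce their source moments", {
  specs <- default_psa_specs(strategies)
  set.seed(123)
  # beta on the cumulative scale: mean within 2% of the published mean
  tab <- cea_tables()$baseline_transitions
  for (i in seq_len(nrow(tab))) {
    d <- draw_dist(specs$baseline[[tab$parameter[i]]]$spec, 2e4)
    expect_equal(mean(d), tab$mean[i], tolerance = 0.02)
  }
  # gamma costs: mean within 2%
  d <- draw_dist(specs$state_costs$amputation_event_cost, 2e4)
  expect_equal(mean(d), strategies$SoC$costs$amputation_event_cost,
               tolerance = 0.02)
  # lognormal risk ratios are median-centred on the reported ratio
  d <- draw_dist(specs$rr_healing$vCPM, 2e4)
  expect_equal(median(d), 2.91, tolerance = 0.02)
})

test_that("a degenerate one-draw PSA equals the deterministic base case", {
  degenerate <- default_psa_specs(strategies)
  fix <- function(m) resolve_distribution(dist_spec("fixed", m))
  tab <- cea_tables()$baseline_transitions
  for (i in seq_len(nrow(tab))) {
    degenerate$baseline[[tab$parameter[i]]]$spec <- fix(tab$mean[i])
  }
  for (lab in names(degenerate$rr_healing)) {
    degenerate$rr_healing[[lab]] <- fix(strategies[[lab]]$effect$rr_healing)
    degenerate$product_total[[lab]] <- fix(total_product_cost(strategies[[lab]]$costs))
  }
  degenerate$rr_class$rr_infection <- fix(0.49)
  degenerate$rr_class$rr_amputation <- fix(0.27)
  ref <- strategies$SoC
  for (fld in names(degenerate$state_costs)) {
    degenerate$state_costs[[fld]] <- fix(ref$costs[[fld]])
  }
  for (fld in names(degenerate$utilities)) {
    degenerate$utilities[[fld]] <- fix(ref$utilities[[fld]])
  }
  psa <- run_psa(strategies, n_draws = 1, seed = 42, specs = degenerate)
  det <- run_strategies(strategies)
  expect_equal(psa$draws$cost, det$cost)
  expect_equal(psa$draws$qalys, det$qalys)
  expect_equal(psa$draws$healed_wounds, det$healed_wounds)
})

test_that("the PSA is bit-reproducible for a fixed seed and requires one", {
  p1 <- run_psa(strategies, n_draws = 25, seed = 7)
  p2 <- run_psa(strategies, n_draws = 25, seed = 7)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(strategies, n_draws = 25, seed = 8)
  expect_false(identical(p1$draws, p3$draws))
  expect_error(run_psa(strategies, n_draws = 10), "seed")
})

test_that("acceptability probabilities sum to one and count wins correctly", {
  psa <- run_psa(strategies, n_draws = 50, seed = 31)
  cc <- ceac(psa, thresholds = c(0, 5e4, 1e5, 2e5))
  sums <- tapply(cc$probability, cc$threshold, sum)
  expect_equal(as.numeric(sums), rep(1, 4))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # hand-built three-draw result: direct counting oracle
  hand <- structure(list(
    draws = data.frame(
      draw = c(1:3, 1:3),
      strategy = rep(c("A", "B"), each = 3),
      cost = c(100, 100, 100, 50, 150, 100),
      qalys = rep(1, 6),
      healed_wounds = c(0.5, 0.5, 0.5, 0.4, 0.9, 0.5)
    ),
    n_draws = 3L, seed = 1, strategies = c("A", "B"),
    diagnostics = list(n_capped_rows = 0L)
  ), class = "psa_result")
  cc0 <- ceac(hand, thresholds = 0)
  # at threshold 0 the cheaper strategy wins; draw 3 ties and is split
  expect_equal(cc0$probability[cc0$strategy == "A"], (1 + 0.5) / 3)
  expect_equal(cc0$probability[cc0$strategy == "B"], (1 + 0.5) / 3)
  cc1 <- ceac(hand, thresholds = 1000)
  # NMB A: 400 x3; B: 350, 750, 400 -> B wins draw 2, draw 1 A, draw 3 split
  expect_equal(cc1$probability[cc1$strategy == "A"], 1.5 / 3)
})

test_that("a single strategy is certainly cost-effective", {
  solo <- strategies["SoC"]
  psa <- run_psa(solo, n_draws = 10, seed = 5)
  cc <- ceac(psa, thresholds = c(0, 1e5))
  expect_equal(cc$probability, rep(1, 2))
})

test_that("two identical strategies split the wins evenly", {
  a <- strategies$vCPM; a$label <- "twinA"
  b <- strategies$vCPM; b$label <- "twinB"
  psa <- run_psa(list(twinA = a, twinB = b), n_draws = 800, seed = 13)
  cc <- ceac(psa, thresholds = 1e5)
  p <- cc$probability[cc$strategy == "twinA"]
  se <- sqrt(0.25 / 800)
  expect_lt(abs(p - 0.5), 3 * se)
})
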