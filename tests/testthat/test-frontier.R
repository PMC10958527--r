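published <- published_results()

test_that("anchoring subtracts the anchor and labels the quadrants", {
  out <- published$base_case
  anc <- anchor_to_soc(out)
  expect_equal(anc$strategy[1], "SoC")
  expect_equal(unlist(anc[1, c("inc_cost", "inc_healed_wounds", "inc_qalys")]),
               c(inc_cost = 0, inc_healed_wounds = 0, inc_qalys = 0))
  vcpm <- anc[anc$strategy == "vCPM", ]
  expect_equal(vcpm$inc_cost, 10907 - 19862)
  expect_equal(vcpm$inc_healed_wounds, 0.914 - 0.601)
  expect_equal(vcpm$inc_healed_wounds, 0.313)
  expect_equal(vcpm$quadrant, "dominant")
  expect_true(is.na(vcpm$cost_per_healed))  # cost saving: no ratio reported
  hsam <- anc[anc$strategy == "HSAM", ]
  expect_equal(hsam$quadrant, "trade-off")
  expect_equal(hsam$cost_per_healed, (24214 - 19862) / (0.829 - 0.601))
  expect_equal(hsam$cost_per_healed, 19077, tolerance = 1e-3)
})

test_that("anchoring a single-strategy list yields one zero row", {
  anc <- anchor_to_soc(published$base_case[published$base_case$strategy == "SoC", ])
  expect_equal(nrow(anc), 1L)
  expect_equal(anc$inc_cost, 0)
  expect_error(anchor_to_soc(published$base_case, anchor = "nope"),
               "not among")
})

test_that("anchored increments are invariant to constant cost shifts", {
  out <- published$base_case
  shifted <- out
  shifted$cost <- shifted$cost + 1234.5
  a1 <- anchor_to_soc(out)
  a2 <- anchor_to_soc(shifted)
  expect_equal(a1$inc_cost, a2$inc_cost)
  expect_equal(a1$inc_healed_wounds, a2$inc_healed_wounds)
})

test_that("two- and three-point frontiers follow the dominance rules", {
  two <- data.frame(strategy = c("A", "B"), cost = c(0, 10),
                    healed_wounds = c(0, 1))
  f2 <- build_frontier(two)
  expect_equal(f2$icer[f2$strategy == "B"], 10)
  expect_equal(f2$dominance, c("none", "none"))
  # B's ICER (20) exceeds the A->C slope (12): extended dominance
  three <- data.frame(strategy = c("A", "B", "C"), cost = c(0, 10, 12),
                      healed_wounds = c(0, 0.5, 1))
  f3 <- build_frontier(three)
  expect_equal(f3$dominance[f3$strategy == "B"], "extended")
  expect_equal(f3$icer[f3$strategy == "C"], 12)
  # simple dominance: costlier and no more effective
  four <- rbind(three, data.frame(strategy = "D", cost = 15, healed_wounds = 0.9))
  f4 <- build_frontier(four)
  expect_equal(f4$dominance[f4$strategy == "D"], "simple")
  expect_error(build_frontier(rbind(two, two)), "duplicate")
})

test_that("random strategy clouds match the convex-hull oracle", {
  for (seed in 1:200) {
    n <- 2 + (seed %% 7)
    cloud <- generate_strategy_cloud(n, seed = seed)
    expect_frontier_matches_oracle(cloud)
  }
})

test_that("collinear strategies are extended-dominated in the interior", {
  cloud <- data.frame(strategy = c("A", "B", "C", "D"),
                      cost = c(0, 100, 200, 300),
                      healed_wounds = c(0, 0.1, 0.2, 0.3))
  front <- build_frontier(cloud)
  expect_equal(front$dominance, c("none", "extended", "extended", "none"))
  expect_equal(front$icer[4], 1000)
})

test_that("adding a strictly dominated strategy never changes surviving ICERs", {
  set.seed(11)
  for (i in 1:25) {
    cloud <- generate_strategy_cloud(5, seed = 1000 + i)
    front <- build_frontier(cloud)
    surv <- front[front$dominance == "none", ]
    worst <- data.frame(strategy = "dom", cost = max(cloud$cost) + 1,
                        healed_wounds = min(cloud$healed_wounds))
    front2 <- build_frontier(rbind(cloud, worst))
    expect_equal(front2$dominance[front2$strategy == "dom"], "simple")
    surv2 <- front2[front2$dominance == "none", ]
    expect_equal(surv2$strategy, surv$strategy)
    expect_equal(surv2$icer, surv$icer)
  }
})

test_that("net monetary benefit is the standard linear form", {
  expect_equal(net_monetary_benefit(100, 2, 100), 100)
  expect_equal(net_monetary_benefit(0, 0, 5e4), 0)
  expect_error(net_monetary_benefit(1, 1, -1), ">= 0")
})

test_that("vCPM maximizes published net monetary benefit at $100,000 per healed wound", {
  out <- published$base_case
  nmb <- net_monetary_benefit(out$cost, out$healed_wounds, 1e5)
  expect_equal(out$strategy[which.max(nmb)], "vCPM")
})

test_that("the NMB maximizer always lies on the dominance frontier", {
  set.seed(23)
  for (i in 1:25) {
    cloud <- generate_strategy_cloud(6, seed = 2000 + i)
    front <- build_frontier(cloud)
    surv <- front$strategy[front$dominance == "none"]
    for (th in c(0, runif(3, 0, 3e5))) {
      nmb <- net_monetary_benefit(cloud$cost, cloud$healed_wounds, th)
      best <- cloud$strategy[nmb == max(nmb)]
      expect_true(any(best %in% surv))
    }
  }
})
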