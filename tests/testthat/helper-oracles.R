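# Independent oracles and small constructors shared across the test files.
# Every oracle here is written without reference to the implementation it
# checks: path enumeration for the cohort trace, gift-wrapping on the lower
# convex hull for the dominance frontier, and a term-by-term transcription
# of the DerSimonian-Laird estimator.

# Exhaustive path enumeration over the non-zero transitions of a matrix:
# returns per-cycle occupancy and cumulative first-passage probability into
# `target`, by summing probability over every state sequence.
enumerate_paths <- function(M, horizon, start = "UNHEALED", target = "HEALED") {
  states <- rownames(M)
  occ <- matrix(0, horizon + 1L, length(states), dimnames = list(0:horizon, states))
  fp <- numeric(horizon + 1L)  # first-passage mass arriving exactly at cycle t
  recurse <- function(state, prob, t, healed, arrived_now) {
    occ[t + 1L, state] <<- occ[t + 1L, state] + prob
    if (arrived_now) fp[t + 1L] <<- fp[t + 1L] + prob
    if (t == horizon) return(invisible())
    for (nxt in states[M[state, ] > 0]) {
      first <- !healed && nxt == target
      recurse(nxt, prob * M[state, nxt], t + 1L, healed || first, first)
    }
  }
  recurse(start, 1, 0L, FALSE, FALSE)
  list(occupancy = occ, cum_healed = cumsum(fp))
}

# Gift-wrapping construction of the efficiency frontier: start from the
# cheapest strategy (ties: most effective), then repeatedly move to the
# point minimizing the cost/effect slope among strictly more effective ones.
hull_frontier <- function(cost, effect, labels) {
  stopifnot(length(cost) == length(effect))
  cur <- which(cost == min(cost))
  if (length(cur) > 1L) cur <- cur[which.max(effect[cur])]
  path <- cur
  repeat {
    cand <- which(effect > effect[cur] + 1e-15)
    if (!length(cand)) break
    slopes <- (cost[cand] - cost[cur]) / (effect[cand] - effect[cur])
    best <- cand[slopes == min(slopes)]
    if (length(best) > 1L) best <- best[which.max(effect[best])]
    path <- c(path, best)
    cur <- best
  }
  labels[path]
}

# Term-by-term DerSimonian-Laird transcription on (yi, vi) pairs.
dl_by_hand <- function(yi, vi) {
  k <- length(yi)
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - mu_fe)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (vi + tau2)
  mu <- sum(ws * yi) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(mu = mu, se = se, tau2 = tau2, Q = Q,
       rr = exp(mu),
       ci = exp(mu + c(-1, 1) * qnorm(0.975) * se))
}

# A minimal valid parameter set for engine tests: every probability settable,
# placeholder-free costs/utilities.
toy_parameter_set <- function(p_heal = 0, p_heal_pi = 0, p_infect = 0,
                              p_amp_dfu = 0, p_amp_inf = 0, p_die_dfu = 0,
                              p_die_amp = 0, p_die_inf = 0, p_bg = 0,
                              rr = c(1, 1, 1), horizon = 52,
                              utilities = c(unhealed = 0, healed = 0,
                                            infected = 0, post_amputation = 0),
                              costs = list(), options = model_options()) {
  cost_args <- utils::modifyList(
    list(product_cost_per_application = 0, n_applications = 0,
         weekly_cost_unhealed = 0, weekly_cost_infected = 0,
         weekly_cost_healed = 0, amputation_event_cost = 0,
         weekly_cost_post_amputation = 0),
    costs
  )
  parameter_set(
    "toy",
    baseline_transitions(
      p_heal_soc = p_heal, p_heal_post_infection = p_heal_pi,
      p_infect = p_infect, p_amputate_from_dfu = p_amp_dfu,
      p_amputate_from_infection = p_amp_inf, p_die_dfu = p_die_dfu,
      p_die_post_amputation = p_die_amp, p_die_infection = p_die_inf,
      p_die_background = p_bg
    ),
    treatment_effect("toy", rr[1], rr[2], rr[3]),
    do.call(cost_inputs, cost_args),
    utility_inputs(utilities[["unhealed"]], utilities[["healed"]],
                   utilities[["infected"]], utilities[["post_amputation"]]),
    horizon_weeks = horizon,
    options = options
  )
}

# Random feasible 8-state matrix for conservation stress tests.
random_valid_matrix <- function() {
  ps <- toy_parameter_set(
    p_heal = runif(1, 0, 0.2), p_heal_pi = runif(1, 0, 0.2),
    p_infect = runif(1, 0, 0.2), p_amp_dfu = runif(1, 0, 0.1),
    p_amp_inf = runif(1, 0, 0.1), p_die_dfu = runif(1, 0, 0.05),
    p_die_amp = runif(1, 0, 0.05), p_die_inf = runif(1, 0, 0.05),
    p_bg = runif(1, 0, 0.01),
    rr = c(runif(1, 0.2, 3), runif(1, 0.2, 2), runif(1, 0.2, 2))
  )
  build_matrix(ps, cap_rows = TRUE)
}

expect_frontier_matches_oracle <- function(cloud) {
  front <- build_frontier(cloud, "healed_wounds")
  surv <- front$strategy[front$dominance == "none"]
  oracle <- hull_frontier(cloud$cost, cloud$healed_wounds, cloud$strategy)
  expect_setequal(surv, oracle)
  icers <- front$icer[!is.na(front$icer)]
  if (length(icers) > 1L) expect_true(all(diff(icers) > 0))
}
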