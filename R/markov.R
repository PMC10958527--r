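#' Health states of the cohort model
#'
#' The eight states of the weekly cycle model. `UNHEALED` and `HEALED` are
#' one-cycle entry states whose occupants move to their persistent post
#' states (`POST_UNHEALED`, `POST_HEALED`) after one cycle, carrying the same
#' costs, utilities and exit probabilities; `AMPUTATION` is likewise the
#' one-cycle surgical event preceding `POST_AMPUTATION`. `DEAD` is absorbing.
#'
#' @return character vector of the eight state names, in matrix order.
#' @export
health_states <- function() {
  c("UNHEALED", "POST_UNHEALED", "HEALED", "POST_HEALED",
    "INFECTED", "AMPUTATION", "POST_AMPUTATION", "DEAD")
}

healed_states <- c("HEALED", "POST_HEALED")

#' Build the weekly transition matrix for a strategy
#'
#' Assembles the 8x8 weekly transition matrix from a [parameter_set()]:
#' treatment risk ratios are applied multiplicatively to the baseline weekly
#' healing, infection and amputation probabilities for as long as the cohort
#' occupies the unhealed states; mortality is strategy-independent. Infected
#' ulcers resolve back to the unhealed state (or directly to healed, per
#' [model_options()]), amputation is a one-cycle event state, and the healed
#' and post-amputation states exit only to death.
#'
#' @param params a [parameter_set()].
#' @param cap_rows if `TRUE`, a row whose competing exit probabilities sum
#'   above 1 is rescaled to feasibility instead of raising an error, and the
#'   affected rows are recorded in the `"capped_rows"` attribute (used by the
#'   probabilistic analysis where extreme joint draws can momentarily exceed
#'   feasibility). Default `FALSE`: such a row is an error naming the state.
#' @return an 8x8 `transition_matrix` with rows summing to 1.
#' @export
build_matrix <- function(params, cap_rows = FALSE) {
  stopifnot(inherits(params, "parameter_set"))
  b <- params$baseline
  eff <- params$effect
  opt <- params$options

  p_heal <- unname(apply_risk_ratio(b$p_heal_soc, eff$rr_healing))
  p_inf <- unname(apply_risk_ratio(b$p_infect, eff$rr_infection))
  p_amp <- unname(apply_risk_ratio(b$p_amputate_from_dfu, eff$rr_amputation))
  bg <- b$p_die_background
  add_bg <- if (opt$add_background_mortality) bg else 0
  p_die_unh <- min(b$p_die_dfu + add_bg, 1)
  p_die_inf <- min(b$p_die_infection + add_bg, 1)
  p_die_amp <- min(b$p_die_post_amputation + add_bg, 1)

  s <- health_states()
  M <- matrix(0, 8, 8, dimnames = list(s, s))
  capped <- character(0)
  fill_row <- function(row, exits, stay_state) {
    tot <- sum(exits)
    if (tot > 1) {
      if (!cap_rows) {
        stop_invalid(
          "competing exit probabilities from state `%s` sum to %.4f > 1", row, tot
        )
      }
      exits <- exits / tot
      tot <- 1
      capped <<- c(capped, row)
    }
    M[row, names(exits)] <<- exits
    M[row, stay_state] <<- M[row, stay_state] + (1 - tot)
  }

  heal_target <- if (opt$infection_healing_to == "unhealed") "UNHEALED" else "HEALED"
  for (row in c("UNHEALED", "POST_UNHEALED")) {
    fill_row(row,
             c(HEALED = p_heal, INFECTED = p_inf, AMPUTATION = p_amp,
               DEAD = p_die_unh),
             "POST_UNHEALED")
  }
  for (row in healed_states) {
    fill_row(row, c(DEAD = bg), "POST_HEALED")
  }
  exits_inf <- stats::setNames(
    c(b$p_heal_post_infection, b$p_amputate_from_infection, p_die_inf),
    c(heal_target, "AMPUTATION", "DEAD")
  )
  fill_row("INFECTED", exits_inf, "INFECTED")
  for (row in c("AMPUTATION", "POST_AMPUTATION")) {
    fill_row(row, c(DEAD = p_die_amp), "POST_AMPUTATION")
  }
  M["DEAD", "DEAD"] <- 1

  structure(M, class = c("transition_matrix", class(M)), capped_rows = capped)
}

#' Validate a transition matrix
#'
#' @param M a square matrix of weekly transition probabilities.
#' @param tol row-sum tolerance.
#' @return `M`, invisibly; errors describe the violated property.
#' @export
validate_transition_matrix <- function(M, tol = 1e-12) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop_invalid("matrix must be square")
  if (any(M < 0) || any(M > 1)) stop_invalid("entries must lie in [0, 1]")
  bad <- which(abs(rowSums(M) - 1) > tol)
  if (length(bad)) {
    stop_invalid("row(s) %s do not sum to 1", paste(rownames(M)[bad] %||% bad, collapse = ", "))
  }
  invisible(M)
}

#' Propagate the cohort over the horizon
#'
#' Starts the whole cohort in the unhealed state and applies the transition
#' matrix for `horizon_weeks` weekly cycles, tracking state occupancy and the
#' cumulative first-passage incidence of wound closure (inflow into the
#' healed state from non-healed states; once healed, a wound cannot reopen,
#' so this is the probability of having ever healed).
#'
#' @param M a `transition_matrix` from [build_matrix()].
#' @param horizon_weeks number of weekly cycles (>= 1).
#' @return a `cohort_trace`: list with `occupancy` (rows = cycles `0:horizon`,
#'   columns = states) and `cum_healed` (length `horizon + 1`).
#' @export
run_cohort <- function(M, horizon_weeks) {
  validate_transition_matrix(M)
  if (!is.numeric(horizon_weeks) || horizon_weeks < 1) {
    stop_invalid("`horizon_weeks` must be >= 1")
  }
  H <- as.integer(horizon_weeks)
  s <- health_states()
  non_healed <- setdiff(s, healed_states)
  occ <- matrix(0, H + 1L, 8L, dimnames = list(0:H, s))
  occ[1L, "UNHEALED"] <- 1
  cum <- numeric(H + 1L)
  x <- occ[1L, ]
  heal_col <- M[non_healed, "HEALED"]
  for (t in seq_len(H)) {
    cum[t + 1L] <- cum[t] + sum(x[non_healed] * heal_col)
    x <- drop(x %*% M)
    occ[t + 1L, ] <- x
  }
  structure(list(occupancy = occ, cum_healed = cum, horizon_weeks = H),
            class = "cohort_trace")
}

#' Accumulate costs, QALYs and healed wounds over a cohort trace
#'
#' Costs and utilities accrue on the occupancy reached after each weekly
#' transition (no half-cycle correction, matching the linear rate
#' conversions); the per-treatment product cost is charged upfront; the
#' amputation event cost is charged once on each cycle's inflow into the
#' amputation state. QALYs are weekly utility-weighted occupancy divided
#' by 52. Nothing is discounted at any horizon.
#'
#' @param trace a [run_cohort()] trace.
#' @param params the [parameter_set()] the trace was generated from (horizons
#'   must agree).
#' @param M the transition matrix used (needed to price amputation inflow);
#'   rebuilt from `params` when omitted.
#' @return a `strategy_outcome`: list with `strategy`, `total_cost`, `qalys`,
#'   `healed_wounds`, `horizon_weeks`.
#' @export
accumulate <- function(trace, params, M = NULL) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(params, "parameter_set"))
  if (trace$horizon_weeks != params$horizon_weeks) {
    stop_invalid("trace horizon (%d) does not match parameter horizon (%d)",
                 trace$horizon_weeks, params$horizon_weeks)
  }
  if (is.null(M)) M <- build_matrix(params)
  cs <- params$costs
  ut <- params$utilities
  s <- health_states()
  cost_vec <- c(cs$weekly_cost_unhealed, cs$weekly_cost_unhealed,
                cs$weekly_cost_healed, cs$weekly_cost_healed,
                cs$weekly_cost_infected, cs$weekly_cost_post_amputation,
                cs$weekly_cost_post_amputation, 0)
  util_vec <- c(ut$unhealed, ut$unhealed, ut$healed, ut$healed,
                ut$infected, ut$post_amputation, ut$post_amputation, 0)
  H <- trace$horizon_weeks
  occ_after <- trace$occupancy[1L + seq_len(H), , drop = FALSE]  # post-transition rows 1..H
  running_cost <- sum(occ_after %*% cost_vec)
  qalys <- sum(occ_after %*% util_vec) / 52
  occ_before <- trace$occupancy[seq_len(H), , drop = FALSE]
  amp_sources <- setdiff(s, "AMPUTATION")
  amp_inflow <- sum(occ_before[, amp_sources, drop = FALSE] %*% M[amp_sources, "AMPUTATION"])
  total_cost <- total_product_cost(cs) + running_cost +
    amp_inflow * cs$amputation_event_cost
  structure(
    list(strategy = params$label, total_cost = total_cost, qalys = qalys,
         healed_wounds = trace$cum_healed[H + 1L], horizon_weeks = H),
    class = "strategy_outcome"
  )
}

#' Run one strategy end to end
#'
#' @param params a [parameter_set()].
#' @return a `strategy_outcome` (see [accumulate()]).
#' @export
run_strategy <- function(params) {
  M <- build_matrix(params)
  trace <- run_cohort(M, params$horizon_weeks)
  accumulate(trace, params, M)
}

#' Run a set of strategies and tabulate per-patient results
#'
#' @param strategies a named list of [parameter_set()] objects, e.g. from
#'   [camp_strategies()].
#' @return a data.frame with one row per strategy: `strategy`, `cost`,
#'   `qalys`, `healed_wounds`, `horizon_weeks` (the published results-table
#'   layout).
#' @export
run_strategies <- function(strategies) {
  if (!length(strategies)) stop_invalid("`strategies` must be non-empty")
  rows <- lapply(strategies, function(ps) {
    out <- run_strategy(ps)
    data.frame(strategy = out$strategy, cost = out$total_cost,
               qalys = out$qalys, healed_wounds = out$healed_wounds,
               horizon_weeks = out$horizon_weeks)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Individual-level microsimulation of the cohort model
#'
#' Simulates `n_patients` independent weekly trajectories through the
#' transition matrix, as a stochastic cross-check of the deterministic cohort
#' trace. Used for engine validation; the cohort trace is the analysis
#' vehicle.
#'
#' @param M a `transition_matrix`.
#' @param horizon_weeks number of weekly cycles.
#' @param n_patients number of simulated patients.
#' @param seed RNG seed (mandatory).
#' @return list with `cum_healed` (proportion ever healed by the horizon),
#'   `se` (its binomial standard error) and `final_occupancy` (proportion per
#'   state at the horizon).
#' @export
simulate_patients <- function(M, horizon_weeks, n_patients = 1e5, seed) {
  validate_transition_matrix(M)
  s <- health_states()
  healed_idx <- match(healed_states, s)
  with_seed(seed, {
    state <- rep.int(1L, n_patients)  # all start unhealed
    ever_healed <- logical(n_patients)
    cum_M <- t(apply(M, 1L, cumsum))
    for (t in seq_len(horizon_weeks)) {
      u <- stats::runif(n_patients)
      new_state <- integer(n_patients)
      for (from in unique(state)) {
        idx <- which(state == from)
        new_state[idx] <- findInterval(u[idx], cum_M[from, ], left.open = TRUE) + 1L
      }
      ever_healed <- ever_healed | (new_state %in% healed_idx)
      state <- new_state
    }
    p <- mean(ever_healed)
    list(
      cum_healed = p,
      se = sqrt(p * (1 - p) / n_patients),
      final_occupancy = stats::setNames(tabulate(state, 8L) / n_patients, s)
    )
  })
}
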