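# Seeded generators for every input the pipeline needs: synthetic two-arm
# trials for the meta-analysis stage, random valid parameter sets, and
# random strategy clouds for frontier stress tests. All generators are pure
# functions of their configuration and seed.

#' Configuration for the synthetic trial generator
#'
#' Defaults mirror the scale of the evidence base behind the pooled
#' treatment effects: a handful of trials with 50-150 patients per arm and a
#' control infection risk of about 0.20.
#'
#' @param n_studies number of studies (>= 1).
#' @param n_range per-arm sample-size range `c(min, max)`.
#' @param control_risk control-arm event risk in (0, 1).
#' @param true_rr true risk ratio (> 0).
#' @param tau between-study standard deviation of the log risk ratio (>= 0).
#' @param seed RNG seed (mandatory).
#' @return a `trial_generator_config` list.
#' @export
trial_generator_config <- function(n_studies = 5, n_range = c(50, 150),
                                   control_risk = 0.20, true_rr = 0.49,
                                   tau = 0.2, seed) {
  if (missing(seed)) stop_invalid("`seed` is mandatory")
  if (n_studies < 1) stop_invalid("`n_studies` must be >= 1")
  if (control_risk <= 0 || control_risk >= 1) {
    stop_invalid("`control_risk` must lie in (0, 1)")
  }
  if (true_rr <= 0) stop_invalid("`true_rr` must be positive")
  if (tau < 0) stop_invalid("`tau` must be >= 0")
  structure(
    list(n_studies = as.integer(n_studies), n_range = n_range,
         control_risk = control_risk, true_rr = true_rr, tau = tau,
         seed = seed),
    class = "trial_generator_config"
  )
}

#' Generate synthetic two-arm trials
#'
#' Per study, a study-level log risk ratio is drawn from
#' `Normal(log(true_rr), tau)`, the treatment-arm risk is
#' `control_risk * exp(log RR)` truncated at 0.99 (truncations are flagged in
#' the `"truncated"` attribute), and binomial event counts are drawn in each
#' arm.
#'
#' @param config a [trial_generator_config()].
#' @return a [two_arm_studies()] table with attribute `"truncated"` (logical
#'   per study).
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "trial_generator_config"))
  with_seed(config$seed, {
    k <- config$n_studies
    sizes <- config$n_range[1]:config$n_range[2]
    # index into the size grid: sample(x) on a length-1 x would expand to 1:x
    n_t <- sizes[sample.int(length(sizes), k, replace = TRUE)]
    n_c <- sizes[sample.int(length(sizes), k, replace = TRUE)]
    lrr <- stats::rnorm(k, log(config$true_rr), config$tau)
    risk_t <- config$control_risk * exp(lrr)
    truncated <- risk_t > 0.99
    risk_t <- pmin(risk_t, 0.99)
    studies <- two_arm_studies(
      label = sprintf("synthetic_%02d", seq_len(k)),
      events_t = stats::rbinom(k, n_t, risk_t),
      n_t = n_t,
      events_c = stats::rbinom(k, n_c, config$control_risk),
      n_c = n_c
    )
    attr(studies, "truncated") <- truncated
    studies
  })
}

#' Generate a random valid parameter set
#'
#' Draws every transition probability, cost, utility and risk ratio from its
#' default PSA distribution around the published fixture means and assembles
#' a valid [parameter_set()]; draws violating row feasibility are rejected
#' and resampled (capped at 1000 attempts).
#'
#' @param seed RNG seed (mandatory).
#' @param strategy which strategy's fixture to draw around (default
#'   `"vCPM"`; use `"SoC"` for a no-treatment set).
#' @param horizon_weeks analysis horizon.
#' @return a [parameter_set()].
#' @export
generate_random_parameter_set <- function(seed, strategy = "vCPM",
                                          horizon_weeks = 52) {
  strategies <- camp_strategies(horizon_weeks = horizon_weeks)
  if (!strategy %in% names(strategies)) {
    stop_invalid("unknown strategy `%s`", strategy)
  }
  specs <- default_psa_specs(strategies)
  base <- strategies[[strategy]]
  conversion <- base$options$conversion
  with_seed(seed, {
    for (attempt in seq_len(1000L)) {
      weekly <- vapply(specs$baseline, function(b) {
        period_to_weekly(draw_dist(b$spec, 1L), b$period_weeks, conversion)
      }, numeric(1))
      ps <- base
      ps$baseline <- do.call(baseline_transitions, as.list(weekly[baseline_fields]))
      if (strategy != "SoC") {
        ps$effect$rr_healing <- draw_dist(specs$rr_healing[[strategy]], 1L)
        ps$effect$rr_infection <- draw_dist(specs$rr_class$rr_infection, 1L)
        ps$effect$rr_amputation <- draw_dist(specs$rr_class$rr_amputation, 1L)
        ps$costs$product_cost_total <- draw_dist(specs$product_total[[strategy]], 1L)
      }
      for (fld in names(specs$state_costs)) {
        ps$costs[[fld]] <- draw_dist(specs$state_costs[[fld]], 1L)
      }
      for (fld in names(specs$utilities)) {
        ps$utilities[[fld]] <- min(draw_dist(specs$utilities[[fld]], 1L), 1)
      }
      ok <- tryCatch({ build_matrix(ps); TRUE }, error = function(e) FALSE)
      if (ok) return(ps)
    }
    stop_invalid("no feasible parameter set after 1000 attempts")
  })
}

#' Generate a random strategy cloud
#'
#' Random (cost, effect) pairs spanning dominated, extended-dominated and
#' frontier geometries, as stress input for the dominance frontier.
#'
#' @param n_strategies number of strategies (>= 2).
#' @param seed RNG seed (mandatory).
#' @param cost_range,effect_range uniform sampling ranges.
#' @return data.frame with `strategy`, `cost`, `healed_wounds`.
#' @export
generate_strategy_cloud <- function(n_strategies, seed,
                                    cost_range = c(0, 25000),
                                    effect_range = c(0, 1)) {
  if (n_strategies < 2) stop_invalid("`n_strategies` must be >= 2")
  with_seed(seed, {
    data.frame(
      strategy = sprintf("S%02d", seq_len(n_strategies)),
      cost = stats::runif(n_strategies, cost_range[1], cost_range[2]),
      healed_wounds = stats::runif(n_strategies, effect_range[1], effect_range[2])
    )
  })
}
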