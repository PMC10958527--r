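# One-way (tornado) sensitivity analysis and horizon scenario analysis.

#' One-way sensitivity specification
#'
#' @param path dotted path to a scalar model input, e.g.
#'   `"baseline.p_heal_soc"`, `"effect.rr_healing"`,
#'   `"costs.product_cost_per_application"`, `"utilities.unhealed"`.
#' @param low,high values at the ends of the range. Published 95% CIs where
#'   available; otherwise base x 0.8 and x 1.2.
#' @param scope strategy labels the change applies to (`NULL` = every
#'   strategy; effect paths should normally be scoped to the CAMPs).
#' @param label display label (defaults to the path).
#' @return an `owsa_spec` list.
#' @export
owsa_spec <- function(path, low, high, scope = NULL, label = path) {
  if (low > high) stop_invalid("`low` must be <= `high` for `%s`", path)
  structure(list(path = path, low = low, high = high, scope = scope,
                 label = label),
            class = "owsa_spec")
}

set_parameter <- function(ps, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("baseline", "effect", "costs", "utilities")) {
    stop_invalid("cannot resolve parameter path `%s`", path)
  }
  block <- ps[[parts[1]]]
  if (!parts[2] %in% names(block)) {
    stop_invalid("cannot resolve parameter path `%s`: no field `%s`", path, parts[2])
  }
  block[[parts[2]]] <- value
  ps[[parts[1]]] <- block
  ps
}

apply_spec <- function(strategies, spec, value) {
  targets <- spec$scope %||% names(strategies)
  unknown <- setdiff(targets, names(strategies))
  if (length(unknown)) {
    stop_invalid("OWSA scope names unknown strategies: %s",
                 paste(unknown, collapse = ", "))
  }
  for (lab in targets) {
    strategies[[lab]] <- set_parameter(strategies[[lab]], spec$path, value)
  }
  strategies
}

owsa_output <- function(outcomes, output, strategy, comparator, threshold,
                        effect_measure) {
  get <- function(lab, col) outcomes[outcomes$strategy == lab, col]
  eff_col <- effect_measure
  switch(output,
    nmb = net_monetary_benefit(get(strategy, "cost"), get(strategy, eff_col), threshold),
    inmb = net_monetary_benefit(get(strategy, "cost"), get(strategy, eff_col), threshold) -
      net_monetary_benefit(get(comparator, "cost"), get(comparator, eff_col), threshold),
    icer = (get(strategy, "cost") - get(comparator, "cost")) /
      (get(strategy, eff_col) - get(comparator, eff_col)),
    inc_cost = get(strategy, "cost") - get(comparator, "cost")
  )
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full pipeline twice per specification (parameter at its low
#' and at its high value, everything else at base) and records the selected
#' output for a focal strategy. The default output is net monetary benefit at
#' $100,000 per healed wound: ICER-based tornadoes are unstable when the
#' increments cross zero, so the ICER is optional.
#'
#' @param strategies named list of [parameter_set()] objects.
#' @param specs list of [owsa_spec()] objects.
#' @param output `"nmb"` (default), `"inmb"` (incremental NMB vs
#'   `comparator`), `"icer"` or `"inc_cost"`.
#' @param strategy focal strategy (default `"vCPM"`).
#' @param comparator comparator for incremental outputs (default `"SoC"`).
#' @param threshold willingness to pay for NMB outputs (default 100000).
#' @param effect_measure `"healed_wounds"` (default) or `"qalys"`.
#' @return an `owsa_result` data.frame sorted by descending swing: `label`,
#'   `path`, `low`, `high`, `outcome_low`, `outcome_high`, `outcome_base`,
#'   `swing = |outcome_high - outcome_low|`.
#' @export
run_owsa <- function(strategies, specs, output = c("nmb", "inmb", "icer", "inc_cost"),
                     strategy = "vCPM", comparator = "SoC", threshold = 1e5,
                     effect_measure = c("healed_wounds", "qalys")) {
  output <- match.arg(output)
  effect_measure <- match.arg(effect_measure)
  if (inherits(specs, "owsa_spec")) specs <- list(specs)
  base_out <- owsa_output(run_strategies(strategies), output, strategy,
                          comparator, threshold, effect_measure)
  rows <- lapply(specs, function(spec) {
    at <- function(value) {
      owsa_output(run_strategies(apply_spec(strategies, spec, value)), output,
                  strategy, comparator, threshold, effect_measure)
    }
    lo <- at(spec$low)
    hi <- at(spec$high)
    data.frame(label = spec$label, path = spec$path, low = spec$low,
               high = spec$high, outcome_low = lo, outcome_high = hi,
               outcome_base = base_out, swing = abs(hi - lo))
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$swing), ]
  rownames(res) <- NULL
  class(res) <- c("owsa_result", "data.frame")
  res
}

#' Default one-way specifications for the base-case model
#'
#' Builds the published sensitivity ranges: baseline transition probabilities
#' over their 95% CIs (on the cumulative scale, converted weekly), risk
#' ratios over their 95% CIs (healing per CAMP, the class effects across all
#' CAMPs), and costs/utilities over +/- 20% (utilities capped at 1), the
#' convention for inputs without published variation.
#'
#' @param strategies named list of [parameter_set()] objects (the scope
#'   labels and base values are read from it).
#' @return list of [owsa_spec()] objects.
#' @export
default_owsa_specs <- function(strategies = camp_strategies()) {
  tab <- cea_tables()
  bl <- tab$baseline_transitions
  conversion <- strategies[[1]]$options$conversion
  camps <- setdiff(names(strategies), "SoC")
  specs <- list()
  for (i in seq_len(nrow(bl))) {
    row <- bl[i, ]
    if (is.na(row$ci_lower)) {
      base <- period_to_weekly(row$mean, row$period_weeks, conversion)
      lo <- 0.8 * base; hi <- 1.2 * base
    } else {
      lo <- period_to_weekly(row$ci_lower, row$period_weeks, conversion)
      hi <- period_to_weekly(row$ci_upper, row$period_weeks, conversion)
    }
    specs[[length(specs) + 1L]] <- owsa_spec(
      paste0("baseline.", row$parameter), lo, hi,
      label = row$parameter
    )
  }
  for (lab in camps) {
    ci <- strategies[[lab]]$effect$ci$rr_healing
    specs[[length(specs) + 1L]] <- owsa_spec(
      "effect.rr_healing", ci[1], ci[2], scope = lab,
      label = paste0("rr_healing (", lab, ")")
    )
    base_app <- strategies[[lab]]$costs$product_cost_per_application
    specs[[length(specs) + 1L]] <- owsa_spec(
      "costs.product_cost_per_application", 0.8 * base_app, 1.2 * base_app,
      scope = lab, label = paste0("product cost (", lab, ")")
    )
  }
  ce <- tab$class_effects
  specs[[length(specs) + 1L]] <- owsa_spec(
    "effect.rr_infection", ce$rr_infection$ci_lower, ce$rr_infection$ci_upper,
    scope = camps, label = "rr_infection (class)"
  )
  specs[[length(specs) + 1L]] <- owsa_spec(
    "effect.rr_amputation", ce$rr_amputation$ci_lower, ce$rr_amputation$ci_upper,
    scope = camps, label = "rr_amputation (class)"
  )
  ref <- strategies[[1]]
  for (fld in c("weekly_cost_unhealed", "weekly_cost_infected",
                "amputation_event_cost", "weekly_cost_post_amputation")) {
    base <- ref$costs[[fld]]
    specs[[length(specs) + 1L]] <- owsa_spec(
      paste0("costs.", fld), 0.8 * base, 1.2 * base, label = fld
    )
  }
  for (fld in c("unhealed", "healed", "infected", "post_amputation")) {
    base <- ref$utilities[[fld]]
    specs[[length(specs) + 1L]] <- owsa_spec(
      paste0("utilities.", fld), 0.8 * base, min(1, 1.2 * base),
      label = paste0("utility (", fld, ")")
    )
  }
  specs
}

#' Horizon scenario analysis
#'
#' Re-runs the full pipeline at a different horizon (the published scenarios
#' use 12 and 26 weeks against the 52-week base case) and ranks the
#' strategies on the dominance frontier. Product costs are still charged
#' upfront, so shorter horizons shift results against the costlier products.
#'
#' @param strategies named list of [parameter_set()] objects.
#' @param horizon_weeks scenario horizon (>= 1).
#' @param effect_measure `"healed_wounds"` (default) or `"qalys"`.
#' @return a `frontier_result` (see [build_frontier()]); the per-strategy
#'   outcome table is attached as `attr(, "outcomes")`.
#' @export
run_scenario <- function(strategies, horizon_weeks,
                         effect_measure = c("healed_wounds", "qalys")) {
  effect_measure <- match.arg(effect_measure)
  strategies <- lapply(strategies, function(ps) {
    ps$horizon_weeks <- as.integer(horizon_weeks)
    ps
  })
  outcomes <- run_strategies(strategies)
  front <- build_frontier(outcomes, effect_measure)
  attr(front, "outcomes") <- outcomes
  front
}
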