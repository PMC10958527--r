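#' Convert a cumulative probability to a weekly transition probability
#'
#' The published weekly transition probabilities are obtained from
#' source-period (12-week trial or 52-week annual) cumulative probabilities by
#' linear division by the period length; that convention reproduces every
#' printed weekly value and is the default. A constant-rate (exponential)
#' conversion, `1 - (1 - p)^(1/period)`, is available behind the
#' `convention` switch for users who prefer the standard actuarial form.
#'
#' @param p_cumulative cumulative probability over the source period, in
#'   `[0, 1]`. Vectorised.
#' @param period_weeks length of the source period in weeks (>= 1).
#' @param convention `"linear"` (division by the period, the default) or
#'   `"constant_rate"`.
#' @return weekly transition probability, same length as `p_cumulative`.
#' @examples
#' period_to_weekly(0.3829, 12)            # 0.0319...
#' period_to_weekly(0.174, 52)             # 0.0033...
#' period_to_weekly(0.3829, 12, "constant_rate")
#' @export
period_to_weekly <- function(p_cumulative, period_weeks,
                             convention = c("linear", "constant_rate")) {
  convention <- match.arg(convention)
  if (any(!is.finite(p_cumulative)) || any(p_cumulative < 0) || any(p_cumulative > 1)) {
    stop_invalid("`p_cumulative` must lie in [0, 1]")
  }
  if (any(!is.finite(period_weeks)) || any(period_weeks < 1)) {
    stop_invalid("`period_weeks` must be >= 1")
  }
  switch(convention,
    linear = p_cumulative / period_weeks,
    constant_rate = 1 - (1 - p_cumulative)^(1 / period_weeks)
  )
}

#' Apply a risk ratio to a weekly probability
#'
#' Treatment effects are multiplicative on the weekly probability scale; the
#' result is capped at 1.
#'
#' @param p_weekly weekly probability in `[0, 1]`. Vectorised.
#' @param rr risk ratio (> 0).
#' @return `min(p_weekly * rr, 1)`.
#' @export
apply_risk_ratio <- function(p_weekly, rr) {
  if (any(!is.finite(p_weekly)) || any(p_weekly < 0) || any(p_weekly > 1)) {
    stop_invalid("`p_weekly` must lie in [0, 1]")
  }
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop_invalid("`rr` must be positive")
  }
  pmin(p_weekly * rr, 1)
}

#' Product cost of one course of treatment
#'
#' @param cost_per_application cost of one application in USD (>= 0).
#' @param n_applications mean number of applications; may be non-integer
#'   (trial-reported means such as 3.5 or 7.1 are accepted).
#' @return `cost_per_application * n_applications`, in USD.
#' @export
product_cost_per_treatment <- function(cost_per_application, n_applications) {
  if (any(!is.finite(cost_per_application)) || any(cost_per_application < 0)) {
    stop_invalid("`cost_per_application` must be >= 0")
  }
  if (any(!is.finite(n_applications)) || any(n_applications < 0)) {
    stop_invalid("`n_applications` must be >= 0")
  }
  cost_per_application * n_applications
}

#' Model structure options
#'
#' Switches for the structurally ambiguous corners of the model.
#'
#' @param conversion convention for [period_to_weekly()]: `"linear"`
#'   (default, matches every published weekly value) or `"constant_rate"`.
#' @param infection_healing_to where resolution of an infected ulcer routes:
#'   `"unhealed"` (default; an infected ulcer that resolves is again an
#'   uncomplicated unhealed ulcer, the reading supported by the stated model
#'   structure and the one that reproduces the published healed-wound totals)
#'   or `"healed"` (resolution counts directly as wound closure).
#' @param add_background_mortality if `TRUE`, all-cause background mortality
#'   is added on top of the state-specific mortality in the unhealed,
#'   infected and post-amputation states. Default `FALSE`: the published
#'   state-specific mortalities are treated as already inclusive, which
#'   avoids double counting.
#' @param age_band optional age band (`"<55"`, `"55-64"`, `"65-74"`,
#'   `">=75"`) selecting an age-specific background mortality instead of the
#'   flat all-ages rate.
#' @return a `model_options` list.
#' @export
model_options <- function(conversion = c("linear", "constant_rate"),
                          infection_healing_to = c("unhealed", "healed"),
                          add_background_mortality = FALSE,
                          age_band = NULL) {
  conversion <- match.arg(conversion)
  infection_healing_to <- match.arg(infection_healing_to)
  if (!is.logical(add_background_mortality) || length(add_background_mortality) != 1L) {
    stop_invalid("`add_background_mortality` must be TRUE or FALSE")
  }
  if (!is.null(age_band)) {
    age_band <- match.arg(age_band, c("<55", "55-64", "65-74", ">=75"))
  }
  structure(
    list(
      conversion = conversion,
      infection_healing_to = infection_healing_to,
      add_background_mortality = add_background_mortality,
      age_band = age_band
    ),
    class = "model_options"
  )
}

baseline_fields <- c(
  "p_heal_soc", "p_heal_post_infection", "p_infect",
  "p_amputate_from_dfu", "p_amputate_from_infection",
  "p_die_dfu", "p_die_post_amputation", "p_die_infection",
  "p_die_background"
)

#' Baseline weekly transition probabilities
#'
#' Container for the nine weekly transition probabilities of the
#' standard-of-care natural history. All arguments are weekly probabilities
#' in `[0, 1]`; use [period_to_weekly()] to derive them from cumulative
#' source-period values (see [soc_baseline()] for the published fixture).
#'
#' @param p_heal_soc weekly healing probability of an uncomplicated unhealed
#'   ulcer under standard of care.
#' @param p_heal_post_infection weekly probability that an infected ulcer
#'   resolves (routing governed by [model_options()]).
#' @param p_infect weekly probability that an unhealed ulcer becomes infected.
#' @param p_amputate_from_dfu weekly amputation probability from the
#'   uncomplicated unhealed state.
#' @param p_amputate_from_infection weekly amputation probability from the
#'   infected state.
#' @param p_die_dfu weekly mortality in the unhealed (uninfected) state.
#' @param p_die_post_amputation weekly mortality after amputation.
#' @param p_die_infection weekly mortality in the infected state.
#' @param p_die_background weekly all-cause background mortality (applies in
#'   the healed states).
#' @return a `baseline_transitions` list.
#' @export
baseline_transitions <- function(p_heal_soc, p_heal_post_infection, p_infect,
                                 p_amputate_from_dfu, p_amputate_from_infection,
                                 p_die_dfu, p_die_post_amputation,
                                 p_die_infection, p_die_background) {
  x <- list(
    p_heal_soc = p_heal_soc,
    p_heal_post_infection = p_heal_post_infection,
    p_infect = p_infect,
    p_amputate_from_dfu = p_amputate_from_dfu,
    p_amputate_from_infection = p_amputate_from_infection,
    p_die_dfu = p_die_dfu,
    p_die_post_amputation = p_die_post_amputation,
    p_die_infection = p_die_infection,
    p_die_background = p_die_background
  )
  for (nm in names(x)) {
    p <- x[[nm]]
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
      stop_invalid("baseline probability `%s` must be a single value in [0, 1]", nm)
    }
  }
  structure(x, class = "baseline_transitions")
}

#' Treatment effect of a strategy
#'
#' Risk ratios versus standard of care. The healing risk ratio is
#' product-specific; the infection and amputation risk ratios are class
#' effects shared by every CAMP. Standard of care itself has all ratios 1.
#'
#' @param label strategy name.
#' @param rr_healing,rr_infection,rr_amputation risk ratios (> 0).
#' @param ci optional named list of `c(lower, upper)` 95% bounds per ratio,
#'   e.g. `list(rr_healing = c(1.61, 5.26))`. Bounds must bracket the mean.
#' @return a `treatment_effect` list.
#' @export
treatment_effect <- function(label, rr_healing = 1, rr_infection = 1,
                             rr_amputation = 1, ci = list()) {
  rr <- c(rr_healing = rr_healing, rr_infection = rr_infection,
          rr_amputation = rr_amputation)
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop_invalid("all risk ratios must be positive")
  }
  for (nm in names(ci)) {
    b <- ci[[nm]]
    if (!nm %in% names(rr) || length(b) != 2L || b[1] > rr[[nm]] || b[2] < rr[[nm]]) {
      stop_invalid("CI for `%s` must be c(lower, upper) bracketing the mean", nm)
    }
  }
  structure(
    list(label = label, rr_healing = rr_healing, rr_infection = rr_infection,
         rr_amputation = rr_amputation, ci = ci),
    class = "treatment_effect"
  )
}

#' Cost inputs for one strategy
#'
#' @param product_cost_per_application product cost of one application (USD).
#' @param n_applications mean number of applications over the course of
#'   treatment (may be non-integer).
#' @param weekly_cost_unhealed,weekly_cost_infected,weekly_cost_healed,weekly_cost_post_amputation
#'   weekly health-state costs (USD); the healed-state cost is zero in the
#'   base case.
#' @param amputation_event_cost one-off cost charged on entry to the
#'   amputation state (hospitalization plus one year of subsequent care).
#' @param product_cost_total optional override of the per-treatment product
#'   cost; when supplied it takes precedence over
#'   `product_cost_per_application * n_applications` (used where the
#'   published per-treatment total disagrees with its own factors).
#' @return a `cost_inputs` list; `total_product_cost()` gives the upfront
#'   product cost actually charged.
#' @export
cost_inputs <- function(product_cost_per_application = 0, n_applications = 0,
                        weekly_cost_unhealed = 0, weekly_cost_infected = 0,
                        weekly_cost_healed = 0, amputation_event_cost = 0,
                        weekly_cost_post_amputation = 0,
                        product_cost_total = NULL) {
  x <- list(
    product_cost_per_application = product_cost_per_application,
    n_applications = n_applications,
    weekly_cost_unhealed = weekly_cost_unhealed,
    weekly_cost_infected = weekly_cost_infected,
    weekly_cost_healed = weekly_cost_healed,
    amputation_event_cost = amputation_event_cost,
    weekly_cost_post_amputation = weekly_cost_post_amputation,
    product_cost_total = product_cost_total
  )
  for (nm in setdiff(names(x), "product_cost_total")) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop_invalid("cost input `%s` must be a single non-negative number", nm)
    }
  }
  if (!is.null(product_cost_total) &&
      (!is.numeric(product_cost_total) || product_cost_total < 0)) {
    stop_invalid("`product_cost_total` must be non-negative")
  }
  structure(x, class = "cost_inputs")
}

#' Upfront product cost of a strategy
#'
#' @param costs a [cost_inputs()] object.
#' @return per-treatment product cost in USD.
#' @export
total_product_cost <- function(costs) {
  costs$product_cost_total %||%
    product_cost_per_treatment(costs$product_cost_per_application,
                               costs$n_applications)
}

#' Health-state utility weights
#'
#' Annual-scale utility weights in `[0, 1]`; death is fixed at 0. Post states
#' inherit their parent's utility.
#'
#' @param unhealed,healed,infected,post_amputation utility weights.
#' @return a `utility_inputs` list.
#' @export
utility_inputs <- function(unhealed, healed, infected, post_amputation) {
  x <- list(unhealed = unhealed, healed = healed, infected = infected,
            post_amputation = post_amputation, dead = 0)
  for (nm in setdiff(names(x), "dead")) {
    u <- x[[nm]]
    if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u < 0 || u > 1) {
      stop_invalid("utility `%s` must lie in [0, 1]", nm)
    }
  }
  structure(x, class = "utility_inputs")
}

#' Full parameter set for one strategy
#'
#' Bundles baseline transitions, treatment effect, costs, utilities, the
#' analysis horizon and the model-structure options into the unit the cohort
#' engine consumes.
#'
#' @param label strategy name.
#' @param baseline a [baseline_transitions()] object.
#' @param effect a [treatment_effect()] object.
#' @param costs a [cost_inputs()] object.
#' @param utilities a [utility_inputs()] object.
#' @param horizon_weeks analysis horizon in weekly cycles (positive integer;
#'   the published scenarios use 12, 26 and 52). No discounting is applied at
#'   any horizon.
#' @param options a [model_options()] object.
#' @return a `parameter_set` list.
#' @export
parameter_set <- function(label, baseline, effect, costs, utilities,
                          horizon_weeks = 52, options = model_options()) {
  stopifnot(inherits(baseline, "baseline_transitions"),
            inherits(effect, "treatment_effect"),
            inherits(costs, "cost_inputs"),
            inherits(utilities, "utility_inputs"),
            inherits(options, "model_options"))
  if (!is.numeric(horizon_weeks) || length(horizon_weeks) != 1L ||
      horizon_weeks < 1 || horizon_weeks != round(horizon_weeks)) {
    stop_invalid("`horizon_weeks` must be a positive integer")
  }
  structure(
    list(label = label, baseline = baseline, effect = effect, costs = costs,
         utilities = utilities, horizon_weeks = as.integer(horizon_weeks),
         options = options),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %s, horizon %d weeks\n", x$label, x$horizon_weeks))
  cat(sprintf("  rr: healing %.3g, infection %.3g, amputation %.3g\n",
              x$effect$rr_healing, x$effect$rr_infection, x$effect$rr_amputation))
  cat(sprintf("  upfront product cost: $%.2f\n", total_product_cost(x$costs)))
  invisible(x)
}
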