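# Probabilistic sensitivity analysis: distribution assignment, Monte Carlo
# propagation, and cost-effectiveness acceptability curves.

#' Distribution specification for a sampled input
#'
#' The conventional families: gamma for costs, beta for utilities and
#' probabilities, lognormal for risk ratios. Uncertainty is given either as a
#' 95% CI (from which a normal-theory standard error
#' `(upper - lower) / (2 * 1.959964)` is derived for moment matching) or as a
#' standard error directly. The lognormal is centred on the reported ratio as
#' its median (`meanlog = log(mean)`), matching CI symmetry on the log scale.
#'
#' @param family `"gamma"`, `"beta"`, `"lognormal"`, or `"fixed"` (degenerate
#'   at the mean, for inputs excluded from sampling).
#' @param mean central value.
#' @param ci_lower,ci_upper optional 95% bounds bracketing the mean.
#' @param se optional standard error (used when no CI is given).
#' @return a `dist_spec` list.
#' @export
dist_spec <- function(family = c("gamma", "beta", "lognormal", "fixed"),
                      mean, ci_lower = NULL, ci_upper = NULL, se = NULL) {
  family <- match.arg(family)
  if (!is.null(ci_lower) || !is.null(ci_upper)) {
    if (is.null(ci_lower) || is.null(ci_upper) || ci_lower > mean || ci_upper < mean) {
      stop_invalid("CI bounds must bracket the mean")
    }
  }
  structure(list(family = family, mean = mean, ci_lower = ci_lower,
                 ci_upper = ci_upper, se = se),
            class = "dist_spec")
}

#' Resolve a distribution specification to sampling parameters
#'
#' Moment matching: gamma `shape = m^2/s^2`, `rate = m/s^2`; beta
#' `shape1 = m (m(1-m)/s^2 - 1)`, `shape2 = shape1 (1-m)/m`; lognormal
#' `meanlog = log(mean)` (median-centred),
#' `sdlog = (log(upper) - log(lower)) / (2 * 1.959964)`.
#'
#' @param spec a [dist_spec()].
#' @return the spec with a `params` element holding the resolved parameters.
#' @export
resolve_distribution <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  z2 <- 2 * stats::qnorm(0.975)
  m <- spec$mean
  if (spec$family == "fixed") {
    spec$params <- list(value = m)
    return(spec)
  }
  if (spec$family == "lognormal") {
    if (is.null(spec$ci_lower)) stop_invalid("lognormal specs need a 95%% CI")
    if (m <= 0 || spec$ci_lower <= 0) stop_invalid("lognormal inputs must be positive")
    spec$params <- list(meanlog = log(m),
                        sdlog = (log(spec$ci_upper) - log(spec$ci_lower)) / z2)
    return(spec)
  }
  s <- spec$se %||% ((spec$ci_upper - spec$ci_lower) / z2)
  if (is.null(s) || length(s) != 1L || !is.finite(s) || s < 0) {
    stop_invalid("`%s` spec needs a CI or a standard error", spec$family)
  }
  if (s == 0 || m == 0) {
    spec$family <- "fixed"
    spec$params <- list(value = m)
    return(spec)
  }
  if (spec$family == "gamma") {
    if (m <= 0) stop_invalid("gamma mean must be positive")
    spec$params <- list(shape = m^2 / s^2, rate = m / s^2)
  } else {  # beta
    if (m <= 0 || m >= 1) stop_invalid("beta mean must lie in (0, 1)")
    if (s^2 >= m * (1 - m)) {
      stop_invalid("beta variance %.4g is infeasible for mean %.4g", s^2, m)
    }
    a <- m * (m * (1 - m) / s^2 - 1)
    spec$params <- list(shape1 = a, shape2 = a * (1 - m) / m)
  }
  spec
}

#' Draw from a (resolved) distribution specification
#'
#' @param spec a [dist_spec()]; resolved automatically if needed.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n = 1L) {
  if (is.null(spec$params)) spec <- resolve_distribution(spec)
  p <- spec$params
  switch(spec$family,
    fixed = rep.int(p$value, n),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    gamma = stats::rgamma(n, shape = p$shape, rate = p$rate),
    beta = stats::rbeta(n, p$shape1, p$shape2)
  )
}

pm_se <- function(m) 0.2 * m / stats::qnorm(0.975)  # +/-20% as an SE-equivalent

#' Default PSA distribution assignment for the base-case model
#'
#' Baseline transition probabilities are sampled from beta distributions on
#' the cumulative source-period scale (where their CIs are published) and
#' converted weekly per draw; risk ratios are lognormal from their 95% CIs
#' (healing per CAMP, infection/amputation as shared class effects);
#' state costs and the per-treatment product costs are gamma and utilities
#' beta, both with a +/-20% SE-equivalent spread, the convention for inputs
#' with no published variation. The zero healed-state cost stays fixed.
#'
#' @param strategies named list of [parameter_set()] objects.
#' @return a `psa_specs` list with elements `baseline` (specs plus source
#'   periods), `rr_healing` (per CAMP), `rr_class`, `state_costs`,
#'   `utilities`, `product_total` (per CAMP).
#' @export
default_psa_specs <- function(strategies = camp_strategies()) {
  tab <- cea_tables()
  bl <- tab$baseline_transitions
  camps <- setdiff(names(strategies), "SoC")
  baseline <- list()
  for (i in seq_len(nrow(bl))) {
    row <- bl[i, ]
    spec <- if (is.na(row$ci_lower)) {
      dist_spec("beta", row$mean, se = pm_se(row$mean))
    } else {
      dist_spec("beta", row$mean, row$ci_lower, row$ci_upper)
    }
    baseline[[row$parameter]] <- list(spec = resolve_distribution(spec),
                                      period_weeks = row$period_weeks)
  }
  rr_healing <- list()
  for (lab in camps) {
    eff <- strategies[[lab]]$effect
    ci <- eff$ci$rr_healing
    rr_healing[[lab]] <- resolve_distribution(
      dist_spec("lognormal", eff$rr_healing, ci[1], ci[2])
    )
  }
  ce <- tab$class_effects
  rr_class <- list(
    rr_infection = resolve_distribution(dist_spec(
      "lognormal", ce$rr_infection$mean, ce$rr_infection$ci_lower,
      ce$rr_infection$ci_upper
    )),
    rr_amputation = resolve_distribution(dist_spec(
      "lognormal", ce$rr_amputation$mean, ce$rr_amputation$ci_lower,
      ce$rr_amputation$ci_upper
    ))
  )
  ref <- strategies[[1]]
  g <- function(m) resolve_distribution(dist_spec("gamma", m, se = pm_se(m)))
  b <- function(m) resolve_distribution(dist_spec("beta", m, se = pm_se(m)))
  state_costs <- list(
    weekly_cost_unhealed = g(ref$costs$weekly_cost_unhealed),
    weekly_cost_infected = g(ref$costs$weekly_cost_infected),
    weekly_cost_post_amputation = g(ref$costs$weekly_cost_post_amputation),
    amputation_event_cost = g(ref$costs$amputation_event_cost)
  )
  utilities <- list(
    unhealed = b(ref$utilities$unhealed),
    healed = b(ref$utilities$healed),
    infected = b(ref$utilities$infected),
    post_amputation = b(ref$utilities$post_amputation)
  )
  product_total <- list()
  for (lab in camps) {
    product_total[[lab]] <- g(total_product_cost(strategies[[lab]]$costs))
  }
  structure(
    list(baseline = baseline, rr_healing = rr_healing, rr_class = rr_class,
         state_costs = state_costs, utilities = utilities,
         product_total = product_total),
    class = "psa_specs"
  )
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: per draw, one shared set
#' of baseline transitions, class-effect risk ratios, state costs and
#' utilities is sampled and applied to every strategy (common random numbers
#' mirror the shared evidence base), product-specific healing risk ratios and
#' product costs are drawn per CAMP, and every strategy is run through the
#' cohort engine. Draws whose sampled exit probabilities momentarily exceed
#' row feasibility are rescaled to the feasible boundary and counted in
#' `diagnostics$n_capped_rows`. Deterministic given `seed`.
#'
#' @param strategies named list of [parameter_set()] objects.
#' @param n_draws number of Monte Carlo draws (the published analysis uses
#'   5000).
#' @param seed RNG seed (mandatory).
#' @param specs a `psa_specs` object; defaults to
#'   [default_psa_specs()]`(strategies)`.
#' @return a `psa_result`: list with `draws` (data.frame: `draw`, `strategy`,
#'   `cost`, `qalys`, `healed_wounds`), `n_draws`, `seed`, `diagnostics`.
#' @export
run_psa <- function(strategies, n_draws = 5000, seed,
                    specs = default_psa_specs(strategies)) {
  if (missing(seed)) stop_invalid("`seed` is mandatory for the PSA")
  if (n_draws < 1) stop_invalid("`n_draws` must be >= 1")
  n_draws <- as.integer(n_draws)
  camps <- setdiff(names(strategies), "SoC")
  conversion <- strategies[[1]]$options$conversion

  samples <- with_seed(seed, {
    bl <- sapply(specs$baseline, function(b) {
      period_to_weekly(draw_dist(b$spec, n_draws), b$period_weeks, conversion)
    })
    list(
      baseline = bl,
      rr_infection = draw_dist(specs$rr_class$rr_infection, n_draws),
      rr_amputation = draw_dist(specs$rr_class$rr_amputation, n_draws),
      rr_healing = sapply(specs$rr_healing, draw_dist, n = n_draws),
      state_costs = sapply(specs$state_costs, draw_dist, n = n_draws),
      utilities = sapply(specs$utilities, draw_dist, n = n_draws),
      product_total = sapply(specs$product_total, draw_dist, n = n_draws)
    )
  })
  # sapply() drops to a vector when n_draws == 1
  as_mat <- function(x, nms) matrix(x, nrow = n_draws,
                                    dimnames = list(NULL, nms))
  if (n_draws == 1L) {
    samples$baseline <- as_mat(samples$baseline, names(specs$baseline))
    samples$rr_healing <- as_mat(samples$rr_healing, names(specs$rr_healing))
    samples$state_costs <- as_mat(samples$state_costs, names(specs$state_costs))
    samples$utilities <- as_mat(samples$utilities, names(specs$utilities))
    samples$product_total <- as_mat(samples$product_total, names(specs$product_total))
  }

  n_strat <- length(strategies)
  out_cost <- out_qaly <- out_hw <- matrix(
    NA_real_, n_draws, n_strat, dimnames = list(NULL, names(strategies))
  )
  n_capped <- 0L
  for (d in seq_len(n_draws)) {
    bl_d <- do.call(baseline_transitions,
                    as.list(pmin(samples$baseline[d, baseline_fields], 1)))
    for (lab in names(strategies)) {
      ps <- strategies[[lab]]
      ps$baseline <- bl_d
      if (lab %in% camps) {
        ps$effect$rr_healing <- samples$rr_healing[d, lab]
        ps$effect$rr_infection <- samples$rr_infection[d]
        ps$effect$rr_amputation <- samples$rr_amputation[d]
        ps$costs$product_cost_total <- samples$product_total[d, lab]
      }
      for (fld in colnames(samples$state_costs)) {
        ps$costs[[fld]] <- samples$state_costs[d, fld]
      }
      for (fld in colnames(samples$utilities)) {
        ps$utilities[[fld]] <- min(samples$utilities[d, fld], 1)
      }
      M <- build_matrix(ps, cap_rows = TRUE)
      if (length(attr(M, "capped_rows"))) n_capped <- n_capped + 1L
      trace <- run_cohort(M, ps$horizon_weeks)
      out <- accumulate(trace, ps, M)
      out_cost[d, lab] <- out$total_cost
      out_qaly[d, lab] <- out$qalys
      out_hw[d, lab] <- out$healed_wounds
    }
  }
  draws <- data.frame(
    draw = rep(seq_len(n_draws), times = n_strat),
    strategy = rep(names(strategies), each = n_draws),
    cost = as.vector(out_cost),
    qalys = as.vector(out_qaly),
    healed_wounds = as.vector(out_hw)
  )
  structure(
    list(draws = draws, n_draws = n_draws, seed = seed,
         strategies = names(strategies),
         diagnostics = list(n_capped_rows = n_capped)),
    class = "psa_result"
  )
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws in which
#' each strategy attains the maximal net monetary benefit; exact ties are
#' split equally among the tied strategies, so the probabilities sum to 1 at
#' every threshold.
#'
#' @param psa a [run_psa()] result.
#' @param thresholds willingness-to-pay grid (USD per effect unit).
#' @param effect_measure `"healed_wounds"` (default) or `"qalys"`.
#' @return data.frame with `threshold`, `strategy`, `probability`.
#' @export
ceac <- function(psa, thresholds = seq(0, 200000, by = 5000),
                 effect_measure = c("healed_wounds", "qalys")) {
  stopifnot(inherits(psa, "psa_result"))
  effect_measure <- match.arg(effect_measure)
  if (!length(thresholds)) stop_invalid("`thresholds` must be non-empty")
  strategies <- psa$strategies
  cost <- matrix(psa$draws$cost, ncol = length(strategies),
                 dimnames = list(NULL, strategies))
  eff <- matrix(psa$draws[[effect_measure]], ncol = length(strategies),
                dimnames = list(NULL, strategies))
  rows <- lapply(thresholds, function(th) {
    nmb <- net_monetary_benefit(cost, eff, th)
    best <- nmb == row_max(nmb)
    wins <- best / rowSums(best)
    data.frame(threshold = th, strategy = strategies,
               probability = colMeans(wins))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# row-wise maxima of a numeric matrix
row_max <- function(m) {
  do.call(pmax, as.data.frame(m))
}
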