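# Incremental cost-effectiveness ranking: anchored comparison, dominance
# frontier and net monetary benefit.

#' Net monetary benefit
#'
#' @param cost total cost (USD). Vectorised.
#' @param effect effect (healed wounds or QALYs).
#' @param threshold willingness to pay per effect unit (USD, >= 0).
#' @return `threshold * effect - cost`.
#' @export
net_monetary_benefit <- function(cost, effect, threshold) {
  if (any(threshold < 0)) stop_invalid("`threshold` must be >= 0")
  threshold * effect - cost
}

effect_column <- function(outcomes, effect_measure) {
  if (!effect_measure %in% names(outcomes)) {
    stop_invalid("outcomes lack an `%s` column", effect_measure)
  }
  outcomes[[effect_measure]]
}

#' Anchor every strategy to standard of care
#'
#' Subtracts the anchor's cost and effects from every strategy, making the
#' anchor the origin of the cost-effectiveness plane. Cost-per-healed-wound
#' and cost-per-QALY ratios versus the anchor are reported only where both
#' the incremental cost and incremental effect are positive (a cost-saving,
#' more effective strategy dominates the anchor and carries no ICER).
#'
#' @param outcomes data.frame with columns `strategy`, `cost` and at least
#'   one of `healed_wounds`, `qalys` (the [run_strategies()] layout).
#' @param anchor label of the anchor strategy (default `"SoC"`).
#' @return data.frame with the anchor first: incremental columns
#'   (`inc_cost`, `inc_healed_wounds`, `inc_qalys` as available),
#'   `cost_per_healed` / `cost_per_qaly`, and a `quadrant` label
#'   (`"anchor"`, `"dominant"` = cheaper and more effective, `"dominated"` =
#'   costlier and less effective, `"trade-off"` otherwise, by the primary
#'   effect column).
#' @export
anchor_to_soc <- function(outcomes, anchor = "SoC") {
  if (!anchor %in% outcomes$strategy) {
    stop_invalid("anchor strategy `%s` is not among the outcomes", anchor)
  }
  base <- outcomes[outcomes$strategy == anchor, ]
  res <- data.frame(strategy = outcomes$strategy,
                    inc_cost = outcomes$cost - base$cost)
  eff_cols <- intersect(c("healed_wounds", "qalys"), names(outcomes))
  for (col in eff_cols) {
    res[[paste0("inc_", col)]] <- outcomes[[col]] - base[[col]]
  }
  ratio <- function(inc_eff) {
    ifelse(res$inc_cost > 0 & inc_eff > 0, res$inc_cost / inc_eff, NA_real_)
  }
  if ("healed_wounds" %in% eff_cols) res$cost_per_healed <- ratio(res$inc_healed_wounds)
  if ("qalys" %in% eff_cols) res$cost_per_qaly <- ratio(res[["inc_qalys"]])
  prim <- res[[paste0("inc_", eff_cols[1])]]
  res$quadrant <- ifelse(
    res$strategy == anchor, "anchor",
    ifelse(res$inc_cost <= 0 & prim >= 0, "dominant",
           ifelse(res$inc_cost >= 0 & prim <= 0, "dominated", "trade-off"))
  )
  res <- res[order(res$strategy != anchor, res$inc_cost), ]
  rownames(res) <- NULL
  res
}

#' Cost-effectiveness frontier with simple and extended dominance
#'
#' Ranks strategies by ascending cost (ties broken by descending effect),
#' flags simple dominance (a strategy no cheaper and no more effective than
#' another, strictly worse on at least one axis), then iteratively removes
#' extended dominance (a strategy whose frontier ICER exceeds that of the
#' next more effective survivor) until the ICERs along the surviving frontier
#' are strictly increasing. Final ICERs are recomputed between surviving
#' neighbours only.
#'
#' @param outcomes data.frame with `strategy`, `cost` and the chosen effect
#'   column; duplicate labels are an error.
#' @param effect_measure `"healed_wounds"` (default) or `"qalys"`.
#' @return a `frontier_result` data.frame sorted by cost: `strategy`, `cost`,
#'   `effect`, `dominance` (`"none"`, `"simple"`, `"extended"`), and for
#'   frontier strategies `inc_cost`, `inc_effect`, `icer` versus the previous
#'   survivor (`NA` for the cheapest).
#' @export
build_frontier <- function(outcomes, effect_measure = c("healed_wounds", "qalys")) {
  effect_measure <- match.arg(effect_measure)
  if (anyDuplicated(outcomes$strategy)) stop_invalid("duplicate strategy labels")
  if (nrow(outcomes) < 2L) stop_invalid("at least two strategies are required")
  eff <- effect_column(outcomes, effect_measure)
  if (any(!is.finite(outcomes$cost)) || any(!is.finite(eff))) {
    stop_invalid("costs and effects must be finite")
  }
  ord <- order(outcomes$cost, -eff)
  res <- data.frame(strategy = outcomes$strategy[ord], cost = outcomes$cost[ord],
                    effect = eff[ord], dominance = "none",
                    stringsAsFactors = FALSE)
  n <- nrow(res)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dominated <- any(
      res$cost[others] <= res$cost[i] & res$effect[others] >= res$effect[i] &
        (res$cost[others] < res$cost[i] | res$effect[others] > res$effect[i])
    )
    if (dominated) res$dominance[i] <- "simple"
  }
  # extended dominance: drop survivors until frontier ICERs strictly increase
  alive <- which(res$dominance == "none")
  repeat {
    if (length(alive) < 3L) break
    ic <- diff(res$cost[alive]) / diff(res$effect[alive])
    # >= up to relative rounding noise: an equal-slope predecessor is a
    # mixture of its neighbours and falls to extended dominance
    worse <- which(ic[-length(ic)] >= ic[-1] * (1 - 1e-9))
    if (!length(worse)) break
    drop_idx <- alive[worse[1] + 1L]
    res$dominance[drop_idx] <- "extended"
    alive <- setdiff(alive, drop_idx)
  }
  res$inc_cost <- NA_real_
  res$inc_effect <- NA_real_
  res$icer <- NA_real_
  if (length(alive) > 1L) {
    later <- alive[-1]
    res$inc_cost[later] <- diff(res$cost[alive])
    res$inc_effect[later] <- diff(res$effect[alive])
    res$icer[later] <- res$inc_cost[later] / res$inc_effect[later]
  }
  attr(res, "effect_measure") <- effect_measure
  class(res) <- c("frontier_result", "data.frame")
  res
}

#' Cost-effectiveness plane coordinates
#'
#' Incremental cost and effect of every strategy versus an anchor, for
#' scatter plotting.
#'
#' @inheritParams anchor_to_soc
#' @param effect_measure effect column to plot against.
#' @return data.frame with `strategy`, `inc_cost`, `inc_effect`.
#' @export
ce_plane <- function(outcomes, anchor = "SoC",
                     effect_measure = c("healed_wounds", "qalys")) {
  effect_measure <- match.arg(effect_measure)
  anc <- anchor_to_soc(outcomes, anchor)
  data.frame(strategy = anc$strategy, inc_cost = anc$inc_cost,
             inc_effect = anc[[paste0("inc_", effect_measure)]])
}
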