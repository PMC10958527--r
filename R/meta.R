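# Random-effects synthesis of two-arm event tables on the risk-ratio scale.

#' Two-arm study table
#'
#' @param label study labels.
#' @param events_t,n_t events and sample size in the treatment arm.
#' @param events_c,n_c events and sample size in the control arm.
#' @return a validated `two_arm_studies` data.frame.
#' @export
two_arm_studies <- function(label, events_t, n_t, events_c, n_c) {
  df <- data.frame(label = as.character(label), events_t = events_t, n_t = n_t,
                   events_c = events_c, n_c = n_c)
  if (any(df$n_t <= 0) || any(df$n_c <= 0)) {
    stop_invalid("every arm must have a positive sample size")
  }
  if (any(df$events_t < 0) || any(df$events_t > df$n_t) ||
      any(df$events_c < 0) || any(df$events_c > df$n_c)) {
    stop_invalid("event counts must lie in [0, n] in each arm")
  }
  structure(df, class = c("two_arm_studies", "data.frame"))
}

#' Per-study log risk ratio and sampling variance
#'
#' Computes the log risk ratio `log((a/n1) / (c/n2))` with sampling variance
#' `1/a - 1/n1 + 1/c - 1/n2`. Studies with a zero or boundary cell get a 0.5
#' continuity correction added to every cell (0.5 to events, 1 to each arm
#' size).
#'
#' @param studies a [two_arm_studies()] table.
#' @return data.frame with columns `label`, `yi` (log RR) and `vi` (variance).
#' @export
study_log_rr <- function(studies) {
  stopifnot(inherits(studies, "two_arm_studies"))
  if (any(studies$events_t + studies$events_c == 0)) {
    stop_invalid("a study has no events in either arm; its risk ratio is undefined")
  }
  a <- studies$events_t; n1 <- studies$n_t
  c_ <- studies$events_c; n2 <- studies$n_c
  needs_cc <- a == 0 | c_ == 0 | a == n1 | c_ == n2
  a <- a + 0.5 * needs_cc
  c_ <- c_ + 0.5 * needs_cc
  n1 <- n1 + 1 * needs_cc
  n2 <- n2 + 1 * needs_cc
  data.frame(
    label = studies$label,
    yi = log(a / n1) - log(c_ / n2),
    vi = 1 / a - 1 / n1 + 1 / c_ - 1 / n2
  )
}

#' DerSimonian-Laird random-effects pooling of risk ratios
#'
#' Moment-based random-effects meta-analysis: the between-study variance
#' `tau^2` is estimated from Cochran's Q as
#' `max(0, (Q - (k - 1)) / (S1 - S2/S1))` with `S1 = sum(w)`,
#' `S2 = sum(w^2)` and fixed-effect weights `w = 1/v`; studies are then
#' re-weighted by `1/(v + tau^2)` and the pooled log risk ratio is
#' exponentiated with a Wald 95% interval.
#'
#' @param studies a [two_arm_studies()] table (>= 1 study).
#' @return a `pooled_effect`: list with `rr`, `ci_lower`, `ci_upper`, `tau2`,
#'   `q_statistic`, `df`, `i2`, `n_studies`, `log_rr`, `se_log_rr` and the
#'   per-study `weights` (normalized random-effects weights).
#' @export
pool_dersimonian_laird <- function(studies) {
  stopifnot(inherits(studies, "two_arm_studies"))
  if (nrow(studies) < 1L) stop_invalid("at least one study is required")
  eff <- study_log_rr(studies)
  yi <- eff$yi; vi <- eff$vi
  k <- length(yi)
  w <- 1 / vi
  mu_fixed <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - mu_fixed)^2)
  tau2 <- if (k > 1L) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  w_re <- 1 / (vi + tau2)
  mu <- sum(w_re * yi) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  z <- stats::qnorm(0.975)
  structure(
    list(
      rr = exp(mu), ci_lower = exp(mu - z * se), ci_upper = exp(mu + z * se),
      tau2 = tau2, q_statistic = q, df = k - 1L,
      i2 = if (k > 1L) max(0, (q - (k - 1)) / q) else 0,
      n_studies = k, log_rr = mu, se_log_rr = se,
      weights = stats::setNames(w_re / sum(w_re), eff$label)
    ),
    class = "pooled_effect"
  )
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf(
    "Random-effects (DerSimonian-Laird) pooled risk ratio\n  RR %.3f (95%% CI %.3f to %.3f), %d studies\n  tau^2 = %.4f, Q = %.3f on %d df, I^2 = %.1f%%\n",
    x$rr, x$ci_lower, x$ci_upper, x$n_studies, x$tau2, x$q_statistic, x$df,
    100 * x$i2
  ))
  invisible(x)
}

#' Read a delimited two-arm study table
#'
#' Expects columns `label`, `events_t`, `n_t`, `events_c`, `n_c`.
#'
#' @param path CSV/TSV file path (delimiter inferred from the extension).
#' @return a [two_arm_studies()] table.
#' @export
read_study_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("label", "events_t", "n_t", "events_c", "n_c")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_invalid("study table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  two_arm_studies(df$label, df$events_t, df$n_t, df$events_c, df$n_c)
}
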