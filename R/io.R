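# Configuration, result files and the reproducible pipeline runner. The
# pipeline is driven from R: load_config() + run_pipeline() are the
# programmatic equivalent of a command-line surface, with stages
# ("run", "owsa", "scenario", "psa", "meta", "synth") independently
# selectable and composable.

run_config_schema <- list(
  strategies = "character",
  horizon_weeks = "numeric",
  effect_measure = "character",
  thresholds = "numeric",
  conversion = "character",
  infection_healing_to = "character",
  add_background_mortality = "logical",
  age_band = "character",
  applications = "character",
  stages = "character",
  scenario_horizons = "numeric",
  n_draws = "numeric",
  seed = "numeric",
  meta_studies_file = "character",
  synth = "list",
  output_dir = "character"
)

run_config_defaults <- list(
  strategies = c("SoC", "vCPM", "HAMA", "dHACM", "hFDS", "BLCC", "HSAM"),
  horizon_weeks = 52,
  effect_measure = "healed_wounds",
  thresholds = seq(0, 200000, by = 5000),
  conversion = "linear",
  infection_healing_to = "unhealed",
  add_background_mortality = FALSE,
  applications = "base",
  stages = "run",
  scenario_horizons = c(12, 26),
  n_draws = 5000
)

stochastic_stages <- c("psa", "synth")

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, rejects unknown keys, checks every
#' value against the schema, applies documented defaults and reports each
#' applied default via `message()`.
#'
#' @param path configuration file path.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file `%s` does not exist", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_invalid("config must be a mapping of keys to values")
  unknown <- setdiff(names(cfg), names(run_config_schema))
  if (length(unknown)) {
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  for (key in names(cfg)) {
    want <- run_config_schema[[key]]
    val <- cfg[[key]]
    ok <- switch(want,
      character = is.character(val) || is.null(val),
      numeric = is.numeric(val),
      logical = is.logical(val),
      list = is.list(val)
    )
    if (!isTRUE(ok)) {
      stop_invalid("config key `%s` must be of type %s", key, want)
    }
  }
  for (key in names(run_config_defaults)) {
    if (is.null(cfg[[key]])) {
      cfg[[key]] <- run_config_defaults[[key]]
      message(sprintf("config: `%s` defaulted to %s", key,
                      paste(format(cfg[[key]]), collapse = " ")[1]))
    }
  }
  if (cfg$horizon_weeks < 1 || cfg$horizon_weeks != round(cfg$horizon_weeks)) {
    stop_invalid("config key `horizon_weeks` must be a positive integer")
  }
  if (!cfg$effect_measure %in% c("healed_wounds", "qalys")) {
    stop_invalid("config key `effect_measure` must be healed_wounds or qalys")
  }
  if (!all(cfg$stages %in% c("run", "owsa", "scenario", "psa", "meta", "synth"))) {
    stop_invalid("config key `stages` must be among run, owsa, scenario, psa, meta, synth")
  }
  if (any(cfg$stages %in% stochastic_stages) && is.null(cfg$seed)) {
    stop_invalid("config key `seed` is mandatory for stochastic stages (%s)",
                 paste(intersect(cfg$stages, stochastic_stages), collapse = ", "))
  }
  if (!is.null(cfg$age_band) &&
      !cfg$age_band %in% c("<55", "55-64", "65-74", ">=75")) {
    stop_invalid("config key `age_band` must be one of <55, 55-64, 65-74, >=75")
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

write_result <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline from a configuration
#'
#' Executes the configured stages and writes delimited result tables plus a
#' run manifest (config hash, seed, package version, timestamp) to the
#' output directory. The `"run"` stage writes the per-strategy outcome table,
#' the SoC-anchored comparison and the dominance frontier; `"owsa"`,
#' `"scenario"`, `"psa"`, `"meta"` and `"synth"` add their respective tables.
#' Result tables are written unrounded; re-running with the same
#' configuration and seed reproduces them byte for byte.
#'
#' @param config a [load_config()] result or a path to a config file.
#' @param output_dir output directory (created if missing); defaults to the
#'   config's `output_dir`.
#' @return invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  output_dir <- output_dir %||% config$output_dir
  if (is.null(output_dir)) stop_invalid("an output directory is required")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(output_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop_invalid("output directory `%s` is not writable", output_dir)
  unlink(probe)

  options <- model_options(
    conversion = config$conversion,
    infection_healing_to = config$infection_healing_to,
    add_background_mortality = config$add_background_mortality,
    age_band = config$age_band
  )
  strategies <- camp_strategies(
    horizon_weeks = config$horizon_weeks,
    applications = config$applications,
    options = options
  )[config$strategies]
  if (any(vapply(strategies, is.null, logical(1)))) {
    stop_invalid("config names unknown strategies: %s",
                 paste(setdiff(config$strategies, names(camp_strategies())),
                       collapse = ", "))
  }

  written <- list()
  outcomes <- run_strategies(strategies)
  if ("run" %in% config$stages) {
    written$outcomes <- write_result(outcomes, output_dir, "outcomes.csv")
    if (nrow(outcomes) >= 2L) {
      if ("SoC" %in% outcomes$strategy) {
        written$anchored <- write_result(anchor_to_soc(outcomes), output_dir,
                                         "anchored.csv")
      }
      written$frontier <- write_result(
        as.data.frame(build_frontier(outcomes, config$effect_measure)),
        output_dir, "frontier.csv"
      )
    } else {
      message("single strategy configured; frontier and anchored tables skipped")
    }
  }
  if ("owsa" %in% config$stages) {
    owsa <- run_owsa(strategies, default_owsa_specs(strategies),
                     effect_measure = config$effect_measure,
                     threshold = max(config$thresholds))
    written$owsa <- write_result(as.data.frame(owsa), output_dir, "owsa.csv")
  }
  if ("scenario" %in% config$stages) {
    for (h in config$scenario_horizons) {
      front <- run_scenario(strategies, h, config$effect_measure)
      written[[sprintf("scenario_%d", h)]] <- write_result(
        as.data.frame(front), output_dir, sprintf("scenario_%dw.csv", h)
      )
    }
  }
  if ("psa" %in% config$stages) {
    psa <- run_psa(strategies, n_draws = config$n_draws, seed = config$seed)
    written$psa_draws <- write_result(psa$draws, output_dir, "psa_draws.csv")
    written$ceac <- write_result(
      ceac(psa, config$thresholds, config$effect_measure),
      output_dir, "ceac.csv"
    )
  }
  if ("meta" %in% config$stages) {
    if (is.null(config$meta_studies_file)) {
      stop_invalid("the meta stage needs `meta_studies_file`")
    }
    pooled <- pool_dersimonian_laird(read_study_table(config$meta_studies_file))
    written$meta <- write_result(
      data.frame(rr = pooled$rr, ci_lower = pooled$ci_lower,
                 ci_upper = pooled$ci_upper, tau2 = pooled$tau2,
                 q_statistic = pooled$q_statistic, df = pooled$df,
                 n_studies = pooled$n_studies),
      output_dir, "meta.csv"
    )
  }
  if ("synth" %in% config$stages) {
    synth_args <- config$synth %||% list()
    synth_args$seed <- synth_args$seed %||% config$seed
    trials <- generate_trials(do.call(trial_generator_config, synth_args))
    written$synthetic_trials <- write_result(as.data.frame(trials), output_dir,
                                             "synthetic_trials.csv")
  }

  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("campcea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = lapply(written, basename)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written$manifest <- file.path(output_dir, "manifest.json")
  invisible(written)
}

#' Export a cohort trace as a long table
#'
#' @param trace a [run_cohort()] trace.
#' @return data.frame with `cycle`, `state`, `proportion`, `cum_healed`.
#' @export
trace_table <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- trace$occupancy
  data.frame(
    cycle = rep(0:trace$horizon_weeks, times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    proportion = as.vector(occ),
    cum_healed = rep(trace$cum_healed, times = ncol(occ))
  )
}
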