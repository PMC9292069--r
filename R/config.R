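#' Parse and validate a run configuration
#'
#' The configuration document (YAML or JSON) drives a full model run. An
#' empty document means: the six bundled scenarios, one million adults, the
#' default accrual schedule. Unknown keys are an error at every level —
#' this catches typos before they silently fall back to defaults.
#'
#' Recognized top-level keys:
#' \describe{
#'   \item{scenarios}{character vector of bundled scenario names, or a list
#'     `list(file = "path.yaml")` pointing to a document of scenario blocks
#'     (each block: `condition` with fields exactly as in
#'     [condition_params()], `intervention` as in [intervention_params()]).}
#'   \item{population}{`n_adults`, `reporting_unit`.}
#'   \item{schedule}{named horizon list of `[frac_short, frac_long]` pairs.}
#'   \item{psa}{`n_draws`, `seed`, `spread`, `keep_draws`, optional
#'     `distributions` (each: `target`, `family`, family parameters).}
#'   \item{dsa}{`scenario`, `parameter`, `values`.}
#'   \item{output_dir, seed, log_level}{run plumbing.}
#' }
#'
#' @param document Path to a YAML/JSON file, or an already-parsed list.
#' @return A validated `run_config` list with defaults applied.
#' @export
parse_and_validate_config <- function(document = NULL) {
  doc <- if (is.null(document)) list()
         else if (is.character(document)) read_config_file(document)
         else if (is.list(document)) document
         else stop("config must be a file path or a list")
  if (is.null(doc)) doc <- list()

  chk_keys(doc, c("scenarios", "population", "schedule", "psa", "dsa",
                  "output_dir", "seed", "log_level"), "top level")

  pop <- doc$population %||% list()
  chk_keys(pop, c("n_adults", "reporting_unit"), "population")
  scale <- population_scale(pop$n_adults %||% 1e6,
                            pop$reporting_unit %||% "per million adults")

  schedule <- if (is.null(doc$schedule)) default_accrual_schedule()
              else accrual_schedule(doc$schedule)

  scenarios <- load_scenarios(doc$scenarios)

  psa <- NULL
  if (!is.null(doc$psa)) {
    p <- doc$psa
    chk_keys(p, c("n_draws", "seed", "spread", "keep_draws", "distributions"),
             "psa")
    psa <- list(n_draws = p$n_draws %||% 10000,
                seed = p$seed %||% (doc$seed %||% 1),
                spread = p$spread %||% 0.2,
                keep_draws = isTRUE(p$keep_draws),
                distributions = lapply(p$distributions, parse_distribution))
  }

  dsa <- NULL
  if (!is.null(doc$dsa)) {
    d <- doc$dsa
    chk_keys(d, c("scenario", "parameter", "values"), "dsa")
    if (is.null(d$scenario) || is.null(d$parameter) || is.null(d$values))
      stop("dsa block requires 'scenario', 'parameter' and 'values'")
    if (!d$scenario %in% names(scenarios))
      stop("dsa.scenario '", d$scenario, "' does not resolve to a scenario")
    dsa <- list(scenario = d$scenario, parameter = d$parameter,
                values = as.numeric(unlist(d$values)))
  }

  list(scenarios = scenarios, population = scale, schedule = schedule,
       psa = psa, dsa = dsa,
       output_dir = doc$output_dir %||% ".",
       seed = as.integer(doc$seed %||% 1L),
       log_level = doc$log_level %||% "info")
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

chk_keys <- function(x, allowed, where) {
  if (length(x) == 0) return(invisible(NULL))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ",
         paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(NULL)
}

load_scenarios <- function(spec) {
  bundled <- build_bundled_scenarios()
  if (is.null(spec)) return(bundled)
  if (is.character(spec)) {
    missing <- setdiff(spec, names(bundled))
    if (length(missing))
      stop("unknown bundled scenario name(s): ",
           paste(missing, collapse = ", "))
    return(bundled[spec])
  }
  if (is.list(spec) && !is.null(spec$file)) {
    chk_keys(spec, "file", "scenarios")
    return(read_scenario_file(spec$file))
  }
  stop("scenarios must be bundled names or list(file = path)")
}

#' Read scenario definitions from a configuration document
#'
#' Each named block supplies a `condition` (fields exactly as in
#' [condition_params()]; `short_term`/`long_term` as
#' `{cost_per_episode, qaly_loss_per_episode}` or, alternatively, QALY
#' components `{utility_decrement, duration_years, case_fatality,
#' qalys_lost_per_death}` plus `cost_per_episode`) and an `intervention`
#' (fields as in [intervention_params()]). Unknown field names are an error.
#'
#' @param path YAML or JSON file of scenario blocks.
#' @return Named list of [cea_scenario()] objects.
#' @export
read_scenario_file <- function(path) {
  doc <- read_config_file(path)
  if (is.null(doc) || length(doc) == 0) stop("no scenarios in ", path)
  out <- list()
  for (nm in names(doc)) {
    block <- doc[[nm]]
    chk_keys(block, c("condition", "intervention"), paste0("scenario ", nm))
    out[[nm]] <- cea_scenario(nm,
                              parse_condition(block$condition, nm),
                              parse_intervention(block$intervention, nm))
  }
  out
}

parse_condition <- function(x, nm) {
  where <- paste0("scenario ", nm, " condition")
  chk_keys(x, c("name", "baseline_prevalence", "rr_pandemic", "rr_range",
                "short_term", "long_term", "severity_multiplier",
                "long_term_lag_years", "discount_rate",
                "severity_applies_to_costs"), where)
  condition_params(
    name = x$name %||% nm,
    baseline_prevalence = x$baseline_prevalence,
    rr_pandemic = x$rr_pandemic,
    rr_range = if (is.null(x$rr_range)) c(x$rr_pandemic, x$rr_pandemic)
               else as.numeric(unlist(x$rr_range)),
    short_term = parse_impact(x$short_term, paste0(where, ".short_term")),
    long_term = parse_impact(x$long_term, paste0(where, ".long_term")),
    severity_multiplier = x$severity_multiplier %||% 1.0,
    long_term_lag_years = x$long_term_lag_years %||% 10,
    discount_rate = x$discount_rate %||% 0.03,
    severity_applies_to_costs = isTRUE(x$severity_applies_to_costs))
}

parse_impact <- function(x, where) {
  if (is.null(x)) return(episode_impact())
  chk_keys(x, c("cost_per_episode", "qaly_loss_per_episode",
                "utility_decrement", "duration_years", "case_fatality",
                "qalys_lost_per_death"), where)
  qaly <- if (!is.null(x$qaly_loss_per_episode)) x$qaly_loss_per_episode
          else if (!is.null(x$utility_decrement))
            qaly_loss_from_components(health_outcome_components(
              x$utility_decrement, x$duration_years %||% 0,
              x$case_fatality %||% 0, x$qalys_lost_per_death %||% 0))
          else 0
  episode_impact(x$cost_per_episode %||% 0, qaly)
}

parse_intervention <- function(x, nm) {
  where <- paste0("scenario ", nm, " intervention")
  chk_keys(x, c("name", "coverage", "efficacy", "cost_per_participant",
                "cost_timing"), where)
  intervention_params(
    name = x$name %||% nm,
    coverage = x$coverage %||% 0.20,
    efficacy = x$efficacy,
    cost_per_participant = x$cost_per_participant,
    cost_timing = x$cost_timing %||% "year_one_undiscounted")
}

parse_distribution <- function(x) {
  chk_keys(x, c("target", "family", "value", "low", "high", "mode",
                "median", "domain"), "psa distribution")
  if (is.null(x$target) || is.null(x$family))
    stop("psa distribution requires 'target' and 'family'")
  args <- x[setdiff(names(x), c("target", "family", "domain"))]
  do.call(param_distribution,
          c(list(target = x$target, family = x$family), args,
            list(domain = if (!is.null(x$domain)) as.numeric(unlist(x$domain)))))
}
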