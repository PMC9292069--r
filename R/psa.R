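#' Configuration for a probabilistic sensitivity analysis
#'
#' @param distributions List of [param_distribution()] objects, one per
#'   varied parameter. Parameters are sampled independently on each draw.
#' @param n_draws Number of Monte-Carlo draws, `>= 1` (default 10,000).
#' @param seed Integer seed; the same seed and configuration give
#'   bit-identical results.
#' @param percentiles Lower/upper prediction-interval probabilities
#'   (default 2.5 and 97.5 percent; empirical, type-7 interpolation).
#' @param keep_draws Retain the per-draw output matrix (for
#'   cost-effectiveness-plane plotting).
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(distributions, n_draws = 10000, seed = 1,
                       percentiles = c(0.025, 0.975), keep_draws = FALSE) {
  stopifnot(is.list(distributions),
            all(vapply(distributions, inherits, TRUE, "param_distribution")))
  if (n_draws < 1) stop("n_draws must be >= 1")
  stopifnot(length(percentiles) == 2, percentiles[1] < percentiles[2])
  structure(list(distributions = distributions,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 percentiles = percentiles,
                 keep_draws = isTRUE(keep_draws)),
            class = "psa_config")
}

#' Probabilistic sensitivity analysis over a scenario
#'
#' On each draw, every listed parameter is resampled jointly (independent
#' draws), the full model (burden + intervention) is rerun end-to-end, and
#' QALYs gained plus net savings at every schedule horizon are collected.
#' Draws producing an invalid model state (e.g. total prevalence above one)
#' are rejected and resampled, with a logged count; the run errors if more
#' than half of all attempted draws are rejected.
#'
#' @param scenario A [cea_scenario()].
#' @param cfg A [psa_config()].
#' @param scale A [population_scale()].
#' @param schedule An [accrual_schedule()].
#' @return An object of class `psa_result`: a `summary` data frame (one row
#'   per output: mean, lower and upper prediction bounds), `n_draws`,
#'   `seed`, `n_rejected`, and the per-draw matrix `draws` when
#'   `keep_draws = TRUE`.
#' @export
run_psa <- function(scenario, cfg, scale = population_scale(),
                    schedule = default_accrual_schedule()) {
  stopifnot(inherits(scenario, "cea_scenario"), inherits(cfg, "psa_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  outputs <- c("qalys_gained_total",
               paste0("net_savings_", schedule$horizons))
  draws <- matrix(NA_real_, nrow = cfg$n_draws, ncol = length(outputs),
                  dimnames = list(NULL, outputs))
  n_rejected <- 0L

  for (i in seq_len(cfg$n_draws)) {
    ok <- FALSE
    for (attempt in seq_len(1000)) {
      sc <- scenario
      for (d in cfg$distributions)
        sc <- set_param_path(sc, d$target, sample_distribution(d))
      res <- tryCatch(
        suppressWarnings(run_scenario(sc, scale, schedule)),
        error = function(e) NULL)
      if (!is.null(res)) { ok <- TRUE; break }
      n_rejected <- n_rejected + 1L
      if (n_rejected > cfg$n_draws)
        stop("PSA rejection rate exceeds 50%; check parameter distributions")
    }
    if (!ok) stop("could not obtain a valid draw after 1000 attempts")
    draws[i, ] <- c(res$intervention$qalys_gained_total,
                    res$intervention$net_savings_by_horizon)
  }

  qs <- apply(draws, 2, stats::quantile, probs = cfg$percentiles,
              type = 7, names = FALSE)
  summary <- data.frame(
    output = outputs,
    mean = colMeans(draws),
    lower = qs[1, ],
    upper = qs[2, ],
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(summary = summary,
                 n_draws = cfg$n_draws, seed = cfg$seed,
                 percentiles = cfg$percentiles,
                 n_rejected = n_rejected,
                 draws = if (cfg$keep_draws) draws),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d, %d rejected), %g%%-%g%% prediction interval\n",
              x$n_draws, x$seed, x$n_rejected,
              100 * x$percentiles[1], 100 * x$percentiles[2]))
  s <- x$summary
  s[, -1] <- lapply(s[, -1], signif, 6)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Default parameter distributions for a scenario
#'
#' Standard health-economics PSA mapping: the relative risk follows a
#' lognormal matched to the condition's 95% uncertainty range; proportions
#' (efficacy) follow a beta; costs (per participant and per episode) follow
#' gammas. Where no published range exists the range is taken as
#' `(1 - spread, 1 + spread)` times the base value.
#'
#' @param scenario A [cea_scenario()].
#' @param spread Half-width of the default relative range (default 0.2).
#' @return List of [param_distribution()] objects.
#' @export
default_psa_distributions <- function(scenario, spread = 0.2) {
  cond <- scenario$condition
  interv <- scenario$intervention
  ds <- list()
  rlo <- cond$rr_range[1]; rhi <- cond$rr_range[2]
  ds$rr <- if (rlo < rhi)
    param_distribution("condition.rr_pandemic", "lognormal-from-95CI",
                       low = rlo, high = rhi, domain = c(1e-9, Inf))
  else
    param_distribution("condition.rr_pandemic", "point", value = cond$rr_pandemic)
  e <- interv$efficacy
  ds$efficacy <- param_distribution(
    "intervention.efficacy", "beta-from-95CI",
    low = max(1e-4, e * (1 - spread)), high = min(0.9999, e * (1 + spread)),
    domain = c(0, 1))
  ds$unit_cost <- param_distribution(
    "intervention.cost_per_participant", "gamma-from-95CI",
    low = interv$cost_per_participant * (1 - spread),
    high = interv$cost_per_participant * (1 + spread),
    domain = c(0, Inf))
  ds$cost_short <- param_distribution(
    "condition.short_term.cost_per_episode", "gamma-from-95CI",
    low = cond$short_term$cost_per_episode * (1 - spread),
    high = cond$short_term$cost_per_episode * (1 + spread),
    domain = c(0, Inf))
  if (cond$long_term$cost_per_episode > 0)
    ds$cost_long <- param_distribution(
      "condition.long_term.cost_per_episode", "gamma-from-95CI",
      low = cond$long_term$cost_per_episode * (1 - spread),
      high = cond$long_term$cost_per_episode * (1 + spread),
      domain = c(0, Inf))
  unname(ds[!vapply(ds, is.null, TRUE)])
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the model once per supplied value of a single parameter, all other
#' parameters held at base case.
#'
#' @param scenario A [cea_scenario()].
#' @param parameter_path Dot path to the varied parameter
#'   (e.g. `"condition.rr_pandemic"`).
#' @param values Numeric values to evaluate.
#' @param scale,schedule Model settings.
#' @return Data frame: one row per value, with QALYs gained, net savings per
#'   horizon, and the lifetime cost-effectiveness class.
#' @examples
#' sc <- build_bundled_scenarios()$homelessness
#' one_way_dsa(sc, "condition.rr_pandemic", c(6.67, 1.67))
#' @export
one_way_dsa <- function(scenario, parameter_path, values,
                        scale = population_scale(),
                        schedule = default_accrual_schedule()) {
  stopifnot(inherits(scenario, "cea_scenario"), length(values) >= 1)
  get_param_path(scenario, parameter_path)  # errors early if unresolvable
  rows <- lapply(values, function(v) {
    sc <- set_param_path(scenario, parameter_path, v)
    res <- run_scenario(sc, scale, schedule)
    net <- res$intervention$net_savings_by_horizon
    cbind(data.frame(value = v,
                     qalys_gained = res$intervention$qalys_gained_total),
          as.data.frame(as.list(stats::setNames(
            net, paste0("net_savings_", names(net))))),
          data.frame(ce_class = format(res$intervention$ce_class)))
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter_path
  out
}

# --- dot-path access into a scenario ---------------------------------------

resolve_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

get_param_path <- function(scenario, path) {
  keys <- resolve_path(path)
  node <- scenario
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]]))
      stop("unresolvable parameter path: ", path)
    node <- node[[k]]
  }
  node
}

set_param_path <- function(scenario, path, value) {
  keys <- resolve_path(path)
  rec <- function(node, keys) {
    k <- keys[[1]]
    if (!is.list(node) || is.null(node[[k]]))
      stop("unresolvable parameter path: ", path)
    if (length(keys) == 1) node[[k]] <- value
    else node[[k]] <- rec(node[[k]], keys[-1])
    node
  }
  rec(scenario, keys)
}
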