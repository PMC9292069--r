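#' Per-episode economic and health impact
#'
#' One episode of a condition carries a societal cost (direct medical plus
#' direct non-medical, 2020 USD) and a QALY loss. Short-term and long-term
#' consequences of the same condition are represented by two separate
#' `episode_impact` objects; long-term values are stored undiscounted and
#' discounted at model run time.
#'
#' @param cost_per_episode Nonnegative societal cost per episode (USD, 2020).
#' @param qaly_loss_per_episode Nonnegative QALYs lost per episode.
#' @return An object of class `episode_impact`.
#' @examples
#' episode_impact(cost_per_episode = 32599, qaly_loss_per_episode = 0.67)
#' @export
episode_impact <- function(cost_per_episode = 0, qaly_loss_per_episode = 0) {
  stopifnot(is.numeric(cost_per_episode), length(cost_per_episode) == 1,
            is.numeric(qaly_loss_per_episode), length(qaly_loss_per_episode) == 1)
  if (cost_per_episode < 0)
    stop("cost_per_episode must be >= 0, got ", cost_per_episode)
  if (qaly_loss_per_episode < 0)
    stop("qaly_loss_per_episode must be >= 0, got ", qaly_loss_per_episode)
  structure(list(cost_per_episode = as.numeric(cost_per_episode),
                 qaly_loss_per_episode = as.numeric(qaly_loss_per_episode)),
            class = "episode_impact")
}

#' Morbidity/mortality components of a per-episode QALY loss
#'
#' A per-episode QALY loss can be supplied directly or built from its
#' components: a health-state utility decrement applied over a duration
#' (morbidity) plus a case-fatality probability times the QALYs lost per
#' death (mortality).
#'
#' @param utility_decrement Utility loss per year while in the health state,
#'   in `[0, 1]` (0 = full health, 1 = utility of death).
#' @param duration_years Duration of the decrement, years, `>= 0`.
#' @param case_fatality Probability of death per episode, in `[0, 1]`.
#' @param qalys_lost_per_death QALYs lost per death, `>= 0`.
#' @return An object of class `health_outcome_components`.
#' @seealso [qaly_loss_from_components()]
#' @export
health_outcome_components <- function(utility_decrement, duration_years,
                                      case_fatality = 0,
                                      qalys_lost_per_death = 0) {
  chk_prob(utility_decrement, "utility_decrement")
  chk_prob(case_fatality, "case_fatality")
  if (duration_years < 0) stop("duration_years must be >= 0")
  if (qalys_lost_per_death < 0) stop("qalys_lost_per_death must be >= 0")
  structure(list(utility_decrement = utility_decrement,
                 duration_years = duration_years,
                 case_fatality = case_fatality,
                 qalys_lost_per_death = qalys_lost_per_death),
            class = "health_outcome_components")
}

#' Collapse morbidity and mortality components into a per-episode QALY loss
#'
#' QALY loss per episode = utility_decrement x duration_years +
#' case_fatality x qalys_lost_per_death.
#'
#' @param c A [health_outcome_components()] object.
#' @return Nonnegative QALY loss per episode.
#' @examples
#' qaly_loss_from_components(health_outcome_components(0.2, 5))      # 1.0
#' qaly_loss_from_components(health_outcome_components(0.1, 2, 0.05, 12)) # 0.8
#' @export
qaly_loss_from_components <- function(c) {
  stopifnot(inherits(c, "health_outcome_components"))
  c$utility_decrement * c$duration_years +
    c$case_fatality * c$qalys_lost_per_death
}

#' Epidemiological and economic description of one indirect health condition
#'
#' Describes a condition exacerbated by the pandemic: its pre-pandemic adult
#' prevalence, the relative risk (RR) under the pandemic with its uncertainty
#' range, per-episode short-term and long-term impacts, a severity multiplier
#' applied to health outcomes (QALY losses) only, the lag at which long-term
#' consequences are assumed to occur, and the annual discount rate.
#'
#' @param name Condition label.
#' @param baseline_prevalence Pre-pandemic adult prevalence, in `(0, 1)`.
#' @param rr_pandemic Relative risk of the condition during the pandemic
#'   versus baseline, `> 0`.
#' @param rr_range Length-2 numeric `(low, high)` uncertainty range with
#'   `low <= rr_pandemic <= high`. Defaults to a degenerate range at
#'   `rr_pandemic`.
#' @param short_term,long_term [episode_impact()] objects. Long-term values
#'   are undiscounted; the model discounts them by
#'   `(1 + discount_rate)^long_term_lag_years`.
#' @param severity_multiplier Scalar in `(0, 1]` scaling per-episode QALY
#'   losses (not costs); used when pandemic-era episodes are expected to be
#'   milder than the literature-derived typical episode (e.g. acute rather
#'   than chronic homelessness, modeled with 0.25).
#' @param long_term_lag_years Mean lag, years, at which long-term
#'   consequences occur (default 10).
#' @param discount_rate Annual discount rate (default 0.03).
#' @param severity_applies_to_costs If `TRUE`, `severity_multiplier` also
#'   scales per-episode costs. Default `FALSE`: the multiplier modifies
#'   health outcome values only.
#' @return An object of class `condition_params`.
#' @export
condition_params <- function(name,
                             baseline_prevalence,
                             rr_pandemic,
                             rr_range = c(rr_pandemic, rr_pandemic),
                             short_term = episode_impact(),
                             long_term = episode_impact(),
                             severity_multiplier = 1.0,
                             long_term_lag_years = 10,
                             discount_rate = 0.03,
                             severity_applies_to_costs = FALSE) {
  if (!is.numeric(baseline_prevalence) || baseline_prevalence <= 0 ||
      baseline_prevalence >= 1)
    stop("baseline_prevalence must be in (0, 1), got ", baseline_prevalence)
  if (rr_pandemic <= 0) stop("rr_pandemic must be > 0")
  stopifnot(length(rr_range) == 2)
  if (rr_range[1] > rr_pandemic || rr_range[2] < rr_pandemic)
    stop("rr_range must satisfy low <= rr_pandemic <= high")
  if (severity_multiplier <= 0 || severity_multiplier > 1)
    stop("severity_multiplier must be in (0, 1]")
  if (long_term_lag_years < 0) stop("long_term_lag_years must be >= 0")
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  stopifnot(inherits(short_term, "episode_impact"),
            inherits(long_term, "episode_impact"))
  structure(list(name = as.character(name),
                 baseline_prevalence = baseline_prevalence,
                 rr_pandemic = rr_pandemic,
                 rr_range = as.numeric(rr_range),
                 short_term = short_term,
                 long_term = long_term,
                 severity_multiplier = severity_multiplier,
                 long_term_lag_years = long_term_lag_years,
                 discount_rate = discount_rate,
                 severity_applies_to_costs = isTRUE(severity_applies_to_costs)),
            class = "condition_params")
}

#' Population scale for absolute outputs
#'
#' @param n_adults Number of adults the model is scaled to (default one
#'   million, the conventional reporting denominator).
#' @param reporting_unit Label used when printing results.
#' @return An object of class `population_scale`.
#' @export
population_scale <- function(n_adults = 1e6,
                             reporting_unit = "per million adults") {
  if (n_adults <= 0) stop("n_adults must be > 0")
  structure(list(n_adults = as.numeric(n_adults),
                 reporting_unit = reporting_unit),
            class = "population_scale")
}

#' Mitigation intervention parameters
#'
#' @param name Intervention label.
#' @param coverage Proportion of all affected adults reached (total
#'   pandemic-era prevalence, not excess cases only), in `(0, 1]`.
#'   Default 0.20.
#' @param efficacy Relative reduction in the condition among participants,
#'   in `[0, 1]`.
#' @param cost_per_participant Cost per participant, USD 2020, `>= 0`.
#' @param cost_timing When intervention costs are incurred. Only
#'   `"year_one_undiscounted"` is supported: program costs fall entirely or
#'   predominantly in year one and are not discounted.
#' @return An object of class `intervention_params`.
#' @export
intervention_params <- function(name,
                                coverage = 0.20,
                                efficacy,
                                cost_per_participant,
                                cost_timing = "year_one_undiscounted") {
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  chk_prob(efficacy, "efficacy")
  if (cost_per_participant < 0) stop("cost_per_participant must be >= 0")
  cost_timing <- match.arg(cost_timing, "year_one_undiscounted")
  structure(list(name = as.character(name),
                 coverage = coverage,
                 efficacy = efficacy,
                 cost_per_participant = as.numeric(cost_per_participant),
                 cost_timing = cost_timing),
            class = "intervention_params")
}

#' Cost accrual schedule across reporting horizons
#'
#' Fractions of short-term and of (discounted) long-term averted costs
#' assumed to have been incurred by each horizon. The default phases 60/90/95
#' percent of short-term costs and 0/20/50 percent of long-term costs by
#' years 1, 3 and 10, with the lifetime horizon accruing everything.
#'
#' @param entries Named list, in horizon order, of length-2 numeric vectors
#'   `c(frac_short, frac_long)`. Must contain a `lifetime` entry equal to
#'   `c(1, 1)`; fractions must lie in `[0, 1]` and be nondecreasing across
#'   the horizon order.
#' @return An object of class `accrual_schedule`.
#' @examples
#' default_accrual_schedule()
#' @export
accrual_schedule <- function(entries) {
  stopifnot(is.list(entries), length(entries) >= 1,
            !is.null(names(entries)), all(nzchar(names(entries))))
  m <- do.call(rbind, lapply(entries, function(e) {
    stopifnot(is.numeric(e), length(e) == 2)
    as.numeric(e)
  }))
  colnames(m) <- c("frac_short", "frac_long")
  if (any(m < 0 | m > 1))
    stop("accrual fractions must lie in [0, 1]")
  if (any(diff(m[, 1]) < 0) || any(diff(m[, 2]) < 0))
    stop("accrual fractions must be nondecreasing across the horizon order")
  if (!"lifetime" %in% rownames(m))
    stop("accrual schedule must contain a 'lifetime' entry")
  if (!isTRUE(all.equal(unname(m["lifetime", ]), c(1, 1))))
    stop("the 'lifetime' entry must be c(1, 1)")
  structure(list(horizons = rownames(m), fractions = m),
            class = "accrual_schedule")
}

#' @rdname accrual_schedule
#' @export
default_accrual_schedule <- function() {
  accrual_schedule(list(year1    = c(0.60, 0.00),
                        year3    = c(0.90, 0.20),
                        year10   = c(0.95, 0.50),
                        lifetime = c(1.00, 1.00)))
}

# internal: scalar probability check
chk_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single number in [0, 1]")
  invisible(x)
}

#' @export
print.condition_params <- function(x, ...) {
  cat("Condition:", x$name, "\n")
  cat(sprintf("  baseline prevalence  %.4g\n", x$baseline_prevalence))
  cat(sprintf("  relative risk        %.3g (range %.3g-%.3g)\n",
              x$rr_pandemic, x$rr_range[1], x$rr_range[2]))
  cat(sprintf("  short-term/episode   $%s, %.4g QALYs\n",
              format(round(x$short_term$cost_per_episode), big.mark = ","),
              x$short_term$qaly_loss_per_episode))
  cat(sprintf("  long-term/episode    $%s, %.4g QALYs (lag %g y, rate %g)\n",
              format(round(x$long_term$cost_per_episode), big.mark = ","),
              x$long_term$qaly_loss_per_episode,
              x$long_term_lag_years, x$discount_rate))
  if (x$severity_multiplier < 1)
    cat(sprintf("  severity multiplier  %.3g (health outcomes only)\n",
                x$severity_multiplier))
  invisible(x)
}

#' @export
print.accrual_schedule <- function(x, ...) {
  cat("Accrual schedule (fraction of averted costs incurred by horizon):\n")
  print(round(x$fractions, 3))
  invisible(x)
}
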