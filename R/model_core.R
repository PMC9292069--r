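#' Present value under annual discounting
#'
#' @param value Cost (USD) or QALYs.
#' @param rate Annual discount rate, `>= 0`.
#' @param years Years into the future at which `value` occurs, `>= 0`.
#' @return `value / (1 + rate)^years`.
#' @examples
#' discount(1000, 0.03, 10)  # 744.09
#' @export
discount <- function(value, rate, years) {
  if (any(rate < 0)) stop("rate must be >= 0")
  if (any(years < 0)) stop("years must be >= 0")
  value / (1 + rate)^years
}

#' Total and excess prevalence under a pandemic relative risk
#'
#' Total pandemic-era prevalence is `baseline * rr`; the excess attributable
#' to the pandemic is `baseline * (rr - 1)`. A relative risk below one would
#' imply a pandemic-era *reduction*; the framework models pandemic-increased
#' conditions, so the excess is floored at zero with a warning.
#'
#' @param baseline Pre-pandemic prevalence, in `(0, 1)`.
#' @param rr Relative risk, `> 0`. `baseline * rr` must not exceed 1.
#' @return Named list with `total` and `excess` proportions.
#' @examples
#' excess_prevalence(0.10, 1.37)  # total 0.137, excess 0.037
#' @export
excess_prevalence <- function(baseline, rr) {
  if (baseline <= 0 || baseline >= 1)
    stop("baseline must be in (0, 1)")
  if (rr <= 0) stop("rr must be > 0")
  total <- baseline * rr
  if (total > 1)
    stop(sprintf(
      "implausible prevalence: baseline * rr = %.4g exceeds 1", total))
  excess <- baseline * (rr - 1)
  if (excess < 0) {
    warning("rr < 1 implies a pandemic-era reduction; excess floored at 0")
    excess <- 0
  }
  list(total = total, excess = excess)
}

#' Excess burden of a condition attributable to the pandemic
#'
#' The added-burden section of the model: the number of adults affected in
#' excess of the pre-pandemic baseline, and the excess QALYs lost and excess
#' societal costs they carry. Short-term consequences are valued in year-one
#' terms; long-term consequences are assumed to occur after a mean lag (10
#' years by default) and discounted to the present. The severity multiplier
#' scales QALY losses only unless the condition opts in to cost scaling.
#'
#' @param cond A [condition_params()] object.
#' @param scale A [population_scale()] object.
#' @return An object of class `burden_result`: counts (`total_affected`,
#'   `excess_affected`), `excess_qalys_short`, `excess_qalys_long_discounted`,
#'   `excess_cost_short`, `excess_cost_long_discounted`, per-capita QALY and
#'   cost totals, and the discount factor applied to long-term values.
#' @examples
#' cond <- condition_params("example", baseline_prevalence = 0.10,
#'   rr_pandemic = 1.37,
#'   short_term = episode_impact(25784, 0.671),
#'   long_term  = episode_impact(46385, 1.591))
#' compute_added_burden(cond, population_scale())
#' @export
compute_added_burden <- function(cond, scale = population_scale()) {
  stopifnot(inherits(cond, "condition_params"),
            inherits(scale, "population_scale"))
  prev <- excess_prevalence(cond$baseline_prevalence, cond$rr_pandemic)
  n <- scale$n_adults
  total_affected <- prev$total * n
  excess_affected <- prev$excess * n

  df_long <- 1 / (1 + cond$discount_rate)^cond$long_term_lag_years
  sev <- cond$severity_multiplier
  sev_cost <- if (cond$severity_applies_to_costs) sev else 1

  q_short <- excess_affected * cond$short_term$qaly_loss_per_episode * sev
  q_long  <- excess_affected * cond$long_term$qaly_loss_per_episode * sev * df_long
  c_short <- excess_affected * cond$short_term$cost_per_episode * sev_cost
  c_long  <- excess_affected * cond$long_term$cost_per_episode * sev_cost * df_long

  structure(list(
    condition = cond$name,
    n_adults = n,
    reporting_unit = scale$reporting_unit,
    total_affected = total_affected,
    excess_affected = excess_affected,
    excess_qalys_short = q_short,
    excess_qalys_long_discounted = q_long,
    excess_qalys_total = q_short + q_long,
    excess_cost_short = c_short,
    excess_cost_long_discounted = c_long,
    excess_cost_total = c_short + c_long,
    per_capita_qalys = (q_short + q_long) / n,
    per_capita_cost = (c_short + c_long) / n,
    discount_factor_long = df_long
  ), class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Excess pandemic burden:", x$condition,
      sprintf("(%s)\n", x$reporting_unit))
  cat(sprintf("  affected adults      %s total, %s excess\n",
              format(round(x$total_affected), big.mark = ","),
              format(round(x$excess_affected), big.mark = ",")))
  cat(sprintf("  excess QALYs lost    %s short-term + %s long-term (disc.) = %s\n",
              format(round(x$excess_qalys_short), big.mark = ","),
              format(round(x$excess_qalys_long_discounted), big.mark = ","),
              format(round(x$excess_qalys_total), big.mark = ",")))
  cat(sprintf("  excess societal cost $%.1fM short-term + $%.1fM long-term (disc.) = $%.1fM\n",
              x$excess_cost_short / 1e6, x$excess_cost_long_discounted / 1e6,
              x$excess_cost_total / 1e6))
  invisible(x)
}
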