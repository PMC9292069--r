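#' Intervention outcomes for a condition
#'
#' The intervention section of the model. Participants are drawn from the
#' *total* affected population during the pandemic (not excess cases only):
#' mitigation helps pre-existing and pandemic-attributable cases alike.
#' Cases averted remove both the short-term and the (discounted) long-term
#' per-episode consequences. Intervention costs are charged entirely in year
#' one, undiscounted. Net savings at each horizon phase the averted costs
#' through the accrual schedule:
#'
#' `net(h) = frac_short(h) * averted_short + frac_long(h) * averted_long_disc
#'           - intervention_cost`
#'
#' @param cond A [condition_params()] object.
#' @param burden The [compute_added_burden()] result for `cond` at the same
#'   population scale.
#' @param interv An [intervention_params()] object.
#' @param schedule An [accrual_schedule()]; must contain a `lifetime` entry.
#' @return An object of class `intervention_result` with participants, cases
#'   averted, QALYs gained (short, long-discounted, total), averted costs,
#'   total intervention cost, `net_savings_by_horizon` (named numeric, USD),
#'   and the lifetime cost-effectiveness classification
#'   (see [classify_cost_effectiveness()]).
#' @export
compute_intervention <- function(cond, burden, interv,
                                 schedule = default_accrual_schedule()) {
  stopifnot(inherits(cond, "condition_params"),
            inherits(burden, "burden_result"),
            inherits(interv, "intervention_params"),
            inherits(schedule, "accrual_schedule"))
  if (!"lifetime" %in% schedule$horizons)
    stop("accrual schedule missing the 'lifetime' entry")

  participants <- burden$total_affected * interv$coverage
  cases_averted <- participants * interv$efficacy

  df_long <- burden$discount_factor_long
  sev <- cond$severity_multiplier
  sev_cost <- if (cond$severity_applies_to_costs) sev else 1

  q_short <- cases_averted * cond$short_term$qaly_loss_per_episode * sev
  q_long  <- cases_averted * cond$long_term$qaly_loss_per_episode * sev * df_long
  a_short <- cases_averted * cond$short_term$cost_per_episode * sev_cost
  a_long  <- cases_averted * cond$long_term$cost_per_episode * sev_cost * df_long

  cost_total <- participants * interv$cost_per_participant

  fr <- schedule$fractions
  net <- fr[, "frac_short"] * a_short + fr[, "frac_long"] * a_long - cost_total
  names(net) <- schedule$horizons

  ce <- classify_cost_effectiveness(net[["lifetime"]], q_short + q_long)

  structure(list(
    condition = cond$name,
    intervention = interv$name,
    participants = participants,
    cases_averted = cases_averted,
    qalys_gained_short = q_short,
    qalys_gained_long_discounted = q_long,
    qalys_gained_total = q_short + q_long,
    averted_cost_short = a_short,
    averted_cost_long_discounted = a_long,
    intervention_cost_total = cost_total,
    net_savings_by_horizon = net,
    ce_class = ce
  ), class = "intervention_result")
}

#' Dominance / ICER classification versus doing nothing
#'
#' An intervention whose lifetime savings exceed its cost while gaining QALYs
#' is *dominant*: it both saves money and improves health. Otherwise the net
#' cost per QALY gained (the incremental cost-effectiveness ratio against no
#' intervention) is reported.
#'
#' @param lifetime_net_savings Lifetime net savings, USD (negative = net cost).
#' @param qalys_gained Nonnegative QALYs gained.
#' @return A list of class `ce_class` with `class` one of `"dominant"`,
#'   `"icer"`, `"undefined"`, and `icer` (USD per QALY) when applicable.
#' @examples
#' classify_cost_effectiveness(10e6, 1000)   # dominant
#' classify_cost_effectiveness(-5e6, 1000)   # ICER $5,000/QALY
#' @export
classify_cost_effectiveness <- function(lifetime_net_savings, qalys_gained) {
  if (qalys_gained < 0) stop("qalys_gained must be >= 0")
  if (qalys_gained == 0)
    return(structure(list(class = "undefined", icer = NA_real_),
                     class = "ce_class"))
  if (lifetime_net_savings > 0)
    structure(list(class = "dominant", icer = NA_real_), class = "ce_class")
  else
    structure(list(class = "icer",
                   icer = -lifetime_net_savings / qalys_gained),
              class = "ce_class")
}

#' @export
format.ce_class <- function(x, ...) {
  switch(x$class,
         dominant = "Dominant",
         icer = sprintf("$%s/QALY", format(round(x$icer), big.mark = ",")),
         "undefined (no QALYs gained)")
}

#' @export
print.ce_class <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Full-reach intervention parameters for a fixed-budget campaign
#'
#' For population-wide campaigns (the stroke-mortality public-awareness
#' campaign) reach is 100% of the at-risk pool and the per-participant cost
#' is the total campaign cost spread over that pool.
#'
#' @param at_risk_pool Number of people at risk, `> 0`.
#' @param total_campaign_cost Total campaign cost, USD.
#' @param efficacy Relative reduction in the condition among those reached.
#' @param name Intervention label.
#' @return An [intervention_params()] with `coverage = 1` and
#'   `cost_per_participant = total_campaign_cost / at_risk_pool`.
#' @examples
#' stroke_reach_adjustment(1000, 14350, efficacy = 0.11)
#' @export
stroke_reach_adjustment <- function(at_risk_pool, total_campaign_cost,
                                    efficacy,
                                    name = "public awareness campaign") {
  if (at_risk_pool <= 0) stop("at_risk_pool must be > 0")
  intervention_params(name, coverage = 1.0, efficacy = efficacy,
                      cost_per_participant = total_campaign_cost / at_risk_pool)
}

#' @export
print.intervention_result <- function(x, ...) {
  cat("Intervention:", x$intervention, "for", x$condition, "\n")
  cat(sprintf("  participants         %s (cases averted %s)\n",
              format(round(x$participants), big.mark = ","),
              format(round(x$cases_averted), big.mark = ",")))
  cat(sprintf("  QALYs gained         %s\n",
              format(round(x$qalys_gained_total), big.mark = ",")))
  cat(sprintf("  intervention cost    %s\n", fmt_money(x$intervention_cost_total)))
  cat("  net savings by horizon:\n")
  for (h in names(x$net_savings_by_horizon))
    cat(sprintf("    %-9s %s\n", h, fmt_money(x$net_savings_by_horizon[[h]])))
  cat("  cost-effectiveness (lifetime):", format(x$ce_class), "\n")
  invisible(x)
}

# money formatter: millions to 0.1M like published tables, parentheses for
# net costs
fmt_money <- function(x) {
  neg <- x < 0
  ax <- abs(x)
  s <- if (ax >= 1e6) sprintf("$%.1fM", ax / 1e6)
       else sprintf("$%s", format(round(ax), big.mark = ","))
  if (neg) paste0("(", s, ")") else s
}
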