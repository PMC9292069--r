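---
title: "Modeling the cost-effectiveness of mitigating indirect pandemic health effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the cost-effectiveness of mitigating indirect pandemic health effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pandemicCEA)
```

Pandemics harm health far beyond the infections themselves: depression,
substance use, family violence, homelessness and delayed acute care all rose
during the COVID-19 era, and those conditions carry costs and quality-of-life
losses that persist for years. `pandemicCEA` is a deliberately simple,
condition-agnostic cost-effectiveness engine for this setting. It trades the
disease-specific nuance of state-transition models for a uniform two-part
structure that can be applied rapidly and identically across many conditions,
which is the right tool when the question is *where* mitigation money does
the most good, not *how* a single disease progresses.

## The model

### Added burden

Each condition is described by its pre-pandemic adult prevalence $p_0$ and a
pandemic relative risk $RR$. Pandemic-era prevalence is $p_0 \cdot RR$, and
the excess attributable to the pandemic is

$$\Delta p = p_0 (RR - 1).$$

In a population of $N$ adults (one million by default), the excess affected
are $E = \Delta p \cdot N$. Every episode carries a short-term and a
long-term consequence, each an `episode_impact` pairing a societal cost
$c$ (direct medical plus direct non-medical, 2020 USD) with a QALY loss $q$
(supplied directly, or assembled as utility decrement × duration +
case fatality × QALYs per death via `qaly_loss_from_components()`).
Short-term consequences fall in year one and are not discounted. Long-term
consequences are assumed to occur at a single mean lag $T$ (10 years by
default) and are discounted once at that mean with annual rate $r$ (3%):

$$\text{excess QALYs} = E\,s\left(q_S + \frac{q_L}{(1+r)^T}\right), \qquad
  \text{excess cost} = E\left(c_S + \frac{c_L}{(1+r)^T}\right),$$

where $s \in (0, 1]$ is a severity multiplier applied to *health outcomes
only*. The multiplier exists because pandemic-era episodes of a condition
can be systematically milder than the literature-derived typical episode:
the bundled homelessness scenario uses $s = 0.25$ on the reasoning that
newly precipitated homelessness is acute (people doubling up with friends
or family) rather than chronic. Whether the multiplier should also scale
costs is genuinely open; we default to health-outcomes-only, with a
`severity_applies_to_costs` flag for the other reading.

Discounting at the point mass $T$ rather than over a lag distribution is a
deliberate simplification: with a single mean lag the discount factor is a
constant, all outputs stay linear in every per-episode parameter, and the
back-solving calibration below becomes exact.

A relative risk below one would mean the pandemic *reduced* the condition;
the framework models pandemic-increased conditions, so the excess is floored
at zero with a warning rather than allowed to go negative. A draw with
$p_0 \cdot RR > 1$ is an error (and, inside the PSA, a rejected draw).

### Intervention outcomes

A mitigation strategy has a coverage $\kappa$ (default 20%), an efficacy
$\varepsilon$ (relative reduction of the condition among participants), and
a per-participant cost. Two structural choices matter:

* **Participants come from the total affected pool** $p_0 RR \cdot N$, not
  the excess: a counselor does not ask whether a depression predates the
  pandemic. This makes program costs scale with total prevalence while
  benefits scale with cases averted.
* **One averted case removes both its short- and long-term consequences.**
  Effect durability is not modeled separately; proportionality is the
  minimal assumption consistent with the published outcome tables.

Cases averted are $A = \kappa\, p_0 RR\, N \varepsilon$; QALYs gained and
averted costs are $A$ times the per-episode values (long-term discounted,
severity as above). Program costs are charged entirely in year one,
undiscounted — the interventions modeled are short, front-loaded programs.
QALYs gained are reported as a lifetime total; only costs are phased over
time.

### The accrual schedule and net savings

Averted costs do not materialize at once. An `accrual_schedule` maps each
reporting horizon to the fraction of short-term and of (present-value)
long-term averted costs incurred by then; the default is

| horizon | short-term | long-term |
|---------|-----------:|----------:|
| year 1 | 60% | 0% |
| year 3 | 90% | 20% |
| year 10 | 95% | 50% |
| lifetime | 100% | 100% |

and net savings at horizon $h$ are
$f_S(h)\,S + f_L(h)\,L - C$ for averted short/long costs $S, L$ and program
cost $C$. Fractions must be nondecreasing in the horizon order and the
lifetime entry must be $(1, 1)$, which together guarantee net savings are
nondecreasing across horizons. The lifetime row is implied rather than
published, but it is what makes a "lifetime" dominance classification
well-defined.

An intervention whose lifetime savings exceed its cost while gaining QALYs
is *dominant*; otherwise `classify_cost_effectiveness()` reports the net
cost per QALY gained against doing nothing. With zero QALYs gained the
ratio is undefined and flagged rather than forced.

## Calibration of the bundled scenarios

The six bundled scenarios (depressive symptoms, intimate partner violence,
homelessness, excessive alcohol use, opioid use disorder, stroke mortality)
are reconstructed from published per-million summary tables, because the
underlying per-episode parameters (utility decrements, case-fatality
ratios, baseline prevalences) were published only in supplementary material
that is not redistributable here. The reconstruction is deterministic:

1. **Burden side.** Per-episode QALY losses and costs are chosen so the
   forward model reproduces the four published burden cells exactly
   (`backsolve_condition()`); long-term values are un-discounted through
   $(1.03)^{10}$ before storage so the forward pass re-discounts them.
2. **Baseline prevalence.** Per-million outputs are invariant to the
   baseline (per-episode values absorb the scaling), so the baseline is a
   free choice. Rather than inventing one, we anchor it so the total
   (short + discounted long) cost per excess episode equals the published
   per-episode cost — a convention, flagged as illustrative, that keeps
   per-episode magnitudes plausible.
3. **Intervention side.** The published outcome rows (QALYs gained, net
   savings at three horizons) were rounded independently, so no single
   cases-averted fraction reproduces every cell exactly. Efficacy is
   therefore calibrated by minimizing the worst relative deviation across
   {QALYs gained, net savings at years 1, 3, 10} — a piecewise-linear
   convex objective with a unique minimum (`stats::optimize`). The result
   lands within 0.25% of every published cell for all six scenarios, and
   the implied efficacies are plausible round numbers (e.g. 0.25 for
   CBT + antidepressants, 0.15 for alcohol screening-and-brief-
   intervention).
4. **Stroke.** The awareness campaign reaches 100% of the at-risk pool, so
   its coverage is 1.0 and its unit cost spreads the fixed campaign budget
   over that pool (`stroke_reach_adjustment()`); the condition has no
   long-term component (its published long-term cells are empty).

The held-out check: averted short/long costs back-solved from the program
cost and the 1- and 10-year net savings predict the *3-year* net savings,
a cell never used in that solve, within 1% for all five 20%-coverage rows
(`backsolve_averted_costs()`; the residual ~0.04–0.8% is table rounding).

```{r}
sc <- build_bundled_scenarios()
t <- sc$depression$targets
bs <- backsolve_averted_costs(t$intervention_cost, t$net1, t$net10)
accrued_net_savings(bs$averted_short, bs$averted_long,
                    t$intervention_cost)[["year3"]] / 1e6  # vs published 161.7
```

## Uncertainty analysis

### Probabilistic sensitivity analysis

`run_psa()` resamples all listed parameters jointly (independently — no
correlation structure was available to estimate; a future rank-correlation
hook would slot in at the sampling step), reruns the full pipeline per
draw, and reports means with empirical 2.5/97.5 percentile prediction
intervals (type-7 interpolation). Determinism is strict: the same seed and
configuration give bit-identical summaries. Draws that produce an invalid
model state (total prevalence above one) are rejected and resampled with a
logged count, and the run aborts if the rejection rate passes 50% — at that
point the distributions, not the draws, are wrong.

Distribution families follow standard health-economics practice, since the
original analyses named none: relative risks are lognormal, proportions
beta, costs gamma, each matched so the distribution's 2.5/97.5 quantiles
equal the 95% uncertainty range (closed form on the log scale for the
lognormal; numerical quantile matching for beta/gamma). Where no published
range exists, defaults use ±20% of the base value
(`default_psa_distributions()`). One subtlety: exact quantile matching
places the lognormal's median at the geometric midpoint of the range, not
at the base-case value — for skewed ranges (depression RR 1.37 with range
1.20–2.56) the PSA mean therefore sits above the deterministic result.
That is a property of honoring the published range exactly; passing
`median =` instead anchors the base case at the median at the price of
approximate bounds. We default to exact bounds because the range is the
only published uncertainty statement. For this reason the package treats
published PSA means/intervals as qualitative context only, and its tests
assert sign and ordering properties (savings reliably positive), not
interval endpoints.

### One-way deterministic sensitivity analysis

`one_way_dsa()` sweeps a single parameter (addressed by a dot path such as
`condition.rr_pandemic`) with everything else at base case. The canonical
use is the homelessness relative risk, the most uncertain input in the
bundled set (its value is proxied from a previous recession, since eviction
moratoria had delayed the observable rise): quartering the RR from 6.67 to
1.67 shrinks QALYs gained and savings roughly proportionally, leaves rent
subsidies dominant, and leaves year one as a net cost with savings arriving
by later horizons. In this linear model, coverage and RR scale participants
and cases averted together, so per-participant margins — and hence the
*signs* of each horizon's net savings — are invariant to the RR; only
magnitudes move.

## The synthetic scenario generator

`random_scenario(seed)` draws a plausible condition/intervention pair:
baseline prevalence 0.001–0.3, RR 1–8 truncated so total prevalence stays
below one, per-episode costs $10^3$–$10^5$ USD log-uniform, per-episode
QALY losses 0.01–5, efficacy 0.05–0.8, coverage 0.05–1, unit cost
$10^2$–$10^4$ USD log-uniform, severity 0.25–1. Those ranges bracket the
six calibrated scenarios with room to spare. Generated scenarios exercise
the model's *structural* properties — linearity, accrual monotonicity,
back-solve/forward round-trips, seeded reproducibility — under fixed seeds.
What they do not emulate: correlation between prevalence and per-episode
severity, parameter uncertainty (each draw is a point scenario), or any
claim about real conditions; a passing property suite says the engine's
arithmetic and invariants are right, not that any particular scenario is
realistic.

## Numerical choices and degenerate inputs

* Long-term discounting uses a single factor $(1+r)^{-T}$; $r = 0$ or
  $T = 0$ are legal and give factor 1.
* `excess_prevalence()` errors on $p_0 RR > 1$ and floors $RR < 1$ at zero
  excess with a warning.
* The 2×2 accrual back-solve errors on a singular system (possible only
  for degenerate schedules); solved costs within $10^{-9}$ of zero are
  clamped to zero, genuinely negative solutions warn.
* Quantile matching for beta/gamma runs Nelder–Mead on log-parameters from
  a normal-approximation start and warns if the objective fails to reach
  $10^{-6}$.
* Zero QALYs gained yields an explicit `undefined` cost-effectiveness
  class, never a division by zero.
* Problem sizes used by the shipped checks: PSA examples run at 200–4,000
  draws; the sampler's CI-recovery check uses $10^6$ draws; property
  sweeps use 1,000 generated scenarios. All are chosen to hold Monte-Carlo
  error comfortably below the asserted tolerances.

## Known limitations

The model is linear end-to-end: no disease progression, no interaction
between conditions, no capacity constraints, no cost-sharing between
simultaneously deployed programs, no productivity losses or spillovers to
children — each omission inherited deliberately from the framework's
rapid-assessment design. Baseline prevalences in the bundled scenarios are
calibration conventions, not estimates; any analysis that depends on
absolute prevalence (rather than per-million burden and savings) should
supply its own. Intervention costs recur only in year one; multi-year
programs would need a cost schedule the published tables do not provide.
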