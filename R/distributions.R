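#' Parameter distribution for probabilistic sensitivity analysis
#'
#' Binds a sampling distribution to a model parameter, addressed by a dot
#' path into a scenario (e.g. `"condition.rr_pandemic"`,
#' `"intervention.efficacy"`, `"condition.short_term.cost_per_episode"`).
#'
#' Families follow standard health-economics PSA practice:
#' \describe{
#'   \item{point}{degenerate at `value`.}
#'   \item{uniform}{on `(low, high)`.}
#'   \item{pert}{modified-PERT (beta rescaled to `(low, high)` with mode
#'     `mode`, shape 4).}
#'   \item{lognormal-from-95CI}{lognormal whose 2.5/97.5 percent quantiles
#'     equal `(low, high)`; if `median` is supplied the distribution is
#'     anchored at that median instead and only the CI *width* is matched on
#'     the log scale.}
#'   \item{beta-from-95CI}{beta with 2.5/97.5 percent quantiles `(low, high)`
#'     (solved numerically); for proportions.}
#'   \item{gamma-from-95CI}{gamma with 2.5/97.5 percent quantiles
#'     `(low, high)` (solved numerically); for costs.}
#' }
#'
#' @param target Dot path to the parameter within a scenario.
#' @param family One of the families above.
#' @param ... Family parameters: `value` (point); `low`, `high` (uniform and
#'   the three CI families); `mode` (pert); optional `median`
#'   (lognormal-from-95CI).
#' @param domain Optional length-2 vector; sampled values outside it are
#'   resampled (used to keep probabilities in `[0,1]`, RR positive, ...).
#' @return An object of class `param_distribution`.
#' @examples
#' param_distribution("condition.rr_pandemic", "lognormal-from-95CI",
#'                    low = 1.20, high = 2.56)
#' @export
param_distribution <- function(target, family, ..., domain = NULL) {
  family <- match.arg(family, c("point", "uniform", "pert",
                                "lognormal-from-95CI", "beta-from-95CI",
                                "gamma-from-95CI"))
  pars <- list(...)
  d <- structure(list(target = target, family = family, params = pars,
                      domain = domain, fit = NULL),
                 class = "param_distribution")
  # validate and precompute the fitted shape once
  d$fit <- switch(family,
    point = {
      if (is.null(pars$value)) stop("family 'point' needs 'value'")
      list()
    },
    uniform = {
      chk_bounds(pars$low, pars$high, positive = FALSE)
      list()
    },
    pert = {
      chk_bounds(pars$low, pars$high, positive = FALSE)
      if (is.null(pars$mode) || pars$mode < pars$low || pars$mode > pars$high)
        stop("family 'pert' needs low <= mode <= high")
      rng <- pars$high - pars$low
      list(shape1 = 1 + 4 * (pars$mode - pars$low) / rng,
           shape2 = 1 + 4 * (pars$high - pars$mode) / rng)
    },
    `lognormal-from-95CI` = {
      chk_bounds(pars$low, pars$high, positive = TRUE)
      z <- stats::qnorm(0.975)
      sdlog <- (log(pars$high) - log(pars$low)) / (2 * z)
      meanlog <- if (!is.null(pars$median)) log(pars$median)
                 else (log(pars$low) + log(pars$high)) / 2
      list(meanlog = meanlog, sdlog = sdlog)
    },
    `beta-from-95CI` = {
      chk_bounds(pars$low, pars$high, positive = TRUE)
      if (pars$high >= 1) stop("beta-from-95CI bounds must lie in (0, 1)")
      fit_ci_family(pars$low, pars$high, stats::qbeta)
    },
    `gamma-from-95CI` = {
      chk_bounds(pars$low, pars$high, positive = TRUE)
      fit_ci_family(pars$low, pars$high, stats::qgamma)
    })
  d
}

chk_bounds <- function(low, high, positive) {
  if (is.null(low) || is.null(high))
    stop("this family needs 'low' and 'high'")
  if (low > high) stop("CI bounds inverted: low > high")
  if (positive && low <= 0)
    stop("bounds must be positive for this family")
  invisible(NULL)
}

# Solve two-parameter (shape1, shape2) quantile-matching on the log-parameter
# scale; qfun is qbeta or qgamma (shape/rate).
fit_ci_family <- function(low, high, qfun) {
  if (low == high) return(list(degenerate = low))
  obj <- function(lp) {
    p <- exp(lp)
    q <- qfun(c(0.025, 0.975), p[1], p[2])
    sum((log(q) - log(c(low, high)))^2)
  }
  # moment-style start from a normal approximation
  m <- (low + high) / 2
  s <- (high - low) / (2 * stats::qnorm(0.975))
  start <- if (identical(qfun, stats::qbeta)) {
    v <- s^2
    k <- m * (1 - m) / v - 1
    log(pmax(c(m * k, (1 - m) * k), 1e-3))
  } else {
    log(pmax(c(m^2 / s^2, m / s^2), 1e-8))
  }
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-12))
  if (o$value > 1e-6)
    warning("quantile matching converged poorly (objective ",
            signif(o$value, 3), ")")
  p <- exp(o$par)
  list(shape1 = p[1], shape2 = p[2])
}

#' Draw one value from a parameter distribution
#'
#' Uses R's global RNG stream; seed via `set.seed()` or through
#' [psa_config()]. Draws falling outside the distribution's `domain` are
#' resampled (up to 1000 attempts).
#'
#' @param d A [param_distribution()].
#' @param n Number of draws (default 1).
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(d, n = 1) {
  stopifnot(inherits(d, "param_distribution"))
  p <- d$params
  f <- d$fit
  draw <- function(n) switch(d$family,
    point = rep(p$value, n),
    uniform = if (p$low == p$high) rep(p$low, n)
              else stats::runif(n, p$low, p$high),
    pert = p$low + (p$high - p$low) * stats::rbeta(n, f$shape1, f$shape2),
    `lognormal-from-95CI` = stats::rlnorm(n, f$meanlog, f$sdlog),
    `beta-from-95CI` = if (!is.null(f$degenerate)) rep(f$degenerate, n)
                       else stats::rbeta(n, f$shape1, f$shape2),
    `gamma-from-95CI` = if (!is.null(f$degenerate)) rep(f$degenerate, n)
                        else stats::rgamma(n, f$shape1, f$shape2))
  x <- draw(n)
  if (!is.null(d$domain)) {
    for (i in seq_len(1000)) {
      bad <- x < d$domain[1] | x > d$domain[2]
      if (!any(bad)) break
      x[bad] <- draw(sum(bad))
    }
    x <- pmin(pmax(x, d$domain[1]), d$domain[2])
  }
  x
}
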