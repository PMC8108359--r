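#' Weibull parameter pair
#'
#' Small container for the scale/shape parameterisation used throughout:
#' density f(x) = (shape/scale) * (x/scale)^(shape-1) * exp(-(x/scale)^shape),
#' identical to [stats::dweibull()].
#'
#' @param scale Positive scale parameter (same units as the time axis).
#' @param shape Positive shape parameter.
#' @return An object of class `weibull_params` (named list with `scale`,
#'   `shape`).
#' @export
weibull_params <- function(scale, shape) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale), scale > 0,
            is.numeric(shape), length(shape) == 1L, is.finite(shape), shape > 0)
  structure(list(scale = scale, shape = shape), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull(scale = %g, shape = %g)\n", x$scale, x$shape))
  invisible(x)
}

## validate a (time, event) pair; returns them as a clean data.frame
check_censored <- function(time, event) {
  if (length(time) == 0L) stop("no samples provided")
  if (length(time) != length(event)) stop("'time' and 'event' lengths differ")
  if (anyNA(time) || anyNA(event)) stop("missing values in 'time' or 'event'")
  if (any(time <= 0)) stop("all times must be strictly positive")
  event <- as.logical(event)
  if (anyNA(event)) stop("'event' must be logical or 0/1")
  data.frame(time = as.numeric(time), event = event)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function from right-censored data.
#' The returned step function is right-continuous: `surv[i]` is S(t) for
#' t in \[times\[i\], times\[i+1\]).
#'
#' @param time Positive observed times (minimum of event and censoring time).
#' @param event Logical (or 0/1); `TRUE` means the event was observed.
#' @param max_as_event If `TRUE` and the largest time is censored, that record
#'   is treated as observed so the curve reaches zero. This tail closure is
#'   what the mean-residual-life and Kaplan-Meier imputation steps use; the
#'   exponential-tail variant turns it off.
#' @return Object of class `km_curve`: list with `times` (distinct event
#'   times, increasing), `surv` (S(t) just after each event time), `n_risk`,
#'   `n_event`, and `all_censored` flag.
#' @export
km_curve <- function(time, event, max_as_event = FALSE) {
  d <- check_censored(time, event)
  if (max_as_event && !all(d$event)) {
    i_max <- which(d$time == max(d$time))
    d$event[i_max] <- TRUE
  }
  if (!any(d$event)) {
    warning("all records censored: survival curve is flat at 1")
    return(structure(list(times = numeric(0), surv = numeric(0),
                          n_risk = integer(0), n_event = integer(0),
                          all_censored = TRUE),
                     class = "km_curve"))
  }
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  keep <- sf$n.event > 0
  structure(list(times = sf$time[keep], surv = sf$surv[keep],
                 n_risk = sf$n.risk[keep], n_event = sf$n.event[keep],
                 all_censored = FALSE),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d event times, S(max) = %s\n",
              length(x$times),
              if (length(x$surv)) format(min(x$surv)) else "1"))
  invisible(x)
}

## evaluate the right-continuous step function S(t)
km_surv_at <- function(curve, t) {
  if (length(curve$times) == 0L) return(rep(1, length(t)))
  vapply(t, function(ti) {
    i <- findInterval(ti, curve$times)
    if (i == 0L) 1 else curve$surv[i]
  }, numeric(1))
}

#' Mean residual life from a survival curve
#'
#' Expected remaining time to the event given survival past `t`:
#' mrl(t) = integral of S(u) du over (t, Inf) divided by S(t), with the step
#' function integrated exactly. The curve must reach zero (use
#' `max_as_event = TRUE` in [km_curve()] when the largest time is censored),
#' otherwise the tail mass is unbounded.
#'
#' @param curve A `km_curve`.
#' @param t Nonnegative time at which to evaluate; requires S(t) > 0.
#' @return Nonnegative scalar, the mean residual life at `t`.
#' @export
mean_residual_life <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), is.numeric(t), length(t) == 1L, t >= 0)
  if (length(curve$times) == 0L)
    stop("survival curve has no events; mean residual life is undefined")
  if (min(curve$surv) > 1e-12)
    stop("survival curve does not reach zero; refit with max_as_event = TRUE")
  s_t <- km_surv_at(curve, t)
  if (s_t <= 0) stop("S(t) = 0: no remaining survival mass beyond t")
  # exact integral of the step function over (t, Inf): knots at event times
  knots <- c(t, curve$times[curve$times > t])
  heights <- km_surv_at(curve, knots)   # S on [knots[i], knots[i+1])
  widths <- diff(knots)                 # last height is 0 (curve reaches 0)
  sum(heights[-length(heights)] * widths) / s_t
}

#' Censored Weibull maximum likelihood fit
#'
#' Fits a Weibull distribution to right-censored data by maximum likelihood
#' (censored records contribute survival-function terms).
#'
#' @inheritParams km_curve
#' @return A [weibull_params()] object with the ML scale and shape.
#' @export
fit_weibull_censored <- function(time, event) {
  d <- check_censored(time, event)
  if (sum(d$event) < 2L) stop("need at least 2 observed events to fit a Weibull")
  fit <- survival::survreg(survival::Surv(time, event) ~ 1, data = d,
                           dist = "weibull")
  if (is.na(fit$scale) || !all(is.finite(coef(fit))))
    stop("Weibull fit did not converge: ", paste(fit$iter, collapse = " "))
  # survreg: log(T) = mu + sigma*W  =>  scale = exp(mu), shape = 1/sigma
  weibull_params(scale = unname(exp(coef(fit)[1])), shape = 1 / fit$scale)
}

#' Expected censoring rate P(C < X)
#'
#' Probability that a Weibull censoring time falls below an independent
#' Weibull event time, computed by one-dimensional adaptive quadrature of
#' integral f_X(x) * F_C(x) dx (the inner integral over c has the closed form
#' F_C(x) = 1 - exp(-(x/scale_c)^shape_c)).
#'
#' @param event_params,censor_params [weibull_params()] for the event and
#'   censoring distributions.
#' @return Scalar in (0, 1).
#' @export
censoring_probability <- function(event_params, censor_params) {
  stopifnot(inherits(event_params, "weibull_params"),
            inherits(censor_params, "weibull_params"))
  integrand <- function(x) {
    stats::dweibull(x, shape = event_params$shape, scale = event_params$scale) *
      stats::pweibull(x, shape = censor_params$shape, scale = censor_params$scale)
  }
  # split at the scale knots: a near-degenerate censoring distribution makes
  # F_C a step around its scale that a single (0, Inf) quadrature can miss
  knots <- sort(unique(c(0, event_params$scale, censor_params$scale)))
  pieces <- vapply(seq_len(length(knots) - 1L), function(i) {
    stats::integrate(integrand, knots[i], knots[i + 1L], rel.tol = 1e-9)$value
  }, numeric(1))
  tail <- stats::integrate(integrand, knots[length(knots)], Inf,
                           rel.tol = 1e-9)$value
  min(max(sum(pieces) + tail, 0), 1)
}

#' Solve the censoring shape for a target censoring rate
#'
#' Given the event-time Weibull and the censoring scale, finds the censoring
#' shape such that the expected censoring rate P(C < X) equals `target_rate`,
#' by bracketed root search on the log-shape over \[1e-3, 1e3\].
#'
#' @param target_rate Desired expected censoring rate, strictly in (0, 1).
#' @param event_params [weibull_params()] of the event-time distribution.
#' @param censor_scale Positive scale of the censoring distribution.
#' @return The censoring shape (positive scalar).
#' @export
solve_censoring_shape <- function(target_rate, event_params, censor_scale) {
  stopifnot(is.numeric(target_rate), length(target_rate) == 1L,
            target_rate > 0, target_rate < 1,
            inherits(event_params, "weibull_params"),
            is.numeric(censor_scale), censor_scale > 0)
  f <- function(log_shape) {
    censoring_probability(event_params,
                          weibull_params(censor_scale, exp(log_shape))) -
      target_rate
  }
  lo <- log(1e-3); hi <- log(1e3)
  f_lo <- f(lo); f_hi <- f(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(paste0("no censoring shape in [1e-3, 1e3] achieves rate %.3f ",
                        "at censor scale %g; achievable rates span ",
                        "[%.4f, %.4f] (pick a different censor scale)"),
                 target_rate, censor_scale,
                 min(f_lo, f_hi) + target_rate,
                 max(f_lo, f_hi) + target_rate))
  }
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Default censoring scale for a target censoring rate
#'
#' Solving the censoring shape at a fixed censoring scale can only reach
#' expected censoring rates between 1 - 1/e (about 0.632, the shape -> 0
#' limit, where the censoring CDF tends to 1 - 1/e pointwise) and
#' P(X > censor scale) (the shape -> infinity limit, where censoring becomes
#' degenerate at its scale). This helper picks a censoring scale that makes
#' the requested rate solvable: 1.5x the event scale for rates up to 0.6 and
#' 0.3x the event scale for higher rates.
#'
#' @param censoring_rate Target expected censoring rate in (0, 1).
#' @param event_params [weibull_params()] of the event-time distribution.
#' @return Positive censoring scale.
#' @export
default_censor_scale <- function(censoring_rate, event_params) {
  stopifnot(censoring_rate > 0, censoring_rate < 1)
  if (censoring_rate <= 0.6) 1.5 * event_params$scale
  else 0.3 * event_params$scale
}

#' Generate right-censored Weibull data
#'
#' Draws event times X and censoring times C from independent Weibull
#' distributions and records T = min(X, C) with the event indicator X <= C
#' (ties count as observed events).
#'
#' @param n Number of records.
#' @param event_params,censor_params [weibull_params()] for X and C.
#' @param seed Optional integer seed for reproducibility.
#' @return data.frame with columns `time` (observed T), `event` (logical),
#'   and `true_time` (the latent X, kept for simulation ground truth).
#' @export
generate_censored <- function(n, event_params, censor_params, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rweibull(n, shape = event_params$shape, scale = event_params$scale)
  c_ <- stats::rweibull(n, shape = censor_params$shape, scale = censor_params$scale)
  data.frame(time = pmin(x, c_), event = x <= c_, true_time = x)
}
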