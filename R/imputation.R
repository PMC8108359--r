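## Single-dataset completion strategies for a right-censored covariate.
##
## All imputers take a data.frame with columns `time` (observed value,
## minimum of the true value and the censoring time) and `event` (TRUE if
## observed), keep any other columns untouched, and return the data.frame
## with an added `imputed_time` column (complete-case analysis instead drops
## the censored rows). The method tag is recorded in attr(, "method").

finish_imputed <- function(data, imputed, method) {
  data$imputed_time <- imputed
  attr(data, "method") <- method
  data
}

#' Complete-case analysis (listwise deletion)
#'
#' Drops every record whose covariate value is censored; observed records are
#' returned untouched with `imputed_time` equal to the observed time.
#'
#' @param data data.frame with columns `time` and `event`.
#' @return The observed-record subset with an `imputed_time` column.
#' @export
impute_cc <- function(data) {
  check_censored(data$time, data$event)
  if (!any(data$event)) stop("complete-case analysis requires >= 1 observed record")
  out <- data[as.logical(data$event), , drop = FALSE]
  finish_imputed(out, out$time, "cc")
}

## risk set of a censored value: indices with time strictly greater
risk_set_idx <- function(times, t_l) which(times > t_l)

#' Risk-set imputation
#'
#' Each censored value t is replaced by a uniform random draw from its risk
#' set \{T_j : T_j > t\} (all later times, observed or censored). A censored
#' value equal to the sample maximum has an empty risk set and is kept as if
#' observed (maximum-value convention).
#'
#' @inheritParams impute_cc
#' @param seed Optional integer seed.
#' @return `data` with an `imputed_time` column.
#' @export
impute_rs <- function(data, seed = NULL) {
  check_censored(data$time, data$event)
  if (!is.null(seed)) set.seed(seed)
  imputed <- data$time
  for (l in which(!data$event)) {
    rs <- risk_set_idx(data$time, data$time[l])
    if (length(rs) == 0L) next                     # empty risk set: keep value
    imputed[l] <- data$time[sample(rep(rs, 2L), 1L)[1L]]  # rep guards sample(n)
  }
  finish_imputed(data, imputed, "rs")
}

## conditional probability mass of each event time of a km_curve
## (S just before each event time minus S just after; with the tail closed
## the masses sum to 1)
km_event_mass <- function(curve) {
  s_before <- c(1, curve$surv[-length(curve$surv)])
  s_before - curve$surv
}

## draw one value from the KM curve of the risk set of t_l; exponential tail
## handles residual mass when tail = "exponential"
draw_km <- function(time, event, t_l, tail = c("max_as_event", "exponential")) {
  tail <- match.arg(tail)
  rs <- risk_set_idx(time, t_l)
  if (length(rs) == 0L) return(NA_real_)          # caller applies the convention
  t_rs <- time[rs]; e_rs <- event[rs]
  if (tail == "max_as_event") {
    curve <- km_curve(t_rs, e_rs, max_as_event = TRUE)
    mass <- km_event_mass(curve)
    return(curve$times[sample.int(length(mass), 1L, prob = mass)])
  }
  # exponential tail: keep the raw curve, put the residual mass S(last event)
  # into a shifted exponential fitted to the curve
  if (!any(e_rs)) {                               # no events: draw from tail only
    rate <- 1 / mean(t_rs - t_l)                  # moment fallback, see docs
    return(t_l + stats::rexp(1L, rate = rate))
  }
  curve <- suppressWarnings(km_curve(t_rs, e_rs, max_as_event = FALSE))
  mass <- km_event_mass(curve)
  s_last <- curve$surv[length(curve$surv)]
  rate <- km_tail_rate(curve)
  if (s_last > 0 && stats::runif(1L) < s_last) {
    curve$times[length(curve$times)] + stats::rexp(1L, rate = rate)
  } else {
    curve$times[sample.int(length(mass), 1L, prob = mass)]
  }
}

## exponential tail rate: least squares of log S(t) ~ t (through the origin
## offset) over the last quartile of event times, floored at 2 points
km_tail_rate <- function(curve) {
  k <- length(curve$times)
  n_tail <- max(2L, ceiling(k / 4))
  idx <- seq.int(max(1L, k - n_tail + 1L), k)
  idx <- idx[curve$surv[idx] > 0]
  if (length(idx) < 2L) {                         # single usable point: -log S / t
    i <- idx[length(idx)]
    return(max(-log(curve$surv[i]) / curve$times[i], 1e-12))
  }
  x <- curve$times[idx]; y <- log(curve$surv[idx])
  max(-sum(x * y) / sum(x * x), 1e-12)            # slope of y ~ x through 0
}

#' Kaplan-Meier imputation
#'
#' Each censored value t is replaced by an event time drawn from the
#' Kaplan-Meier curve fitted to its risk set, with probability equal to that
#' time's conditional probability mass. The risk-set curve is closed by
#' treating its largest time as observed. Empty risk sets follow the
#' maximum-value convention (value kept).
#'
#' @inheritParams impute_rs
#' @return `data` with an `imputed_time` column.
#' @export
impute_km <- function(data, seed = NULL) {
  check_censored(data$time, data$event)
  if (!is.null(seed)) set.seed(seed)
  imputed <- data$time
  for (l in which(!data$event)) {
    v <- draw_km(data$time, as.logical(data$event), data$time[l], "max_as_event")
    if (!is.na(v)) imputed[l] <- v
  }
  finish_imputed(data, imputed, "km")
}

#' Kaplan-Meier imputation with an exponential tail
#'
#' As [impute_km()], but when the risk-set survival curve does not reach zero
#' (its largest member is censored) the residual mass beyond the last event
#' time is modelled by an exponential distribution fitted to the tail of the
#' curve (least squares on log S(t) over the last quartile of event times),
#' and tail draws come from that exponential shifted past the last event time.
#'
#' @inheritParams impute_rs
#' @return `data` with an `imputed_time` column.
#' @export
impute_kme <- function(data, seed = NULL) {
  check_censored(data$time, data$event)
  if (!is.null(seed)) set.seed(seed)
  imputed <- data$time
  for (l in which(!data$event)) {
    v <- draw_km(data$time, as.logical(data$event), data$time[l], "exponential")
    if (!is.na(v)) imputed[l] <- v
  }
  finish_imputed(data, imputed, "kme")
}

#' Mean-residual-life imputation (conditional single imputation)
#'
#' Deterministic: fits one Kaplan-Meier curve on the full dataset (largest
#' time treated as observed) and replaces each censored value t by
#' t + mrl(t), the expected remaining time to the event. Because it is
#' deterministic it must be embedded in bootstrap resampling to be used for
#' multiple imputation (see [run_mi()]).
#'
#' @inheritParams impute_cc
#' @return `data` with an `imputed_time` column.
#' @export
impute_mrl <- function(data) {
  check_censored(data$time, data$event)
  imputed <- data$time
  cens <- which(!data$event)
  if (length(cens)) {
    curve <- km_curve(data$time, data$event, max_as_event = TRUE)
    for (l in cens) {
      t_l <- data$time[l]
      if (km_surv_at(curve, t_l) <= 0) next       # at/after the max: keep value
      imputed[l] <- t_l + mean_residual_life(curve, t_l)
    }
  }
  finish_imputed(data, imputed, "mrl")
}

#' Predictive mean matching
#'
#' Treats censored values as missing at random: a linear model of time on the
#' remaining covariates is fitted to the observed records, each missing record
#' is matched to its `donors` nearest observed records by predicted mean, and
#' one donor's observed time is drawn uniformly. With no covariates the draw
#' falls back to an unconditional draw from the observed times. Unlike the
#' censoring-aware imputers, pmm values need not exceed the censored time.
#'
#' @inheritParams impute_rs
#' @param covariates Character vector of covariate column names used by the
#'   predictive model (default: none, unconditional draws).
#' @param donors Size of the donor pool (default 5, common MI practice).
#' @return `data` with an `imputed_time` column.
#' @export
impute_pmm <- function(data, covariates = character(), seed = NULL, donors = 5L) {
  check_censored(data$time, data$event)
  obs <- which(as.logical(data$event)); mis <- which(!data$event)
  if (length(obs) < donors)
    stop(sprintf("need >= %d observed records for a donor pool of %d",
                 donors, donors))
  if (!is.null(seed)) set.seed(seed)
  imputed <- data$time
  if (length(mis)) {
    if (length(covariates)) {
      fml <- stats::reformulate(covariates, response = "time")
      fit <- stats::lm(fml, data = data[obs, , drop = FALSE])
      pred_obs <- stats::predict(fit)
      pred_mis <- stats::predict(fit, newdata = data[mis, , drop = FALSE])
      for (k in seq_along(mis)) {
        pool <- obs[order(abs(pred_obs - pred_mis[k]))[seq_len(donors)]]
        imputed[mis[k]] <- data$time[sample(rep(pool, 2L), 1L)[1L]]
      }
    } else {
      imputed[mis] <- data$time[sample(rep(obs, 2L), length(mis), replace = TRUE)]
    }
  }
  finish_imputed(data, imputed, "pmm")
}
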