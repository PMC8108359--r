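## Binomial GLMM with logit link, fixed effects, Gaussian random intercepts
## and an observation-level random effect (OLRE) for overdispersion.
##
## Estimation is by Laplace approximation through lme4::glmer. Continuous
## fixed-effect covariates are standardised internally (a survival time on
## the scale of hundreds of days otherwise dominates the Hessian scaling);
## coefficients and their covariance are transformed back exactly, so the
## reported fit is on the original covariate scale.

#' Fit a binomial logit GLMM to per-sample counts
#'
#' Models `successes` out of `totals` per sample with a logit link, the named
#' fixed-effect covariates, optional Gaussian random intercepts for grouping
#' factors, and (by default) an observation-level random intercept capturing
#' overdispersion relative to the binomial.
#'
#' @param data data.frame with one row per sample holding the covariate and
#'   grouping columns.
#' @param successes,totals Nonnegative integer vectors, one entry per row of
#'   `data`, with `successes <= totals` and `totals > 0`.
#' @param fixed Character vector of fixed-effect column names (intercept is
#'   implicit).
#' @param random Character vector of grouping-factor column names receiving
#'   independent Gaussian random intercepts.
#' @param olre Include the observation-level random effect (default `TRUE`).
#' @return Object of class `glmm_fit`: `coefficients` (named), `vcov`
#'   (matrix), `re_variances` (named, `.olre` is the observation-level term),
#'   `loglik`, `converged`, `n` (samples), `p` (number of coefficients),
#'   `messages`.
#' @export
fit_binomial_glmm <- function(data, successes, totals, fixed,
                              random = character(), olre = TRUE) {
  stopifnot(is.data.frame(data), length(successes) == nrow(data),
            length(totals) == nrow(data))
  if (any(totals <= 0)) stop("all totals must be positive")
  if (any(successes < 0) || any(successes > totals))
    stop("successes must lie in [0, totals]")
  if (!all(fixed %in% names(data)))
    stop("fixed-effect columns missing from data: ",
         paste(setdiff(fixed, names(data)), collapse = ", "))
  if (!all(random %in% names(data)))
    stop("grouping columns missing from data: ",
         paste(setdiff(random, names(data)), collapse = ", "))
  if (all(successes == totals) || all(successes == 0))
    return(structure(list(coefficients = NULL, vcov = NULL,
                          re_variances = NULL, loglik = NA_real_,
                          converged = FALSE, n = nrow(data),
                          p = length(fixed) + 1L,
                          messages = "degenerate response: complete separation at the boundary"),
                     class = "glmm_fit"))
  if (!olre && length(random) == 0L)
    return(fit_binomial_glm(data, successes, totals, fixed))

  d <- data[, union(fixed, random), drop = FALSE]
  d$.y <- successes
  d$.n <- totals
  d$.olre <- factor(seq_len(nrow(d)))

  # standardise continuous covariates; remember the linear map
  scales <- rep(1, length(fixed)); names(scales) <- fixed
  for (v in fixed) {
    if (is.numeric(d[[v]]) && length(unique(d[[v]])) > 2L) {
      s <- stats::sd(d[[v]])
      if (is.finite(s) && s > 0) { d[[v]] <- d[[v]] / s; scales[v] <- s }
    }
  }

  re_terms <- c(sprintf("(1 | %s)", random), if (olre) "(1 | .olre)")
  fml <- stats::as.formula(paste("cbind(.y, .n - .y) ~",
                                 paste(c(fixed, re_terms), collapse = " + ")))
  messages <- character()
  fit <- withCallingHandlers(
    tryCatch(suppressMessages(
      lme4::glmer(fml, data = d, family = stats::binomial())),
      error = function(e) e),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, vcov = NULL,
                          re_variances = NULL, loglik = NA_real_,
                          converged = FALSE, n = nrow(d),
                          p = length(fixed) + 1L,
                          messages = conditionMessage(fit)),
                     class = "glmm_fit"))
  }

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  # collinearity check on the fixed-effects model matrix
  X <- stats::model.matrix(stats::reformulate(fixed), d)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effects design; check columns: ",
         paste(fixed, collapse = ", "))
  # undo the covariate standardisation: beta_raw = beta_std / s
  full_scales <- c("(Intercept)" = 1, scales)[names(beta)]
  beta <- beta / full_scales
  V <- V / tcrossprod(full_scales)
  dimnames(V) <- list(names(beta), names(beta))

  vc <- lme4::VarCorr(fit)
  re_var <- vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1))
  re_var[re_var < 1e-8] <- 0

  # scaling-related warnings are benign after internal standardisation, but
  # failure-to-converge / degenerate-Hessian messages are honest non-convergence
  all_msgs <- c(messages, unlist(fit@optinfo$conv$lme4$messages))
  bad <- grepl("failed to converge|unidentifiable|degenerate|Hessian",
               all_msgs, ignore.case = TRUE)
  conv_ok <- fit@optinfo$conv$opt == 0 && !any(bad)

  structure(list(coefficients = beta, vcov = V, re_variances = re_var,
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = conv_ok, n = nrow(d), p = length(beta),
                 messages = messages),
            class = "glmm_fit")
}

## plain binomial GLM (no random effects): used when olre = FALSE and no
## grouping factors are requested
fit_binomial_glm <- function(data, successes, totals, fixed) {
  d <- data[, fixed, drop = FALSE]
  d$.y <- successes
  d$.n <- totals
  fml <- stats::as.formula(paste("cbind(.y, .n - .y) ~",
                                 paste(fixed, collapse = " + ")))
  fit <- stats::glm(fml, data = d, family = stats::binomial())
  X <- stats::model.matrix(stats::reformulate(fixed), d)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effects design; check columns: ",
         paste(fixed, collapse = ", "))
  structure(list(coefficients = stats::coef(fit),
                 vcov = as.matrix(stats::vcov(fit)),
                 re_variances = numeric(0),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = fit$converged, n = nrow(d),
                 p = length(stats::coef(fit)),
                 messages = character()),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial logit GLMM fit",
      if (!x$converged) "(NOT converged)", "\n")
  if (!is.null(x$coefficients)) {
    print(cbind(estimate = x$coefficients, se = sqrt(diag(x$vcov))))
    if (length(x$re_variances)) {
      cat("Random-effect variances:\n"); print(x$re_variances)
    }
  }
  invisible(x)
}

#' Wald test for one coefficient
#'
#' Computes the statistic estimate/SE and a two-sided p-value under a normal
#' reference (`df = NULL`, used for direct single-dataset fits) or a
#' Student-t reference with `df` degrees of freedom (supplied by Rubin
#' pooling).
#'
#' @param fit A `glmm_fit`.
#' @param coef Name of the coefficient to test.
#' @param df Degrees of freedom for the t reference, or `NULL` for normal.
#' @return List with `statistic` and `p_value`.
#' @export
wald_test <- function(fit, coef, df = NULL) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (is.null(fit$coefficients) || !(coef %in% names(fit$coefficients)))
    stop("coefficient not present in fit: ", coef)
  se <- sqrt(fit$vcov[coef, coef])
  if (!is.finite(se) || se <= 0) stop("zero or undefined standard error for ", coef)
  stat <- unname(fit$coefficients[coef] / se)
  p <- if (is.null(df)) 2 * stats::pnorm(-abs(stat))
       else             2 * stats::pt(-abs(stat), df = df)
  list(statistic = stat, p_value = p)
}
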