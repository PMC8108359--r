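## Multiple-imputation orchestration: classical MI and the bootstrap
## resampling variant, Rubin's-rules pooling with the Barnard-Rubin
## small-sample degrees of freedom, and the per-cluster differential
## abundance workflow with Benjamini-Hochberg correction.

#' Pool coefficient estimates across imputations with Rubin's rules
#'
#' Combines the m per-imputation estimates q_i and squared standard errors
#' u_i of one coefficient: pooled estimate qbar = mean(q), within-imputation
#' variance W = mean(u), between-imputation variance B = var(q), total
#' variance T = W + (1 + 1/m) B. Degrees of freedom follow the Barnard-Rubin
#' small-sample formula, bounded by the complete-data degrees of freedom
#' `df_com` (number of samples minus number of coefficients). The p-value is
#' the two-sided t tail of qbar / sqrt(T).
#'
#' @param fits List of converged `glmm_fit` objects (m >= 2), or `NULL`s for
#'   failed rounds (dropped with a warning).
#' @param coef Name of the coefficient to pool.
#' @param df_com Complete-data degrees of freedom; defaults to n - p from the
#'   first converged fit.
#' @return Object of class `pooled_result`: `estimate`, `within_var`,
#'   `between_var`, `total_var`, `df`, `statistic`, `p_value`, `ci` (95%),
#'   `m` (imputations pooled).
#' @export
pool_rubin <- function(fits, coef, df_com = NULL) {
  ok <- vapply(fits, function(f)
    inherits(f, "glmm_fit") && isTRUE(f$converged) &&
      coef %in% names(f$coefficients), logical(1))
  if (!any(ok)) stop("no converged fits to pool")
  if (sum(!ok) > 0)
    warning(sprintf("dropping %d non-converged fit(s) from pooling", sum(!ok)))
  fits <- fits[ok]
  m <- length(fits)
  if (m < 2L) stop("Rubin pooling requires at least 2 converged fits")
  q <- vapply(fits, function(f) unname(f$coefficients[coef]), numeric(1))
  u <- vapply(fits, function(f) f$vcov[coef, coef], numeric(1))
  if (is.null(df_com)) df_com <- fits[[1]]$n - fits[[1]]$p

  qbar <- mean(q)
  W <- mean(u)
  B <- stats::var(q)
  Tvar <- W + (1 + 1 / m) * B

  # Barnard-Rubin adjusted degrees of freedom
  lambda <- (1 + 1 / m) * B / Tvar
  if (lambda < .Machine$double.eps) {
    df <- df_com
  } else {
    df_old <- (m - 1) / lambda^2
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
    df <- df_old * df_obs / (df_old + df_obs)
  }

  stat <- qbar / sqrt(Tvar)
  p <- 2 * stats::pt(-abs(stat), df = df)
  half <- stats::qt(0.975, df = df) * sqrt(Tvar)
  structure(list(estimate = qbar, within_var = W, between_var = B,
                 total_var = Tvar, df = df, statistic = stat, p_value = p,
                 ci = c(qbar - half, qbar + half), m = m),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf(paste0("Rubin-pooled result (m = %d)\n",
                     "  estimate %.6g  (95%% CI %.6g to %.6g)\n",
                     "  total var %.3g = within %.3g + (1+1/m) x between %.3g\n",
                     "  t = %.3f on df = %.1f, p = %.4g\n"),
              x$m, x$estimate, x$ci[1], x$ci[2],
              x$total_var, x$within_var, x$between_var,
              x$statistic, x$df, x$p_value))
  invisible(x)
}

## stratified bootstrap: resample observed and censored records separately so
## no bootstrap dataset is all-censored
bootstrap_stratified <- function(data) {
  idx_e <- which(as.logical(data$event))
  idx_c <- which(!data$event)
  take <- c(if (length(idx_e)) idx_e[sample.int(length(idx_e),
                                                length(idx_e), replace = TRUE)],
            if (length(idx_c)) idx_c[sample.int(length(idx_c),
                                                length(idx_c), replace = TRUE)])
  data[take, , drop = FALSE]
}

impute_with <- function(data, method, covariates) {
  switch(method,
         rs  = impute_rs(data),
         km  = impute_km(data),
         kme = impute_kme(data),
         mrl = impute_mrl(data),
         pmm = impute_pmm(data, covariates = covariates),
         stop("unknown imputation method: ", method))
}

#' Multiple imputation of a censored covariate with GLMM analysis
#'
#' Runs the three MI steps for one cell population: (1) generate m completed
#' datasets with the chosen imputation method; (2) fit the binomial logit
#' GLMM to each; (3) pool the tested coefficient with Rubin's rules. In
#' classical mode each round imputes the full dataset; in resampling mode
#' each round first draws a bootstrap sample (stratified on the event
#' indicator), then imputes, then fits. Mean-residual-life imputation is
#' deterministic, so it is only valid with resampling: every classical
#' imputed dataset would be identical and the between-imputation variance
#' would vanish.
#'
#' @param data data.frame with columns `time`, `event`, the covariate columns
#'   and any grouping columns.
#' @param successes,totals Per-sample counts (aligned with `data` rows).
#' @param method One of `"rs"`, `"km"`, `"kme"`, `"mrl"`, `"pmm"`.
#' @param coef Coefficient to test (default `"time"`, the imputed covariate;
#'   the imputed values enter the model under the name `time`).
#' @param fixed Fixed-effect columns besides the imputed time (e.g. a binary
#'   group covariate).
#' @param random Grouping columns for random intercepts.
#' @param olre Include the observation-level random effect (default `TRUE`).
#' @param m Number of imputations (default 50; results stabilise around 50).
#' @param seed Master seed; per-round seeds are derived deterministically.
#' @param resampling Use the bootstrap variant (default `TRUE` only for mrl,
#'   where it is required).
#' @param min_converged Minimum fraction of converged rounds required to pool
#'   (default 0.8); below it an error is raised.
#' @return A `pooled_result` for `coef`.
#' @export
run_mi <- function(data, successes, totals, method,
                   coef = "time", fixed = character(), random = character(),
                   olre = TRUE, m = 50L, seed = NULL,
                   resampling = identical(method, "mrl"),
                   min_converged = 0.8) {
  method <- match.arg(method, c("rs", "km", "kme", "mrl", "pmm"))
  if (m < 2L) stop("multiple imputation requires m >= 2")
  if (method == "mrl" && !resampling)
    stop("mrl imputation is deterministic and would not work in classical ",
         "multiple imputation (each imputed dataset would be the same); ",
         "use resampling = TRUE")
  if (!is.null(seed)) set.seed(seed)
  round_seeds <- sample.int(.Machine$integer.max - 1L, m)

  d <- data
  d$.y <- successes
  d$.n <- totals

  fits <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(round_seeds[i])
    di <- if (resampling) bootstrap_stratified(d) else d
    di <- impute_with(di, method, covariates = fixed)
    di$time <- di$imputed_time
    fits[[i]] <- tryCatch(
      fit_binomial_glmm(di, di$.y, di$.n, fixed = c("time", fixed),
                        random = random, olre = olre),
      error = function(e) NULL)
  }
  n_conv <- sum(vapply(fits, function(f)
    inherits(f, "glmm_fit") && isTRUE(f$converged), logical(1)))
  if (n_conv < max(2L, ceiling(min_converged * m)))
    stop(sprintf("only %d of %d imputation fits converged (< %d%%)",
                 n_conv, m, round(100 * min_converged)))
  pool_rubin(fits, coef = coef, df_com = nrow(d) - (length(fixed) + 2L))
}

#' Differential abundance testing against a censored covariate
#'
#' Runs the per-cluster DA workflow on a cluster-by-sample count matrix: for
#' every cluster, the response is (cluster count, sample total) and the
#' binomial logit GLMM with an observation-level random effect is fitted
#' against the (imputed) survival time and any further covariates. For the
#' multiple-imputation methods the per-cluster result is Rubin-pooled over m
#' completions; complete-case analysis deletes censored samples and fits the
#' GLMM once (normal-reference Wald test). P-values are Benjamini-Hochberg
#' adjusted across clusters.
#'
#' @param counts Cluster-by-sample matrix of nonnegative integer counts with
#'   cluster ids as rownames; column order must match `metadata` rows.
#' @param metadata data.frame with one row per sample: columns `time`,
#'   `event`, plus covariate/grouping columns.
#' @param method One of `"cc"`, `"rs"`, `"km"`, `"kme"`, `"mrl"`, `"pmm"`.
#' @param fixed Additional fixed-effect columns (the time covariate is always
#'   included and is the tested coefficient by default).
#' @param random Grouping columns for random intercepts.
#' @param coef Tested coefficient (default `"time"`).
#' @inheritParams run_mi
#' @return data.frame (one row per cluster, sorted by adjusted p-value):
#'   `cluster_id`, `coef`, `estimate`, `se`, `df`, `statistic`, `p_value`,
#'   `adj_p_value`, `m_converged`. Clusters with all-zero counts get an NA
#'   row and a warning.
#' @export
run_da <- function(counts, metadata, method, fixed = character(),
                   random = character(), coef = "time", m = 50L,
                   seed = NULL, olre = TRUE,
                   resampling = identical(method, "mrl")) {
  method <- match.arg(method, c("cc", "rs", "km", "kme", "mrl", "pmm"))
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(metadata))
    stop("metadata rows must match count matrix columns")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cluster", seq_len(nrow(counts)))
  check_censored(metadata$time, metadata$event)
  totals <- colSums(counts)
  if (!is.null(seed)) set.seed(seed)
  cluster_seeds <- sample.int(.Machine$integer.max - 1L, nrow(counts))

  na_row <- function(id) data.frame(
    cluster_id = id, coef = coef, estimate = NA_real_, se = NA_real_,
    df = NA_real_, statistic = NA_real_, p_value = NA_real_,
    adj_p_value = NA_real_, m_converged = NA_integer_,
    stringsAsFactors = FALSE)

  rows <- lapply(seq_len(nrow(counts)), function(i) {
    id <- rownames(counts)[i]
    y <- counts[i, ]
    if (all(y == 0)) {
      warning("cluster with all-zero counts skipped: ", id)
      return(na_row(id))
    }
    res <- tryCatch({
      if (method == "cc") {
        md <- metadata
        md$.y <- y; md$.n <- totals
        md <- md[as.logical(md$event), , drop = FALSE]
        fit <- fit_binomial_glmm(md, md$.y, md$.n, fixed = c("time", fixed),
                                 random = random, olre = olre)
        if (!fit$converged) stop("fit did not converge")
        wt <- wald_test(fit, coef)
        se <- sqrt(fit$vcov[coef, coef])
        data.frame(cluster_id = id, coef = coef,
                   estimate = unname(fit$coefficients[coef]), se = se,
                   df = NA_real_, statistic = wt$statistic,
                   p_value = wt$p_value, adj_p_value = NA_real_,
                   m_converged = 1L, stringsAsFactors = FALSE)
      } else {
        pr <- run_mi(metadata, y, totals, method = method, coef = coef,
                     fixed = fixed, random = random, olre = olre, m = m,
                     seed = cluster_seeds[i], resampling = resampling)
        data.frame(cluster_id = id, coef = coef, estimate = pr$estimate,
                   se = sqrt(pr$total_var), df = pr$df,
                   statistic = pr$statistic, p_value = pr$p_value,
                   adj_p_value = NA_real_, m_converged = pr$m,
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      warning(sprintf("cluster %s: %s", id, conditionMessage(e)))
      na_row(id)
    })
    res
  })
  out <- do.call(rbind, rows)
  out$adj_p_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$adj_p_value, out$p_value), , drop = FALSE]
}
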