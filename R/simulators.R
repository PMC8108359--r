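## Synthetic-data generators: the single-cluster binomial GLMM world used to
## check statistical validity of the imputation methods, and the
## multi-cluster Dirichlet-multinomial world with injected covariate
## associations used to benchmark differential abundance performance.

#' Configuration for the single-cluster simulation
#'
#' One cell population observed across samples. Counts are binomial with a
#' logit-linear mean in a censored continuous covariate T (survival time), a
#' balanced binary covariate Z and a Gaussian observation-level random
#' effect: logit(p_j) = beta0 + beta1 T_j + beta2 Z_j + R_j,
#' Y_j ~ Bin(n_j, p_j), n_j ~ U(n_range). T is Weibull and right-censored by
#' an independent Weibull censoring time.
#'
#' Default coefficients are beta0 = -2, beta1 = -1e-4, beta2 = 1 with random
#' effect variance 1 and totals uniform on \[1e4, 1e5\]. The default Weibull
#' parameters (event scale 1000, shape 1.2; censoring scale 1000) emulate a
#' clinical time-to-event scale of roughly three years in days; they are this
#' package's defaults, chosen as plausible for cytometry survival studies.
#'
#' @param beta0,beta1,beta2 Regression coefficients (intercept, censored
#'   covariate, binary covariate).
#' @param sigma2 Variance of the observation-level random effect.
#' @param n_range Length-2 range of per-sample cell totals (uniform).
#' @param n_samples Number of samples.
#' @param event_params [weibull_params()] of the survival-time distribution.
#' @param censor_scale Scale of the censoring Weibull; default picked by
#'   [default_censor_scale()] so the target rate is solvable.
#' @param censoring_rate Expected censoring rate in (0, 1); the censoring
#'   shape is solved to hit it. Alternatively pass `censor_shape` directly.
#' @param censor_shape Censoring shape, used when `censoring_rate` is `NULL`.
#' @return Object of class `single_cluster_config`.
#' @export
single_cluster_config <- function(beta0 = -2, beta1 = -1e-4, beta2 = 1,
                                  sigma2 = 1, n_range = c(1e4, 1e5),
                                  n_samples = 100L,
                                  event_params = weibull_params(1000, 1.2),
                                  censor_scale = NULL,
                                  censoring_rate = 0.3,
                                  censor_shape = NULL) {
  stopifnot(sigma2 >= 0, length(n_range) == 2L, n_range[1] >= 1,
            n_range[1] <= n_range[2], n_samples >= 1)
  if (is.null(censor_shape)) {
    stopifnot(!is.null(censoring_rate))
    if (is.null(censor_scale))
      censor_scale <- default_censor_scale(censoring_rate, event_params)
    censor_shape <- solve_censoring_shape(censoring_rate, event_params,
                                          censor_scale)
  } else if (is.null(censor_scale)) {
    censor_scale <- 1.5 * event_params$scale
  }
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, sigma2 = sigma2,
                 n_range = n_range, n_samples = as.integer(n_samples),
                 event_params = event_params,
                 censor_params = weibull_params(censor_scale, censor_shape)),
            class = "single_cluster_config")
}

#' Simulate the single-cluster dataset
#'
#' @param cfg A [single_cluster_config()].
#' @param seed Optional integer seed.
#' @return data.frame with one row per sample: `sample_id`, `y` (cluster
#'   count), `n` (total cells), `time` (observed, censored T), `event`,
#'   `true_time` (latent survival time), `z` (balanced binary covariate).
#' @export
simulate_single_cluster <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "single_cluster_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_samples
  surv <- generate_censored(n, cfg$event_params, cfg$censor_params)
  z <- rep_len(c(0, 1), n)[sample.int(n)]           # balanced binary covariate
  r <- stats::rnorm(n, 0, sqrt(cfg$sigma2))
  totals <- round(stats::runif(n, cfg$n_range[1], cfg$n_range[2]))
  p <- stats::plogis(cfg$beta0 + cfg$beta1 * surv$true_time + cfg$beta2 * z + r)
  y <- stats::rbinom(n, totals, p)
  data.frame(sample_id = paste0("s", seq_len(n)), y = y, n = totals,
             time = surv$time, event = surv$event,
             true_time = surv$true_time, z = z,
             stringsAsFactors = FALSE)
}

#' Fit a Dirichlet-multinomial distribution to a count matrix
#'
#' Maximum-likelihood concentration parameters alpha by the fixed-point
#' iteration of the DM log-likelihood (each update is a ratio of digamma
#' sums), initialised from method-of-moments proportions.
#'
#' @param counts Cluster-by-sample matrix of nonnegative integer counts
#'   (>= 2 clusters, >= 2 samples).
#' @param max_iter,tol Iteration controls.
#' @return Numeric vector of concentration parameters, one per cluster.
#' @export
fit_dirichlet_multinomial <- function(counts, max_iter = 1000L, tol = 1e-8) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least 2 clusters and 2 samples")
  if (any(counts < 0)) stop("counts must be nonnegative")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("samples with zero total counts")
  K <- nrow(counts)
  prop <- sweep(counts, 2, totals, "/")
  p_bar <- rowMeans(prop)
  always_zero <- p_bar == 0
  if (any(always_zero)) {
    warning(sum(always_zero), " cluster(s) with all-zero counts: alpha floored")
    p_bar[always_zero] <- 1e-8
    p_bar <- p_bar / sum(p_bar)
  }
  # moment start for the total concentration from the variance of proportions
  v <- apply(prop, 1, stats::var)
  keep <- p_bar > 1e-6 & v > 0
  s0 <- if (any(keep)) stats::median(p_bar[keep] * (1 - p_bar[keep]) / v[keep] - 1)
        else K
  alpha <- p_bar * max(s0, K)

  for (it in seq_len(max_iter)) {
    a0 <- sum(alpha)
    num <- rowSums(digamma(counts + alpha)) - ncol(counts) * digamma(alpha)
    den <- sum(digamma(totals + a0)) - ncol(counts) * digamma(a0)
    alpha_new <- alpha * num / den
    alpha_new[!is.finite(alpha_new) | alpha_new <= 0] <- 1e-8
    if (max(abs(alpha_new - alpha) / pmax(alpha, 1e-8)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  unname(alpha)
}

#' Solve association coefficients from border constraints
#'
#' Converts target mean proportions at the covariate borders into the
#' logit-linear coefficients of the association: beta0 = logit(pi at T = 0,
#' Z = 0); beta1 = (logit(pi at t_max) - beta0) / t_max; beta2 =
#' logit(pi at T = 0 plus the specified mean-abundance difference) - beta0.
#'
#' @param pi_t0 Mean proportion of the cluster at T = 0 (Z = 0), in (0, 1).
#' @param pi_tmax Mean proportion at T = t_max (Z = 0), in (0, 1).
#' @param t_max Positive covariate value at which `pi_tmax` holds.
#' @param z_effect Difference in mean proportion at T = 0 between Z = 1 and
#'   Z = 0 (default 0: no binary-covariate association).
#' @return Named numeric vector `c(beta0, beta1, beta2)`.
#' @export
solve_association_betas <- function(pi_t0, pi_tmax, t_max, z_effect = 0) {
  stopifnot(pi_t0 > 0, pi_t0 < 1, pi_tmax > 0, pi_tmax < 1)
  if (t_max <= 0) stop("t_max must be positive")
  pi_z <- pi_t0 + z_effect
  if (pi_z <= 0 || pi_z >= 1)
    stop("pi_t0 + z_effect must stay strictly inside (0, 1)")
  beta0 <- stats::qlogis(pi_t0)
  beta1 <- (stats::qlogis(pi_tmax) - beta0) / t_max
  beta2 <- stats::qlogis(pi_z) - beta0
  c(beta0 = beta0, beta1 = unname(beta1), beta2 = unname(beta2))
}

#' Default baseline concentration parameters
#'
#' A plausible cytometry-like composition: K clusters with geometrically
#' decaying expected proportions (a few common populations, a long tail of
#' rare ones) and a given total concentration controlling overdispersion.
#' These defaults stand in for concentrations that would in practice be
#' fitted from a real cluster-by-sample matrix with
#' [fit_dirichlet_multinomial()].
#'
#' @param n_clusters Number of clusters (default 20).
#' @param total_concentration Sum of the concentration parameters (default
#'   30; smaller means more across-sample variability of proportions).
#' @param decay Geometric decay rate of expected proportions (default 0.25).
#' @return Positive numeric vector of length `n_clusters`.
#' @export
default_base_alpha <- function(n_clusters = 20L, total_concentration = 30,
                               decay = 0.25) {
  w <- exp(-decay * seq_len(n_clusters))
  total_concentration * w / sum(w)
}

#' Configuration for the multi-cluster Dirichlet-multinomial simulation
#'
#' Counts per sample follow a Dirichlet-multinomial whose concentration
#' parameters depend on a censored continuous covariate T and a binary
#' covariate Z for the associated clusters:
#' A_ij = logit^-1(beta0_i + beta1_i T_j + beta2_i Z_j) * A_sum_j, with the
#' remaining clusters at their baseline concentration. Associated clusters
#' come in compensating pairs of similar baseline proportion with mirrored
#' border constraints, so the concentration sum is exactly conserved at T = 0
#' and T = t_max and drifts only slightly in between. All concentrations are
#' multiplied by `concentration_multiplier` (default 5), which preserves
#' every expected proportion while reducing the across-sample variance of the
#' proportions.
#'
#' @param base_alpha Baseline concentration parameters, one per cluster.
#' @param assoc List of association descriptors; each is a list with elements
#'   `pair` (two cluster indices of similar baseline proportion), and
#'   optionally `pi_t0`, `pi_tmax` (border proportions for the first cluster
#'   of the pair; defaults are the pair's baseline proportions) and
#'   `z_effect` (difference in mean proportion at T = 0; default 0). The
#'   second cluster of the pair receives the mirrored constraints.
#' @param n_samples Number of samples.
#' @param totals_range Length-2 range of per-sample cell totals (uniform).
#' @param concentration_multiplier Factor applied to all concentrations
#'   (default 5).
#' @param t_max Border value of the covariate for the beta solve; default is
#'   the 99.5% quantile of the event-time distribution.
#' @inheritParams single_cluster_config
#' @return Object of class `dm_config`.
#' @export
dm_config <- function(base_alpha = default_base_alpha(),
                      assoc = list(),
                      n_samples = 100L,
                      totals_range = c(1e4, 1e5),
                      concentration_multiplier = 5,
                      event_params = weibull_params(1000, 1.2),
                      censor_scale = NULL,
                      censoring_rate = 0.3,
                      censor_shape = NULL,
                      t_max = NULL) {
  stopifnot(all(base_alpha > 0), n_samples >= 1,
            concentration_multiplier > 0)
  if (is.null(censor_shape)) {
    stopifnot(!is.null(censoring_rate))
    if (is.null(censor_scale))
      censor_scale <- default_censor_scale(censoring_rate, event_params)
    censor_shape <- solve_censoring_shape(censoring_rate, event_params,
                                          censor_scale)
  } else if (is.null(censor_scale)) {
    censor_scale <- 1.5 * event_params$scale
  }
  if (is.null(t_max))
    t_max <- stats::qweibull(0.995, shape = event_params$shape,
                             scale = event_params$scale)
  K <- length(base_alpha)
  pi_base <- base_alpha / sum(base_alpha)
  used <- integer(0)
  assoc <- lapply(assoc, function(a) {
    stopifnot(length(a$pair) == 2L, all(a$pair %in% seq_len(K)))
    if (any(a$pair %in% used))
      stop("a cluster appears in more than one associated pair")
    used <<- c(used, a$pair)
    if (is.null(a$pi_t0)) a$pi_t0 <- pi_base[a$pair[1]]
    if (is.null(a$pi_tmax)) a$pi_tmax <- pi_base[a$pair[2]]
    if (is.null(a$z_effect)) a$z_effect <- 0
    a
  })
  structure(list(base_alpha = base_alpha, assoc = assoc,
                 n_samples = as.integer(n_samples),
                 totals_range = totals_range,
                 concentration_multiplier = concentration_multiplier,
                 event_params = event_params,
                 censor_params = weibull_params(censor_scale, censor_shape),
                 t_max = t_max),
            class = "dm_config")
}

#' Simulate a multi-cluster count matrix with injected associations
#'
#' Draws the covariates, builds the per-sample concentration matrix from the
#' solved association coefficients, and samples counts Dirichlet-
#' multinomially (Gamma-normalised Dirichlet proportions followed by a
#' multinomial draw).
#'
#' @param cfg A [dm_config()].
#' @param seed Optional integer seed.
#' @return List with `counts` (cluster-by-sample integer matrix), `metadata`
#'   (data.frame: `sample_id`, `time`, `event`, `true_time`, `z`), `truth`
#'   (data.frame: `cluster_id`, `t_associated`, `z_associated`, `beta0`,
#'   `beta1`, `beta2`), and `alpha` (the concentration matrix used).
#' @export
simulate_multicluster <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "dm_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- length(cfg$base_alpha)
  N <- cfg$n_samples
  mult <- cfg$concentration_multiplier

  surv <- generate_censored(N, cfg$event_params, cfg$censor_params)
  z <- rep_len(c(0, 1), N)[sample.int(N)]
  totals <- round(stats::runif(N, cfg$totals_range[1], cfg$totals_range[2]))

  alpha_base <- cfg$base_alpha * mult
  a_sum <- sum(alpha_base)

  betas <- matrix(0, nrow = K, ncol = 3,
                  dimnames = list(NULL, c("beta0", "beta1", "beta2")))
  t_assoc <- z_assoc <- rep(FALSE, K)
  for (a in cfg$assoc) {
    b1 <- solve_association_betas(a$pi_t0, a$pi_tmax, cfg$t_max, a$z_effect)
    b2 <- solve_association_betas(a$pi_tmax, a$pi_t0, cfg$t_max, -a$z_effect)
    betas[a$pair[1], ] <- b1
    betas[a$pair[2], ] <- b2
    t_assoc[a$pair] <- b1["beta1"] != 0
    z_assoc[a$pair] <- a$z_effect != 0
  }
  assoc_idx <- unique(unlist(lapply(cfg$assoc, `[[`, "pair")))

  A <- matrix(rep(alpha_base, N), nrow = K)
  for (i in assoc_idx) {
    A[i, ] <- stats::plogis(betas[i, 1] + betas[i, 2] * surv$true_time +
                              betas[i, 3] * z) * a_sum
  }
  if (any(A <= 0)) stop("non-positive concentration parameter produced")

  counts <- matrix(0L, nrow = K, ncol = N,
                   dimnames = list(paste0("cluster", seq_len(K)),
                                   paste0("s", seq_len(N))))
  for (j in seq_len(N)) {
    g <- stats::rgamma(K, shape = A[, j], rate = 1)
    pi_j <- g / sum(g)
    counts[, j] <- stats::rmultinom(1, size = totals[j], prob = pi_j)
  }

  list(counts = counts,
       metadata = data.frame(sample_id = colnames(counts),
                             time = surv$time, event = surv$event,
                             true_time = surv$true_time, z = z,
                             stringsAsFactors = FALSE),
       truth = data.frame(cluster_id = rownames(counts),
                          t_associated = t_assoc, z_associated = z_assoc,
                          beta0 = betas[, 1], beta1 = betas[, 2],
                          beta2 = betas[, 3], stringsAsFactors = FALSE),
       alpha = A)
}
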