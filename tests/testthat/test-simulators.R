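test_that("single-cluster simulator hits closed-form means", {
  # beta1 = beta2 = 0, sigma2 = 0: mean proportion = inverse-logit(beta0)
  cfg <- single_cluster_config(beta0 = -2, beta1 = 0, beta2 = 0, sigma2 = 0,
                               n_samples = 5000, censoring_rate = 0.3)
  d <- simulate_single_cluster(cfg, seed = 1)
  expect_equal(mean(d$y / d$n), plogis(-2), tolerance = 0.005)

  # Z log-odds contrast ~ beta2 = 1 at sigma2 = 0
  cfg2 <- single_cluster_config(beta0 = -2, beta1 = 0, beta2 = 1, sigma2 = 0,
                                n_samples = 10000, censoring_rate = 0.3)
  d2 <- simulate_single_cluster(cfg2, seed = 2)
  lo <- qlogis(sum(d2$y[d2$z == 1]) / sum(d2$n[d2$z == 1])) -
        qlogis(sum(d2$y[d2$z == 0]) / sum(d2$n[d2$z == 0]))
  expect_equal(lo, 1, tolerance = 0.02)

  # balanced binary covariate, totals within range, determinism
  expect_lte(abs(sum(d$z) - 2500), 1)
  expect_true(all(d$n >= 1e4 & d$n <= 1e5))
  expect_identical(d, simulate_single_cluster(cfg, seed = 1))
})

test_that("simulator reproduces the requested censoring rate", {
  for (target in c(0.3, 0.5)) {
    cfg <- single_cluster_config(n_samples = 20000, censoring_rate = target)
    d <- simulate_single_cluster(cfg, seed = 3)
    se3 <- 3 * sqrt(target * (1 - target) / nrow(d))
    expect_lt(abs(mean(!d$event) - target), se3)
  }
})

test_that("Dirichlet-multinomial ML recovers concentration parameters", {
  set.seed(70)
  alpha <- c(5, 3, 2)
  counts <- sapply(1:500, function(j) {
    g <- rgamma(3, alpha)
    rmultinom(1, 2000, g / sum(g))
  })
  est <- fit_dirichlet_multinomial(counts)
  expect_true(all(abs(est - alpha) / alpha < 0.1))

  # exchangeable clusters: equal estimates within Monte-Carlo error
  counts2 <- sapply(1:500, function(j) {
    g <- rgamma(4, 3)
    rmultinom(1, 1000, g / sum(g))
  })
  est2 <- fit_dirichlet_multinomial(counts2)
  expect_lt(max(est2) / min(est2), 1.2)

  # near-multinomial data: total concentration diverges upward
  counts3 <- sapply(1:200, function(j) rmultinom(1, 1000, c(.5, .3, .2)))
  est3 <- fit_dirichlet_multinomial(counts3, max_iter = 200)
  expect_gt(sum(est3), 1000)

  expect_error(fit_dirichlet_multinomial(matrix(1, 1, 5)), "at least 2")
  expect_warning(
    fit_dirichlet_multinomial(rbind(c(10, 12, 9), c(0, 0, 0), c(8, 9, 11))),
    "alpha floored")
})

test_that("association betas follow the border-constraint closed form", {
  b <- solve_association_betas(0.1, 0.2, t_max = 10)
  expect_equal(unname(b["beta0"]), qlogis(0.1), tolerance = 1e-10)
  expect_equal(unname(b["beta1"]), (qlogis(0.2) - qlogis(0.1)) / 10)
  expect_equal(unname(b["beta2"]), 0)
  # plugging back reproduces the borders in mean-proportion space
  expect_equal(plogis(b["beta0"] + b["beta1"] * 10), 0.2,
               ignore_attr = TRUE)
  # equal borders: no association
  expect_equal(unname(solve_association_betas(0.15, 0.15, 5)["beta1"]), 0)
  # z shift in proportion space
  bz <- solve_association_betas(0.1, 0.1, 5, z_effect = 0.05)
  expect_equal(plogis(bz["beta0"] + bz["beta2"]), 0.15, ignore_attr = TRUE)
  expect_error(solve_association_betas(0.1, 0.2, t_max = 0), "positive")
  expect_error(solve_association_betas(0.1, 0.2, 5, z_effect = 0.95),
               "inside \\(0, 1\\)")
})

test_that("multicluster counts conserve totals and baseline DM means", {
  cfg <- dm_config(base_alpha = default_base_alpha(8, 30), n_samples = 500,
                   censoring_rate = 0.3)
  sim <- simulate_multicluster(cfg, seed = 80)
  expect_equal(unname(colSums(sim$counts)),
               round(unname(colSums(sim$counts))))
  expect_true(all(colSums(sim$counts) >= 1e4))
  # no associations: per-cluster mean proportions ~ alpha_i / sum(alpha)
  props <- sweep(sim$counts, 2, colSums(sim$counts), "/")
  expect_equal(rowMeans(props), cfg$base_alpha / sum(cfg$base_alpha),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_false(any(sim$truth$t_associated))
})

test_that("injected associations are recovered by logit-link regression on
           the empirical proportions", {
  base <- default_base_alpha(10, total_concentration = 40)
  cfg <- dm_config(base_alpha = base,
                   assoc = list(list(pair = c(2, 3), pi_t0 = 0.05,
                                     pi_tmax = 0.25)),
                   n_samples = 500, concentration_multiplier = 50,
                   censoring_rate = 0.3)
  sim <- simulate_multicluster(cfg, seed = 81)
  props <- sweep(sim$counts, 2, colSums(sim$counts), "/")
  tr <- sim$truth[sim$truth$cluster_id == "cluster2", ]
  # the injected structure is on the mean-proportion scale,
  # E(pi | T) = logit^-1(b0 + b1 T): fit it there (quasibinomial logit GLM)
  fit <- glm(props["cluster2", ] ~ sim$metadata$true_time,
             family = quasibinomial())
  est <- coef(fit)[2]; se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(est - tr$beta1), 3 * se)
  # mirrored cluster gets the opposite slope sign
  tr3 <- sim$truth[sim$truth$cluster_id == "cluster3", ]
  expect_equal(tr3$beta1, -tr$beta1, tolerance = 1e-12)
  # the mirrored member absorbs the (documented) concentration-sum drift, so
  # its mean curve follows the logit line only approximately: bound the
  # relative slope error instead of the sampling SE
  fit3 <- glm(props["cluster3", ] ~ sim$metadata$true_time,
              family = quasibinomial())
  expect_lt(abs(coef(fit3)[2] - tr3$beta1) / abs(tr3$beta1), 0.10)
  expect_lt(abs(est - tr$beta1) / abs(tr$beta1), 0.10)
})

test_that("concentration multiplier preserves expected proportions and
           shrinks their spread", {
  base <- default_base_alpha(6, 20)
  cfg1 <- dm_config(base_alpha = base, n_samples = 300,
                    concentration_multiplier = 1, censoring_rate = 0.3)
  cfg5 <- dm_config(base_alpha = base, n_samples = 300,
                    concentration_multiplier = 5, censoring_rate = 0.3)
  # expected proportions identical on the parameter scale (exact identity)
  expect_equal(cfg1$base_alpha / sum(cfg1$base_alpha),
               cfg5$base_alpha / sum(cfg5$base_alpha))
  s1 <- simulate_multicluster(cfg1, seed = 82)
  s5 <- simulate_multicluster(cfg5, seed = 82)
  p1 <- sweep(s1$counts, 2, colSums(s1$counts), "/")
  p5 <- sweep(s5$counts, 2, colSums(s5$counts), "/")
  expect_lt(mean(apply(p5, 1, var)), mean(apply(p1, 1, var)))
})

test_that("compensating pairs keep the concentration sum nearly constant", {
  base <- default_base_alpha(10, 40)
  cfg <- dm_config(base_alpha = base,
                   assoc = list(list(pair = c(2, 3)),
                                list(pair = c(5, 6), z_effect = 0.01)),
                   n_samples = 200, censoring_rate = 0.3)
  sim <- simulate_multicluster(cfg, seed = 83)
  a_sum <- colSums(sim$alpha)
  target <- sum(cfg$base_alpha * cfg$concentration_multiplier)
  expect_lt(max(abs(a_sum - target) / target), 0.05)
})
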