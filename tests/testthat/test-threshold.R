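# small-but-honest sampler settings used throughout these tests
quick_cfg <- function(seed, ...) {
  args <- utils::modifyList(
    list(chains = 2, iterations = 2000, burn_in = 500, thin = 3,
         seed = seed),
    list(...))
  do.call(gam_config, args)
}

sim_linear_data <- function(seed, n = 150, beta0 = -4, beta1 = 0.2,
                            noise_sd = 1.5, site_sd = 0.5) {
  set.seed(seed)
  site <- sample(c("A", "B"), n, replace = TRUE)
  a <- stats::setNames(rnorm(2, 0, site_sd), c("A", "B"))
  lcc <- runif(n, 0, 60)
  depth <- sample(c(2, 3, 6, 9, 17), n, replace = TRUE)
  data.frame(net = beta0 + beta1 * lcc + a[site] + rnorm(n, 0, noise_sd),
             lcc = lcc, depth = depth, site = site)
}

test_that("gam_config validates its fields and demands a seed", {
  expect_error(gam_config(), "seed")
  expect_error(gam_config(seed = 1, iterations = 100, burn_in = 200))
  cfg <- gam_config(seed = 7)
  expect_equal(cfg$n_knots, 5)
  expect_equal(cfg$chains, 3)
})

test_that("sampler is reproducible and returns the declared draw count", {
  d <- sim_linear_data(1)
  cfg <- quick_cfg(42)
  f1 <- fit_threshold_model(d, cfg)
  f2 <- fit_threshold_model(d, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 2 * (2000 - 500) %/% 3)
  expect_true(all(f1$draws[, c("sigma2_e", "sigma2_u", "sigma2_a")] > 0))
})

test_that("no-spline, no-random-effect reduction matches the closed form", {
  # conjugate check: with a known residual variance and flat-ish normal
  # prior, the posterior for (intercept, slope) is available in closed
  # form; the sampler's coefficient block must agree to Monte-Carlo error
  set.seed(5)
  n <- 120
  x <- runif(n, 0, 50)
  y <- 1 + 0.3 * x + rnorm(n, 0, 1)
  d <- data.frame(net = y, lcc = x, depth = rep(3, n),
                  site = rep(c("A", "B"), length.out = n))
  fit <- fit_threshold_model(d, quick_cfg(8, iterations = 4000,
                                          burn_in = 1000, thin = 2))
  # closed-form posterior mean for ridge-like prior at the posterior-mean
  # residual variance (spline and site contributions are ~0 here)
  s2 <- mean(fit$draws[, "sigma2_e"])
  X <- cbind(1, x)
  V <- solve(crossprod(X) / s2 + diag(1e-6, 2))
  mu <- V %*% crossprod(X, y) / s2
  # the identifiable intercept is beta0 + mean site effect (the model
  # carries an intercept AND both site intercepts)
  site_cols <- grep("^site", colnames(fit$draws))
  got_b0 <- mean(fit$draws[, "(Intercept)"] +
                   rowMeans(fit$draws[, site_cols, drop = FALSE]))
  got_b1 <- mean(fit$draws[, "lcc"])
  expect_lt(abs(got_b0 - mu[1]), 0.1)
  expect_lt(abs(got_b1 - mu[2]), 0.01)
  # residual variance concentrates near the truth
  expect_lt(abs(s2 - 1), 0.35)
})

test_that("posterior mean curve recovers a linear truth within its band", {
  d <- sim_linear_data(2, noise_sd = 1)
  fit <- fit_threshold_model(d, quick_cfg(9))
  expect_true(fit$converged)
  grid <- seq(5, 55, 5)
  eta <- reefcarb:::curve_draws(fit, "2", grid)
  lo <- apply(eta, 1, quantile, 0.025)
  hi <- apply(eta, 1, quantile, 0.975)
  truth <- -4 + 0.2 * grid
  expect_gt(mean(truth >= lo & truth <= hi), 0.85)
})

test_that("threshold extraction finds known crossings and censors", {
  d <- sim_linear_data(3, beta0 = -5, beta1 = 0.2, noise_sd = 1)
  fit <- fit_threshold_model(d, quick_cfg(10))
  th <- coral_cover_threshold(fit, "2", grid_step = 0.05)
  expect_gt(th$threshold_lcc, 15)
  expect_lt(th$threshold_lcc, 35)
  expect_true(th$ci_lower <= th$threshold_lcc &
                th$threshold_lcc <= th$ci_upper)

  # everywhere-positive curve censors at the lower boundary
  d_pos <- d; d_pos$net <- d_pos$net + 50
  fit_pos <- fit_threshold_model(d_pos, quick_cfg(11))
  th_pos <- coral_cover_threshold(fit_pos, "2", grid_step = 0.1)
  expect_equal(th_pos$threshold_lcc, 0)

  # shifting all net values up strictly decreases the threshold
  fit_up <- fit
  fit_up$draws[, "(Intercept)"] <- fit_up$draws[, "(Intercept)"] + 1
  th_up <- coral_cover_threshold(fit_up, "2", grid_step = 0.05)
  expect_lt(th_up$threshold_lcc, th$threshold_lcc)
})

test_that("thresholds table covers every depth plus the average", {
  d <- sim_linear_data(4, noise_sd = 1)
  fit <- fit_threshold_model(d, quick_cfg(12))
  th <- coral_cover_thresholds(fit, grid_step = 0.1)
  expect_equal(nrow(th), 6)
  expect_equal(th$depth_m[6], "average")
  expect_equal(th$threshold_lcc[6], mean(th$threshold_lcc[1:5]))
})

test_that("sampler agrees with an independent MCMC engine (rjags)", {
  skip_if_not_installed("rjags")
  # linear-only reduction fitted both ways on one dataset
  set.seed(21)
  n <- 100
  x <- runif(n, 0, 50)
  site <- rep(c("A", "B"), length.out = n)
  y <- -2 + 0.15 * x + c(A = 0.4, B = -0.4)[site] + rnorm(n, 0, 1)
  d <- data.frame(net = y, lcc = x, depth = rep(3, n), site = site)
  fit <- fit_threshold_model(d, quick_cfg(22, iterations = 4000,
                                          burn_in = 1000, thin = 2))

  model_str <- "model {
    for (i in 1:n) {
      y[i] ~ dnorm(b0 + b1 * x[i] + a[s[i]], tau)
    }
    for (j in 1:2) { a[j] ~ dnorm(0, tau_a) }
    b0 ~ dnorm(0, 1e-6); b1 ~ dnorm(0, 1e-6)
    tau ~ dgamma(0.01, 0.01); tau_a ~ dgamma(0.01, 0.01)
  }"
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(y = y, x = x,
                                      s = as.integer(factor(site)), n = n),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 1))
  update(jm, 1000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("b0", "b1", "a"), 4000,
                              progress.bar = "none")
  jm_means <- colMeans(as.matrix(samp))
  # compare the identifiable population-mean regression line at two covers
  # (intercepts and site effects trade off within each sampler)
  site_cols <- grep("^site", colnames(fit$draws))
  site_mean <- rowMeans(fit$draws[, site_cols, drop = FALSE])
  ours_at <- rowMeans(reefcarb:::curve_draws(fit, "3", c(10, 40))) +
    mean(site_mean)
  jags_at <- jm_means[["b0"]] + jm_means[["b1"]] * c(10, 40) +
    mean(jm_means[c("a[1]", "a[2]")])
  expect_lt(max(abs(ours_at - jags_at)), 0.2)
})
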