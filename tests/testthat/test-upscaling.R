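test_that("collinearity screen drops the lower-priority of a collinear pair", {
  set.seed(1)
  x <- rnorm(100)
  df <- data.frame(lcc = x, algal_substrate = -x + rnorm(100, 0, 0.01),
                   depth = rnorm(100))
  scr <- collinearity_screen(df, priority = c("lcc", "depth",
                                              "algal_substrate"))
  expect_true("lcc" %in% scr$retained)
  expect_true("algal_substrate" %in% scr$dropped)
  expect_true("depth" %in% scr$retained)

  # independent features are all retained
  df2 <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  scr2 <- collinearity_screen(df2)
  expect_equal(sort(scr2$retained), c("a", "b", "c"))

  df3 <- data.frame(a = rnorm(50), k = rep(1, 50))
  expect_warning(scr3 <- collinearity_screen(df3), "constant")
  expect_equal(scr3$dropped, "k")
})

test_that("Cook's-distance filter flags a spiked outlier and little else", {
  set.seed(2)
  n <- 100
  X <- data.frame(lcc = runif(n, 0, 60))
  y <- -4 + 0.2 * X$lcc + rnorm(n, 0, 1)
  flags <- cooks_outlier_filter(y, X)
  expect_lt(sum(flags), 10)

  y_sp <- y
  y_sp[17] <- y[17] + 25
  flags_sp <- cooks_outlier_filter(y_sp, X)
  expect_true(flags_sp[17])
  expect_equal(attr(flags_sp, "cooks")[17],
               max(attr(flags_sp, "cooks")))
  expect_error(cooks_outlier_filter(y[1:2], X[1:2, , drop = FALSE]),
               "n > p")
})

test_that("PLSR component selection finds rank-1 signal and is seeded", {
  set.seed(3)
  n <- 150
  latent <- rnorm(n)
  X <- data.frame(a = latent + rnorm(n, 0, 0.2),
                  b = -latent + rnorm(n, 0, 0.2),
                  c = 2 * latent + rnorm(n, 0, 0.2))
  y <- 3 * latent + rnorm(n, 0, 0.5)
  # parsimonious count under the 1-SE rule is the single latent direction
  k1 <- plsr_component_selection(y, X, seed = 99, one_se = TRUE)
  expect_equal(as.integer(k1), 1L)
  # the CV curve collapses after the first component
  cv <- attr(plsr_component_selection(y, X, seed = 99), "cv_mse")
  expect_lt(cv[["1"]] / cv[["0"]], 0.2)
  expect_lt(abs(cv[["3"]] - cv[["1"]]) / cv[["1"]], 0.25)
  expect_identical(
    as.integer(plsr_component_selection(y, X, seed = 99, one_se = TRUE)),
    as.integer(k1))

  y_noise <- rnorm(n)
  expect_warning(k0 <- plsr_component_selection(y_noise, X, seed = 99),
                 "flat CV")
  expect_lte(as.integer(k0), 1L)
})

test_that("fit_and_select recovers an LCC-only truth and honors the split", {
  set.seed(4)
  n <- 150
  df <- data.frame(lcc = runif(n, 0, 60), rugosity = 1 + rlnorm(n, -0.5, 0.3),
                   depth = sample(c(2, 3, 6, 9, 17), n, TRUE))
  df$net <- -4 + 0.2 * df$lcc + rnorm(n, 0, 3)
  mod <- fit_and_select(df, list(c("lcc", "rugosity", "depth"),
                                 c("lcc", "rugosity"), "lcc"),
                        split_seed = 10)
  expect_equal(mod$predictors, "lcc")
  ci <- confint(mod$fit)
  expect_true(ci["(Intercept)", 1] <= -4 && -4 <= ci["(Intercept)", 2])
  expect_true(ci["lcc", 1] <= 0.2 && 0.2 <= ci["lcc", 2])
  expect_equal(nrow(mod$metrics), 3)

  # train/test discipline: refitting on the stored training rows alone
  # reproduces the training-split coefficients, so test rows never entered
  train_fit <- lm(net ~ lcc, data = df[mod$train_idx, ])
  mod2 <- fit_and_select(df, list("lcc"), split_seed = 10)
  expect_identical(mod$train_idx, mod2$train_idx)
  expect_error(fit_and_select(df, list(), split_seed = 1), "empty")
})

test_that("raster prediction is the scalar model applied pixelwise", {
  fit <- lm(net ~ lcc, data = data.frame(lcc = c(0, 50, 100),
                                         net = c(-4.01792, 5.64258,
                                                 15.30308)))
  # slope 0.19321, intercept -4.01792 by construction
  ras <- raster_grid(matrix(26, 2, 2))
  out <- predict_raster(fit, ras)
  expect_equal(out$net$values,
               matrix(0.19321 * 26 - 4.01792, 2, 2), tolerance = 1e-9)
  expect_equal(out$summary$prop_positive, 1)

  # single pixel equals the scalar prediction exactly
  one <- predict_raster(fit, raster_grid(matrix(40, 1, 1)))
  expect_equal(one$net$values[1, 1],
               unname(predict(fit, data.frame(lcc = 40))))
  expect_equal(one$accretion$values[1, 1],
               vertical_accretion(one$net$values[1, 1]))

  # nodata propagates, out-of-range covers are clamped and counted
  m <- matrix(c(NA, 120, -5, 30), 2, 2)
  out2 <- predict_raster(fit, raster_grid(m))
  expect_true(is.na(out2$net$values[1, 1]))
  expect_equal(out2$summary$n_clamped, 2)
  expect_equal(out2$net$values[2, 1],
               unname(predict(fit, data.frame(lcc = 100))))
})
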