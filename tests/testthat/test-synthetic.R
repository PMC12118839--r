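test_that("generators are pure functions of the seed", {
  cfg <- simulation_config(seed = 123, depths = c(3, 9), n_replicates = 4,
                           n_belts = 2, raster_nrow = 20, raster_ncol = 20)
  g1 <- generate_survey(cfg)
  g2 <- generate_survey(cfg)
  for (tab in c("transects", "intercepts", "urchins", "fishes"))
    expect_identical(g1$survey[[tab]], g2$survey[[tab]])
  r1 <- generate_lcc_raster(cfg)
  r2 <- generate_lcc_raster(cfg)
  expect_identical(r1$lcc$values, r2$lcc$values)
})

test_that("default design reproduces the target survey shape", {
  g <- generate_survey(simulation_config(seed = 5))
  expect_equal(nrow(g$survey$quadrats), 150)
  expect_equal(nrow(g$survey$transects), 150)
  expect_equal(nrow(g$survey$belts), 60)
  expect_equal(nrow(g$survey$pairing), 150)
  # generated datasets always satisfy the survey invariants
  expect_silent(validate_survey(g$survey))
})

test_that("urchin counts track the configured group-by-depth means", {
  # law-of-large-numbers check at inflated replication
  cfg <- simulation_config(seed = 31, n_replicates = 120,
                           depths = c(2, 17))
  g <- generate_survey(cfg)
  ur <- dplyr::left_join(g$survey$urchins, g$survey$quadrats,
                         by = "quadrat_id")
  n_quads <- 2 * 120
  for (d in c(2, 17)) for (grp in c("echinometra", "diadematidae")) {
    mu <- cfg$urchin_means[[grp]][[as.character(d)]]
    cnt <- sum(ur$group == grp & ur$depth_m == d) / n_quads
    se <- sqrt(mu * (1 + mu / cfg$urchin_dispersion) / n_quads)
    expect_lt(abs(cnt - mu), 4 * se + 1e-9)
  }
})

test_that("benthic tiling makes Dirichlet proportions exact per transect", {
  cfg <- simulation_config(seed = 8, depths = 6, n_replicates = 10,
                           n_belts = 0)
  g <- generate_survey(cfg)
  for (tid in g$survey$transects$transect_id) {
    ic <- g$survey$intercepts[g$survey$intercepts$transect_id == tid, ]
    truth_lcc <- g$truth$per_transect$lcc_percent[
      g$truth$per_transect$transect_id == tid]
    expect_equal(100 * benthic_proportions(ic)$categories[["coral"]],
                 truth_lcc, tolerance = 1e-9)
  }
})

test_that("zero coral concentration produces coral-free budgets", {
  cfg <- simulation_config(seed = 9, depths = 6, n_replicates = 8,
                           n_belts = 0,
                           coral_cover_pct = c(`6` = 0))
  g <- generate_survey(cfg)
  expect_equal(sum(g$survey$intercepts$category == "coral"), 0)
  # coral-free cells warn per cell about the table-mean density fallback
  # (asserted once in the bioerosion tests); here only the result matters
  bud <- suppressWarnings(compute_budget(g$survey, quiet = TRUE))
  expect_true(all(bud$lcc_percent == 0))
  expect_true(all(bud$gross >= 0))
})

test_that("cover raster has beta marginals, correlation, and truth field", {
  cfg <- simulation_config(seed = 77, raster_nrow = 80, raster_ncol = 80,
                           raster_corr_length = 4)
  r <- generate_lcc_raster(cfg, nodata_margin = 2)
  v <- r$lcc$values[!is.na(r$lcc$values)]
  expect_true(all(v >= 0 & v <= 100))
  # KS on pixels thinned to > 3 correlation lengths apart, so the
  # independence assumption of the test holds
  thin <- r$lcc$values[seq(3, 78, 15), seq(3, 78, 15)]
  ks <- suppressWarnings(
    ks.test(as.vector(thin) / 100, "pbeta", cfg$raster_beta[1],
            cfg$raster_beta[2]))
  expect_gt(ks$p.value, 0.01)
  # smoothing induces positive correlation between horizontal neighbours
  inner <- r$lcc$values[3:78, 3:78]
  expect_gt(cor(as.vector(inner[, -1]), as.vector(inner[, -ncol(inner)])),
            0.5)
  # latent net field is exactly beta0 + beta1 * cover
  expect_equal(r$net_truth$values, -4 + 0.2 * r$lcc$values,
               tolerance = 1e-12)

  # correlation length 0 gives white noise
  cfg0 <- simulation_config(seed = 78, raster_nrow = 50, raster_ncol = 50,
                            raster_corr_length = 0)
  r0 <- generate_lcc_raster(cfg0, nodata_margin = 0)
  expect_lt(abs(cor(as.vector(r0$lcc$values[, -1]),
                    as.vector(r0$lcc$values[, -50]))), 0.1)
  ks0 <- suppressWarnings(
    ks.test(as.vector(r0$lcc$values) / 100, "pbeta",
            cfg0$raster_beta[1], cfg0$raster_beta[2]))
  expect_gt(ks0$p.value, 0.01)
})
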