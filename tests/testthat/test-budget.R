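test_that("net production applies the signed sedimentation rule", {
  expect_equal(net_production(7.03, 5.16), 2.40, tolerance = 1e-12)
  expect_equal(net_production(5.67, 8.31), -2.11, tolerance = 1e-12)
  # high terrigenous load flips the sign
  sed_neg <- sedimentation_config(daily_load = 0.1)
  expect_equal(sed_neg$sign, -1)
  expect_equal(net_production(1.0, 1.0, sed_neg), -0.53, tolerance = 1e-12)
  # swapping the sign shifts net by exactly twice the annual rate
  expect_equal(net_production(3, 1) - net_production(3, 1, sed_neg),
               2 * 0.53, tolerance = 1e-12)
})

test_that("vertical accretion shrinks |Cp| toward zero via the quadratic", {
  expect_equal(vertical_accretion(0), 0)
  expect_equal(round_half_up(vertical_accretion(2.40)), 2.29)
  expect_equal(round_half_up(vertical_accretion(-2.11)), -2.20)
  cps <- seq(-10, 10, 0.25)
  acc <- vertical_accretion(cps)
  expect_true(all(acc[cps > 0] < cps[cps > 0]))
  expect_true(all(acc[cps < 0] > -abs(cps[cps < 0]) * 1.5))
  expect_true(all(acc[cps < 0] < cps[cps < 0]))  # more negative than Cp
  expect_equal(acc, oracle_accretion(cps), tolerance = 1e-12)
})

test_that("budget aggregation recovers known cell means and flags singletons", {
  bud <- tibble::tibble(
    transect_id = sprintf("t%d", 1:5),
    site_id = c("S1", "S1", "S1", "S2", "S2"),
    depth_m = c(2, 2, 6, 2, 6),
    rugosity = 1, lcc_percent = 20, algal_substrate_percent = 40,
    gross = c(4, 6, 3, 5, 2), parrotfish = 0, urchin = 0, macro = 0,
    micro = 0, bioerosion_total = c(1, 3, 2, 2, 1),
    sedimentation_term = 0.53,
    net = c(3.53, 3.53, 1.53, 3.53, 1.53),
    accretion = vertical_accretion(c(3.53, 3.53, 1.53, 3.53, 1.53)))
  class(bud) <- c("budget_result", class(bud))
  agg <- aggregate_budget(bud)

  d2 <- agg[agg$level == "depth" & agg$depth_m == 2, ]
  expect_equal(d2$gross_mean, 5)
  expect_equal(d2$bioerosion_mean, -2)
  expect_equal(d2$gross_se, sd(c(4, 6, 5)) / sqrt(3))
  # canonical aggregate accretion applies the conversion to the mean net
  expect_equal(d2$accretion_of_mean, vertical_accretion(3.53))

  single <- agg[agg$level == "site_depth" & agg$site_id == "S1" &
                  agg$depth_m == 6, ]
  expect_true(single$se_flag)
  expect_equal(single$gross_se, 0)

  ov <- agg[agg$level == "overall", ]
  expect_equal(ov$n, 5)
  expect_equal(ov$net_mean, mean(bud$net))
})

test_that("the tabletop fixture budget equals the hand-computed oracle", {
  fx <- tabletop_fixture()
  bud <- compute_budget(fx)
  t1 <- bud[bud$transect_id == "T1", ]
  t2 <- bud[bud$transect_id == "T2", ]

  # hand calculation, term by term (T1: 250-cm tape, rugosity 1.25,
  # 100 cm Porites lobata, 25 cm CCA, 50 cm carbonate, 25 cm rubble,
  # 50 cm sand; paired quadrat one 30-mm Echinometra + one 60-mm Diadema;
  # one belt with a single 30-cm Chlorurus spilurus)
  g_por <- 16.2 * exp(-0.032 * 6) / 10
  x <- 1.0 * (100 / 250) * 1.41 * g_por * 10
  ca <- 0.036 * (25 / 250) * 10
  gross1 <- 1.25 * (x + ca)
  expect_equal(t1$gross, gross1, tolerance = 1e-9)

  urch1 <- (3e-4 * 30^1.9671 * 0.365 * 0.57 +
              3e-6 * 60^3.2887 * 0.365 * 0.57) / 0.25
  expect_equal(t1$urchin, urch1, tolerance = 1e-9)

  vol <- exp(1.3172 + 0.0624 * 30) / 1000
  sp <- 1 / (1 + exp(-(-2.46142 + 0.08864 * 30)))
  br <- 60 * abs((4.31 + 2.8 - 0.355) - 0.045 * 10 * 30)
  pf <- vol * sp * br * 1.41 * 365 * 0.001 / 125
  expect_equal(t1$parrotfish, pf, tolerance = 1e-9)

  mac1 <- 1.25 * 0.21 * (100 / 250)
  mic1 <- 1.25 * 0.20 * (75 / 250)
  expect_equal(t1$macro, mac1, tolerance = 1e-9)
  expect_equal(t1$micro, mic1, tolerance = 1e-9)

  net1 <- gross1 + 0.53 - (pf + urch1 + mac1 + mic1)
  expect_equal(t1$net, net1, tolerance = 1e-9)
  expect_equal(t1$accretion, net1 - 0.01949 * net1^2, tolerance = 1e-9)

  # T2 is flat sand with an empty quadrat: only the broadcast parrotfish
  # rate erodes, nothing calcifies
  expect_equal(t2$gross, 0)
  expect_equal(t2$urchin, 0)
  expect_equal(t2$parrotfish, pf, tolerance = 1e-9)
  expect_equal(t2$net, 0.53 - pf, tolerance = 1e-9)
})

test_that("compute_budget demands complete pairing", {
  fx <- tabletop_fixture()
  fx$pairing <- fx$pairing[1, ]
  expect_error(compute_budget(fx), "without a paired quadrat")
})
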