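tables <- lookup_tables()

test_that("parrotfish bite models match direct evaluation and are monotone", {
  expect_equal(bite_volume(30), exp(3.1892) / 1000, tolerance = 1e-12)
  expect_lt(abs(bite_volume(30) - 0.0243), 2e-4)
  expect_lt(abs(bite_volume(1e-9) - exp(1.3172) / 1000), 1e-6)
  expect_gt(bite_volume(40), bite_volume(30))

  expect_equal(scar_proportion(2.46142 / 0.08864), 0.5, tolerance = 1e-12)
  expect_lt(abs(scar_proportion(50) - 0.878), 1e-3)
  sp <- scar_proportion(seq(1, 120, 1))
  expect_true(all(sp > 0 & sp < 1))
  expect_true(all(diff(sp) > 0))

  L0 <- 3.955 / 0.45
  expect_equal(bite_rate(L0, brc = 0), 0, tolerance = 1e-9)
  expect_equal(bite_rate(20, brc = 2), 60 * abs(5.955 - 9),
               tolerance = 1e-12)
  expect_equal(bite_rate(20, brc = 2), 182.7, tolerance = 1e-9)
  # symmetry of the absolute value about its interior zero
  expect_equal(bite_rate(L0 + 3, brc = 0), bite_rate(L0 - 3, brc = 0),
               tolerance = 1e-9)
})

test_that("site mean skeletal density is cover-weighted with table fallback", {
  ic <- make_intercepts("t", c("coral:Porites lobata" = 100, sand = 100))
  expect_equal(site_mean_skeletal_density(ic, tables), 1.41)

  ic2 <- make_intercepts("t", c("coral:Porites lobata" = 50,
                                "coral:Montipora capitata" = 50,
                                sand = 100))
  expect_equal(site_mean_skeletal_density(ic2, tables),
               (1.41 + 1.65) / 2, tolerance = 1e-12)

  ic3 <- make_intercepts("t", c(sand = 200))
  expect_warning(d <- site_mean_skeletal_density(ic3, tables),
                 "no coral")
  expect_equal(d, mean(tables$density$value))
})

test_that("parrotfish belt erosion matches the single-term oracle", {
  empty <- tibble::tibble(belt_id = character(), species = character(),
                          fork_length_cm = numeric())
  expect_equal(parrotfish_erosion(empty, 1.4, tables), 0)

  one <- tibble::tibble(belt_id = "B", species = "Chlorurus spilurus",
                        fork_length_cm = 30)
  expect_equal(parrotfish_erosion(one, 1.41, tables),
               oracle_parrotfish_belt(30, 2.8, 1.41), tolerance = 1e-12)

  # spec's worked single-fish example with fixed vol/sp/br components
  expect_lt(abs(0.02 * 0.5 * 100 * 1.4 * 365 * 0.001 / 125 - 0.00409),
            5e-6)

  set.seed(11)
  for (i in 1:10) {
    n <- sample(1:6, 1)
    lens <- runif(n, 10, 50)
    fish <- tibble::tibble(belt_id = "B", species = "Scarus psittacus",
                           fork_length_cm = lens)
    expect_equal(parrotfish_erosion(fish, 1.5, tables),
                 oracle_parrotfish_belt(lens, rep(3.1, n), 1.5),
                 tolerance = 1e-9)
  }
})

test_that("urchin erosion follows the group power laws with corrections", {
  expect_equal(urchin_erosion_individual("echinometra", 30),
               3e-4 * 30^1.9671 * 0.365 * 0.57, tolerance = 1e-12)
  expect_lt(abs(urchin_erosion_individual("echinometra", 30) - 0.0502),
            5e-4)
  expect_lt(abs(urchin_erosion_individual("diadematidae", 60) - 0.44),
            5e-3)
  expect_equal(urchin_erosion_individual("non_eroding", 80), 0)
  expect_error(urchin_erosion_individual("starfish", 30), "unknown")

  # monotone in size within each eroding group
  for (g in c("diadematidae", "echinometra", "other_eroding"))
    expect_true(all(diff(urchin_erosion_individual(
      rep(g, 50), seq(10, 108, 2))) > 0))
})

test_that("quadrat erosion normalizes by area and is linear in density", {
  empty <- tibble::tibble(quadrat_id = character(), species = character(),
                          group = character(), test_diameter_mm = numeric())
  expect_equal(urchin_erosion_quadrat(empty), 0)

  one <- tibble::tibble(quadrat_id = "Q", species = "Echinometra mathaei",
                        group = "echinometra", test_diameter_mm = 30)
  expect_equal(urchin_erosion_quadrat(one),
               oracle_urchin_quadrat("echinometra", 30), tolerance = 1e-12)
  expect_lt(abs(urchin_erosion_quadrat(one) - 0.201), 2e-3)

  # doubling every individual doubles the rate at fixed size distribution
  two <- dplyr::bind_rows(one, one)
  expect_equal(urchin_erosion_quadrat(two),
               2 * urchin_erosion_quadrat(one), tolerance = 1e-12)
})

test_that("macro- and microboring availability sets differ by CCA", {
  props <- c(coral = 0.2, coralline_algae = 0.1, halimeda = 0,
             carbonate_substrate = 0.3, rubble = 0.1,
             turf_macroalgae = 0.1, sand = 0.2, other_noncarbonate = 0)
  expect_equal(macroboring(1.5, props), 1.5 * 0.21 * 0.6,
               tolerance = 1e-12)
  expect_equal(microboring(1.5, props), 1.5 * 0.20 * 0.5,
               tolerance = 1e-12)
  # CCA present means the micro substrate is a strict subset
  expect_lt(microboring(1, props) / 0.20, macroboring(1, props) / 0.21)
  zero <- props * 0
  expect_equal(macroboring(2, zero), 0)
  expect_equal(microboring(2, zero), 0)
  one_mac <- c(coral = 0, coralline_algae = 0, halimeda = 0,
               carbonate_substrate = 1, rubble = 0, turf_macroalgae = 0,
               sand = 0, other_noncarbonate = 0)
  expect_equal(macroboring(1, one_mac), 0.21)
  expect_equal(microboring(1, one_mac), 0.20)
})

test_that("total bioerosion sums the four terms with broadcast parrotfish", {
  tr <- make_transect_row("T1", 2.5)
  ic <- make_intercepts("T1", c("coral:Porites lobata" = 100,
                                carbonate_substrate = 100, sand = 50))
  ur <- tibble::tibble(quadrat_id = "Q", species = "Echinometra mathaei",
                       group = "echinometra", test_diameter_mm = 40)
  b <- total_bioerosion(tr, ic, ur, parrotfish_rate = 0.1)
  expect_equal(b$total, b$parrotfish + b$urchin + b$macro + b$micro,
               tolerance = 1e-12)
  expect_equal(b$parrotfish, 0.1)
  expect_equal(b$macro, 1.25 * 0.21 * (100 / 250), tolerance = 1e-12)
  expect_equal(b$micro, 1.25 * 0.20 * (100 / 250), tolerance = 1e-12)
})
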