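# Default per-depth expected urchin counts per 0.25-m2 quadrat, seeded from
# published Hawaiian depth-gradient surveys (see the package vignette).
default_urchin_means <- list(
  diadematidae  = c(`2` = 0.87, `3` = 1.17, `6` = 0.40, `9` = 0.17,
                    `17` = 0.33),
  echinometra   = c(`2` = 15.13, `3` = 12.17, `6` = 15.57, `9` = 10.37,
                    `17` = 1.73),
  other_eroding = c(`2` = 0.30, `3` = 0.90, `6` = 2.07, `9` = 1.07,
                    `17` = 0.27),
  non_eroding   = c(`2` = 0.10, `3` = 0.10, `6` = 0.20, `9` = 0.50,
                    `17` = 0.23)
)

# Per-depth mean live coral cover (%) seeding the benthic Dirichlet draw,
# from the same surveys.
default_coral_cover <- c(`2` = 23.23, `3` = 28.16, `6` = 31.16, `9` = 34.65,
                         `17` = 25.11)

#' Simulation configuration for synthetic surveys and rasters
#'
#' All tunables of the seeded generators. The defaults emulate the study
#' design the package targets: 2 sites x depths \{2, 3, 6, 9, 17\} m x 15
#' paired quadrat/transect replicates with 6 fish belts per cell; per-depth
#' urchin means and coral-cover means seeded from published Hawaiian survey
#' tables; negative-binomial urchin counts (quadrat SEs imply
#' overdispersion); sparse parrotfish records.
#'
#' @param seed Integer seed; mandatory.
#' @param sites Site labels (default 2 sites).
#' @param depths Depths below MSL, m.
#' @param n_replicates Quadrat/transect pairs per site x depth (default 15).
#' @param n_belts Fish belts per site x depth (default 6).
#' @param urchin_means Named list (per [urchin_groups]) of per-depth
#'   expected counts per quadrat.
#' @param urchin_dispersion Negative-binomial size parameter (default 3.5).
#' @param urchin_size_params Named list of `c(mean, sd)` test diameters, mm.
#' @param coral_cover_pct Per-depth mean live coral cover, percent.
#' @param benthic_concentration Dirichlet concentration (sum of alphas)
#'   controlling transect-to-transect cover variability (default 12).
#' @param rugosity_meanlog,rugosity_sdlog Log-normal parameters of the
#'   excess rugosity (rugosity = 1 + lognormal).
#' @param fish_rate Expected parrotfish per belt (default 2; parrotfish
#'   were sparse in the emulated surveys).
#' @param raster_nrow,raster_ncol,raster_corr_length Cover-raster grid and
#'   spatial-correlation length (cells).
#' @param raster_beta Beta-distribution shape pair of the cover field.
#' @param truth Named vector `c(beta0, beta1)` of the latent
#'   cover-to-production line used by recovery tests (default -4, 0.2:
#'   zero net production at 20% cover).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              sites = c("S1", "S2"),
                              depths = c(2, 3, 6, 9, 17),
                              n_replicates = 15, n_belts = 6,
                              urchin_means = default_urchin_means,
                              urchin_dispersion = 3.5,
                              urchin_size_params = list(
                                diadematidae = c(60, 15),
                                echinometra = c(30, 8),
                                other_eroding = c(40, 12),
                                non_eroding = c(70, 15)),
                              coral_cover_pct = default_coral_cover,
                              benthic_concentration = 12,
                              rugosity_meanlog = log(0.6),
                              rugosity_sdlog = 0.35,
                              fish_rate = 2,
                              raster_nrow = 60, raster_ncol = 60,
                              raster_corr_length = 5,
                              raster_beta = c(2, 5),
                              truth = c(beta0 = -4, beta1 = 0.2)) {
  if (missing(seed) || is.null(seed))
    stop("simulation_config: a seed is mandatory", call. = FALSE)
  stopifnot(n_replicates >= 1, n_belts >= 0, urchin_dispersion > 0,
            benthic_concentration > 0, all(coral_cover_pct >= 0),
            fish_rate >= 0, raster_corr_length >= 0,
            all(raster_beta > 0))
  structure(as.list(environment()), class = "simulation_config")
}

# deterministic largest-remainder apportionment of n_cm tape centimetres to
# category proportions, so generated proportions are exact
apportion_cm <- function(props, n_cm) {
  raw <- props * n_cm
  base <- floor(raw)
  left <- n_cm - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

rtnorm_pos <- function(n, mean, sd, lower = 1) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic survey dataset with known ground truth
#'
#' Draws a complete field campaign from a [simulation_config()]: urchin
#' counts ~ negative binomial with the configured per-depth group means and
#' truncated-normal test diameters; benthic transects built by drawing
#' per-category cover ~ Dirichlet (coral mean set per depth) and tiling the
#' contour tape deterministically at 1 cm so realized proportions are
#' exact; rugosity ~ 1 + lognormal; parrotfish ~ Poisson-thinned species
#' mixture. Deterministic given the seed.
#'
#' @param config A [simulation_config()].
#' @return List with `survey` (a [survey_dataset()]) and `truth` (the
#'   config plus per-transect latent covers), serializable with
#'   [jsonlite::write_json()].
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cats <- benthic_categories
  species_by_group <- list(
    diadematidae = c("Echinothrix calamaris", "Diadema paucispinum"),
    echinometra = "Echinometra mathaei",
    other_eroding = c("Heterocentrotus mammillatus",
                      "Eucidaris metularia"),
    non_eroding = "Tripneustes gratilla"
  )
  coral_pool <- c("Porites lobata", "Porites compressa",
                  "Montipora capitata", "Pocillopora meandrina",
                  "Pavona varians")
  coral_w <- c(0.55, 0.2, 0.12, 0.08, 0.05)
  fish_pool <- c("Chlorurus spilurus", "Scarus psittacus",
                 "Scarus rubroviolaceus", "Calotomus carolinus")
  fish_w <- c(0.6, 0.2, 0.1, 0.1)

  transects <- list(); intercepts <- list(); quadrats <- list()
  urchins <- list(); belts <- list(); fishes <- list(); pairing <- list()
  truth_rows <- list()
  for (site in config$sites) for (depth in config$depths) {
    dkey <- as.character(depth)
    lcc_mean <- config$coral_cover_pct[[dkey]] / 100
    # Dirichlet alphas: coral mean as configured, remainder split over the
    # other categories (halimeda only present at the deepest stations)
    rest <- c(coralline_algae = 0.03, halimeda = 0.02,
              carbonate_substrate = 0.35, rubble = 0.12,
              turf_macroalgae = 0.25, sand = 0.18, other_noncarbonate = 0.05)
    if (depth < 15) {
      rest["carbonate_substrate"] <- rest["carbonate_substrate"] +
        rest["halimeda"]
      rest["halimeda"] <- 0
    }
    alphas <- c(coral = lcc_mean, (1 - lcc_mean) * rest / sum(rest)) *
      config$benthic_concentration
    for (rep in seq_len(config$n_replicates)) {
      tid <- sprintf("%s_d%s_t%02d", site, dkey, rep)
      qid <- sprintf("%s_d%s_q%02d", site, dkey, rep)
      rug <- 1 + stats::rlnorm(1, config$rugosity_meanlog,
                               config$rugosity_sdlog)
      contour <- round(2 * rug, 2)
      n_cm <- round(contour * 100)
      gam_draw <- stats::rgamma(length(alphas),
                                shape = pmax(alphas, 1e-8)) *
        (alphas > 0)
      props <- if (sum(gam_draw) > 0) gam_draw / sum(gam_draw)
               else stats::setNames(rep(1 / length(alphas),
                                        length(alphas)), names(alphas))
      names(props) <- names(alphas)
      counts <- apportion_cm(props[cats], n_cm)
      cat_vec <- rep(cats, counts)
      taxa <- ifelse(cat_vec == "coral", NA_character_, cat_vec)
      n_coral <- sum(cat_vec == "coral")
      if (n_coral > 0)
        taxa[cat_vec == "coral"] <- sample(coral_pool, n_coral,
                                           replace = TRUE, prob = coral_w)
      transects[[tid]] <- tibble::tibble(
        transect_id = tid, site_id = site, depth_m = depth,
        planar_length_m = 2, contour_length_m = contour)
      intercepts[[tid]] <- tibble::tibble(
        transect_id = tid, position_cm = seq_len(n_cm),
        category = cat_vec, taxon = taxa)
      quadrats[[qid]] <- tibble::tibble(
        quadrat_id = qid, site_id = site, depth_m = depth, area_m2 = 0.25)
      pairing[[tid]] <- tibble::tibble(transect_id = tid, quadrat_id = qid)
      urows <- list()
      for (grp in urchin_groups) {
        mu <- config$urchin_means[[grp]][[dkey]]
        k <- stats::rnbinom(1, size = config$urchin_dispersion, mu = mu)
        if (k > 0) {
          sz <- config$urchin_size_params[[grp]]
          urows[[grp]] <- tibble::tibble(
            quadrat_id = qid,
            species = sample(species_by_group[[grp]], k, replace = TRUE),
            group = grp,
            test_diameter_mm = round(rtnorm_pos(k, sz[1], sz[2],
                                                lower = 5) * 2) / 2)
        }
      }
      if (length(urows)) urchins[[qid]] <- dplyr::bind_rows(urows)
      truth_rows[[tid]] <- tibble::tibble(
        transect_id = tid, site_id = site, depth_m = depth,
        lcc_percent = 100 * counts[["coral"]] / n_cm, rugosity = rug)
    }
    for (b in seq_len(config$n_belts)) {
      bid <- sprintf("%s_d%s_b%d", site, dkey, b)
      belts[[bid]] <- tibble::tibble(
        belt_id = bid, site_id = site, depth_m = depth,
        length_m = 25, width_m = 5)
      nf <- stats::rpois(1, config$fish_rate)
      if (nf > 0)
        fishes[[bid]] <- tibble::tibble(
          belt_id = bid,
          species = sample(fish_pool, nf, replace = TRUE, prob = fish_w),
          fork_length_cm = round(rtnorm_pos(nf, 25, 8, lower = 5)))
    }
  }
  empty_urchins <- tibble::tibble(quadrat_id = character(),
                                  species = character(),
                                  group = character(),
                                  test_diameter_mm = numeric())
  empty_fishes <- tibble::tibble(belt_id = character(),
                                 species = character(),
                                 fork_length_cm = numeric())
  survey <- survey_dataset(
    dplyr::bind_rows(transects), dplyr::bind_rows(intercepts),
    dplyr::bind_rows(quadrats),
    if (length(urchins)) dplyr::bind_rows(urchins) else empty_urchins,
    dplyr::bind_rows(belts),
    if (length(fishes)) dplyr::bind_rows(fishes) else empty_fishes,
    dplyr::bind_rows(pairing))
  list(survey = survey,
       truth = list(seed = config$seed,
                    truth = as.list(config$truth),
                    per_transect = dplyr::bind_rows(truth_rows)))
}

#' Generate a spatially correlated live-coral-cover raster
#'
#' Builds a percent-cover field with known marginals and ground truth: a
#' Gaussian random field (white noise smoothed by a separable Gaussian
#' kernel of the configured correlation length; length 0 gives white
#' noise), mapped through its normal CDF to exact Beta marginals, scaled to
#' [0, 100]. The latent net-production field `beta0 + beta1 * cover` is
#' returned as truth for round-trip tests. A nodata border mimics unmapped
#' pixels.
#'
#' @param config A [simulation_config()].
#' @param nodata_margin Cells of nodata border (default 2).
#' @return List with `lcc` (a [raster_grid()]), `net_truth` (latent
#'   production raster), and `truth` (generator parameters).
#' @export
generate_lcc_raster <- function(config, nodata_margin = 2) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  nr <- config$raster_nrow; nc <- config$raster_ncol
  ell <- config$raster_corr_length
  if (ell > 0) {
    pad <- ceiling(3 * ell)
    z0 <- matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
                 nr + 2 * pad, nc + 2 * pad)
    k <- stats::dnorm(seq(-pad, pad), sd = ell)
    k <- k / sqrt(sum(k^2))
    sm <- apply(z0, 2, function(col)
      stats::convolve(col, rev(k), type = "filter"))
    sm <- t(apply(sm, 1, function(row)
      stats::convolve(row, rev(k), type = "filter")))
    z <- sm[seq_len(nr), seq_len(nc)]
  } else {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
  }
  u <- stats::pnorm(z)  # uniform marginals, spatial structure preserved
  cover <- 100 * stats::qbeta(u, config$raster_beta[1],
                              config$raster_beta[2])
  if (nodata_margin > 0) {
    idx <- seq_len(nodata_margin)
    cover[idx, ] <- NA; cover[nr + 1 - idx, ] <- NA
    cover[, idx] <- NA; cover[, nc + 1 - idx] <- NA
  }
  net <- config$truth[["beta0"]] + config$truth[["beta1"]] * cover
  list(
    lcc = raster_grid(cover, cellsize = 2, crs = "synthetic local grid"),
    net_truth = raster_grid(net, cellsize = 2, crs = "synthetic local grid"),
    truth = list(seed = config$seed, beta = as.list(config$truth),
                 beta_marginal = config$raster_beta,
                 corr_length = ell)
  )
}

#' Tiny hand-checkable survey fixture
#'
#' A deterministic two-transect dataset small enough to audit by hand: one
#' structured transect (40% *Porites lobata*, 10% coralline algae, mixed
#' substrate, rugosity 1.25) paired with a two-urchin quadrat and one belt
#' with a single parrotfish, plus one flat all-sand transect with an empty
#' quadrat. Its complete budget is verified against literal arithmetic in
#' the test suite.
#'
#' @return A [survey_dataset()].
#' @export
tabletop_fixture <- function() {
  transects <- tibble::tibble(
    transect_id = c("T1", "T2"), site_id = "S1", depth_m = 6,
    planar_length_m = 2, contour_length_m = c(2.5, 2.0))
  ic1 <- tibble::tibble(
    transect_id = "T1", position_cm = 1:250,
    category = rep(c("coral", "coralline_algae", "carbonate_substrate",
                     "rubble", "sand"), c(100, 25, 50, 25, 50)),
    taxon = rep(c("Porites lobata", NA, NA, NA, NA),
                c(100, 25, 50, 25, 50)))
  ic2 <- tibble::tibble(
    transect_id = "T2", position_cm = 1:200,
    category = "sand", taxon = NA_character_)
  quadrats <- tibble::tibble(
    quadrat_id = c("Q1", "Q2"), site_id = "S1", depth_m = 6, area_m2 = 0.25)
  urchins <- tibble::tibble(
    quadrat_id = "Q1",
    species = c("Echinometra mathaei", "Diadema paucispinum"),
    group = c("echinometra", "diadematidae"),
    test_diameter_mm = c(30, 60))
  belts <- tibble::tibble(
    belt_id = "B1", site_id = "S1", depth_m = 6, length_m = 25, width_m = 5)
  fishes <- tibble::tibble(
    belt_id = "B1", species = "Chlorurus spilurus", fork_length_cm = 30)
  pairing <- tibble::tibble(transect_id = c("T1", "T2"),
                            quadrat_id = c("Q1", "Q2"))
  survey_dataset(transects, dplyr::bind_rows(ic1, ic2), quadrats, urchins,
                 belts, fishes, pairing)
}
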