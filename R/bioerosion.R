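# Size-specific sea-urchin erosion power-law coefficients (a, b) per group,
# the day->year conversion (g d-1 to kg y-1) and the re-ingestion correction.
urchin_coeffs <- list(
  diadematidae  = c(a = 3e-06, b = 3.2887),
  echinometra   = c(a = 3e-04, b = 1.9671),
  other_eroding = c(a = 3e-05, b = 2.6414)
)
urchin_day_to_year <- 0.365
urchin_reingestion <- 0.57

#' Parrotfish bite volume
#'
#' Volume of a single bite (cm3) as an exponential function of fork length:
#' `exp(1.3172 + 0.0624 * length) / 1000`, the division converting mm3 to
#' cm3. Monotone increasing; the intercept sets a small positive floor for
#' vanishing lengths.
#'
#' @param length_cm Fork length, cm (> 0). Vectorized.
#' @param coeffs The two regression constants.
#' @return Bite volume, cm3.
#' @export
bite_volume <- function(length_cm, coeffs = c(1.3172, 0.0624)) {
  stopifnot(all(length_cm > 0))
  exp(coeffs[1] + coeffs[2] * length_cm) / 1000
}

#' Proportion of parrotfish bites leaving scars
#'
#' Logistic regression on fork length:
#' `1 / (1 + exp(-(-2.46142 + 0.08864 * length)))`, bounded in (0, 1) and
#' crossing 0.5 near 27.8 cm.
#'
#' @param length_cm Fork length, cm (> 0). Vectorized.
#' @param coeffs The two logit constants.
#' @return Scar proportion in (0, 1).
#' @export
scar_proportion <- function(length_cm, coeffs = c(-2.46142, 0.08864)) {
  stopifnot(all(length_cm > 0))
  stats::plogis(coeffs[1] + coeffs[2] * length_cm)
}

#' Parrotfish bite rate
#'
#' Daily bite rate (bites day-1):
#' `60 * |(4.31 + brc - 0.355) - 0.045 * bitetime * length|`, with `brc` the
#' species bite-rate constant and `bitetime` the grazing hours per day
#' (default 10). The constants and the absolute-value structure are applied
#' exactly as published.
#'
#' @param length_cm Fork length, cm (> 0). Vectorized.
#' @param brc Species bite-rate constant.
#' @param bitetime_h Grazing time, hours day-1 (default 10).
#' @param coeffs The three rate constants and the minutes-to-hours factor.
#' @return Bites day-1 (>= 0).
#' @export
bite_rate <- function(length_cm, brc, bitetime_h = 10,
                      coeffs = c(4.31, -0.355, 0.045, 60)) {
  stopifnot(all(length_cm > 0))
  coeffs[4] * abs((coeffs[1] + brc + coeffs[2]) -
                    coeffs[3] * bitetime_h * length_cm)
}

#' Cover-weighted mean coral skeletal density of a site-depth cell
#'
#' The substrate density eroded by parrotfish grazing: the mean of the
#' species skeletal densities weighted by coral cover across the cell's
#' benthic transects. When no coral was observed in the cell, falls back to
#' the unweighted mean of all table densities (with a warning).
#'
#' @param intercepts Intercept records of all transects in the cell.
#' @param tables A [lookup_tables()] object.
#' @return Mean skeletal density, g cm-3.
#' @export
site_mean_skeletal_density <- function(intercepts, tables) {
  coral <- intercepts[intercepts$category == "coral", , drop = FALSE]
  if (nrow(coral) == 0) {
    warning("no coral observed in cell; using unweighted table-mean ",
            "skeletal density", call. = FALSE)
    return(mean(tables$density$value))
  }
  counts <- table(coral$taxon)
  dens <- vapply(names(counts),
                 function(tx) lookup_row(tables$density, tx)$row$value,
                 numeric(1))
  sum(dens * as.numeric(counts)) / sum(counts)
}

#' Parrotfish erosion of one belt transect
#'
#' Per-transect parrotfish bioerosion (kg CaCO3 m-2 y-1): for each fish,
#' bite volume x scar proportion x bite rate x substrate density, converted
#' by 365 (days to years) and 0.001 (g to kg) and normalized by the belt
#' area (25 x 5 m). An empty belt erodes nothing.
#'
#' @param fishes Fish records of one belt (columns `species`,
#'   `fork_length_cm`).
#' @param D_k Site-depth mean coral skeletal density, g cm-3
#'   (see [site_mean_skeletal_density()]).
#' @param tables A [lookup_tables()] object (bite-rate constants).
#' @param belt_area_m2 Belt area, m2 (default 125).
#' @param bitetime_h Grazing hours per day (default 10).
#' @param quiet Suppress bite-rate-constant fallback warnings.
#' @return kg CaCO3 m-2 y-1.
#' @export
parrotfish_erosion <- function(fishes, D_k, tables, belt_area_m2 = 125,
                               bitetime_h = 10, quiet = TRUE) {
  if (nrow(fishes) == 0) return(0)
  brc <- vapply(fishes$species, resolve_brc, numeric(1),
                tables = tables, quiet = quiet)
  len <- fishes$fork_length_cm
  per_fish <- bite_volume(len) * scar_proportion(len) *
    bite_rate(len, brc, bitetime_h) * D_k * 365 * 0.001 / belt_area_m2
  sum(per_fish)
}

#' Site-depth parrotfish erosion rate
#'
#' Mean of the per-belt parrotfish erosion rates over the belts surveyed in
#' one site-depth cell (six by design; the mean generalizes to the belts
#' present, with a warning when that is not six).
#'
#' @param belts Belt metadata of the cell.
#' @param fishes Fish records of those belts.
#' @param D_k Site-depth mean coral skeletal density, g cm-3.
#' @param tables A [lookup_tables()] object.
#' @param bitetime_h Grazing hours per day.
#' @param quiet Suppress warnings.
#' @return kg CaCO3 m-2 y-1; 0 (with a warning) when the cell has no belts.
#' @export
parrotfish_site_rate <- function(belts, fishes, D_k, tables,
                                 bitetime_h = 10, quiet = TRUE) {
  if (nrow(belts) == 0) {
    if (!quiet)
      warning("no fish belts in cell; parrotfish erosion set to 0",
              call. = FALSE)
    return(0)
  }
  if (nrow(belts) != 6 && !quiet)
    warning("cell has ", nrow(belts), " fish belts (6 by design)",
            call. = FALSE)
  rates <- vapply(belts$belt_id, function(id) {
    f <- fishes[fishes$belt_id == id, , drop = FALSE]
    parrotfish_erosion(f, D_k, tables,
                       belt_area_m2 = belts$length_m[belts$belt_id == id][1] *
                         belts$width_m[belts$belt_id == id][1],
                       bitetime_h = bitetime_h, quiet = quiet)
  }, numeric(1))
  mean(rates)
}

#' Erosion rate of one sea urchin
#'
#' Size-specific annual erosion (kg CaCO3 y-1 per individual):
#' `a * diameter^b * 0.365 * 0.57`, with the power-law pair `(a, b)` set by
#' functional group, 0.365 converting g day-1 to kg y-1 and 0.57 correcting
#' for re-ingested sediment. Non-eroding urchins (*Tripneustes gratilla*)
#' contribute 0.
#'
#' @param group One of [urchin_groups]. Vectorized with `diameter_mm`.
#' @param diameter_mm Test diameter, mm (> 0).
#' @return kg CaCO3 y-1 per individual.
#' @export
urchin_erosion_individual <- function(group, diameter_mm) {
  stopifnot(all(diameter_mm > 0))
  if (any(bad <- !(group %in% urchin_groups)))
    stop("unknown urchin group '", group[which(bad)[1]], "'", call. = FALSE)
  out <- numeric(length(diameter_mm))
  group <- rep_len(group, length(diameter_mm))
  for (g in names(urchin_coeffs)) {
    idx <- group == g
    if (any(idx)) {
      cf <- urchin_coeffs[[g]]
      out[idx] <- cf[["a"]] * diameter_mm[idx]^cf[["b"]] *
        urchin_day_to_year * urchin_reingestion
    }
  }
  out  # non_eroding stays 0
}

#' Sea-urchin erosion of one quadrat
#'
#' Sum of individual erosion rates divided by the quadrat area (0.25 m2 by
#' design), giving kg CaCO3 m-2 y-1. Empty quadrats erode nothing.
#'
#' @param urchins Urchin records of one quadrat (columns `group`,
#'   `test_diameter_mm`).
#' @param area_m2 Quadrat area, m2 (default 0.25).
#' @return kg CaCO3 m-2 y-1.
#' @export
urchin_erosion_quadrat <- function(urchins, area_m2 = 0.25) {
  stopifnot(area_m2 > 0)
  if (nrow(urchins) == 0) return(0)
  sum(urchin_erosion_individual(urchins$group, urchins$test_diameter_mm)) /
    area_m2
}

# Default substrate -> eroder-availability mapping. CCA is macroborable
# (thick crusts do not protect the substrate beneath) but not microborable
# (its net rate already nets out microboring, as does coral's).
macroboring_categories <- c("carbonate_substrate", "rubble",
                            "turf_macroalgae", "coralline_algae")
microboring_categories <- c("carbonate_substrate", "rubble",
                            "turf_macroalgae")

#' Macroboring erosion of one transect
#'
#' `r * 0.21 * pmacro` (kg CaCO3 m-2 y-1), with `pmacro` the planar
#' proportion of substrate available to boring sponges, worms and bivalves:
#' carbonate substrate, rubble (including algae-covered), and coralline
#' algae.
#'
#' @param r Transect rugosity.
#' @param proportions Named category-proportion vector from
#'   [benthic_proportions()].
#' @param rate Areal macroboring rate, kg m-2 y-1 (default 0.21).
#' @param categories Benthic categories counted as macroborable.
#' @return kg CaCO3 m-2 y-1.
#' @export
macroboring <- function(r, proportions, rate = 0.21,
                        categories = macroboring_categories) {
  r * rate * sum(proportions[categories])
}

#' Microboring erosion of one transect
#'
#' `r * 0.20 * pmicro` (kg CaCO3 m-2 y-1), with `pmicro` the planar
#' proportion of substrate available to cyanobacteria, chlorophytes and
#' fungi: carbonate substrate and rubble (including algae-covered); coral
#' and coralline algae are excluded because their net calcification rates
#' already account for microboring.
#'
#' @inheritParams macroboring
#' @param rate Areal microboring rate, kg m-2 y-1 (default 0.20).
#' @param categories Benthic categories counted as microborable.
#' @return kg CaCO3 m-2 y-1.
#' @export
microboring <- function(r, proportions, rate = 0.20,
                        categories = microboring_categories) {
  r * rate * sum(proportions[categories])
}

#' Total bioerosion of one transect
#'
#' Sums the four erosion terms for a benthic transect: the broadcast
#' site-depth parrotfish rate, the paired quadrat's urchin erosion, and the
#' transect's macro- and microboring.
#'
#' @param transect One row of the `transects` table.
#' @param intercepts Intercept records of that transect.
#' @param urchins Urchin records of the paired quadrat.
#' @param parrotfish_rate Site-depth parrotfish erosion, kg m-2 y-1.
#' @param quadrat_area_m2 Paired quadrat area, m2.
#' @param macro_rate,micro_rate Areal boring rates, kg m-2 y-1.
#' @return A `bioerosion_result` list: `parrotfish`, `urchin`, `macro`,
#'   `micro`, `total` (all kg CaCO3 m-2 y-1).
#' @export
total_bioerosion <- function(transect, intercepts, urchins, parrotfish_rate,
                             quadrat_area_m2 = 0.25,
                             macro_rate = 0.21, micro_rate = 0.20) {
  r <- rugosity(transect$contour_length_m, transect$planar_length_m)
  props <- benthic_proportions(intercepts)$categories
  parts <- list(
    parrotfish = parrotfish_rate,
    urchin = urchin_erosion_quadrat(urchins, quadrat_area_m2),
    macro = macroboring(r, props, macro_rate),
    micro = microboring(r, props, micro_rate)
  )
  parts$total <- parts$parrotfish + parts$urchin + parts$macro + parts$micro
  structure(parts, class = "bioerosion_result")
}
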