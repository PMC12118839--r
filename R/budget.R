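#' Sedimentation configuration
#'
#' Calcareous sedimentation enters the net-production balance with a sign
#' set by the observed terrigenous sediment load: positive (contributing to
#' accretion) when the daily load is below 0.05 kg m-2 d-1, negative
#' (smothering) otherwise. The default annual rate of 0.53 kg CaCO3 m-2 y-1
#' is a Hawaiian literature value.
#'
#' @param annual_rate Annual calcareous sedimentation, kg CaCO3 m-2 y-1
#'   (default 0.53).
#' @param daily_load Observed terrigenous load, kg m-2 d-1 (default 0).
#' @param sign_threshold Load above which the sign flips negative,
#'   kg m-2 d-1 (default 0.05).
#' @return A `sedimentation_config` list with the resolved `sign` (+1/-1).
#' @export
sedimentation_config <- function(annual_rate = 0.53, daily_load = 0,
                                 sign_threshold = 0.05) {
  stopifnot(annual_rate >= 0, daily_load >= 0, sign_threshold > 0)
  structure(
    list(annual_rate = annual_rate, daily_load = daily_load,
         sign_threshold = sign_threshold,
         sign = if (daily_load < sign_threshold) 1 else -1),
    class = "sedimentation_config"
  )
}

#' Net carbonate production
#'
#' The transect-level carbonate balance:
#' `Cp = gross + sign * sedimentation - bioerosion` (kg CaCO3 m-2 y-1),
#' with the sedimentation sign set by the daily-load rule of
#' [sedimentation_config()].
#'
#' @param gross Gross carbonate production, kg CaCO3 m-2 y-1 (>= 0).
#' @param bio_total Total bioerosion, kg CaCO3 m-2 y-1 (>= 0, i.e. as a
#'   magnitude, not the negative presentation used in summary tables).
#' @param sed A [sedimentation_config()].
#' @return Net production `Cp`, kg CaCO3 m-2 y-1. Vectorized.
#' @examples
#' net_production(7.03, 5.16)  # 2.40
#' @export
net_production <- function(gross, bio_total, sed = sedimentation_config()) {
  stopifnot(all(gross >= 0), all(bio_total >= 0),
            inherits(sed, "sedimentation_config"))
  gross + sed$sign * sed$annual_rate - bio_total
}

#' Vertical reef-accretion potential
#'
#' Converts net carbonate production `Cp` (kg CaCO3 m-2 y-1) to potential
#' vertical reef growth (mm y-1) via the published quadratic best-fit
#' `Cp + Cp * (Cp * (-0.01949))`. The correction shrinks the magnitude
#' toward zero for |Cp| below ~51, so accretion is slightly less than Cp
#' for producing reefs and slightly more negative than Cp for eroding ones.
#'
#' @param Cp Net carbonate production, kg CaCO3 m-2 y-1. Vectorized.
#' @param coef The quadratic coefficient (default -0.01949).
#' @return Accretion potential, mm y-1.
#' @examples
#' vertical_accretion(2.40)   # 2.288
#' vertical_accretion(-2.11)  # -2.197
#' @export
vertical_accretion <- function(Cp, coef = -0.01949) {
  Cp + Cp * (Cp * coef)
}

#' Compute the full carbonate budget of a survey dataset
#'
#' Runs the whole census-based budget: per-transect rugosity and benthic
#' proportions, gross production, the four bioerosion terms (the site-depth
#' parrotfish rate broadcast to its transects), signed sedimentation, net
#' production, and accretion potential.
#'
#' @param survey A [survey_dataset()]. Every transect must have a paired
#'   quadrat.
#' @param tables A [lookup_tables()] object.
#' @param sed A [sedimentation_config()].
#' @param bitetime_h Parrotfish grazing hours per day.
#' @param quiet Suppress per-cell warnings.
#' @return A tibble (class `budget_result`) with one row per transect:
#'   ids, `depth_m`, `site_id`, `rugosity`, `lcc_percent`,
#'   `algal_substrate_percent`, `gross`, `parrotfish`, `urchin`, `macro`,
#'   `micro`, `bioerosion_total`, `sedimentation_term`, `net`, `accretion`.
#' @export
compute_budget <- function(survey, tables = lookup_tables(),
                           sed = sedimentation_config(),
                           bitetime_h = 10, quiet = TRUE) {
  stopifnot(inherits(survey, "survey_dataset"))
  if (nrow(survey$transects) == 0)
    stop("compute_budget: dataset has no benthic transects", call. = FALSE)
  unpaired <- setdiff(survey$transects$transect_id,
                      survey$pairing$transect_id)
  if (length(unpaired))
    stop("compute_budget: transect(s) without a paired quadrat: ",
         paste(utils::head(unpaired, 5), collapse = ", "), call. = FALSE)

  # site-depth parrotfish rates and mean skeletal densities, computed once
  cells <- dplyr::distinct(survey$transects, .data$site_id, .data$depth_m)
  cell_rate <- purrr::pmap_dbl(cells, function(site_id, depth_m) {
    tr_ids <- survey$transects$transect_id[
      survey$transects$site_id == site_id &
        survey$transects$depth_m == depth_m]
    ic <- survey$intercepts[survey$intercepts$transect_id %in% tr_ids, ]
    D_k <- site_mean_skeletal_density(ic, tables)
    bl <- survey$belts[survey$belts$site_id == site_id &
                         survey$belts$depth_m == depth_m, ]
    fs <- survey$fishes[survey$fishes$belt_id %in% bl$belt_id, ]
    parrotfish_site_rate(bl, fs, D_k, tables, bitetime_h = bitetime_h,
                         quiet = quiet)
  })
  cells$parrotfish_rate <- cell_rate

  rows <- purrr::map(seq_len(nrow(survey$transects)), function(i) {
    tr <- survey$transects[i, ]
    ic <- survey$intercepts[survey$intercepts$transect_id == tr$transect_id, ]
    q_id <- survey$pairing$quadrat_id[
      survey$pairing$transect_id == tr$transect_id]
    qd <- survey$quadrats[survey$quadrats$quadrat_id == q_id, ]
    ur <- survey$urchins[survey$urchins$quadrat_id == q_id, ]
    pf <- cells$parrotfish_rate[cells$site_id == tr$site_id &
                                  cells$depth_m == tr$depth_m]
    g <- gross_production(tr, ic, tables, quiet = quiet)
    b <- total_bioerosion(tr, ic, ur, pf, quadrat_area_m2 = qd$area_m2)
    props <- benthic_proportions(ic)$categories
    Cp <- net_production(g$gross, b$total, sed)
    tibble::tibble(
      transect_id = tr$transect_id, site_id = tr$site_id,
      depth_m = tr$depth_m, rugosity = g$rugosity,
      lcc_percent = 100 * props[["coral"]],
      algal_substrate_percent = 100 * sum(props[c(
        "carbonate_substrate", "rubble", "turf_macroalgae",
        "coralline_algae", "halimeda")]),
      gross = g$gross, parrotfish = b$parrotfish, urchin = b$urchin,
      macro = b$macro, micro = b$micro, bioerosion_total = b$total,
      sedimentation_term = sed$sign * sed$annual_rate,
      net = Cp, accretion = vertical_accretion(Cp)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("budget_result", class(out))
  out
}

#' Aggregate transect budgets to site-depth, depth, and overall summaries
#'
#' Mean and standard error of gross production, bioerosion (presented as a
#' negative rate, as in summary tables), net production, and accretion at
#' three aggregation levels. The canonical aggregate accretion
#' (`accretion_of_mean`) applies the quadratic conversion to the mean net
#' production; the mean of per-transect accretions is also emitted
#' (`accretion_mean`) with its SE.
#'
#' @param budget A `budget_result` tibble from [compute_budget()].
#' @return A tibble with `level` (`"site_depth"`, `"depth"`, `"overall"`),
#'   grouping keys, `n`, and `*_mean`/`*_se` columns. Single-transect cells
#'   report `se = 0` and `se_flag = TRUE`.
#' @export
aggregate_budget <- function(budget) {
  stopifnot(inherits(budget, "budget_result") || is.data.frame(budget))
  se <- function(x) if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  summarise_cell <- function(df) {
    tibble::tibble(
      n = nrow(df),
      se_flag = nrow(df) < 2,
      gross_mean = mean(df$gross), gross_se = se(df$gross),
      bioerosion_mean = mean(-df$bioerosion_total),
      bioerosion_se = se(df$bioerosion_total),
      net_mean = mean(df$net), net_se = se(df$net),
      accretion_of_mean = vertical_accretion(mean(df$net)),
      accretion_mean = mean(df$accretion), accretion_se = se(df$accretion)
    )
  }
  by_sd <- dplyr::group_modify(
    dplyr::group_by(budget, .data$site_id, .data$depth_m),
    ~summarise_cell(.x))
  by_sd <- dplyr::mutate(dplyr::ungroup(by_sd), level = "site_depth",
                         .before = 1)
  by_d <- dplyr::group_modify(dplyr::group_by(budget, .data$depth_m),
                              ~summarise_cell(.x))
  by_d <- dplyr::mutate(dplyr::ungroup(by_d), level = "depth", .before = 1)
  overall <- dplyr::mutate(summarise_cell(budget), level = "overall",
                           .before = 1)
  dplyr::bind_rows(by_sd, by_d, overall)
}

#' Round half-up for report tables
#'
#' Base `round()` rounds half to even; printed summary tables use half-up
#' at 2 decimals, so 2.285 renders as 2.29.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
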