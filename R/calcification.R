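#' Coral contribution to gross carbonate production
#'
#' Planar coral calcification of one transect, summed over coral species j:
#' `x = sum_j m_j * px_j * d_j * g_j * 10` (kg CaCO3 m-2 y-1), where `m` is
#' the morphology adjustment coefficient, `px` the planar proportion of the
#' species on the tape, `d` its skeletal density (g cm-3), `g` its vertical
#' growth rate (cm y-1), and 10 converts g cm-2 y-1 to kg m-2 y-1.
#'
#' @param intercepts Intercept records of one transect.
#' @param depth_m Standardized depth below MSL, m (drives *Porites* growth).
#' @param tables A [lookup_tables()] object.
#' @param quiet Suppress taxon-fallback warnings.
#' @return List with `x` (total, kg CaCO3 m-2 y-1) and `per_species`
#'   (named vector of contributions).
#' @export
coral_production <- function(intercepts, depth_m, tables, quiet = TRUE) {
  props <- benthic_proportions(intercepts)
  sp <- props$coral_species
  if (length(sp) == 0)
    return(list(x = 0, per_species = stats::setNames(numeric(0), character(0))))
  contrib <- vapply(names(sp), function(taxon) {
    p <- resolve_coral_params(taxon, depth_m, tables, quiet = quiet)
    p$m * sp[[taxon]] * p$d * p$g * 10
  }, numeric(1))
  list(x = sum(contrib), per_species = contrib)
}

#' Coralline-algae contribution to gross production
#'
#' `ca = rate * pca * 10` (kg CaCO3 m-2 y-1) with `pca` the planar
#' proportion of crustose coralline algae and `rate` in g cm-2 y-1.
#'
#' @param pca Planar proportion of coralline algae in `[0, 1]`.
#' @param cca_rate CCA calcification rate, g cm-2 y-1 (default 0.036).
#' @return kg CaCO3 m-2 y-1. Vectorized over `pca`.
#' @export
cca_production <- function(pca, cca_rate = 0.036) {
  stopifnot(all(pca >= 0 & pca <= 1))
  cca_rate * pca * 10
}

#' *Halimeda* contribution to gross production
#'
#' `h = rate * ph` (kg CaCO3 m-2 y-1) with `ph` the planar proportion of
#' *Halimeda*; the default rate is a 20-m-depth literature value, applied at
#' every depth where *Halimeda* occurs.
#'
#' @param ph Planar proportion of *Halimeda* in `[0, 1]`.
#' @param halimeda_rate Calcification rate, kg m-2 y-1 (default 1.694).
#' @return kg CaCO3 m-2 y-1. Vectorized over `ph`.
#' @export
halimeda_production <- function(ph, halimeda_rate = 1.694) {
  stopifnot(all(ph >= 0 & ph <= 1))
  halimeda_rate * ph
}

#' Gross carbonate production of one transect
#'
#' Rugosity-scaled sum of the calcifier contributions:
#' `gross = r * (x + ca + h)` in kg CaCO3 m-2 y-1, with `r` the transect
#' rugosity; the planar proportions feeding `x`, `ca` and `h` are per unit
#' of contoured (surveyed) surface, so rugosity enters only here.
#'
#' @param transect One row of the `transects` table (needs
#'   `planar_length_m`, `contour_length_m`, `depth_m`).
#' @param intercepts Intercept records of that transect.
#' @param tables A [lookup_tables()] object.
#' @param quiet Suppress taxon-fallback warnings.
#' @return A `calcification_result` list: `x`, `ca`, `h`, `rugosity`,
#'   `gross`, `per_species`.
#' @export
gross_production <- function(transect, intercepts, tables, quiet = TRUE) {
  r <- rugosity(transect$contour_length_m, transect$planar_length_m)
  props <- benthic_proportions(intercepts)
  cp <- coral_production(intercepts, transect$depth_m, tables, quiet = quiet)
  ca <- cca_production(props$categories[["coralline_algae"]], tables$cca_rate)
  h <- halimeda_production(props$categories[["halimeda"]],
                           tables$halimeda_rate)
  structure(
    list(x = cp$x, ca = ca, h = h, rugosity = r,
         gross = r * (cp$x + ca + h), per_species = cp$per_species),
    class = "calcification_result"
  )
}
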