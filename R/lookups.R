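#' Load calcification and bioerosion lookup tables
#'
#' Loads the editable coefficient tables driving the budget engine: coral
#' morphology adjustment coefficients, skeletal densities (g cm-3), vertical
#' growth rates (cm y-1, either fixed or the depth-dependent *Porites*
#' model), and parrotfish bite-rate constants. The package ships synthetic
#' representative defaults (see `inst/extdata/lookups/`); supply your own
#' CSVs with the same schema (`taxon, level, value, source`; growth adds a
#' `kind` column) to localize the engine. Taxon values are never hard-coded
#' in the engine — only the *Porites* depth-model coefficients and the two
#' algal constants are, and both are overridable here.
#'
#' @param morphology_csv,density_csv,growth_csv,brc_csv Paths to replacement
#'   tables; defaults are the shipped synthetic tables.
#' @param cca_rate Calcification rate of crustose coralline algae,
#'   g cm-2 y-1 (default 0.036).
#' @param halimeda_rate Calcification rate of *Halimeda*, kg m-2 y-1
#'   (default 1.694, a 20-m-depth rate).
#' @param porites_coeffs Numeric vector `c(a1, b1, a2, b2)` of the
#'   *Porites* growth model: `(a1 - b1*depth)/10` below 6 m depth and
#'   `a2*exp(-b2*depth)/10` at >= 6 m (defaults 13.37, 0.21, 16.2, 0.032).
#' @return A `lookup_tables` object.
#' @export
lookup_tables <- function(morphology_csv = NULL, density_csv = NULL,
                          growth_csv = NULL, brc_csv = NULL,
                          cca_rate = 0.036, halimeda_rate = 1.694,
                          porites_coeffs = c(13.37, 0.21, 16.2, 0.032)) {
  pick <- function(path, default)
    if (is.null(path)) system.file("extdata", "lookups", default,
                                   package = "reefcarb", mustWork = TRUE)
    else path
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE,
                                    progress = FALSE)
  morph  <- rd(pick(morphology_csv, "coral_morphology_synthetic.csv"))
  dens   <- rd(pick(density_csv, "coral_density_synthetic.csv"))
  growth <- rd(pick(growth_csv, "coral_growth_synthetic.csv"))
  brc    <- rd(pick(brc_csv, "parrotfish_brc_synthetic.csv"))
  stopifnot(all(c("taxon", "level", "value") %in% names(morph)),
            all(c("taxon", "level", "value") %in% names(dens)),
            all(c("taxon", "level", "kind", "value") %in% names(growth)),
            all(c("species", "brc") %in% names(brc)))
  if (any(morph$value <= 0, na.rm = TRUE) ||
      any(dens$value <= 0, na.rm = TRUE) ||
      any(growth$value[growth$kind == "fixed"] <= 0, na.rm = TRUE))
    stop("lookup tables: all coefficient values must be > 0", call. = FALSE)
  stopifnot(length(porites_coeffs) == 4, cca_rate > 0, halimeda_rate > 0)
  structure(
    list(morphology = morph, density = dens, growth = growth, brc = brc,
         cca_rate = cca_rate, halimeda_rate = halimeda_rate,
         porites_coeffs = porites_coeffs),
    class = "lookup_tables"
  )
}

#' @export
print.lookup_tables <- function(x, ...) {
  cat("<lookup_tables>\n")
  cat(sprintf("  morphology: %d entries | density: %d | growth: %d | brc: %d\n",
              nrow(x$morphology), nrow(x$density), nrow(x$growth),
              nrow(x$brc)))
  cat(sprintf("  cca_rate = %g g cm-2 y-1; halimeda_rate = %g kg m-2 y-1\n",
              x$cca_rate, x$halimeda_rate))
  invisible(x)
}

# Species -> genus -> default fallback on one table; returns the matched row.
lookup_row <- function(tab, taxon) {
  hit <- tab[tab$level == "species" & tab$taxon == taxon, , drop = FALSE]
  if (nrow(hit)) return(list(row = hit[1, ], level = "species"))
  genus <- strsplit(taxon, " ", fixed = TRUE)[[1]][1]
  hit <- tab[tab$level == "genus" & tab$taxon == genus, , drop = FALSE]
  if (nrow(hit)) return(list(row = hit[1, ], level = "genus"))
  hit <- tab[tab$level == "default", , drop = FALSE]
  if (nrow(hit)) return(list(row = hit[1, ], level = "default"))
  stop("unresolvable coral taxon '", taxon,
       "': tried species '", taxon, "', genus '", genus,
       "', and the default entry", call. = FALSE)
}

#' Depth-dependent growth rate of *Porites* corals
#'
#' Vertical extension rate (cm y-1) of *Porites* as a function of depth
#' below MSL: linear `(13.37 - 0.21*depth)/10` shallower than 6 m and
#' exponential `16.2*exp(-0.032*depth)/10` at 6 m and deeper, applied
#' exactly as published (the two branches meet only approximately near 6 m;
#' the >= 6 m rule is applied as printed).
#'
#' @param depth_m Depth below MSL, m (>= 0). Vectorized.
#' @param coeffs The four model coefficients (see [lookup_tables()]).
#' @return Growth rate, cm y-1.
#' @examples
#' porites_growth_rate(0)   # 1.337
#' porites_growth_rate(17)  # ~0.940
#' @export
porites_growth_rate <- function(depth_m,
                                coeffs = c(13.37, 0.21, 16.2, 0.032)) {
  stopifnot(all(depth_m >= 0), length(coeffs) == 4)
  ifelse(depth_m < 6,
         (coeffs[1] - coeffs[2] * depth_m) / 10,
         coeffs[3] * exp(-coeffs[4] * depth_m) / 10)
}

#' Resolve calcification parameters for a coral taxon
#'
#' Returns the morphology coefficient `m`, skeletal density `d` (g cm-3)
#' and vertical growth rate `g` (cm y-1) for one coral taxon, preferring a
#' species-level table entry and falling back to genus, then to the default
#' row (with a warning naming the fallback). Growth entries of kind
#' `porites_depth_model` are evaluated with [porites_growth_rate()] at the
#' transect's standardized depth.
#'
#' @param taxon Coral species or genus label, e.g. `"Porites lobata"`.
#' @param depth_m Standardized depth below MSL, m.
#' @param tables A [lookup_tables()] object.
#' @param quiet Suppress fallback warnings.
#' @return Named list `m`, `d`, `g` plus `resolution` (the levels matched in
#'   each table).
#' @export
resolve_coral_params <- function(taxon, depth_m, tables, quiet = FALSE) {
  stopifnot(inherits(tables, "lookup_tables"))
  m_hit <- lookup_row(tables$morphology, taxon)
  d_hit <- lookup_row(tables$density, taxon)
  g_hit <- lookup_row(tables$growth, taxon)
  levels <- c(m = m_hit$level, d = d_hit$level, g = g_hit$level)
  if (!quiet && any(levels != "species"))
    warning("taxon '", taxon, "' resolved at ",
            paste0(names(levels)[levels != "species"], "=",
                   levels[levels != "species"], collapse = ", "),
            " level", call. = FALSE)
  g <- if (identical(g_hit$row$kind, "porites_depth_model"))
    porites_growth_rate(depth_m, tables$porites_coeffs)
  else g_hit$row$value
  list(m = m_hit$row$value, d = d_hit$row$value, g = g,
       resolution = levels)
}

# Parrotfish bite-rate constant with sister-species (default-row) fallback.
resolve_brc <- function(species, tables, quiet = FALSE) {
  hit <- tables$brc[tables$brc$species == species, , drop = FALSE]
  if (nrow(hit)) return(hit$brc[1])
  def <- tables$brc[tables$brc$species == "default", , drop = FALSE]
  if (!nrow(def))
    stop("no bite-rate constant for parrotfish species '", species,
         "' and no default entry", call. = FALSE)
  if (!quiet)
    warning("parrotfish '", species, "': using default bite-rate constant",
            call. = FALSE)
  def$brc[1]
}
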