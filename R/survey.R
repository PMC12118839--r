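#' Benthic category vocabulary
#'
#' Closed vocabulary of benthic categories recorded under every centimetre of
#' the contoured line-intercept tape. `turf_macroalgae` denotes turf or
#' macroalgae growing on carbonate substrate; `other_noncarbonate` collects
#' soft corals, sponges and other non-calcifying cover.
#'
#' @export
benthic_categories <- c(
  "coral", "coralline_algae", "halimeda", "carbonate_substrate",
  "rubble", "turf_macroalgae", "sand", "other_noncarbonate"
)

#' Sea-urchin erosion groups
#'
#' Functional groups used by the size-specific urchin erosion models:
#' Diadematidae (*Diadema* and *Echinothrix*, which share one coefficient
#' set), *Echinometra*, other eroding species, and non-eroding species
#' (*Tripneustes gratilla*).
#'
#' @export
urchin_groups <- c("diadematidae", "echinometra", "other_eroding", "non_eroding")

survey_tables <- c("transects", "intercepts", "quadrats", "urchins",
                   "belts", "fishes", "pairing")

#' Construct a survey dataset
#'
#' Bundles the seven normalized survey tables into a validated
#' `survey_dataset` object. Most users will obtain one from [read_survey()]
#' or [generate_survey()] rather than calling this directly.
#'
#' @param transects Tibble with columns `transect_id`, `site_id`, `depth_m`,
#'   `planar_length_m`, `contour_length_m`.
#' @param intercepts Tibble with columns `transect_id`, `position_cm`,
#'   `category`, `taxon`; one row per contour centimetre.
#' @param quadrats Tibble with columns `quadrat_id`, `site_id`, `depth_m`,
#'   `area_m2`.
#' @param urchins Tibble with columns `quadrat_id`, `species`, `group`,
#'   `test_diameter_mm`.
#' @param belts Tibble with columns `belt_id`, `site_id`, `depth_m`,
#'   `length_m`, `width_m`.
#' @param fishes Tibble with columns `belt_id`, `species`, `fork_length_cm`.
#' @param pairing Tibble with columns `transect_id`, `quadrat_id` mapping each
#'   benthic transect to its co-located urchin quadrat (one-to-one).
#' @return A `survey_dataset`: a named list of the seven tables.
#' @export
survey_dataset <- function(transects, intercepts, quadrats, urchins,
                           belts, fishes, pairing) {
  out <- list(
    transects  = tibble::as_tibble(transects),
    intercepts = tibble::as_tibble(intercepts),
    quadrats   = tibble::as_tibble(quadrats),
    urchins    = tibble::as_tibble(urchins),
    belts      = tibble::as_tibble(belts),
    fishes     = tibble::as_tibble(fishes),
    pairing    = tibble::as_tibble(pairing)
  )
  class(out) <- "survey_dataset"
  validate_survey(out)
  out
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat(sprintf("  %d benthic transects (%d intercept records)\n",
              nrow(x$transects), nrow(x$intercepts)))
  cat(sprintf("  %d urchin quadrats (%d urchins)\n",
              nrow(x$quadrats), nrow(x$urchins)))
  cat(sprintf("  %d fish belt transects (%d fishes)\n",
              nrow(x$belts), nrow(x$fishes)))
  cells <- dplyr::distinct(x$transects, .data$site_id, .data$depth_m)
  cat(sprintf("  %d site x depth cells\n", nrow(cells)))
  invisible(x)
}

# Type invariants for every table; stops with the offending row index.
validate_survey <- function(x) {
  stopifnot(inherits(x, "survey_dataset"))
  tr <- x$transects
  if (nrow(tr) > 0) {
    if (any(bad <- !(tr$planar_length_m > 0)))
      stop("transects: planar_length_m must be > 0 (row ",
           which(bad)[1], ")", call. = FALSE)
    if (any(bad <- tr$contour_length_m < tr$planar_length_m))
      stop("transects: contour_length_m < planar_length_m (row ",
           which(bad)[1], "): tape-reading inconsistency", call. = FALSE)
    if (anyDuplicated(tr$transect_id))
      stop("transects: duplicated transect_id", call. = FALSE)
  }
  ic <- x$intercepts
  if (nrow(ic) > 0) {
    unknown <- !(ic$category %in% benthic_categories)
    if (any(unknown))
      stop("intercepts: unknown benthic category '",
           ic$category[which(unknown)[1]], "' (row ", which(unknown)[1], ")",
           call. = FALSE)
    # every cm of the contoured tape covered exactly once
    cov <- dplyr::summarise(
      dplyr::group_by(ic, .data$transect_id),
      n = dplyr::n(),
      ok = all(sort(.data$position_cm) == seq_len(dplyr::n())),
      .groups = "drop"
    )
    cov <- dplyr::left_join(cov, tr, by = "transect_id")
    bad <- !cov$ok | cov$n != round(cov$contour_length_m * 100)
    if (any(bad))
      stop("intercepts: transect '", cov$transect_id[which(bad)[1]],
           "' does not tile its contour tape at 1-cm resolution",
           call. = FALSE)
  }
  qd <- x$quadrats
  if (nrow(qd) > 0 && any(bad <- !(qd$area_m2 > 0)))
    stop("quadrats: area_m2 must be > 0 (row ", which(bad)[1], ")",
         call. = FALSE)
  ur <- x$urchins
  if (nrow(ur) > 0) {
    if (any(bad <- !(ur$test_diameter_mm > 0)))
      stop("urchins: test_diameter_mm must be > 0 (row ", which(bad)[1], ")",
           call. = FALSE)
    if (any(bad <- !(ur$group %in% urchin_groups)))
      stop("urchins: unknown group '", ur$group[which(bad)[1]],
           "' (row ", which(bad)[1], ")", call. = FALSE)
  }
  fs <- x$fishes
  if (nrow(fs) > 0 && any(bad <- !(fs$fork_length_cm > 0)))
    stop("fishes: fork_length_cm must be > 0 (row ", which(bad)[1], ")",
         call. = FALSE)
  bl <- x$belts
  if (nrow(bl) > 0 && any(bad <- !(bl$length_m * bl$width_m > 0)))
    stop("belts: length_m * width_m must be > 0 (row ", which(bad)[1], ")",
         call. = FALSE)
  pr <- x$pairing
  if (nrow(pr) > 0) {
    if (anyDuplicated(pr$transect_id) || anyDuplicated(pr$quadrat_id))
      stop("pairing: transect <-> quadrat mapping must be one-to-one",
           call. = FALSE)
    if (!all(pr$transect_id %in% tr$transect_id) ||
        !all(pr$quadrat_id %in% qd$quadrat_id))
      stop("pairing: references unknown transect or quadrat ids",
           call. = FALSE)
  }
  invisible(x)
}

#' Read a survey dataset from delimited text files
#'
#' Reads the seven normalized survey tables (CSV) from a directory and
#' returns a validated [survey_dataset()]. Rows violating type invariants
#' (negative diameters, unknown benthic categories, tapes that do not tile at
#' 1-cm resolution) are fatal, with the offending row named.
#'
#' @param dir Directory containing `transects.csv`, `intercepts.csv`,
#'   `quadrats.csv`, `urchins.csv`, `belts.csv`, `fishes.csv`, `pairing.csv`.
#' @param quiet Suppress the per-cell record-count log.
#' @return A `survey_dataset`.
#' @seealso [write_survey()] for the inverse; [read_survey_xlsx()] for Excel
#'   workbooks with the same sheet schema.
#' @export
read_survey <- function(dir, quiet = FALSE) {
  paths <- file.path(dir, paste0(survey_tables, ".csv"))
  names(paths) <- survey_tables
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing survey file(s): ", paste(paths[missing], collapse = ", "),
         call. = FALSE)
  tabs <- lapply(paths, function(p) {
    tb <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    if (nrow(tb) == 0 && !basename(p) %in%
          c("urchins.csv", "fishes.csv", "halimeda"))
      if (basename(p) %in% c("transects.csv", "intercepts.csv",
                             "quadrats.csv", "belts.csv", "pairing.csv"))
        stop("empty survey file: ", p, call. = FALSE)
    tb
  })
  required_cols <- list(
    transects  = c("transect_id", "site_id", "depth_m",
                   "planar_length_m", "contour_length_m"),
    intercepts = c("transect_id", "position_cm", "category", "taxon"),
    quadrats   = c("quadrat_id", "site_id", "depth_m", "area_m2"),
    urchins    = c("quadrat_id", "species", "group", "test_diameter_mm"),
    belts      = c("belt_id", "site_id", "depth_m", "length_m", "width_m"),
    fishes     = c("belt_id", "species", "fork_length_cm"),
    pairing    = c("transect_id", "quadrat_id")
  )
  for (nm in survey_tables) {
    miss <- setdiff(required_cols[[nm]], names(tabs[[nm]]))
    if (length(miss))
      stop(nm, ".csv: missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  ds <- survey_dataset(tabs$transects, tabs$intercepts, tabs$quadrats,
                       tabs$urchins, tabs$belts, tabs$fishes, tabs$pairing)
  if (!quiet) {
    counts <- dplyr::count(ds$transects, .data$site_id, .data$depth_m)
    message("read_survey: ", nrow(ds$transects), " transects, ",
            nrow(ds$quadrats), " quadrats, ", nrow(ds$belts),
            " belts across ", nrow(counts), " site x depth cells")
  }
  ds
}

#' Write a survey dataset to CSV files
#'
#' Inverse of [read_survey()]: writes the seven normalized tables to a
#' directory so that `read_survey(write_survey(x, d))` reproduces `x`
#' record-for-record.
#'
#' @param x A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(x, dir) {
  stopifnot(inherits(x, "survey_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in survey_tables)
    readr::write_csv(x[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  invisible(dir)
}

#' Read a survey dataset from an Excel workbook
#'
#' Convenience reader for field data distributed as a single workbook whose
#' sheets follow the same schema as the CSV tables of [read_survey()]
#' (sheets named `transects`, `intercepts`, `quadrats`, `urchins`, `belts`,
#' `fishes`, `pairing`).
#'
#' @param path Path to an `.xlsx` workbook.
#' @return A `survey_dataset`.
#' @export
read_survey_xlsx <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("read_survey_xlsx() requires the 'readxl' package", call. = FALSE)
  tabs <- lapply(survey_tables, function(nm) readxl::read_excel(path, sheet = nm))
  names(tabs) <- survey_tables
  survey_dataset(tabs$transects, tabs$intercepts, tabs$quadrats,
                 tabs$urchins, tabs$belts, tabs$fishes, tabs$pairing)
}

#' Reef rugosity from tape lengths
#'
#' Topographic-complexity index: the contoured tape length (total reef
#' surface) divided by the planar tape length. Always >= 1; a flat reef has
#' rugosity exactly 1.
#'
#' @param contour_length_m Contoured (surface-following) tape length, m.
#' @param planar_length_m Planar (linear) tape length, m (2.0 by design).
#' @return Dimensionless ratio >= 1. Vectorized.
#' @examples
#' rugosity(3.0, 2.0)  # 1.5
#' @export
rugosity <- function(contour_length_m, planar_length_m) {
  if (any(contour_length_m <= 0) || any(planar_length_m <= 0))
    stop("tape lengths must be positive", call. = FALSE)
  if (any(contour_length_m < planar_length_m))
    stop("contour length < planar length: tape-reading inconsistency",
         call. = FALSE)
  contour_length_m / planar_length_m
}

#' Planar benthic proportions of one transect
#'
#' Computes the proportion of the contoured tape occupied by each benthic
#' category (and, within coral, by each species) as centimetres of category
#' divided by total contour centimetres. Category proportions form a
#' partition (they sum to 1).
#'
#' @param intercepts Tibble of 1-cm intercept records for one transect
#'   (columns `category`, `taxon`).
#' @return A list with `categories` (named numeric vector over
#'   [benthic_categories], zeros included) and `coral_species` (named vector
#'   of per-species coral proportions).
#' @export
benthic_proportions <- function(intercepts) {
  if (nrow(intercepts) == 0)
    stop("benthic_proportions: empty intercept list", call. = FALSE)
  n <- nrow(intercepts)
  cat_counts <- table(factor(intercepts$category, levels = benthic_categories))
  categories <- as.numeric(cat_counts) / n
  names(categories) <- benthic_categories
  coral <- intercepts[intercepts$category == "coral", , drop = FALSE]
  coral_species <- if (nrow(coral) > 0) {
    tab <- table(coral$taxon)
    stats::setNames(as.numeric(tab) / n, names(tab))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  list(categories = categories, coral_species = coral_species)
}

#' Standardize raw depth to depth below mean sea level
#'
#' Subtracts a tide offset (recorded at survey time, supplied via config;
#' defaults to 0) from the raw depth-gauge reading. Negative results are
#' clamped to 0 with a warning.
#'
#' @param raw_depth_m Raw recorded depth, m.
#' @param tide_offset_m Tide height above MSL at survey time, m. Must be
#'   supplied (possibly 0) unless `assume_msl = TRUE`.
#' @param assume_msl If `TRUE`, a missing offset is treated as 0.
#' @return Depth below MSL, m (>= 0). Vectorized.
#' @export
standardize_depth <- function(raw_depth_m, tide_offset_m = NULL,
                              assume_msl = FALSE) {
  if (is.null(tide_offset_m)) {
    if (!assume_msl)
      stop("tide_offset_m missing; pass assume_msl = TRUE to treat raw ",
           "depths as MSL depths", call. = FALSE)
    tide_offset_m <- 0
  }
  d <- raw_depth_m - tide_offset_m
  if (any(d < 0)) {
    warning("depth below 0 after tide adjustment; clamped to 0",
            call. = FALSE)
    d <- pmax(d, 0)
  }
  d
}

#' Coefficient-of-variation curve over replicate quadrats
#'
#' Survey-effort diagnostic: for one species' per-quadrat counts, computes
#' CV(n) = sd/mean over the first `n` quadrats for n = 3..`max_n`, and the
#' plateau replicate number — the smallest n at which successive CV changes
#' stay below `tol` for `k` consecutive steps. Used to choose how many
#' replicate quadrats are needed to capture urchin variability.
#'
#' @param counts Integer vector of per-quadrat counts, in survey order.
#' @param max_n Largest prefix length to evaluate (default `length(counts)`).
#' @param tol Plateau tolerance on |CV(n) - CV(n+1)| (default 0.05).
#' @param k Number of consecutive sub-tolerance steps required (default 2).
#' @return A list with `curve` (tibble of `n`, `cv`; `cv` is `NA` where the
#'   prefix mean is 0) and `plateau_n` (integer, `NA` if no plateau).
#' @export
cv_replicate_curve <- function(counts, max_n = length(counts),
                               tol = 0.05, k = 2) {
  if (length(counts) < 3)
    stop("cv_replicate_curve: need at least 3 counts", call. = FALSE)
  max_n <- min(max_n, length(counts))
  ns <- 3:max_n
  cvs <- vapply(ns, function(n) {
    x <- counts[seq_len(n)]
    m <- mean(x)
    if (m == 0) NA_real_ else stats::sd(x) / m
  }, numeric(1))
  plateau_n <- NA_integer_
  dif <- abs(diff(cvs))
  ok <- !is.na(dif) & dif < tol
  # k consecutive sub-tolerance steps, allowing the run to truncate at the
  # end of the series (a short flat tail still counts as a plateau)
  for (i in seq_along(ok)) {
    j <- i:min(i + k - 1, length(ok))
    if (all(ok[j])) { plateau_n <- ns[i]; break }
  }
  list(curve = tibble::tibble(n = ns, cv = cvs), plateau_n = plateau_n)
}
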