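#' Construct a georeferenced raster grid
#'
#' Minimal single-band raster container used for the 2-m live-coral-cover
#' input and predicted net-production/accretion outputs: a numeric matrix
#' (rows = north to south, columns = west to east) with lower-left-corner
#' georeferencing, square cells, a nodata value, and opaque CRS metadata.
#' File I/O uses the Esri ASCII grid text format ([read_ascii_grid()],
#' [write_ascii_grid()]).
#'
#' @param values Numeric matrix; `NA` entries are nodata.
#' @param xllcorner,yllcorner Coordinates of the lower-left corner.
#' @param cellsize Cell edge length (map units; 2 for a 2-m product).
#' @param nodata Nodata sentinel used on disk (default -9999).
#' @param crs Free-text CRS metadata carried through, never interpreted.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, xllcorner = 0, yllcorner = 0, cellsize = 2,
                        nodata = -9999, crs = NA_character_) {
  stopifnot(is.matrix(values), is.numeric(values), cellsize > 0)
  structure(list(values = values, xllcorner = xllcorner,
                 yllcorner = yllcorner, cellsize = cellsize,
                 nodata = nodata, crs = crs),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells @ %g units, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize,
              x$xllcorner, x$yllcorner))
  cat(sprintf("  %d valid cells; range [%g, %g]; crs: %s\n", length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              x$crs))
  invisible(x)
}

#' Read an Esri ASCII grid
#'
#' Parses the plain-text `.asc` raster format (6-line header of `ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`, followed
#' by rows of values north to south). A sidecar `.prj` file, if present, is
#' read into the `crs` field.
#'
#' @param path Path to an `.asc` file.
#' @return A [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("read_ascii_grid: incomplete header in ", path, call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("read_ascii_grid: expected ", hdr$ncols * hdr$nrows,
         " values, found ", length(vals), call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  prj <- sub("\\.asc$", ".prj", path)
  crs <- if (file.exists(prj)) paste(readLines(prj), collapse = "\n")
         else NA_character_
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata, crs)
}

#' Write an Esri ASCII grid
#'
#' @param x A [raster_grid()].
#' @param path Output `.asc` path; CRS metadata, when present, goes to a
#'   sidecar `.prj`.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path) {
  stopifnot(inherits(x, "raster_grid"))
  m <- x$values
  m[is.na(m)] <- x$nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", format(x$xllcorner, scientific = FALSE)),
           paste("yllcorner", format(x$yllcorner, scientific = FALSE)),
           paste("cellsize", format(x$cellsize, scientific = FALSE)),
           paste("NODATA_value", format(x$nodata, scientific = FALSE)))
  body <- apply(m, 1, function(row)
    paste(format(row, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, body), path)
  if (!is.na(x$crs))
    writeLines(x$crs, sub("\\.asc$", ".prj", path))
  invisible(path)
}
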