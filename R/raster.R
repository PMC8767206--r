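#' Construct a discrete climate-class raster
#'
#' A `climate_raster` holds a grid of integer class codes on a regular
#' lon/lat grid (WGS84) together with a legend mapping each code to a
#' three-tier climate-class label (e.g. `"Cfb"`). Cells use the half-open
#' convention `[west, east) x (south, north]`: a point exactly on a cell's
#' western or northern edge belongs to that cell; points on the raster's
#' eastern or southern outer boundary are outside the extent.
#'
#' @param grid integer matrix of class codes, row 1 = northernmost row.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid.
#' @param cellsize cell edge length in decimal degrees (square cells).
#' @param nodata integer code marking cells with no class (ocean etc.).
#' @param legend data frame with columns `code` (integer) and `label`
#'   (character); must cover every non-nodata value in `grid`.
#' @return an object of class `climate_raster`.
#' @export
climate_raster <- function(grid, xll, yll, cellsize, nodata = -9999L, legend) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  legend <- validate_legend(legend)
  codes <- unique(grid[grid != nodata & !is.na(grid)])
  unknown <- setdiff(codes, legend$code)
  if (length(unknown) > 0L) {
    stop("grid contains codes absent from the legend: ",
         paste(unknown, collapse = ", "))
  }
  structure(
    list(grid = grid, xll = xll, yll = yll, cellsize = cellsize,
         nodata = as.integer(nodata), legend = legend),
    class = "climate_raster"
  )
}

validate_legend <- function(legend) {
  if (!all(c("code", "label") %in% names(legend))) {
    stop("legend must have columns 'code' and 'label'")
  }
  legend <- data.frame(code = as.integer(legend$code),
                       label = as.character(legend$label),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(legend$code)) stop("legend codes must be unique")
  if (anyDuplicated(legend$label)) stop("legend labels must be unique")
  if (nrow(legend) > 30L) {
    stop("legend has ", nrow(legend), " entries; at most 30 discrete ",
         "climate classes are supported")
  }
  legend
}

#' @export
print.climate_raster <- function(x, ...) {
  cat(sprintf("climate_raster: %d x %d cells of %g deg, %d classes\n",
              nrow(x$grid), ncol(x$grid), x$cellsize, nrow(x$legend)))
  cat(sprintf("  extent: lon [%g, %g), lat (%g, %g]\n",
              x$xll, x$xll + ncol(x$grid) * x$cellsize,
              x$yll, x$yll + nrow(x$grid) * x$cellsize))
  invisible(x)
}

#' Read an ESRI ASCII grid as a climate raster
#'
#' Parses the plain-text ESRI ASCII grid format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`nodata_value` header followed by
#' rows of integers, north first).
#'
#' @param path path to the `.asc` file.
#' @param legend legend data frame (see [climate_raster()]) or path to a
#'   legend CSV readable by [read_legend()].
#' @return a [climate_raster()] object.
#' @export
read_ascii_raster <- function(path, legend) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header incomplete; need ", paste(need, collapse = ", "))
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = integer(), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  }
  grid <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (is.character(legend)) legend <- read_legend(legend)
  climate_raster(grid, xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, nodata = nodata, legend = legend)
}

#' Write a climate raster as an ESRI ASCII grid
#'
#' @param raster a [climate_raster()] object.
#' @param path output path for the `.asc` file.
#' @return `path`, invisibly.
#' @export
write_ascii_raster <- function(raster, path) {
  stopifnot(inherits(raster, "climate_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(raster$grid)),
    paste("nrows", nrow(raster$grid)),
    paste("xllcorner", format(raster$xll, scientific = FALSE)),
    paste("yllcorner", format(raster$yll, scientific = FALSE)),
    paste("cellsize", format(raster$cellsize, scientific = FALSE)),
    paste("nodata_value", raster$nodata)
  ), con)
  writeLines(apply(raster$grid, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a climate-class legend
#'
#' Reads a two-column CSV mapping integer class codes to three-tier class
#' labels. The bundled 30-class Koeppen-Geiger legend ships at
#' `system.file("extdata", "koppen_legend.csv", package = "nichebreadth")`.
#'
#' @param path path to a CSV with columns `code,label`.
#' @return data frame with integer `code` and character `label`.
#' @export
read_legend <- function(path) {
  validate_legend(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Look up the climate class at a point
#'
#' Vectorised point-in-cell lookup under the half-open cell convention
#' `[west, east) x (south, north]`. Points outside the raster extent or in
#' nodata cells return `NA`.
#'
#' @param raster a [climate_raster()] object.
#' @param longitude,latitude numeric vectors of equal length (decimal
#'   degrees, WGS84).
#' @return character vector of class labels, `NA` where no class applies.
#' @export
lookup_class <- function(raster, longitude, latitude) {
  stopifnot(inherits(raster, "climate_raster"),
            length(longitude) == length(latitude))
  nr <- nrow(raster$grid)
  nc <- ncol(raster$grid)
  ytop <- raster$yll + nr * raster$cellsize
  xright <- raster$xll + nc * raster$cellsize
  inside <- is.finite(longitude) & is.finite(latitude) &
    longitude >= raster$xll & longitude < xright &
    latitude > raster$yll & latitude <= ytop
  out <- rep(NA_character_, length(longitude))
  if (!any(inside)) return(out)
  col <- floor((longitude[inside] - raster$xll) / raster$cellsize) + 1L
  row <- floor((ytop - latitude[inside]) / raster$cellsize) + 1L
  row[row < 1L] <- 1L # latitude exactly at the northern boundary
  code <- raster$grid[cbind(row, col)]
  lab <- raster$legend$label[match(code, raster$legend$code)]
  lab[code == raster$nodata] <- NA_character_
  out[inside] <- lab
  out
}

#' The bundled 30-class Koeppen-Geiger legend
#'
#' Convenience accessor for the package's three-tier Koeppen-Geiger legend
#' (5 main groups subdivided into 30 discrete classes).
#'
#' @return data frame with columns `code` and `label` (30 rows).
#' @export
koppen_legend <- function() {
  read_legend(system.file("extdata", "koppen_legend.csv",
                          package = "nichebreadth", mustWork = TRUE))
}
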