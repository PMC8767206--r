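#' Read species occurrence records
#'
#' Reads a delimited table of georeferenced occurrences and drops rows
#' whose latitude or longitude is missing or unparseable. The number of
#' dropped rows is reported with a message and attached as the
#' `n_dropped` attribute; surviving rows keep their input order.
#'
#' @param source path to a delimited file, or a data frame.
#' @param species_col,lat_col,lon_col column names holding the taxon name,
#'   latitude and longitude.
#' @param sep field separator when `source` is a path (`","` for CSV,
#'   `"\t"` for TSV).
#' @param range_check what to do with coordinates outside
#'   \code{[-90, 90] x [-180, 180]}: keep silently (`"ignore"`), keep with a
#'   warning (`"warn"`, default), or fail (`"error"`). Coordinates are
#'   assumed WGS84 lon/lat; no reprojection is performed.
#' @return data frame with columns `species_id`, `latitude`, `longitude`
#'   and attribute `n_dropped` (rows removed for missing coordinates).
#' @export
read_occurrences <- function(source, species_col = "species",
                             lat_col = "latitude", lon_col = "longitude",
                             sep = ",",
                             range_check = c("warn", "ignore", "error")) {
  range_check <- match.arg(range_check)
  tab <- if (is.data.frame(source)) source else {
    utils::read.table(source, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "")
  }
  missing_cols <- setdiff(c(species_col, lat_col, lon_col), names(tab))
  if (length(missing_cols) > 0L) {
    stop("occurrence table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  lat <- suppressWarnings(as.numeric(as.character(tab[[lat_col]])))
  lon <- suppressWarnings(as.numeric(as.character(tab[[lon_col]])))
  keep <- is.finite(lat) & is.finite(lon)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " record(s) dropped for missing or unparseable ",
            "coordinates")
  }
  out <- data.frame(species_id = as.character(tab[[species_col]])[keep],
                    latitude = lat[keep], longitude = lon[keep],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("no occurrence records with usable coordinates")
  if (any(out$species_id == "" | is.na(out$species_id))) {
    stop("empty species identifier in occurrence table")
  }
  suspicious <- abs(out$latitude) > 90 | abs(out$longitude) > 180
  if (any(suspicious) && range_check != "ignore") {
    msg <- paste0(sum(suspicious), " record(s) outside [-90,90] x ",
                  "[-180,180]; coordinates are expected as WGS84 lon/lat")
    if (range_check == "error") stop(msg) else warning(msg)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Tally climate classes per species
#'
#' Looks up the climate class of every occurrence and counts, per species,
#' how many records fall in each class. Records that hit nodata cells or
#' fall outside the raster extent are excluded from the counts and tracked
#' per species in the `n_nodata` attribute.
#'
#' @param records occurrence data frame from [read_occurrences()].
#' @param raster a [climate_raster()] object.
#' @return integer matrix (species x legend labels) of counts, class
#'   `class_tally`, with attributes `n_points` (records per species) and
#'   `n_nodata` (records per species with no class).
#' @export
tally_classes <- function(records, raster) {
  stopifnot(nrow(records) > 0L)
  labels <- lookup_class(raster, records$longitude, records$latitude)
  species <- sort(unique(records$species_id))
  classes <- raster$legend$label
  counts <- matrix(0L, nrow = length(species), ncol = length(classes),
                   dimnames = list(species, classes))
  ok <- !is.na(labels)
  if (any(ok)) {
    tab <- table(factor(records$species_id[ok], levels = species),
                 factor(labels[ok], levels = classes))
    counts[] <- as.integer(tab)
  }
  n_points <- as.integer(table(factor(records$species_id, levels = species)))
  names(n_points) <- species
  n_nodata <- as.integer(table(factor(records$species_id[!ok],
                                      levels = species)))
  names(n_nodata) <- species
  structure(counts, class = c("class_tally", "matrix"),
            n_points = n_points, n_nodata = n_nodata)
}

#' Remove rarely occupied climate classes
#'
#' Applies the minimum-occurrence rule independently per species and per
#' class: a class with `threshold` or fewer of that species' occurrences is
#' removed (count set to zero), guarding against by-chance presences.
#'
#' @param tally a `class_tally` matrix from [tally_classes()].
#' @param threshold classes with counts less than or equal to this are
#'   dropped (default 3, i.e. a class needs at least 4 records to count).
#' @return the filtered `class_tally`.
#' @export
filter_min_occurrences <- function(tally, threshold = 3L) {
  stopifnot(threshold >= 0L)
  out <- unclass(tally)
  out[out <= threshold] <- 0L
  structure(out, class = class(tally),
            n_points = attr(tally, "n_points"),
            n_nodata = attr(tally, "n_nodata"),
            threshold = threshold)
}

#' Niche breadth per species
#'
#' Counts, for each species, the discrete climate classes retained after
#' [filter_min_occurrences()]: the niche-breadth proxy `B_s`.
#'
#' @param tally a filtered `class_tally`.
#' @return data frame with `species_id`, `B_s` (number of retained
#'   classes), `retained_classes` (semicolon-joined labels), `n_points`,
#'   `n_nodata`. Species whose every class was filtered away are kept with
#'   `B_s = 0`.
#' @export
niche_breadth <- function(tally) {
  m <- unclass(tally)
  retained <- apply(m > 0L, 1L, function(r) sort(colnames(m)[r]),
                    simplify = FALSE)
  data.frame(
    species_id = rownames(m),
    B_s = vapply(retained, length, integer(1)),
    retained_classes = vapply(retained, paste, character(1),
                              collapse = ";"),
    n_points = as.integer(attr(tally, "n_points")[rownames(m)]),
    n_nodata = as.integer(attr(tally, "n_nodata")[rownames(m)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Occurrence table to niche breadth in one call
#'
#' Convenience chain: [tally_classes()], [filter_min_occurrences()],
#' [niche_breadth()].
#'
#' @inheritParams tally_classes
#' @inheritParams filter_min_occurrences
#' @return see [niche_breadth()].
#' @export
compute_breadth <- function(records, raster, threshold = 3L) {
  niche_breadth(filter_min_occurrences(tally_classes(records, raster),
                                       threshold))
}
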