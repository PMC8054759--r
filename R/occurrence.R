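#' Read occurrence records from CSV
#'
#' Expects the columns `species`, `lon`, `lat`, `year`, `month`, `day`,
#' `basis_of_record`. Rows with unparseable or out-of-range coordinates or
#' months are rejected with a message naming their line numbers.
#'
#' @param path CSV file path.
#' @return An occurrence data.frame.
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "lon", "lat", "year", "month", "day", "basis_of_record")
  missing <- setdiff(required, names(occ))
  if (length(missing))
    stop("occurrence file is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  occ$lon <- suppressWarnings(as.numeric(occ$lon))
  occ$lat <- suppressWarnings(as.numeric(occ$lat))
  occ$month <- suppressWarnings(as.integer(occ$month))
  bad <- !is.finite(occ$lon) | !is.finite(occ$lat) |
    occ$lon < -180 | occ$lon > 180 | occ$lat < -90 | occ$lat > 90 |
    (!is.na(occ$month) & !(occ$month %in% 1:12))
  if (any(bad)) {
    message(sum(bad), " malformed occurrence row(s) rejected (lines ",
            paste(utils::head(which(bad) + 1L, 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "", ")")
    occ <- occ[!bad, , drop = FALSE]
  }
  occ
}

#' Filter raw occurrence records
#'
#' Retains records with valid, non-(0,0) coordinates, an allowed record type,
#' and a year inside the trailing window `(ref_year - window_years, ref_year]`;
#' exact duplicates on (species, lon, lat, year, month, day) collapse to one.
#'
#' @param occ occurrence data.frame.
#' @param ref_year reference year (window upper bound, inclusive).
#' @param window_years window length in years (default 50, the usual
#'   recency cutoff for archival occurrence data).
#' @param allowed_bases accepted `basis_of_record` values.
#' @return Filtered occurrence data.frame.
#' @export
filter_records <- function(occ, ref_year, window_years = 50,
                           allowed_bases = c("PRESERVED_SPECIMEN",
                                             "HUMAN_OBSERVATION",
                                             "MATERIAL_SAMPLE")) {
  required <- c("species", "lon", "lat", "year", "month", "day", "basis_of_record")
  missing <- setdiff(required, names(occ))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- is.finite(occ$lon) & is.finite(occ$lat) &
    occ$lon >= -180 & occ$lon <= 180 & occ$lat >= -90 & occ$lat <= 90 &
    !(occ$lon == 0 & occ$lat == 0) &
    occ$basis_of_record %in% allowed_bases &
    is.finite(occ$year) & occ$year > ref_year - window_years & occ$year <= ref_year
  occ <- occ[keep, , drop = FALSE]
  key <- paste(occ$species, occ$lon, occ$lat, occ$year, occ$month, occ$day,
               sep = "\r")
  occ[!duplicated(key), , drop = FALSE]
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Reduces sampling bias by keeping at most one record per
#' `cell_deg`-degree grid cell (grid anchored at integer degrees; cell index
#' by `floor(coord / cell_deg)`). The first record in input order wins, so
#' the operation is deterministic and idempotent.
#'
#' @param occ occurrence data.frame.
#' @param cell_deg thinning cell size in degrees (default 1, ~111 km).
#' @return Thinned occurrence data.frame.
#' @export
grid_thin <- function(occ, cell_deg = 1) {
  if (cell_deg <= 0) stop("cell_deg must be > 0", call. = FALSE)
  if (nrow(occ) == 0L) return(occ)
  key <- paste(floor(occ$lon / cell_deg), floor(occ$lat / cell_deg), sep = ",")
  occ[!duplicated(key), , drop = FALSE]
}

#' Assign seasonal labels from month
#'
#' December--February is winter, March--May spring, June--July summer and
#' August--October fall, following the occupancy phenology of North American
#' migratory bats; November, a transitional month not attributed to any
#' season, is labelled `"unassigned"`.
#'
#' @param occ occurrence data.frame with a `month` column.
#' @return The data.frame with a `season` column added.
#' @export
assign_season <- function(occ) {
  if (is.null(occ$month)) stop("month column required", call. = FALSE)
  if (any(!occ$month %in% 1:12))
    stop("month values must be in 1..12", call. = FALSE)
  seasons <- c("winter", "winter", "spring", "spring", "spring",
               "summer", "summer", "fall", "fall", "fall",
               "unassigned", "winter")
  occ$season <- seasons[occ$month]
  occ
}

#' Months belonging to a season
#' @param season one of winter, spring, summer, fall.
#' @return Integer vector of month indices.
#' @export
season_months <- function(season = c("winter", "spring", "summer", "fall")) {
  switch(match.arg(season),
         winter = c(12L, 1L, 2L), spring = 3:5, summer = 6:7, fall = 8:10)
}

#' Sample pseudo-absence (background) points
#'
#' Draws `n` distinct valid cells uniformly without replacement from the mask
#' raster, excluding cells that contain presence points, and returns their
#' cell centers as background records. The default of 1,000 points per month
#' follows common presence-background practice.
#'
#' @param mask `raster_grid`; cells with non-NA values are candidates.
#' @param n number of background points.
#' @param exclude optional occurrence data.frame whose cells are excluded.
#' @param seed integer seed.
#' @param month month label for the background records.
#' @return An occurrence-shaped data.frame of background points.
#' @export
sample_pseudo_absences <- function(mask, n = 1000L, exclude = NULL, seed = 1L,
                                   month = NA_integer_) {
  stopifnot(inherits(mask, "raster_grid"), n >= 1)
  valid <- which(is.finite(mask$values))
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    rc <- cell_from_lonlat(mask, exclude$lon, exclude$lat)
    pres_cells <- (rc$col - 1L) * nrow(mask$values) + rc$row
    valid <- setdiff(valid, pres_cells[!is.na(pres_cells)])
  }
  if (length(valid) < n)
    stop("insufficient background: ", length(valid),
         " available cells for n = ", n, call. = FALSE)
  set.seed(seed)
  cells <- if (length(valid) == n) valid else sample(valid, n)
  nr <- nrow(mask$values)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  ctr <- cell_center(mask, row, col)
  data.frame(species = "background", lon = ctr$lon, lat = ctr$lat,
             year = NA_integer_, month = as.integer(month), day = NA_integer_,
             basis_of_record = "PSEUDO_ABSENCE", stringsAsFactors = FALSE)
}

#' Random k-fold assignment
#'
#' Partitions `n_records` into `k` folds of near-equal size (sizes differ by
#' at most one) for cross-validation with k-1 folds training and one fold
#' testing.
#'
#' @param n_records number of records.
#' @param k number of folds (default 5, i.e. 80/20 train/test splits).
#' @param seed integer seed.
#' @return Integer vector of fold ids in 1..k, one per record.
#' @export
make_folds <- function(n_records, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n_records) stop("k exceeds number of records", call. = FALSE)
  set.seed(seed)
  sample(rep_len(seq_len(k), n_records))
}
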