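#' Coerce and validate an occurrence table
#'
#' Occurrence records are plain tibbles with columns `longitude`, `latitude`,
#' `year`, `presence` (0/1) and `weight` (positive, defaults to 1; after
#' survey-bias weighting, weights lie in \[1, 20\]). Rows with unparseable or
#' out-of-range coordinates are dropped with a warning that reports the count.
#'
#' @param x A data frame with at least `longitude`, `latitude`, `year`.
#' @return A validated tibble of occurrences.
#' @export
as_occurrence_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("longitude", "latitude", "year")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop(
      "occurrence table schema error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x$longitude <- suppressWarnings(as.numeric(x$longitude))
  x$latitude <- suppressWarnings(as.numeric(x$latitude))
  x$year <- suppressWarnings(as.integer(x$year))
  if (!"presence" %in% names(x)) x$presence <- 1L
  x$presence <- as.integer(x$presence)
  if (!"weight" %in% names(x)) x$weight <- 1
  x$weight <- as.numeric(x$weight)
  bad <- !is.finite(x$longitude) | !is.finite(x$latitude) |
    x$longitude < -180 | x$longitude > 180 |
    x$latitude < -90 | x$latitude > 90
  if (any(bad)) {
    warning(sprintf("dropped %d record(s) with invalid coordinates", sum(bad)),
      call. = FALSE
    )
    x <- x[!bad, , drop = FALSE]
  }
  if (any(!x$presence %in% c(0L, 1L))) {
    stop("occurrence table schema error: presence must be 0 or 1", call. = FALSE)
  }
  if (any(!is.finite(x$weight) | x$weight <= 0)) {
    stop("occurrence table schema error: weights must be positive", call. = FALSE)
  }
  x[, union(c("longitude", "latitude", "year", "presence", "weight"), names(x))]
}

#' Read occurrence records from CSV
#'
#' Expects a header with `longitude`, `latitude` and `year` columns (an
#' optional `presence` column defaults to 1, `weight` to 1). Invalid
#' coordinate rows are dropped with a logged count, per
#' [as_occurrence_table()].
#'
#' @param path CSV file.
#' @return A tibble of occurrence records.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_occurrence_table(df)
}

#' Write occurrence records to CSV
#'
#' @param occ Occurrence tibble.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' Geographic calibration/evaluation split by longitude band
#'
#' Splits occurrence records into a training and a testing set by longitude,
#' following the survey's calibration design: training records come from one
#' central band and testing records from flanking bands, so evaluation uses
#' geographic outliers rather than a random subsample. Band membership is
#' half-open, `lon_min <= longitude < lon_max`, except that the last test
#' band's upper edge is closed; a record on the shared edge of two bands
#' therefore belongs to the band whose closed lower edge it sits on (the
#' train band at its lower edge).
#'
#' @param occ Occurrence tibble.
#' @param train_band Numeric length-2, `c(lon_min, lon_max)` in degrees.
#' @param test_bands List of numeric length-2 bands.
#' @return A list with tibbles `train` and `test`; records in no band are in
#'   neither.
#' @export
#' @examples
#' occ <- tibble::tibble(longitude = c(57, 56.2), latitude = 23,
#'                       year = 2007, presence = 1)
#' sp <- split_by_longitude(occ, c(56.5, 59), list(c(56, 56.5), c(59, 59.5)))
#' nrow(sp$train)
split_by_longitude <- function(occ, train_band, test_bands) {
  occ <- as_occurrence_table(occ)
  check_band <- function(b, what) {
    if (!is.numeric(b) || length(b) != 2 || !(b[1] < b[2])) {
      stop("configuration error: ", what,
        " must be a non-degenerate interval c(lon_min, lon_max)",
        call. = FALSE
      )
    }
  }
  check_band(train_band, "train_band")
  for (b in test_bands) check_band(b, "each test band")
  overlaps <- function(a, b) a[1] < b[2] && b[1] < a[2]
  for (b in test_bands) {
    if (overlaps(train_band, b)) {
      stop(sprintf(
        "configuration error: test band [%g, %g] overlaps the train band [%g, %g]",
        b[1], b[2], train_band[1], train_band[2]
      ), call. = FALSE)
    }
  }
  in_band <- function(lon, b) lon >= b[1] & lon < b[2]
  in_train <- in_band(occ$longitude, train_band)
  in_test <- Reduce(`|`, lapply(test_bands, function(b) in_band(occ$longitude, b)))
  # closed upper edge on the outermost test band so the study-extent
  # boundary record is not silently discarded
  top <- max(vapply(test_bands, function(b) b[2], numeric(1)))
  in_test <- in_test | occ$longitude == top
  in_test <- in_test & !in_train
  list(
    train = occ[in_train, , drop = FALSE],
    test = occ[in_test, , drop = FALSE]
  )
}

#' Read daily weather-station series from CSV
#'
#' One row per station-day with columns `station_id`, `longitude`,
#' `latitude`, `date`, `mean_temp`, `min_temp`, `max_temp`, `dew_point`,
#' `wind_speed`, `precipitation`. Rows violating
#' `min_temp <= mean_temp <= max_temp` are rejected.
#'
#' @param path CSV file.
#' @return A tibble of station-day rows.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_station_series(df)
}

#' @rdname read_stations
#' @param x A data frame of station-day rows.
#' @export
as_station_series <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c(
    "station_id", "longitude", "latitude", "date",
    "mean_temp", "min_temp", "max_temp", "dew_point", "wind_speed",
    "precipitation"
  )
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop(
      "station series schema error: missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(x) > 0) {
    bad <- !(x$min_temp <= x$mean_temp & x$mean_temp <= x$max_temp)
    if (any(bad)) {
      stop(sprintf(
        "station series schema error: %d row(s) violate min <= mean <= max temperature",
        sum(bad)
      ), call. = FALSE)
    }
  }
  x
}

#' Convert degree-minute-second to decimal degrees
#'
#' Configuration helper for the survey's band definitions, which are stated
#' in degrees/minutes/seconds (e.g. 56°30'00").
#'
#' @param degrees,minutes,seconds Components; minutes and seconds default 0.
#' @return Decimal degrees.
#' @export
#' @examples
#' dms(56, 30) # 56.5
dms <- function(degrees, minutes = 0, seconds = 0) {
  sign(degrees) * (abs(degrees) + minutes / 60 + seconds / 3600)
}
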