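#' Linear semivariogram specification
#'
#' The hotspot analysis uses ordinary kriging under a linear semivariogram
#' `gamma(h) = nugget + slope * h` (for `h > 0`; `gamma(0) = 0`), the
#' standard reading of a "linear kriging" interpolator.
#'
#' @param slope Semivariogram slope, must be positive.
#' @param nugget Non-negative nugget. A positive nugget trades exactness at
#'   the sample points for numerical robustness.
#' @return A `variogram` object.
#' @export
variogram_linear <- function(slope = 1, nugget = 0) {
  stopifnot(is.numeric(slope), slope > 0, is.numeric(nugget), nugget >= 0)
  structure(list(model = "linear", slope = slope, nugget = nugget),
    class = "variogram"
  )
}

semivariance <- function(vg, h) {
  g <- vg$nugget + vg$slope * h
  g[h == 0] <- 0
  g
}

# Normalize `targets`: either a data frame of points or a raster_grid
# template (predict at every unmasked cell centre).
resolve_targets <- function(targets) {
  if (is_raster_grid(targets)) {
    tab <- as_tibble.raster_grid(targets)
    keep <- !is.na(as.vector(targets$values)) | all(is.na(targets$values))
    list(
      points = tab[, c("longitude", "latitude")],
      template = targets,
      keep = if (all(is.na(targets$values))) rep(TRUE, nrow(tab)) else keep
    )
  } else {
    pts <- tibble::as_tibble(targets)
    stopifnot(all(c("longitude", "latitude") %in% names(pts)))
    list(points = pts[, c("longitude", "latitude")], template = NULL, keep = NULL)
  }
}

fill_template <- function(template, keep, values) {
  out <- rep(NA_real_, template$n_rows * template$n_cols)
  out[keep] <- values
  raster_grid(
    matrix(out, template$n_rows, template$n_cols),
    template$x_origin, template$y_origin, template$cell_size
  )
}

check_samples <- function(samples, min_n) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("longitude", "latitude", "value") %in% names(samples))) {
    stop("samples need longitude, latitude and value columns", call. = FALSE)
  }
  if (nrow(samples) < min_n) {
    stop(sprintf("at least %d sample(s) required", min_n), call. = FALSE)
  }
  if (any(!is.finite(samples$value))) {
    stop("sample values must be finite", call. = FALSE)
  }
  d <- geo_dist_matrix(
    samples$longitude, samples$latitude,
    samples$longitude, samples$latitude
  )
  dup <- which(d < 1e-9 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    clash <- dup[samples$value[dup[, 1]] != samples$value[dup[, 2]], , drop = FALSE]
    if (nrow(clash) > 0) {
      stop(sprintf(
        "duplicate sample locations with different values (rows %d and %d)",
        clash[1, 1], clash[1, 2]
      ), call. = FALSE)
    }
    # identical duplicates: keep the first of each coincident pair
    samples <- samples[-unique(dup[, 2]), , drop = FALSE]
  }
  samples
}

#' Inverse-distance-weighted interpolation
#'
#' Predicts each target as the convex combination of sample values with
#' weights `distance^(-power)`; a target within 1e-9 degrees of a sample
#' returns that sample's value exactly. Distances are equirectangular
#' degrees (longitude scaled by cos of the mean latitude). Predictions are
#' therefore always inside `[min(value), max(value)]` of the samples.
#'
#' @param samples Tibble with `longitude`, `latitude`, `value`.
#' @param targets A data frame of points, or a [raster_grid()] template (the
#'   prediction is made at every unmasked cell centre).
#' @param power Positive IDW exponent; 2 by default.
#' @return For point targets, the input points with a `value` column; for a
#'   raster template, a [raster_grid()].
#' @export
#' @examples
#' s <- tibble::tibble(longitude = c(0, 3), latitude = 0, value = c(0, 30))
#' idw(s, tibble::tibble(longitude = 1, latitude = 0), power = 1)$value # 10
idw <- function(samples, targets, power = 2) {
  stopifnot(is.numeric(power), power > 0)
  samples <- check_samples(samples, min_n = 1)
  tg <- resolve_targets(targets)
  pts <- if (is.null(tg$keep)) tg$points else tg$points[tg$keep, , drop = FALSE]
  d <- geo_dist_matrix(
    pts$longitude, pts$latitude,
    samples$longitude, samples$latitude
  )
  w <- d^(-power)
  hit <- d < 1e-9
  vals <- numeric(nrow(pts))
  exact <- rowSums(hit) > 0
  if (any(exact)) {
    vals[exact] <- samples$value[apply(hit[exact, , drop = FALSE], 1, which.max)]
  }
  if (any(!exact)) {
    ww <- w[!exact, , drop = FALSE]
    vals[!exact] <- as.vector(ww %*% samples$value) / rowSums(ww)
  }
  if (!is.null(tg$template)) {
    return(fill_template(tg$template, tg$keep, vals))
  }
  out <- tg$points
  out$value <- vals
  out
}

#' Ordinary kriging
#'
#' Solves the ordinary-kriging system (sample semivariance matrix bordered
#' by the unbiasedness/Lagrange row) once for all targets. With a zero
#' nugget the predictor is exact at sample locations with zero kriging
#' variance.
#'
#' @param samples Tibble with `longitude`, `latitude`, `value`; at least two
#'   non-collocated samples.
#' @param targets Points data frame or [raster_grid()] template.
#' @param variogram A [variogram_linear()].
#' @return For point targets, a tibble with `value` and `variance` columns;
#'   for a raster template, a list with `prediction` and `variance` rasters.
#' @export
ordinary_kriging <- function(samples, targets, variogram = variogram_linear()) {
  stopifnot(inherits(variogram, "variogram"))
  samples <- check_samples(samples, min_n = 2)
  n <- nrow(samples)
  if (n < 2) stop("at least 2 non-collocated samples required", call. = FALSE)
  tg <- resolve_targets(targets)
  pts <- if (is.null(tg$keep)) tg$points else tg$points[tg$keep, , drop = FALSE]
  d_ss <- geo_dist_matrix(
    samples$longitude, samples$latitude,
    samples$longitude, samples$latitude
  )
  a_mat <- rbind(
    cbind(semivariance(variogram, d_ss), 1),
    c(rep(1, n), 0)
  )
  d_ts <- geo_dist_matrix(
    pts$longitude, pts$latitude,
    samples$longitude, samples$latitude
  )
  b_mat <- rbind(t(semivariance(variogram, d_ts)), 1)
  sol <- tryCatch(solve(a_mat, b_mat), error = function(e) {
    stop("singular kriging system; try a variogram with nugget > 0",
      call. = FALSE
    )
  })
  w <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  vals <- as.vector(crossprod(w, samples$value))
  variance <- colSums(w * t(semivariance(variogram, d_ts))) + mu
  variance <- pmax(variance, 0)
  if (!is.null(tg$template)) {
    return(list(
      prediction = fill_template(tg$template, tg$keep, vals),
      variance = fill_template(tg$template, tg$keep, variance)
    ))
  }
  out <- tg$points
  out$value <- vals
  out$variance <- variance
  out
}

#' Annual hotspot surface by kriging per-cell record counts
#'
#' Counts the year's records per grid cell and krige those counts (occupied
#' cells, plus a deterministic stride-sample of empty cells as zero
#' observations so the surface decays away from records) onto the full grid.
#' With fewer than two records the surface is undefined: an all-NA sentinel
#' raster is returned with a warning.
#'
#' @param occ Occurrence tibble.
#' @param year Year to map.
#' @param geometry A [raster_grid()] template (values are ignored, mask is
#'   honoured).
#' @param variogram A [variogram_linear()].
#' @param max_zero_cells Cap on the number of empty cells entering the
#'   kriging system as zeros.
#' @return A [raster_grid()] of interpolated record density.
#' @export
hotspot_surface <- function(occ, year, geometry,
                            variogram = variogram_linear(),
                            max_zero_cells = 150L) {
  occ <- as_occurrence_table(occ)
  stopifnot(is_raster_grid(geometry))
  rec <- occ[occ$year == year & occ$presence == 1L, , drop = FALSE]
  if (nrow(rec) < 2) {
    warning(sprintf("fewer than 2 records for year %d; empty surface", year),
      call. = FALSE
    )
    return(raster_grid(
      matrix(NA_real_, geometry$n_rows, geometry$n_cols),
      geometry$x_origin, geometry$y_origin, geometry$cell_size
    ))
  }
  loc <- locate_cells(geometry, rec$longitude, rec$latitude)
  ok <- !loc$out_of_bounds
  idx <- (loc$col[ok] - 1L) * geometry$n_rows + loc$row[ok]
  counts <- table(idx)
  cc <- cell_centers(geometry)
  all_lon <- rep(cc$x, each = geometry$n_rows)
  all_lat <- rep(cc$y, times = geometry$n_cols)
  occupied <- as.integer(names(counts))
  unmasked <- if (all(is.na(geometry$values))) {
    seq_along(all_lon)
  } else {
    which(!is.na(as.vector(geometry$values)))
  }
  empties <- setdiff(unmasked, occupied)
  if (length(empties) > max_zero_cells) {
    stride <- ceiling(length(empties) / max_zero_cells)
    empties <- empties[seq(1L, length(empties), by = stride)]
  }
  samples <- tibble::tibble(
    longitude = all_lon[c(occupied, empties)],
    latitude = all_lat[c(occupied, empties)],
    value = c(as.numeric(counts), rep(0, length(empties)))
  )
  template <- geometry
  if (all(is.na(template$values))) template$values[] <- 0
  ordinary_kriging(samples, template, variogram)$prediction
}

#' Hotspot change map between two years
#'
#' Classifies each cell by whether it crosses the "high-density" threshold
#' between the two surfaces. The threshold is the `high_quantile` quantile
#' of the baseline surface `surface_a`, applied to both years, so an
#' isolated increase in year B registers as `gained` without moving the
#' threshold itself.
#'
#' @param surface_a,surface_b Hotspot [raster_grid()]s on one geometry.
#' @param high_quantile Quantile in (0, 1) defining "high"; 0.9 by default.
#' @return A list: `map` (a [raster_grid()] coded 0 stable-low, 1 gained,
#'   2 lost, 3 stable-high), `threshold`, and `counts` (tibble per class).
#' @export
hotspot_change <- function(surface_a, surface_b, high_quantile = 0.9) {
  stopifnot(
    is_raster_grid(surface_a), is_raster_grid(surface_b),
    high_quantile > 0, high_quantile < 1
  )
  if (!same_geometry(surface_a, surface_b)) stop_geometry_mismatch("hotspot surfaces")
  thr <- stats::quantile(surface_a$values, high_quantile, na.rm = TRUE, names = FALSE)
  hi_a <- surface_a$values >= thr
  hi_b <- surface_b$values >= thr
  code <- matrix(NA_real_, surface_a$n_rows, surface_a$n_cols)
  code[!hi_a & !hi_b] <- 0
  code[!hi_a & hi_b] <- 1
  code[hi_a & !hi_b] <- 2
  code[hi_a & hi_b] <- 3
  labels <- c("stable-low", "gained", "lost", "stable-high")
  counts <- tibble::tibble(
    class = labels,
    cells = vapply(0:3, function(k) sum(code == k, na.rm = TRUE), numeric(1))
  )
  list(
    map = raster_grid(
      code, surface_a$x_origin, surface_a$y_origin,
      surface_a$cell_size
    ),
    threshold = thr,
    counts = counts
  )
}
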