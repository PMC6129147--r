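#' Georeferenced raster grid
#'
#' A `raster_grid` is the package's carrier for one gridded surface: a numeric
#' matrix of cell values (row 1 is the northern edge), a no-data mask encoded
#' as `NA`, and a georeference given by the lower-left corner of the grid, the
#' (square) cell size and the row/column counts. Coordinates are WGS84 decimal
#' degrees throughout; grid registration is cell-centre and point-in-cell
#' lookups use half-open cells `[x, x + cell_size)`.
#'
#' @param values Numeric matrix, `NA` marking no-data cells. Row 1 is north.
#' @param x_origin,y_origin Lower-left corner of the grid, decimal degrees.
#' @param cell_size Cell edge length in degrees; must be positive.
#'
#' @return An object of class `raster_grid` with fields `values`, `x_origin`,
#'   `y_origin`, `cell_size`, `n_rows`, `n_cols`.
#' @export
#' @examples
#' rg <- raster_grid(matrix(1:6, 2, 3), x_origin = 56, y_origin = 22,
#'                   cell_size = 0.5)
#' rg$n_rows
raster_grid <- function(values, x_origin, y_origin, cell_size) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(values) & !is.na(values))) {
    stop("raster values must be finite or NA (no-data)", call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(
    list(
      values = values,
      x_origin = as.numeric(x_origin),
      y_origin = as.numeric(y_origin),
      cell_size = as.numeric(cell_size),
      n_rows = nrow(values),
      n_cols = ncol(values)
    ),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  n_na <- sum(is.na(x$values))
  cat(sprintf(
    "<raster_grid> %d x %d cells of %g deg, origin (%g, %g), %d masked\n",
    x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin, n_na
  ))
  rng <- range(x$values, na.rm = !all(is.na(x$values)))
  if (!all(is.na(x$values))) cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @rdname raster_grid
#' @param x A `raster_grid`.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

same_geometry <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_origin - b$x_origin) < tol &&
    abs(a$y_origin - b$y_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_geometry_mismatch <- function(what = "rasters") {
  stop(sprintf("%s do not share grid geometry", what), call. = FALSE)
}

# Cell-centre coordinates for row r (from the north) / column c.
cell_centers <- function(grid) {
  xs <- grid$x_origin + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ys <- grid$y_origin + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cell_size
  list(x = xs, y = ys)
}

#' Tabulate a raster grid as a tibble of cell centres
#'
#' @param x A `raster_grid`.
#' @param ... Unused.
#' @return A tibble with columns `longitude`, `latitude`, `value` (masked
#'   cells carry `NA`), one row per cell in row-major order from the north.
#' @method as_tibble raster_grid
#' @export
as_tibble.raster_grid <- function(x, ...) {
  cc <- cell_centers(x)
  tibble::tibble(
    longitude = rep(cc$x, each = x$n_rows),
    latitude = rep(cc$y, times = x$n_cols),
    value = as.vector(x$values)
  )
}

# row/col of the cell containing each point; NA where out of bounds.
# Half-open cells [x, x + cell) so boundaries are unambiguous.
locate_cells <- function(grid, longitude, latitude) {
  col <- floor((longitude - grid$x_origin) / grid$cell_size) + 1
  row <- grid$n_rows - floor((latitude - grid$y_origin) / grid$cell_size)
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(longitude) | !is.finite(latitude)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col), out_of_bounds = bad)
}

#' Named stack of co-registered climate layers
#'
#' A `climate_stack` holds the bioclim-style predictor layers as an ordered,
#' named list of [raster_grid()]s sharing one geometry. The no-data mask is
#' unioned across layers at construction so every layer masks the same cells.
#'
#' @param layers Named list of `raster_grid`s with identical geometry.
#' @return A `climate_stack`.
#' @export
climate_stack <- function(layers) {
  if (!is.list(layers) || length(layers) == 0) {
    stop("`layers` must be a non-empty named list of raster_grid", call. = FALSE)
  }
  nm <- names(layers)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("layer names must be unique and non-empty", call. = FALSE)
  }
  if (!all(vapply(layers, is_raster_grid, logical(1)))) {
    stop("every layer must be a raster_grid", call. = FALSE)
  }
  ref <- layers[[1]]
  for (i in seq_along(layers)) {
    if (!same_geometry(ref, layers[[i]])) {
      stop_geometry_mismatch(sprintf("layers '%s' and '%s'", nm[1], nm[i]))
    }
  }
  mask <- Reduce(`|`, lapply(layers, function(l) is.na(l$values)))
  layers <- lapply(layers, function(l) {
    l$values[mask] <- NA_real_
    l
  })
  structure(list(layers = layers), class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf(
    "<climate_stack> %d layers (%s) on %d x %d grid\n",
    length(x$layers), paste(names(x$layers), collapse = ", "),
    g$n_rows, g$n_cols
  ))
  invisible(x)
}

#' @rdname climate_stack
#' @param x Object to test.
#' @export
is_climate_stack <- function(x) inherits(x, "climate_stack")

#' @export
names.climate_stack <- function(x) names(x$layers)

stack_geometry <- function(stack) stack$layers[[1]]

stack_mask <- function(stack) is.na(stack$layers[[1]]$values)

#' Extract predictor values at point locations
#'
#' Looks up, for each point, the value of the containing cell in every layer
#' of the stack. Points outside the grid bounds are flagged, not an error;
#' points falling on masked (no-data) cells come back with `NA` values and
#' `masked = TRUE`.
#'
#' @param stack A [climate_stack()] (or a single [raster_grid()]).
#' @param points A data frame with `longitude` and `latitude` columns.
#' @return A tibble: the input coordinates, one column per layer, and logical
#'   columns `out_of_bounds` and `masked`.
#' @export
extract_at <- function(stack, points) {
  if (is_raster_grid(stack)) stack <- climate_stack(list(layer = stack))
  stopifnot(is_climate_stack(stack))
  points <- tibble::as_tibble(points)
  if (!all(c("longitude", "latitude") %in% names(points))) {
    stop("`points` needs longitude and latitude columns", call. = FALSE)
  }
  g <- stack_geometry(stack)
  loc <- locate_cells(g, points$longitude, points$latitude)
  idx <- ifelse(loc$out_of_bounds, NA_integer_,
    (loc$col - 1L) * g$n_rows + loc$row
  )
  vals <- lapply(stack$layers, function(l) l$values[idx])
  out <- tibble::tibble(
    longitude = points$longitude,
    latitude = points$latitude
  )
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  out$out_of_bounds <- loc$out_of_bounds
  out$masked <- !loc$out_of_bounds & is.na(stack$layers[[1]]$values[idx])
  out
}

# Equirectangular distance in degrees: longitudes scaled by cos(mean latitude).
# Adequate at the study extent (northern Oman spans < 4 degrees).
geo_dist <- function(lon1, lat1, lon2, lat2) {
  mean_lat <- mean(c(lat1, lat2), na.rm = TRUE)
  sc <- cos(mean_lat * pi / 180)
  sqrt(((lon1 - lon2) * sc)^2 + (lat1 - lat2)^2)
}

# Cross-distance matrix between two sets of points (degrees, equirectangular).
geo_dist_matrix <- function(lon_a, lat_a, lon_b, lat_b) {
  sc <- cos(mean(c(lat_a, lat_b)) * pi / 180)
  dx <- outer(lon_a, lon_b, "-") * sc
  dy <- outer(lat_a, lat_b, "-")
  sqrt(dx^2 + dy^2)
}
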