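#' Configuration for the synthetic study system
#'
#' Bundles every knob of the synthetic world: grid geometry, number and
#' correlation of climate layers, the "true" suitability coefficients the
#' distribution models must recover, the survey-effort bias kernel and the
#' presence sample size. Defaults describe a northern-Oman-sized study
#' window (56--59.5E, 22--24N at 0.05-degree cells, spanning the region the
#' calibration/evaluation longitude bands partition), seven bioclim-style
#' layers named after the predictor set retained in the motivating analysis,
#' a sharp, low-prevalence unimodal truth driven by three of them (the
#' high-discrimination regime a strong suitability analysis presumes), the
#' full record count of the motivating survey, and a coastal-style no-data
#' margin.
#'
#' @param seed Integer master seed; every generator is a pure function of it.
#' @param n_rows,n_cols Grid size in cells.
#' @param n_layers Number of climate layers.
#' @param layer_names Names for the layers (recycled from bio-style names).
#' @param layer_correlation Shared-field mixing weight in \[0, 1): the
#'   approximate pairwise Pearson correlation between layers.
#' @param spatial_range Gaussian smoothing length in cells (autocorrelation
#'   range); must be >= 1.
#' @param true_coefficients Named list, `layer = c(linear, quadratic)`, on
#'   standardized layer values; the truth surface is the logistic transform
#'   of their sum plus `true_intercept`. The default (`NULL`) uses a sharp
#'   unimodal niche on bio10/bio11/bio16, restricted to the layers actually
#'   present; with none of those present the first layer drives the truth.
#' @param true_intercept Baseline log-odds of suitability. The default is
#'   strongly negative so the species is a low-prevalence one: most of the
#'   region is near-unsuitable and high suitability is confined to where
#'   several layers sit near their optima, which is the regime a
#'   high-discrimination (AUC about 0.95) suitability analysis presumes.
#' @param bias_center `c(lon, lat)` of the survey-effort kernel.
#' @param bias_sd Survey-effort kernel standard deviation, degrees.
#' @param n_presence Number of presence records to draw.
#' @param noise_sd Noise standard deviation on the station-infestation link.
#' @param x_origin,y_origin,cell_size Grid georeference (degrees).
#' @param years Candidate record years (assigned uniformly).
#' @param mask_fraction Fraction of cells masked as no-data "sea" (a smooth
#'   contiguous margin, not salt-and-pepper).
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_rows = 40L,
                         n_cols = 70L,
                         n_layers = 7L,
                         layer_names = NULL,
                         layer_correlation = 0.3,
                         spatial_range = 5,
                         true_coefficients = NULL,
                         true_intercept = -8,
                         bias_center = c(57.75, 23.0),
                         bias_sd = 1.0,
                         n_presence = 1708L,
                         noise_sd = 1,
                         x_origin = 56,
                         y_origin = 22,
                         cell_size = 0.05,
                         years = c(2007:2011, 2015L),
                         mask_fraction = 0.06) {
  if (is.null(layer_names)) {
    pool <- c("bio7", "bio8", "bio9", "bio10", "bio11", "bio15", "bio16",
              paste0("x", seq_len(max(0, n_layers - 7))))
    layer_names <- pool[seq_len(n_layers)]
  }
  stopifnot(
    length(layer_names) == n_layers,
    layer_correlation >= 0, layer_correlation < 1,
    spatial_range >= 1,
    bias_sd > 0, n_presence >= 1, noise_sd >= 0,
    mask_fraction >= 0, mask_fraction < 1
  )
  if (is.null(true_coefficients)) {
    canonical <- list(bio10 = c(10, -8), bio11 = c(7, -6), bio16 = c(5, -4))
    true_coefficients <- canonical[intersect(names(canonical), layer_names)]
    if (length(true_coefficients) == 0) {
      true_coefficients <- stats::setNames(list(c(2, -2)), layer_names[1])
    }
  }
  unknown <- setdiff(names(true_coefficients), layer_names)
  if (length(unknown) > 0) {
    stop("true_coefficients name unknown layer(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      seed = as.integer(seed), n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols), n_layers = as.integer(n_layers),
      layer_names = layer_names, layer_correlation = layer_correlation,
      spatial_range = spatial_range, true_coefficients = true_coefficients,
      true_intercept = true_intercept,
      bias_center = bias_center, bias_sd = bias_sd,
      n_presence = as.integer(n_presence), noise_sd = noise_sd,
      x_origin = x_origin, y_origin = y_origin, cell_size = cell_size,
      years = as.integer(years), mask_fraction = mask_fraction
    ),
    class = "synth_config"
  )
}

# Gaussian random field: white noise circularly convolved with a Gaussian
# kernel of sd `range_cells`, then standardized. FFT keeps this fast and the
# wrap-around has no visible effect at the default extents.
gaussian_field <- function(n_rows, n_cols, range_cells) {
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells <= 0) {
    return((noise - mean(noise)) / stats::sd(noise))
  }
  ri <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  ci <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  kern <- exp(-0.5 * (outer(ri^2, ci^2, "+") / range_cells^2))
  kern <- kern / sum(kern)
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (n_rows * n_cols)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic climate stack
#'
#' Builds `n_layers` spatially autocorrelated layers as Gaussian random
#' fields (white noise smoothed over `spatial_range` cells). Cross-layer
#' correlation is induced by mixing a shared field into each layer with
#' weight `sqrt(layer_correlation)`, so the expected pairwise Pearson
#' correlation equals `layer_correlation`. A smooth no-data margin covering
#' roughly `mask_fraction` of the grid emulates the coastline. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A [climate_stack()].
#' @export
gen_climate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    shared <- gaussian_field(cfg$n_rows, cfg$n_cols, cfg$spatial_range)
    rho <- cfg$layer_correlation
    fields <- lapply(seq_len(cfg$n_layers), function(i) {
      own <- gaussian_field(cfg$n_rows, cfg$n_cols, cfg$spatial_range)
      f <- sqrt(rho) * shared + sqrt(1 - rho) * own
      (f - mean(f)) / stats::sd(f)
    })
    mask <- NULL
    if (cfg$mask_fraction > 0) {
      sea <- gaussian_field(cfg$n_rows, cfg$n_cols, cfg$spatial_range * 2)
      cut <- stats::quantile(sea, 1 - cfg$mask_fraction)
      mask <- sea > cut
    }
    layers <- lapply(fields, function(f) {
      if (!is.null(mask)) f[mask] <- NA_real_
      raster_grid(f, cfg$x_origin, cfg$y_origin, cfg$cell_size)
    })
    names(layers) <- cfg$layer_names
    climate_stack(layers)
  })
}

#' True habitat-suitability surface for a synthetic stack
#'
#' The ground truth every distribution model is later judged against: the
#' logistic transform of `true_intercept + sum(linear * z + quadratic * z^2)`
#' over the layers named in `cfg$true_coefficients`, with each layer
#' standardized over its unmasked cells. All-zero coefficients and a zero
#' intercept give a flat 0.5 surface.
#'
#' @param stack A [climate_stack()].
#' @param cfg A [synth_config()].
#' @return A [raster_grid()] with values in \[0, 1\].
#' @export
gen_true_suitability <- function(stack, cfg) {
  stopifnot(is_climate_stack(stack), inherits(cfg, "synth_config"))
  g <- stack_geometry(stack)
  eta <- matrix(cfg$true_intercept, g$n_rows, g$n_cols)
  for (nm in names(cfg$true_coefficients)) {
    if (!nm %in% names(stack)) {
      stop("true_coefficients name a layer absent from the stack: ", nm,
        call. = FALSE
      )
    }
    v <- stack$layers[[nm]]$values
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    co <- cfg$true_coefficients[[nm]]
    eta <- eta + co[1] * z + co[2] * z^2
  }
  suit <- stats::plogis(eta)
  suit[stack_mask(stack)] <- NA_real_
  raster_grid(suit, g$x_origin, g$y_origin, g$cell_size)
}

#' Sample survey-biased presence records from a truth surface
#'
#' Presence cells are drawn (with replacement) with probability proportional
#' to `truth * effort`, where the survey-effort kernel is an isotropic
#' Gaussian centred at `cfg$bias_center` with sd `cfg$bias_sd` degrees —
#' emulating records accumulating near well-surveyed localities. Records are
#' placed at cell centres; years are assigned uniformly over `cfg$years`.
#' Deterministic given `cfg$seed`.
#'
#' @param truth Truth [raster_grid()] in \[0, 1\].
#' @param cfg A [synth_config()].
#' @param bias If `FALSE`, the effort kernel is dropped and sampling is
#'   proportional to truth alone.
#' @return An occurrence tibble (all `presence = 1`, `weight = 1`).
#' @export
sample_occurrences <- function(truth, cfg, bias = TRUE) {
  stopifnot(is_raster_grid(truth), inherits(cfg, "synth_config"))
  cc <- cell_centers(truth)
  lon <- rep(cc$x, each = truth$n_rows)
  lat <- rep(cc$y, times = truth$n_cols)
  p <- as.vector(truth$values)
  if (bias) {
    effort <- exp(-0.5 * ((lon - cfg$bias_center[1])^2 +
      (lat - cfg$bias_center[2])^2) / cfg$bias_sd^2)
    p <- p * effort
  }
  p[is.na(p)] <- 0
  if (sum(p) <= 0) stop("truth surface has no positive sampling mass", call. = FALSE)
  withr::with_seed(cfg$seed + 1L, {
    idx <- sample.int(length(p), cfg$n_presence, replace = TRUE, prob = p)
    yrs <- sample(cfg$years, cfg$n_presence, replace = TRUE)
    as_occurrence_table(tibble::tibble(
      longitude = lon[idx], latitude = lat[idx],
      year = yrs, presence = 1L, weight = 1
    ))
  })
}

#' Synthetic weather stations and a weakly climate-linked infestation table
#'
#' Generates daily station series (seasonal temperatures, dew point, wind
#' speed, precipitation) at uniformly placed stations, then an infestation
#' presence/absence table at uniformly placed survey locations whose
#' response depends on annual-mean dew point, minimum temperature and wind
#' speed through slopes that vary linearly with longitude — the weak,
#' spatially varying signal regime the geographically weighted regression is
#' meant to detect. Covariates at survey locations are inverse-distance
#' interpolations of the station annual means plus microclimate noise;
#' the same construction [climate_to_locations()] applies to real stations.
#'
#' The default `effect` sizes are calibrated once so that the global R2 of a
#' linear probability fit falls in the weak band (about 0.05--0.15) reported
#' for this system; `effect = c(...)* 0` gives the pure-noise regime.
#'
#' @param cfg A [synth_config()] (seed, extent and noise_sd are used).
#' @param n_stations Number of stations.
#' @param n_days Days of record per station (from 1 January of the first
#'   configured year). `n_days = 0` yields an empty, schema-valid series.
#' @param effect Named base slopes on standardized covariates, names among
#'   `dew_point`, `min_temp`, `wind_speed`.
#' @param n_locations Number of infested/survey locations.
#' @param slope_gradient Relative strength of the west-east slope ramp; the
#'   local slope is `effect * (1 + slope_gradient * ramp)` with `ramp` in
#'   \[-1, 1\] across the longitude extent.
#' @return A list: `stations` (station-day tibble), `infestation` (tibble of
#'   `longitude`, `latitude`, `year`, `presence`, the annual-mean covariates
#'   used, and the true local slopes as `true_slope_*` columns).
#' @export
gen_station_series <- function(cfg,
                               n_stations = 12L,
                               n_days = 365L,
                               effect = c(
                                 dew_point = 0.45, min_temp = 0.25,
                                 wind_speed = -0.2
                               ),
                               n_locations = 300L,
                               slope_gradient = 0.6) {
  stopifnot(inherits(cfg, "synth_config"), n_stations >= 1, n_days >= 0)
  factors <- c("dew_point", "min_temp", "wind_speed")
  if (length(effect) > 0 && !all(names(effect) %in% factors)) {
    stop("effect names must be among ", paste(factors, collapse = ", "),
      call. = FALSE
    )
  }
  eff <- stats::setNames(numeric(3), factors)
  eff[names(effect)] <- effect
  x_max <- cfg$x_origin + cfg$n_cols * cfg$cell_size
  y_max <- cfg$y_origin + cfg$n_rows * cfg$cell_size
  year0 <- min(cfg$years)
  withr::with_seed(cfg$seed + 2L, {
    st_lon <- stats::runif(n_stations, cfg$x_origin, x_max)
    st_lat <- stats::runif(n_stations, cfg$y_origin, y_max)
    # smooth regional anomalies so annual means differ across stations
    st_anom_t <- stats::rnorm(n_stations, 0, 1.5) + 2 * (st_lat - mean(st_lat))
    st_anom_d <- stats::rnorm(n_stations, 0, 1.5) - 1.5 * (st_lon - mean(st_lon))
    st_anom_w <- stats::rnorm(n_stations, 0, 0.8)
    day <- seq_len(n_days)
    stations <- purrr::map_dfr(seq_len(n_stations), function(s) {
      if (n_days == 0) {
        return(tibble::tibble(
          station_id = character(0), longitude = numeric(0),
          latitude = numeric(0), date = as.Date(character(0)),
          mean_temp = numeric(0), min_temp = numeric(0),
          max_temp = numeric(0), dew_point = numeric(0),
          wind_speed = numeric(0), precipitation = numeric(0)
        ))
      }
      seasonal <- 28 + 6 * sin(2 * pi * (day - 105) / 365.25)
      mean_t <- seasonal + st_anom_t[s] + stats::rnorm(n_days, 0, 1.2)
      spread_lo <- 4 + abs(stats::rnorm(n_days, 0, 1))
      spread_hi <- 4 + abs(stats::rnorm(n_days, 0, 1))
      dewp <- mean_t - 12 + st_anom_d[s] + stats::rnorm(n_days, 0, 1.5)
      wind <- pmax(0, 3 + st_anom_w[s] + stats::rnorm(n_days, 0, 1.2))
      prec <- ifelse(stats::runif(n_days) < 0.05, stats::rexp(n_days, 1 / 4), 0)
      tibble::tibble(
        station_id = sprintf("ST%02d", s),
        longitude = st_lon[s], latitude = st_lat[s],
        date = as.Date(sprintf("%d-01-01", year0)) + day - 1L,
        mean_temp = mean_t, min_temp = mean_t - spread_lo,
        max_temp = mean_t + spread_hi, dew_point = dewp,
        wind_speed = wind, precipitation = prec
      )
    })
    stations <- as_station_series(stations)
    if (n_days == 0) {
      empty_inf <- tibble::tibble(
        longitude = numeric(0), latitude = numeric(0),
        year = integer(0), presence = integer(0)
      )
      for (f in factors) empty_inf[[f]] <- numeric(0)
      for (f in factors) empty_inf[[paste0("true_slope_", f)]] <- numeric(0)
      return(list(stations = stations, infestation = empty_inf))
    }
    loc <- tibble::tibble(
      longitude = stats::runif(n_locations, cfg$x_origin, x_max),
      latitude = stats::runif(n_locations, cfg$y_origin, y_max)
    )
    covars <- climate_to_locations(stations, loc, year0, factors = factors)
    # microclimate noise on top of the interpolated regional field
    for (f in factors) {
      covars[[f]] <- covars[[f]] + stats::rnorm(n_locations, 0, stats::sd(covars[[f]]) * 0.6 + 0.2)
    }
    ramp <- 2 * (loc$longitude - cfg$x_origin) / (x_max - cfg$x_origin) - 1
    eta <- rep(0, n_locations)
    true_slopes <- list()
    for (f in factors) {
      z <- as.numeric(scale(covars[[f]]))
      if (n_locations <= 1 || !any(is.finite(z))) z <- rep(0, n_locations)
      sl <- eff[[f]] * (1 + slope_gradient * ramp)
      true_slopes[[paste0("true_slope_", f)]] <- sl
      eta <- eta + sl * z
    }
    eta <- eta + stats::rnorm(n_locations, 0, cfg$noise_sd)
    presence <- stats::rbinom(n_locations, 1, stats::plogis(eta))
    infestation <- tibble::tibble(
      longitude = loc$longitude, latitude = loc$latitude,
      year = year0, presence = as.integer(presence)
    )
    for (f in factors) infestation[[f]] <- covars[[f]]
    for (nm in names(true_slopes)) infestation[[nm]] <- true_slopes[[nm]]
    list(stations = stations, infestation = infestation)
  })
}

#' Additive-offset future climate stack
#'
#' Synthetic scenario stacks are built by perturbing the current stack with
#' per-layer additive offsets (e.g. warming all temperature layers), which
#' is enough to exercise projection, class-change mapping and scenario
#' ordering without real circulation-model layers.
#'
#' @param stack Current [climate_stack()].
#' @param offsets Named numeric vector of additive shifts; names must be
#'   layer names. Unnamed layers are left unchanged.
#' @return A [climate_stack()] with identical geometry and mask.
#' @export
perturb_stack <- function(stack, offsets) {
  stopifnot(is_climate_stack(stack))
  unknown <- setdiff(names(offsets), names(stack))
  if (length(unknown) > 0) {
    stop("offsets name unknown layer(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  layers <- stack$layers
  for (nm in names(offsets)) {
    layers[[nm]]$values <- layers[[nm]]$values + offsets[[nm]]
  }
  climate_stack(layers)
}
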