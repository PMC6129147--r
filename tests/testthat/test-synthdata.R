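test_that("generators are pure functions of the seed", {
  cfg <- tiny_config(9)
  s1 <- gen_climate_stack(cfg)
  s2 <- gen_climate_stack(cfg)
  expect_identical(s1, s2)
  t1 <- gen_true_suitability(s1, cfg)
  o1 <- sample_occurrences(t1, cfg)
  o2 <- sample_occurrences(t1, cfg)
  expect_identical(o1, o2)
  g1 <- gen_station_series(cfg, n_stations = 4, n_days = 20, n_locations = 30)
  g2 <- gen_station_series(cfg, n_stations = 4, n_days = 20, n_locations = 30)
  expect_identical(g1, g2)
  # a different seed changes the draw
  expect_false(identical(gen_climate_stack(tiny_config(10)), s1))
})

test_that("layer correlation is controlled by the shared-field mixing weight", {
  mean_abs_r <- function(correlation) {
    mean(sapply(1:20, function(seed) {
      cfg <- synth_config(
        seed = seed, n_rows = 100, n_cols = 100, n_layers = 4,
        layer_correlation = correlation, spatial_range = 3,
        mask_fraction = 0
      )
      st <- gen_climate_stack(cfg)
      m <- sapply(st$layers, function(l) as.vector(l$values))
      r <- stats::cor(m)
      mean(abs(r[upper.tri(r)]))
    }))
  }
  expect_lt(mean_abs_r(0), 0.2)
  expect_gt(mean_abs_r(0.6), 0.4)
})

test_that("spatial_range controls the lag-1 autocorrelation", {
  lag1 <- function(range_cells) {
    cfg <- synth_config(
      seed = 5, n_rows = 60, n_cols = 60, n_layers = 1,
      spatial_range = range_cells, mask_fraction = 0
    )
    v <- gen_climate_stack(cfg)$layers[[1]]$values
    stats::cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  }
  expect_lt(lag1(1), lag1(10))
})

test_that("the truth surface is the logistic of the stated polynomial", {
  # all coefficients and intercept zero -> flat 0.5
  cfg0 <- tiny_config(2, true_coefficients = list(bio10 = c(0, 0)),
                      true_intercept = 0)
  st <- gen_climate_stack(cfg0)
  tr <- gen_true_suitability(st, cfg0)
  expect_true(all(abs(tr$values - 0.5) < 1e-12, na.rm = TRUE))

  # single linear coefficient -> strictly increasing in the layer
  cfg1 <- tiny_config(2, true_coefficients = list(bio10 = c(1, 0)),
                      true_intercept = 0)
  tr1 <- gen_true_suitability(st, cfg1)
  v <- as.vector(st$layers$bio10$values)
  expect_equal(order(v), order(as.vector(tr1$values)))

  # hand-computed cell: standardized value z = 1 with coefficients (2, -1)
  # gives logistic(2*1 - 1*1) = logistic(1)
  hand <- climate_stack(list(
    bio10 = raster_grid(matrix(c(-1, 0, 1), 1, 3), 0, 0, 1)
  ))
  cfg_h <- synth_config(
    n_rows = 1, n_cols = 3, n_layers = 1, layer_names = "bio10",
    true_coefficients = list(bio10 = c(2, -1)), true_intercept = 0,
    mask_fraction = 0
  )
  tr_h <- gen_true_suitability(hand, cfg_h)
  expect_equal(tr_h$values[1, 3], stats::plogis(1), tolerance = 1e-10)
  expect_equal(tr_h$values[1, 3], 0.7311, tolerance = 1e-4)
})

test_that("occurrence sampling is proportional to truth times effort", {
  # flat truth, no bias -> uniform cell frequencies (chi-square)
  cfg <- synth_config(
    seed = 3, n_rows = 5, n_cols = 5, n_layers = 1, mask_fraction = 0,
    n_presence = 10000L, bias_sd = 10
  )
  flat <- const_grid(1, 5, 5, x_origin = 56, y_origin = 22, cell_size = 0.05)
  occ <- sample_occurrences(flat, cfg, bias = FALSE)
  counts <- table(paste(occ$longitude, occ$latitude))
  expect_length(counts, 25)
  chi <- sum((counts - 400)^2 / 400)
  expect_lt(chi, qchisq(0.999, df = 24))

  # truth mass in one cell -> every presence lands there
  point <- flat
  point$values[] <- 0
  point$values[3, 4] <- 1
  occ1 <- sample_occurrences(point, cfg)
  expect_equal(nrow(unique(occ1[, c("longitude", "latitude")])), 1)

  # effort kernel pulls presences toward the bias centre
  cfg_b <- synth_config(
    seed = 3, n_rows = 20, n_cols = 20, n_layers = 1, mask_fraction = 0,
    n_presence = 10000L, bias_center = c(56.5, 22.5), bias_sd = 0.2
  )
  flat_big <- const_grid(1, 20, 20, x_origin = 56, y_origin = 22, cell_size = 0.05)
  d_to <- function(o) mean(sqrt((o$longitude - 56.5)^2 + (o$latitude - 22.5)^2))
  expect_lt(
    d_to(sample_occurrences(flat_big, cfg_b, bias = TRUE)),
    d_to(sample_occurrences(flat_big, cfg_b, bias = FALSE))
  )

  # years drawn from the configured list
  expect_true(all(occ$year %in% cfg$years))
})

test_that("station generator produces schema-valid series and a weak-signal table", {
  cfg <- synth_config(seed = 2)
  empty <- gen_station_series(cfg, n_stations = 3, n_days = 0, n_locations = 5)
  expect_equal(nrow(empty$stations), 0)
  expect_s3_class(empty$stations, "tbl_df")

  ss <- gen_station_series(cfg, n_stations = 6, n_days = 40, n_locations = 50)
  st <- ss$stations
  expect_true(all(st$min_temp <= st$mean_temp & st$mean_temp <= st$max_temp))
  expect_equal(nrow(st), 6 * 40)
  expect_true(all(c("dew_point", "min_temp", "wind_speed", "true_slope_dew_point")
  %in% names(ss$infestation)))
  expect_true(all(ss$infestation$presence %in% 0:1))
})

test_that("zero-effect station world yields near-zero regression R2", {
  r2 <- sapply(1:20, function(seed) {
    cfg <- synth_config(seed = seed, noise_sd = 1.5)
    ss <- gen_station_series(cfg,
      n_stations = 6, n_days = 30,
      effect = c(dew_point = 0, min_temp = 0, wind_speed = 0),
      n_locations = 250
    )
    fit_ols(ss$infestation, "presence", c("dew_point", "min_temp", "wind_speed"))$r_squared
  })
  expect_gte(sum(r2 < 0.05), 18)
})

test_that("a dew-point-only effect is detected as significant by OLS", {
  hits <- sapply(1:50, function(seed) {
    cfg <- synth_config(seed = seed, noise_sd = 0.6)
    ss <- gen_station_series(cfg,
      n_stations = 6, n_days = 30,
      effect = c(dew_point = 1.4), n_locations = 250
    )
    fit <- fit_ols(ss$infestation, "presence", c("dew_point", "min_temp", "wind_speed"))
    fit$p_value[["dew_point"]] < 0.05
  })
  expect_gte(sum(hits), 45)
})

test_that("perturb_stack applies named additive offsets only", {
  w <- tiny_world(4)
  fut <- perturb_stack(w$stack, c(bio10 = 2))
  expect_equal(
    fut$layers$bio10$values,
    w$stack$layers$bio10$values + 2
  )
  expect_identical(fut$layers$bio11$values, w$stack$layers$bio11$values)
  expect_error(perturb_stack(w$stack, c(nope = 1)), "unknown layer")
})
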