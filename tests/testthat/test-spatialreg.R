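test_that("ols recovers exact fits and definitional VIFs", {
  df <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  fit <- fit_ols(df, "y", "x")
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # orthogonal standardized predictors carry no inflation
  orth <- tibble::tibble(
    x1 = rep(c(1, -1), 4), x2 = rep(c(1, 1, -1, -1), 2),
    y = rnorm(8)
  )
  expect_equal(unname(fit_ols(orth, "y", c("x1", "x2"))$vif), c(1, 1),
    tolerance = 1e-10
  )

  expect_error(
    fit_ols(tibble::tibble(a = 1:8, b = 1:8 * 2, y = rnorm(8)), "y", c("a", "b")),
    "collinear"
  )
})

test_that("ols matches an independent normal-equations solve", {
  set.seed(6)
  df <- tibble::tibble(x1 = rnorm(6), x2 = rnorm(6), y = rnorm(6))
  fit <- fit_ols(df, "y", c("x1", "x2"))
  xm <- cbind(1, df$x1, df$x2)
  beta <- solve(t(xm) %*% xm, t(xm) %*% df$y)
  expect_equal(unname(fit$coefficients), as.vector(beta), tolerance = 1e-8)
  rss <- sum((df$y - xm %*% beta)^2)
  expect_equal(fit$aic, 6 * log(rss / 6) + 2 * 4, tolerance = 1e-8)
})

test_that("vif screening drops redundancy in the documented order", {
  set.seed(7)
  n <- 60
  base <- tibble::tibble(
    longitude = runif(n), latitude = runif(n),
    a = rnorm(n), b = rnorm(n)
  )
  base$dup <- base$a # exact duplicate
  base$y <- base$a + rnorm(n)
  sc <- screen_vif(base, "y", c("a", "dup", "b"), vif_max = 7.5)
  expect_setequal(sc$predictors, c("a", "b"))
  expect_equal(nrow(sc$removed), 1)

  # nothing above the cut-off -> identity
  sc2 <- screen_vif(base, "y", c("a", "b"), vif_max = 7.5)
  expect_identical(sc2$predictors, c("a", "b"))
  expect_equal(nrow(sc2$removed), 0)

  # near-collinear pair: iterative screen agrees with exhaustive search
  # over all removal orders
  near <- base
  near$c1 <- near$a + rnorm(n, 0, 0.05)
  preds <- c("a", "c1", "b")
  sc3 <- screen_vif(near, "y", preds, vif_max = 7.5)
  all_ok <- function(set) {
    if (length(set) == 0) {
      return(FALSE)
    }
    all(fit_ols(near, "y", set)$vif <= 7.5)
  }
  # exhaustive: all maximal admissible subsets
  subsets <- unlist(lapply(seq_along(preds), function(k) {
    utils::combn(preds, k, simplify = FALSE)
  }), recursive = FALSE)
  admissible <- Filter(all_ok, subsets)
  sizes <- lengths(admissible)
  best <- admissible[sizes == max(sizes)]
  expect_true(any(vapply(best, function(s) setequal(s, sc3$predictors), logical(1))))
})

test_that("gwr collapses onto ols at enormous bandwidth", {
  set.seed(12)
  n <- 60
  df <- tibble::tibble(
    longitude = runif(n, 56, 58), latitude = runif(n, 22, 24),
    x1 = rnorm(n), x2 = rnorm(n)
  )
  df$y <- 1 + 0.8 * df$x1 - 0.5 * df$x2 + rnorm(n, 0, 0.4)
  ols <- fit_ols(df, "y", c("x1", "x2"))
  for (kern in c("gaussian", "bisquare")) {
    gwr <- fit_gwr(df, "y", c("x1", "x2"), bandwidth = 1e6, kernel = kern)
    co <- as.matrix(gwr$locations[, c("(Intercept)", "x1", "x2")])
    expect_lt(max(abs(sweep(co, 2, ols$coefficients))), 1e-6)
    expect_equal(gwr$global_r_squared, ols$r_squared, tolerance = 1e-6)
  }
})

test_that("each gwr local fit equals a standalone weighted least squares", {
  set.seed(13)
  n <- 40
  df <- tibble::tibble(
    longitude = runif(n, 56, 58), latitude = runif(n, 22, 24),
    x1 = rnorm(n)
  )
  df$y <- df$x1 * df$longitude + rnorm(n, 0, 0.3)
  bw <- 0.5
  gwr <- fit_gwr(df, "y", "x1", bandwidth = bw, kernel = "gaussian")
  xm <- cbind(1, df$x1)
  for (i in c(1, 17, 40)) {
    d <- dubasclim:::geo_dist_matrix(
      df$longitude, df$latitude, df$longitude, df$latitude
    )[i, ]
    w <- exp(-0.5 * (d / bw)^2)
    beta <- stats::lm.wfit(xm, df$y, w)$coefficients
    expect_equal(
      unname(unlist(gwr$locations[i, c("(Intercept)", "x1")])),
      unname(beta),
      tolerance = 1e-8
    )
  }
  expect_true(all(gwr$locations$local_r2 >= 0 & gwr$locations$local_r2 <= 1))
})

test_that("gwr recovers a slope that varies linearly with longitude", {
  cfg <- synth_config(seed = 4, noise_sd = 0)
  ss <- gen_station_series(cfg,
    n_stations = 8, n_days = 30,
    effect = c(dew_point = 1), n_locations = 400, slope_gradient = 0.8
  )
  inf <- ss$infestation
  # regress the latent infestation pressure to isolate slope recovery from
  # binarization noise
  z <- as.numeric(scale(inf$dew_point))
  inf$pressure <- inf$true_slope_dew_point * z + rnorm(400, 0, 0.1)
  gwr <- fit_gwr(inf, "pressure", "dew_point", bandwidth = 0.6)
  # recovered local slope is on the raw scale; truth is per standardized unit
  rec <- gwr$locations$dew_point * stats::sd(inf$dew_point)
  expect_gt(stats::cor(rec, inf$true_slope_dew_point), 0.9)
})

test_that("adding a pure-noise predictor never lowers in-sample R2", {
  set.seed(14)
  n <- 50
  df <- tibble::tibble(
    longitude = runif(n), latitude = runif(n),
    x1 = rnorm(n), noise = rnorm(n)
  )
  df$y <- df$x1 + rnorm(n)
  expect_gte(
    fit_ols(df, "y", c("x1", "noise"))$r_squared + 1e-12,
    fit_ols(df, "y", "x1")$r_squared
  )
})

test_that("station climate is carried to locations by idw", {
  days <- seq.Date(as.Date("2007-01-01"), by = 1, length.out = 10)
  one <- tibble::tibble(
    station_id = "s1", longitude = 56.5, latitude = 23, date = days,
    mean_temp = 20 + 1:10, min_temp = 10 + 1:10, max_temp = 30 + 1:10,
    dew_point = 5 + 1:10, wind_speed = 2, precipitation = 0
  )
  loc <- tibble::tibble(longitude = c(56, 57.3), latitude = c(22.5, 23.8))
  cl <- climate_to_locations(one, loc, 2007)
  expect_equal(cl$min_temp, rep(mean(10 + 1:10), 2))
  expect_equal(cl$dew_point, rep(mean(5 + 1:10), 2))

  two <- dplyr::bind_rows(
    one,
    dplyr::mutate(one,
      station_id = "s2", longitude = 57.5,
      min_temp = min_temp + 4, dew_point = dew_point - 2
    )
  )
  # a location collocated with a station inherits it exactly
  at_station <- climate_to_locations(
    two, tibble::tibble(longitude = 57.5, latitude = 23), 2007
  )
  expect_equal(at_station$min_temp, mean(10 + 1:10) + 4)
  # the midpoint gets the arithmetic mean
  mid <- climate_to_locations(
    two, tibble::tibble(longitude = 57, latitude = 23), 2007
  )
  expect_equal(mid$min_temp, mean(10 + 1:10) + 2)
  expect_error(climate_to_locations(two, loc, 1999), "no station data")
})
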