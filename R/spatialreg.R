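#' Ordinary least squares with collinearity diagnostics
#'
#' Global infestation-climate regression: a least-squares fit of `response`
#' on the named predictors (plus intercept), reporting coefficients,
#' standard errors, R2, an AIC of the form `n * log(RSS / n) + 2 * (K + 2)`
#' (K slopes + intercept + error variance), and the variance inflation
#' factor `VIF_k = 1 / (1 - R2_k)` of each predictor regressed on the
#' others. A binary presence response is fitted as a linear probability
#' model, matching the original analysis' use of OLS on presence data.
#'
#' @param data A data frame; one row per location.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return An `ols_fit`; see [tidy.ols_fit()] and [glance.ols_fit()].
#' @export
fit_ols <- function(data, response, predictors) {
  data <- tibble::as_tibble(data)
  stopifnot(length(predictors) >= 1)
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(data[, predictors, drop = FALSE])
  y <- as.numeric(data[[response]])
  if (anyNA(x) || anyNA(y)) stop("design matrix contains missing cells", call. = FALSE)
  n <- length(y)
  k <- length(predictors)
  if (n <= k + 1) stop("need n > K + 1 observations", call. = FALSE)
  xm <- cbind(`(Intercept)` = 1, x)
  qr_x <- qr(xm)
  if (qr_x$rank < ncol(xm)) {
    bad <- colnames(xm)[qr_x$pivot[(qr_x$rank + 1):ncol(xm)]]
    stop(
      "rank-deficient design; collinear column(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  beta <- qr.coef(qr_x, y)
  fitted <- as.vector(xm %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - k - 1)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - k - 1, lower.tail = FALSE)
  vif <- vapply(seq_len(k), function(j) {
    if (k == 1) {
      return(1)
    }
    xj <- x[, j]
    xo <- cbind(1, x[, -j, drop = FALSE])
    bj <- qr.coef(qr(xo), xj)
    r2j <- 1 - sum((xj - xo %*% bj)^2) / sum((xj - mean(xj))^2)
    1 / max(1 - r2j, .Machine$double.eps)
  }, numeric(1))
  names(vif) <- predictors
  structure(
    list(
      coefficients = beta, std_error = se, statistic = tval, p_value = pval,
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      aic = n * log(rss / n) + 2 * (k + 2),
      vif = vif, n = n, rss = rss,
      fitted = fitted, residuals = resid,
      response = response, predictors = predictors
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "<ols_fit> %s ~ %s | R2 = %.3f, AIC = %.1f, n = %d\n",
    x$response, paste(x$predictors, collapse = " + "), x$r_squared, x$aic, x$n
  ))
  invisible(x)
}

#' Iterative variance-inflation screening
#'
#' Repeatedly drops the predictor with the highest VIF until every remaining
#' VIF is at or below `vif_max`, logging the removal order. This reproduces
#' the redundancy-removal step applied before the geographically weighted
#' fit: highly collinear climate factors are discarded rather than jointly
#' estimated.
#'
#' @param data Data frame of locations.
#' @param response Response column name (used to refit at each step).
#' @param predictors Candidate predictor names.
#' @param vif_max VIF threshold, must exceed 1. Default 7.5 (a common GIS
#'   convention; the analysis this mirrors states none).
#' @return A list: `predictors` (survivors, original order), `removed`
#'   (tibble of step, predictor, vif), `vif` (final values).
#' @export
screen_vif <- function(data, response, predictors, vif_max = 7.5) {
  stopifnot(vif_max > 1)
  kept <- predictors
  removed <- list()
  step <- 0L
  repeat {
    if (length(kept) == 0) {
      stop("degenerate screen: all predictors removed", call. = FALSE)
    }
    # exact duplicates make the full fit rank-deficient before VIF can see
    # them; drop the later duplicate directly
    x <- as.matrix(tibble::as_tibble(data)[, kept, drop = FALSE])
    qr_x <- qr(cbind(1, x))
    if (qr_x$rank < ncol(x) + 1) {
      drop_i <- max(qr_x$pivot[(qr_x$rank + 1):ncol(cbind(1, x))]) - 1L
      step <- step + 1L
      removed[[step]] <- tibble::tibble(
        step = step, predictor = kept[drop_i], vif = Inf
      )
      kept <- kept[-drop_i]
      next
    }
    fit <- fit_ols(data, response, kept)
    if (max(fit$vif) <= vif_max || length(kept) == 1) break
    worst <- which.max(fit$vif)
    step <- step + 1L
    removed[[step]] <- tibble::tibble(
      step = step, predictor = kept[worst], vif = unname(fit$vif[worst])
    )
    kept <- kept[-worst]
  }
  final <- fit_ols(data, response, kept)
  list(
    predictors = kept,
    removed = if (length(removed) > 0) dplyr::bind_rows(removed) else
      tibble::tibble(step = integer(), predictor = character(), vif = numeric()),
    vif = final$vif
  )
}

gwr_kernel <- function(kernel, d, bandwidth) {
  switch(kernel,
    gaussian = exp(-0.5 * (d / bandwidth)^2),
    bisquare = ifelse(d < bandwidth, (1 - (d / bandwidth)^2)^2, 0),
    stop("unknown kernel: ", kernel, call. = FALSE)
  )
}

#' Geographically weighted regression
#'
#' Fits, at every observation location, a weighted least-squares regression
#' with spatial weights `w_ij = kernel(d_ij / bandwidth)` so that the
#' coefficients become smooth functions of position: `y_i = b0(u_i, v_i) +
#' sum_k bk(u_i, v_i) x_ik + e_i`. Local R2 uses locally weighted sums of
#' squares; global R2 pools each location's own fitted value; AIC uses the
#' effective number of parameters (trace of the hat matrix), analogous to
#' the OLS formula `n * log(RSS/n) + 2 * (trace(S) + 1)`. Distances are
#' equirectangular degrees. With an enormous bandwidth (or a constant
#' kernel) every local fit collapses onto the global OLS fit.
#'
#' @param data Data frame with coordinate columns and variables.
#' @param response Response column name.
#' @param predictors Predictor column names.
#' @param coords Names of the coordinate columns, default
#'   `c("longitude", "latitude")`.
#' @param bandwidth Kernel bandwidth in degrees; `NULL` selects it by
#'   leave-one-out cross-validation over a log-spaced grid.
#' @param kernel `"gaussian"` or `"bisquare"`.
#' @return A `gwr_fit` with per-location coefficients and local R2
#'   (`$locations`), residuals, global R2, AIC, the bandwidth used and the
#'   effective parameter count.
#' @export
fit_gwr <- function(data, response, predictors,
                    coords = c("longitude", "latitude"),
                    bandwidth = NULL, kernel = c("gaussian", "bisquare")) {
  kernel <- match.arg(kernel)
  data <- tibble::as_tibble(data)
  miss <- setdiff(c(response, predictors, coords), names(data))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  u <- data[[coords[1]]]
  v <- data[[coords[2]]]
  x <- cbind(`(Intercept)` = 1, as.matrix(data[, predictors, drop = FALSE]))
  y <- as.numeric(data[[response]])
  n <- length(y)
  d <- geo_dist_matrix(u, v, u, v)
  if (is.null(bandwidth)) {
    bandwidth <- select_gwr_bandwidth(x, y, d, kernel)
  }
  stopifnot(bandwidth > 0)
  p <- ncol(x)
  betas <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(x)))
  fitted <- numeric(n)
  local_r2 <- numeric(n)
  tr_s <- 0
  for (i in seq_len(n)) {
    w <- gwr_kernel(kernel, d[i, ], bandwidth)
    xw <- x * w
    xtx <- crossprod(x, xw)
    ok <- tryCatch(
      {
        xtx_inv <- solve(xtx)
        TRUE
      },
      error = function(e) FALSE
    )
    if (!ok) {
      stop(sprintf(
        "bandwidth %g leaves a rank-deficient local system at location %d (%.4f, %.4f)",
        bandwidth, i, u[i], v[i]
      ), call. = FALSE)
    }
    bi <- xtx_inv %*% crossprod(xw, y)
    betas[i, ] <- bi
    fitted[i] <- sum(x[i, ] * bi)
    # hat-matrix diagonal: x_i' (X'WX)^-1 X'W e_i
    tr_s <- tr_s + sum(x[i, ] * (xtx_inv %*% (x[i, ] * w[i])))
    yw_mean <- sum(w * y) / sum(w)
    local_fitted <- as.vector(x %*% bi)
    local_r2[i] <- 1 - sum(w * (y - local_fitted)^2) / sum(w * (y - yw_mean)^2)
  }
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  locations <- tibble::tibble(u = u, v = v)
  for (j in colnames(betas)) locations[[j]] <- betas[, j]
  locations$local_r2 <- local_r2
  structure(
    list(
      locations = locations, residuals = resid, fitted = fitted,
      global_r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      aic = n * log(rss / n) + 2 * (tr_s + 1),
      effective_params = tr_s,
      bandwidth = bandwidth, kernel = kernel, n = n,
      response = response, predictors = predictors
    ),
    class = "gwr_fit"
  )
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf(
    "<gwr_fit> %s ~ %s | %s kernel, bw = %.4g deg, global R2 = %.3f, AIC = %.1f\n",
    x$response, paste(x$predictors, collapse = " + "), x$kernel,
    x$bandwidth, x$global_r_squared, x$aic
  ))
  invisible(x)
}

# Leave-one-out CV bandwidth selection over a log-spaced grid spanning the
# study extent; the smallest-CV bandwidth wins, preferring larger values on
# numerical failure.
select_gwr_bandwidth <- function(x, y, d, kernel, n_grid = 10) {
  extent <- max(d)
  if (extent <= 0) {
    return(1)
  }
  grid <- exp(seq(log(extent / 20), log(extent * 2), length.out = n_grid))
  n <- length(y)
  cv <- vapply(grid, function(bw) {
    err <- 0
    for (i in seq_len(n)) {
      w <- gwr_kernel(kernel, d[i, ], bw)
      w[i] <- 0
      xw <- x * w
      xtx <- crossprod(x, xw)
      bi <- tryCatch(solve(xtx, crossprod(xw, y)), error = function(e) NULL)
      if (is.null(bi)) {
        return(Inf)
      }
      err <- err + (y[i] - sum(x[i, ] * bi))^2
    }
    err
  }, numeric(1))
  grid[which.min(cv)]
}

#' Interpolate station climate factors to survey locations
#'
#' Computes each station's annual means of the requested factors for one
#' year and carries them to the survey locations by inverse-distance
#' weighting — the step that attaches climate covariates to infested
#' locations before the OLS/GWR fits. A location collocated with a station
#' inherits that station's values exactly.
#'
#' @param stations Station-day tibble (see [read_stations()]).
#' @param locations Data frame with `longitude`, `latitude`.
#' @param year Calendar year to average.
#' @param factors Station columns to interpolate.
#' @param power IDW exponent.
#' @return `locations` with one appended column per factor.
#' @export
climate_to_locations <- function(stations, locations, year,
                                 factors = c("min_temp", "dew_point", "wind_speed"),
                                 power = 2) {
  stations <- tibble::as_tibble(stations)
  locations <- tibble::as_tibble(locations)
  yr <- as.integer(format(as.Date(stations$date), "%Y"))
  st <- stations[yr == year, , drop = FALSE]
  if (nrow(st) == 0) {
    stop("no station data for year ", year, call. = FALSE)
  }
  annual <- st |>
    dplyr::group_by(.data$station_id, .data$longitude, .data$latitude) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(factors), \(x) mean(x, na.rm = TRUE)),
      .groups = "drop"
    )
  out <- locations
  for (f in factors) {
    samples <- tibble::tibble(
      longitude = annual$longitude, latitude = annual$latitude,
      value = annual[[f]]
    )
    out[[f]] <- idw(samples, locations, power = power)$value
  }
  out
}
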