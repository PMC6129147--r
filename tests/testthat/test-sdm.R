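test_that("weight surface attains 1 and 20 and inverts sampling density", {
  geom <- const_grid(0, 20, 20, x_origin = 56, y_origin = 22, cell_size = 0.05)
  withr::with_seed(41, {
    occ <- tibble::tibble(
      longitude = c(rnorm(150, 56.3, 0.05), 56.9),
      latitude = c(rnorm(150, 22.3, 0.05), 22.9),
      year = 2007L, presence = 1L
    )
  })
  ws <- kernel_weight_surface(occ, geom)
  expect_equal(min(ws$weights$values, na.rm = TRUE), 1)
  expect_equal(max(ws$weights$values, na.rm = TRUE), 20)
  # the isolated record sits in a low-density, high-weight cell
  w_iso <- extract_at(ws$weights, tibble::tibble(longitude = 56.9, latitude = 22.9))$layer
  w_clu <- extract_at(ws$weights, tibble::tibble(longitude = 56.3, latitude = 22.3))$layer
  expect_gt(w_iso, w_clu)
  d_iso <- extract_at(ws$density, tibble::tibble(longitude = 56.9, latitude = 22.9))$layer
  d_clu <- extract_at(ws$density, tibble::tibble(longitude = 56.3, latitude = 22.3))$layer
  expect_lt(d_iso, d_clu)

  # perfectly uniform records: every cell once -> constant density, weight 1
  cc <- dubasclim:::cell_centers(geom)
  unif <- tibble::tibble(
    longitude = rep(cc$x, each = 20), latitude = rep(cc$y, 20),
    year = 2007L, presence = 1L
  )
  ws_u <- kernel_weight_surface(unif, geom)
  expect_true(all(abs(ws_u$weights$values - 1) < 1e-9))

  expect_error(kernel_weight_surface(occ, geom, sd = 0), "positive")
  occw <- weight_occurrences(occ, ws)
  expect_true(all(occw$weight >= 1 & occw$weight <= 20))
})

test_that("background sampling follows the density and the seed", {
  one <- const_grid(0, 4, 4)
  one$values[2, 3] <- 5
  bg <- sample_background(one, 50, seed = 1)
  expect_equal(nrow(unique(bg)), 1)

  flat <- const_grid(1, 5, 5)
  b1 <- sample_background(flat, 10000, seed = 2)
  counts <- table(paste(b1$longitude, b1$latitude))
  chi <- sum((counts - 400)^2 / 400)
  expect_lt(chi, qchisq(0.999, df = 24))
  expect_identical(sample_background(flat, 100, seed = 3),
    sample_background(flat, 100, seed = 3))

  zero <- const_grid(0, 3, 3)
  expect_warning(bz <- sample_background(zero, 20, seed = 4), "uniform")
  expect_equal(nrow(bz), 20)
})

test_that("feature tables standardize against the background", {
  w <- tiny_world(6)
  bg <- sample_background(const_grid(1, 14, 18,
    x_origin = 56, y_origin = 22, cell_size = 0.05
  ), 300, seed = 5)
  ft <- build_feature_table(w$stack, w$occ, bg, quadratic = TRUE)
  meta <- attr(ft, "feature_meta")
  expect_setequal(
    meta$feature,
    c("bio10", "bio11", "bio16", "bio10_2", "bio11_2", "bio16_2")
  )
  bg_rows <- ft$label == "background"
  for (f in meta$feature) {
    expect_equal(mean(ft[[f]][bg_rows]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(ft[[f]][bg_rows]), 1, tolerance = 1e-10)
  }
  expect_false(anyNA(ft[meta$feature]))
})

test_that("maxent honours its entropy and constraint contracts", {
  # a constant feature imposes no constraint: the distribution stays uniform
  xc <- matrix(1, 20, 1, dimnames = list(NULL, "f"))
  ftc <- manual_features(xc, presence = c(rep(TRUE, 5), rep(FALSE, 15)))
  fitc <- fit_maxent(ftc, beta = 0)
  expect_equal(fitc$background_p, rep(1 / 15, 15), tolerance = 1e-8)

  # two-cell toy: all presences at the cell with feature 1 -> mass moves there
  x2 <- matrix(c(1, 1, 1, 0, 1), ncol = 1, dimnames = list(NULL, "f"))
  ft2 <- manual_features(x2, presence = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  fit2 <- fit_maxent(ft2, beta = 0, max_iter = 5000, tol = 1e-4)
  expect_gt(fit2$background_p[2], 0.99)

  # random 30-cell instance: lambda agrees with the bound-constrained
  # L-BFGS-B oracle; normalization and constraint satisfaction hold
  withr::with_seed(42, {
    x <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
    pres <- c(rep(TRUE, 10), rep(FALSE, 30))
    ft <- manual_features(x, pres)
    beta <- 0.05
    fit <- fit_maxent(ft, beta = beta, tol = 1e-9, max_iter = 5000)
    fb <- x[!pres, ]
    mu <- colMeans(x[pres, ])
    oracle <- maxent_lbfgs_oracle(fb, mu, beta)
    expect_equal(unname(fit$params$lambda), oracle, tolerance = 1e-4)
    expect_equal(sum(fit$background_p), 1, tolerance = 1e-10)
    e_model <- as.vector(crossprod(fb, fit$background_p))
    expect_true(all(abs(e_model - mu) <= beta + 1e-6))
  })
})

test_that("stepwise glm matches direct likelihood maximization and base rates", {
  # balanced labels with useless features -> predicted probability one half
  withr::with_seed(43, {
    x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("n1", "n2")))
    ft <- manual_features(x, presence = rep(c(TRUE, FALSE), 50))
    fit <- fit_glm_stepwise(ft)
    p <- dubasclim:::predict_features(fit, x)
    expect_equal(mean(p), 0.5, tolerance = 0.05)
  })

  # IRLS coefficients equal an independent optim() likelihood maximization
  withr::with_seed(44, {
    x <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("s", "n")))
    y <- rbinom(80, 1, plogis(1.2 * x[, "s"]))
    ft <- manual_features(x, presence = y == 1)
    fit <- fit_glm_stepwise(ft)
    terms <- setdiff(names(fit$params$coefficients), "(Intercept)")
    xm <- cbind(1, x[, terms, drop = FALSE])
    nll <- function(b) {
      eta <- as.vector(xm %*% b)
      -sum(y * eta - log1p(exp(eta)))
    }
    o <- stats::optim(rep(0, ncol(xm)), nll,
      method = "BFGS",
      control = list(maxit = 1000, reltol = 1e-14)
    )
    expect_equal(unname(fit$params$coefficients[c("(Intercept)", terms)]),
      o$par,
      tolerance = 1e-6
    )
  })
})

test_that("stepwise glm finds strong predictors and never beats intercept AIC backwards", {
  res <- sapply(1:50, function(seed) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(1000), 500, 2, dimnames = list(NULL, c("signal", "noise")))
      y <- rbinom(500, 1, plogis(1.5 * x[, "signal"]))
      ft <- manual_features(x, presence = y == 1)
      terms <- names(fit_glm_stepwise(ft)$params$coefficients)
      c(signal = "signal" %in% terms, noise = "noise" %in% terms)
    })
  })
  # the strong term is essentially always found; a pure-noise term enters
  # an AIC-stepwise model with probability P(chisq_1 > 2) ~ 0.16, so its
  # exclusion rate is bounded accordingly
  expect_gte(sum(res["signal", ]), 48)
  expect_gte(sum(!res["noise", ]), 36)

  # stepwise AIC can only improve on the intercept-only model
  withr::with_seed(45, {
    x <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(60, 1, 0.4)
    ft <- manual_features(x, presence = y == 1)
    fit <- fit_glm_stepwise(ft)
    null_aic <- stats::AIC(stats::glm(y ~ 1, family = stats::binomial()))
    expect_lte(fit$aic, null_aic + 1e-9)
  })
})

test_that("brt splits where an exhaustive search says and boosts monotonically", {
  withr::with_seed(46, {
    xv <- c(runif(30, -2, -0.4), runif(30, 0.4, 2))
    x <- matrix(xv, ncol = 1, dimnames = list(NULL, "x"))
    y <- as.integer(xv > 0)
    ft <- manual_features(x, presence = y == 1)
    fit <- fit_brt(ft, n_trees = 1, learning_rate = 0.3, tree_depth = 1,
      bag_fraction = 1, seed = 1, min_obs = 2)
    root <- fit$params$trees[[1]]$nodes[[fit$params$trees[[1]]$root]]
    expect_true(root$split > max(xv[xv < 0]) && root$split < min(xv[xv > 0]))
    # exhaustive oracle over all midpoints for the first-tree residuals
    r <- y - mean(y)
    xs <- sort(xv)
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    sse <- vapply(mids, function(m) {
      sum((r[xv <= m] - mean(r[xv <= m]))^2) + sum((r[xv > m] - mean(r[xv > m]))^2)
    }, numeric(1))
    best_gap <- mids[which.min(sse)]
    expect_equal(root$split, best_gap, tolerance = 1e-12)
  })

  # training deviance is non-increasing without bagging
  withr::with_seed(47, {
    x <- matrix(rnorm(300), 150, 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(150, 1, plogis(x[, 1]))
    ft <- manual_features(x, presence = y == 1)
    fit <- fit_brt(ft, n_trees = 40, learning_rate = 0.1, bag_fraction = 1, seed = 2)
    expect_true(all(diff(fit$train_deviance) <= 1e-9))

    # zero learning rate freezes the base-rate prediction
    fit0 <- fit_brt(ft, n_trees = 3, learning_rate = 0, bag_fraction = 1, seed = 2)
    p <- dubasclim:::predict_features(fit0, x)
    expect_equal(p, rep(mean(y), 150), tolerance = 1e-12)
  })
  expect_error(
    fit_brt(manual_features(matrix(1:10, ncol = 1, dimnames = list(NULL, "x")),
      presence = rep(c(TRUE, FALSE), 5)
    ), bag_fraction = 1.4),
    "bag_fraction"
  )
})

test_that("duplicating a row is equivalent to doubling its weight", {
  withr::with_seed(48, {
    x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
    pres <- rep(c(TRUE, FALSE), 20)
    ft_dup <- manual_features(rbind(x, x[1, , drop = FALSE]), c(pres, pres[1]))
    w <- rep(1, 40)
    w[1] <- 2
    ft_w <- manual_features(x, pres, weight = w)
    newx <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
    for (fitter in list(
      function(ft) fit_maxent(ft, beta = 0.01, tol = 1e-8, max_iter = 5000),
      fit_glm_stepwise,
      function(ft) fit_brt(ft, n_trees = 5, learning_rate = 0.1,
        bag_fraction = 1, seed = 9, min_obs = 2)
    )) {
      p_dup <- dubasclim:::predict_features(fitter(ft_dup), newx)
      p_w <- dubasclim:::predict_features(fitter(ft_w), newx)
      expect_equal(p_dup, p_w, tolerance = 1e-6)
    }
  })
})

test_that("prediction respects masks, extrapolates without clamping, names missing layers", {
  w <- tiny_world(7, mask_fraction = 0.1)
  bg <- sample_background(w$stack$layers[[1]], 200, seed = 6)
  ft <- suppressWarnings(build_feature_table(w$stack, w$occ, bg))
  fit <- fit_glm_stepwise(ft)
  r <- predict_sdm(fit, w$stack)
  expect_identical(is.na(r$values), dubasclim:::stack_mask(w$stack))
  expect_true(all(r$values >= 0 & r$values <= 1, na.rm = TRUE))

  # glm on all-zero features predicts logistic(intercept) everywhere
  co <- fit$params$coefficients
  zero <- matrix(0, 3, length(setdiff(names(co), "(Intercept)")),
    dimnames = list(NULL, setdiff(names(co), "(Intercept)"))
  )
  expect_equal(
    dubasclim:::predict_features(fit, zero),
    rep(plogis(co[["(Intercept)"]]), 3),
    tolerance = 1e-12
  )

  # a cell far outside the training range still gets a finite, untruncated score
  far <- w$stack
  far$layers$bio10$values[1, 1] <- max(w$stack$layers$bio10$values, na.rm = TRUE) + 50
  rf <- predict_sdm(fit, far)
  expect_true(is.finite(rf$values[1, 1]) || is.na(rf$values[1, 1]))
  # manual extrapolated linear predictor agrees
  meta <- fit$feature_meta
  raw <- sapply(names(far$layers), function(nm) far$layers[[nm]]$values[1, 1])
  if (!any(is.na(raw))) {
    xrow <- dubasclim:::features_from_raw(fit, t(as.matrix(raw)))
    expect_equal(rf$values[1, 1],
      dubasclim:::predict_features(fit, xrow),
      tolerance = 1e-12
    )
  }

  # maxent scores are a monotone transform of the fitted Gibbs distribution
  fitm <- fit_maxent(ft)
  fp <- dubasclim:::ft_parts(ft)
  sc <- dubasclim:::predict_features(fitm, fp$x[!fp$presence, , drop = FALSE])
  expect_equal(
    stats::cor(sc, fitm$background_p, method = "spearman"), 1,
    tolerance = 1e-12
  )

  dropped <- climate_stack(w$stack$layers[c("bio10", "bio11")])
  expect_error(predict_sdm(fit, dropped), "bio16")
})
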