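# Circular Gaussian smoothing of a matrix (FFT); sigma in cells. Shared by
# the survey-effort density estimate. NA cells contribute zero mass.
smooth_matrix <- function(m, sigma) {
  n_rows <- nrow(m)
  n_cols <- ncol(m)
  m[is.na(m)] <- 0
  if (sigma <= 0) {
    return(m)
  }
  ri <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  ci <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  kern <- exp(-0.5 * outer(ri^2, ci^2, "+") / sigma^2)
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(m) * stats::fft(kern), inverse = TRUE)) / (n_rows * n_cols)
}

#' Survey-effort density and record-weight surface
#'
#' Estimates the survey-effort (record) density with a Gaussian kernel over
#' the grid, normalized by the smoothed terrestrial-cell indicator so the
#' coastline does not depress densities (the edge-corrected
#' "records per weighted terrestrial cell" construction), then converts it
#' to record weights: weights are *inversely* related to relative density —
#' records from under-sampled areas matter more — and linearly rescaled to
#' the interval \[1, 20\]. Any non-constant density therefore attains both
#' 1 and 20 exactly; a perfectly uniform density maps every weight to 1.
#'
#' @param occ Occurrence tibble.
#' @param geometry [raster_grid()] template; its NA cells define sea.
#' @param sd Kernel standard deviation in degrees. Default: the shorter of
#'   the extent's width/height divided by 8. The bandwidth must be wider
#'   than the habitat autocorrelation scale: a too-narrow kernel
#'   reconstructs the species' own distribution instead of survey effort,
#'   and a background matched to it cancels the climatic signal the models
#'   are meant to find (see the methods vignette).
#' @return A `weight_surface`: list with `weights` and `density`
#'   [raster_grid()]s and the `sd` used.
#' @export
kernel_weight_surface <- function(occ, geometry, sd = NULL) {
  occ <- as_occurrence_table(occ)
  stopifnot(is_raster_grid(geometry))
  if (nrow(occ) < 1) stop("at least one record required", call. = FALSE)
  if (is.null(sd)) {
    sd <- min(
      geometry$n_cols * geometry$cell_size,
      geometry$n_rows * geometry$cell_size
    ) / 8
  }
  if (sd <= 0) stop("kernel sd must be positive", call. = FALSE)
  loc <- locate_cells(geometry, occ$longitude, occ$latitude)
  ok <- !loc$out_of_bounds
  counts <- matrix(0, geometry$n_rows, geometry$n_cols)
  for (i in which(ok)) {
    counts[loc$row[i], loc$col[i]] <- counts[loc$row[i], loc$col[i]] + 1
  }
  land <- !is.na(geometry$values)
  if (!any(land)) land <- matrix(TRUE, geometry$n_rows, geometry$n_cols)
  sigma_cells <- sd / geometry$cell_size
  num <- smooth_matrix(counts, sigma_cells)
  den <- smooth_matrix(land * 1, sigma_cells)
  density <- num / pmax(den, .Machine$double.eps)
  density[!land] <- NA_real_
  rng <- range(density, na.rm = TRUE)
  w <- matrix(NA_real_, geometry$n_rows, geometry$n_cols)
  if (diff(rng) < 1e-12) {
    w[land] <- 1 # degenerate rule: uniform sampling needs no reweighting
  } else {
    w[land] <- 1 + 19 * (rng[2] - density[land]) / (rng[2] - rng[1])
  }
  structure(
    list(
      weights = raster_grid(w, geometry$x_origin, geometry$y_origin, geometry$cell_size),
      density = raster_grid(density, geometry$x_origin, geometry$y_origin, geometry$cell_size),
      sd = sd
    ),
    class = "weight_surface"
  )
}

#' Attach survey-bias weights to occurrence records
#'
#' @param occ Occurrence tibble.
#' @param ws A [kernel_weight_surface()].
#' @return `occ` with its `weight` column replaced by the weight of the
#'   containing cell (records on masked cells keep weight 1).
#' @export
weight_occurrences <- function(occ, ws) {
  stopifnot(inherits(ws, "weight_surface"))
  occ <- as_occurrence_table(occ)
  ex <- extract_at(ws$weights, occ[, c("longitude", "latitude")])
  w <- ex$layer
  w[is.na(w)] <- 1
  occ$weight <- w
  occ
}

#' Bias-matched background sample
#'
#' Draws background (pseudo-absence) cells with probability proportional to
#' the survey-effort density, so the background carries the same sampling
#' bias as the presences and the models contrast environment, not effort.
#' An all-zero density falls back to uniform sampling with a warning.
#'
#' @param density A [raster_grid()] of non-negative density.
#' @param n Number of draws (with replacement).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A tibble of `longitude`, `latitude` cell centres.
#' @export
sample_background <- function(density, n, seed) {
  stopifnot(is_raster_grid(density), n >= 1)
  p <- as.vector(density$values)
  usable <- !is.na(p)
  p[!usable] <- 0
  p[p < 0] <- 0
  if (sum(p) <= 0) {
    warning("all-zero background density; falling back to uniform sampling",
      call. = FALSE
    )
    p[usable] <- 1
  }
  cc <- cell_centers(density)
  lon <- rep(cc$x, each = density$n_rows)
  lat <- rep(cc$y, times = density$n_cols)
  withr::with_seed(seed, {
    idx <- sample.int(length(p), n, replace = TRUE, prob = p)
    tibble::tibble(longitude = lon[idx], latitude = lat[idx])
  })
}

#' Build a standardized presence/background feature table
#'
#' Extracts the stack's layer values at presence and background points,
#' expands them to linear (and optionally quadratic) features, and
#' standardizes every feature against the *background* mean and standard
#' deviation — the background defines the available environment, so
#' presence features stay comparable across replicates. Points falling
#' outside the grid or on masked cells are dropped (with a warning when any
#' presences are lost). No missing values remain.
#'
#' @param stack A [climate_stack()].
#' @param presence Occurrence tibble (its `weight` column is kept).
#' @param background Tibble of background points.
#' @param quadratic Add squared-value features (named `<layer>_2`)?
#' @return A `feature_table` tibble: feature columns, `label`
#'   (`"presence"`/`"background"`) and `weight`; attributes `feature_meta`
#'   (feature, layer, power, center, scale).
#' @export
build_feature_table <- function(stack, presence, background, quadratic = TRUE) {
  stopifnot(is_climate_stack(stack))
  presence <- as_occurrence_table(presence)
  nm <- names(stack)
  exp_ <- extract_at(stack, presence)
  exb <- extract_at(stack, background)
  keep_p <- !exp_$out_of_bounds & !exp_$masked
  keep_b <- !exb$out_of_bounds & !exb$masked
  if (any(!keep_p)) {
    warning(sprintf("%d presence record(s) off-grid or masked; dropped", sum(!keep_p)),
      call. = FALSE
    )
  }
  raw <- rbind(
    as.matrix(exp_[keep_p, nm, drop = FALSE]),
    as.matrix(exb[keep_b, nm, drop = FALSE])
  )
  n_p <- sum(keep_p)
  n_b <- sum(keep_b)
  if (n_p < 1 || n_b < 2) {
    stop("need at least 1 usable presence and 2 background points", call. = FALSE)
  }
  meta <- tibble::tibble(feature = nm, layer = nm, power = 1)
  feats <- raw
  if (quadratic) {
    feats <- cbind(feats, raw^2)
    meta <- rbind(meta, tibble::tibble(
      feature = paste0(nm, "_2"), layer = nm, power = 2
    ))
  }
  colnames(feats) <- meta$feature
  bg_rows <- (n_p + 1):(n_p + n_b)
  centers <- colMeans(feats[bg_rows, , drop = FALSE])
  scales <- apply(feats[bg_rows, , drop = FALSE], 2, stats::sd)
  scales[scales < 1e-12] <- 1
  feats <- sweep(sweep(feats, 2, centers), 2, scales, "/")
  out <- tibble::as_tibble(as.data.frame(feats))
  out$label <- rep(c("presence", "background"), c(n_p, n_b))
  out$weight <- c(presence$weight[keep_p], rep(1, n_b))
  meta$center <- unname(centers)
  meta$scale <- unname(scales)
  attr(out, "feature_meta") <- meta
  class(out) <- c("feature_table", class(out))
  out
}

ft_parts <- function(features) {
  meta <- attr(features, "feature_meta")
  fn <- meta$feature
  list(
    meta = meta,
    x = as.matrix(features[, fn, drop = FALSE]),
    presence = features$label == "presence",
    weight = features$weight
  )
}

new_sdm_fit <- function(kind, params, feature_meta, converged = TRUE,
                        iterations = NA_integer_, aic = NA_real_, extra = list()) {
  structure(
    c(
      list(
        kind = kind, params = params, feature_meta = feature_meta,
        converged = converged, iterations = iterations, aic = aic
      ),
      extra
    ),
    class = "sdm_fit"
  )
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf(
    "<sdm_fit:%s> %d features%s%s\n",
    x$kind, nrow(x$feature_meta),
    if (!is.na(x$aic)) sprintf(", AIC = %.1f", x$aic) else "",
    if (!x$converged) " (NOT converged)" else ""
  ))
  invisible(x)
}

#' Maximum-entropy presence-background model
#'
#' Fits the Gibbs distribution `p(x) proportional to exp(sum lambda_f f(x))`
#' over the background rows that maximizes the L1-penalized log-likelihood
#' of the presences — the minimum-relative-entropy distribution whose
#' feature expectations match the (weighted) presence feature means to
#' within the regularization budget: at convergence
#' `|E_p[f] - mean_presence[f]| <= beta + tol` for every feature. Solved by
#' proximal gradient (FISTA with backtracking and soft-thresholding).
#'
#' The fitted raw distribution over background rows is exposed as
#' `$background_p`; map-scale predictions use the logistic output
#' `plogis(lambda . f(x) - alpha)` with `alpha` fixed so the weighted mean
#' presence score sits at 0.5 (the classic default output transform).
#'
#' @param features A [build_feature_table()] table.
#' @param beta L1 regularization budget per (standardized) feature. The
#'   default `NULL` uses `1 / sqrt(m)` with `m` the number of presence
#'   rows — the sampling-error scale of a standardized presence feature
#'   mean, so constraints are only enforced beyond what the presence sample
#'   can resolve.
#' @param max_iter Iteration cap; non-convergence returns the fit with
#'   `converged = FALSE` and a warning.
#' @param tol Tolerance on the Karush-Kuhn-Tucker violation.
#' @return An `sdm_fit` of kind `"maxent"`.
#' @export
fit_maxent <- function(features, beta = NULL, max_iter = 1000L, tol = 1e-5) {
  fp <- ft_parts(features)
  if (is.null(beta)) beta <- 1 / sqrt(max(sum(fp$presence), 1))
  stopifnot(beta >= 0)
  if (sum(fp$presence) < 1 || sum(!fp$presence) < 2) {
    stop("need at least 1 presence and 2 background rows", call. = FALSE)
  }
  fb <- fp$x[!fp$presence, , drop = FALSE]
  wp <- fp$weight[fp$presence]
  mu <- colSums(fp$x[fp$presence, , drop = FALSE] * wp) / sum(wp)
  m <- ncol(fb)
  lambda <- numeric(m)
  # concave smooth part: g(lambda) = lambda.mu - logsumexp(Fb lambda)
  smooth_val <- function(l) {
    eta <- as.vector(fb %*% l)
    mx <- max(eta)
    sum(l * mu) - (mx + log(sum(exp(eta - mx))))
  }
  smooth_grad <- function(l) {
    eta <- as.vector(fb %*% l)
    p <- exp(eta - max(eta))
    p <- p / sum(p)
    mu - as.vector(crossprod(fb, p))
  }
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  kkt <- function(l) {
    g <- smooth_grad(l)
    v <- pmax(abs(g) - beta, 0)
    v[l > 0] <- abs(g[l > 0] - beta)
    v[l < 0] <- abs(g[l < 0] + beta)
    max(v)
  }
  step <- 1
  z <- lambda
  t_acc <- 1
  converged <- FALSE
  iter <- 0L
  f_old <- smooth_val(lambda)
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- smooth_grad(z)
    repeat {
      cand <- soft(z + step * g, step * beta)
      fc <- smooth_val(cand)
      dz <- cand - z
      if (fc >= smooth_val(z) + sum(g * dz) - sum(dz^2) / (2 * step) - 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    z <- cand + ((t_acc - 1) / t_new) * (cand - lambda)
    lambda <- cand
    t_acc <- t_new
    if (iter %% 5 == 0 && kkt(lambda) <= tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && kkt(lambda) <= tol) converged <- TRUE
  if (!converged) {
    warning(sprintf(
      "maxent did not converge in %d iterations (KKT violation %.2e)",
      max_iter, kkt(lambda)
    ), call. = FALSE)
  }
  eta_b <- as.vector(fb %*% lambda)
  p_b <- exp(eta_b - max(eta_b))
  p_b <- p_b / sum(p_b)
  eta_p <- as.vector(fp$x[fp$presence, , drop = FALSE] %*% lambda)
  alpha <- sum(wp * eta_p) / sum(wp)
  new_sdm_fit(
    "maxent",
    params = list(lambda = stats::setNames(lambda, colnames(fb)), alpha = alpha,
                  beta = beta),
    feature_meta = fp$meta, converged = converged, iterations = iter,
    extra = list(background_p = p_b, presence_mean = mu)
  )
}

#' Stepwise-AIC logistic regression
#'
#' A binomial GLM fitted by iteratively reweighted least squares with
#' bidirectional stepwise term selection by AIC (`-2 loglik + 2 (terms+1)`),
#' starting from the intercept-only model with all linear and quadratic
#' features in scope — so the returned model's AIC can never exceed the
#' intercept-only model's. Complete separation is handled by capping
#' coefficients at +/-15 (on standardized features) with a warning;
#' predictions use the capped coefficients.
#'
#' @param features A [build_feature_table()] table.
#' @param max_steps Cap on stepwise moves.
#' @param coef_bound Separation cap for coefficients.
#' @return An `sdm_fit` of kind `"glm"` (AIC recorded).
#' @export
fit_glm_stepwise <- function(features, max_steps = 50L, coef_bound = 15) {
  fp <- ft_parts(features)
  df <- as.data.frame(fp$x)
  df$.y <- as.integer(fp$presence)
  w <- fp$weight
  terms_all <- colnames(fp$x)
  upper <- stats::as.formula(paste(".y ~", paste(terms_all, collapse = " + ")))
  base <- suppressWarnings(
    stats::glm(.y ~ 1, data = df, family = stats::binomial(), weights = w)
  )
  fit <- suppressWarnings(
    stats::step(base,
      scope = list(lower = ~1, upper = upper),
      direction = "both", trace = 0, steps = max_steps
    )
  )
  co <- stats::coef(fit)
  capped <- abs(co) > coef_bound
  if (any(capped) || !fit$converged) {
    warning(
      "possible complete separation; coefficient(s) capped at +/-",
      coef_bound,
      call. = FALSE
    )
    co <- pmin(pmax(co, -coef_bound), coef_bound)
  }
  new_sdm_fit(
    "glm",
    params = list(coefficients = co),
    feature_meta = fp$meta, converged = fit$converged,
    iterations = fit$iter, aic = stats::AIC(fit)
  )
}

# ---- boosted regression trees --------------------------------------------

# Greedy weighted-variance-reduction regression tree on residuals.
# Returns a node table; leaves carry Newton-step values for binomial loss,
# with an L2 (ridge) term on the Hessian so near-saturated leaves cannot
# produce unbounded logit jumps.
fit_gradient_tree <- function(x, r, w, h, depth, min_obs = 10, leaf_lambda = 1) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  grow <- function(rows, d) {
    id <- new_node()
    nodes[[id]] <<- list(
      feature = NA_integer_, split = NA_real_, left = NA_integer_,
      right = NA_integer_, value = sum(w[rows] * r[rows]) / (sum(h[rows]) + leaf_lambda)
    )
    if (d >= depth || length(rows) < 2 * min_obs) {
      return(id)
    }
    best <- list(gain = 1e-12, feature = NA, split = NA)
    sw <- sum(w[rows])
    sr <- sum(w[rows] * r[rows])
    for (j in seq_len(ncol(x))) {
      xv <- x[rows, j]
      ord <- order(xv)
      xs <- xv[ord]
      wr <- (w[rows] * r[rows])[ord]
      ww <- w[rows][ord]
      cw <- cumsum(ww)
      cr <- cumsum(wr)
      nr <- length(rows)
      valid <- which(xs[-nr] < xs[-1] - 1e-12)
      valid <- valid[cw[valid] > 1e-12 & (sw - cw[valid]) > 1e-12]
      if (length(valid) == 0) next
      gain <- cr[valid]^2 / cw[valid] + (sr - cr[valid])^2 / (sw - cw[valid]) - sr^2 / sw
      b <- which.max(gain)
      if (gain[b] > best$gain) {
        best <- list(
          gain = gain[b], feature = j,
          split = (xs[valid[b]] + xs[valid[b] + 1]) / 2
        )
      }
    }
    if (is.na(best$feature)) {
      return(id)
    }
    go_left <- x[rows, best$feature] <= best$split
    left_id <- grow(rows[go_left], d + 1L)
    right_id <- grow(rows[!go_left], d + 1L)
    nodes[[id]]$feature <<- best$feature
    nodes[[id]]$split <<- best$split
    nodes[[id]]$gain <<- best$gain
    nodes[[id]]$left <<- left_id
    nodes[[id]]$right <<- right_id
    id
  }
  root <- grow(seq_along(r), 0L)
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  walk <- function(id, rows) {
    nd <- tree$nodes[[id]]
    if (is.na(nd$feature)) {
      out[rows] <<- nd$value
      return(invisible(NULL))
    }
    go_left <- x[rows, nd$feature] <= nd$split
    if (any(go_left)) walk(nd$left, rows[go_left])
    if (any(!go_left)) walk(nd$right, rows[!go_left])
  }
  walk(tree$root, seq_len(nrow(x)))
  out
}

#' Boosted regression trees on binomial deviance
#'
#' Stagewise gradient boosting: starting from the base-rate logit, each
#' stage fits a shallow regression tree to the current negative gradient
#' (`y - p`) by greedy weighted-variance-reduction splits, applies a Newton
#' step per leaf, and adds `learning_rate` times the tree to the score.
#' Optional bagging subsamples rows per stage (`bag_fraction`); with
#' `bag_fraction = 1` the training deviance is non-increasing in the tree
#' index. With `valid_fraction > 0` a row subset is held out of every
#' stage and the returned model is truncated at the stage minimizing the
#' held-out deviance (the usual guard against boosting past the optimum).
#' Deterministic given `seed`. Defaults follow the common boosted-tree
#' recommendations for ecological data (slow learning rate, depth-3 trees,
#' 0.75 bagging).
#'
#' @param features A [build_feature_table()] table.
#' @param n_trees Number of boosting stages, >= 1.
#' @param learning_rate Shrinkage in \[0, 1\]; 0 freezes the base rate.
#' @param tree_depth Maximum tree depth, >= 1.
#' @param bag_fraction Row subsampling fraction in (0, 1].
#' @param seed Integer seed for bagging and the validation split.
#' @param min_obs Minimum rows per split.
#' @param valid_fraction Fraction of rows held out for choosing the number
#'   of trees; 0 keeps all `n_trees`.
#' @param leaf_lambda L2 regularization added to the per-leaf Hessian in the
#'   Newton step, bounding leaf values where predicted probabilities
#'   saturate.
#' @return An `sdm_fit` of kind `"brt"`; `$train_deviance` traces the
#'   full-sample weighted deviance per stage.
#' @export
fit_brt <- function(features, n_trees = 500L, learning_rate = 0.01,
                    tree_depth = 3L, bag_fraction = 0.75, seed = 1L,
                    min_obs = 10, valid_fraction = 0, leaf_lambda = 1) {
  if (!(bag_fraction > 0 && bag_fraction <= 1)) {
    stop("bag_fraction must be in (0, 1]", call. = FALSE)
  }
  stopifnot(n_trees >= 1, tree_depth >= 1, learning_rate >= 0)
  fp <- ft_parts(features)
  x <- fp$x
  y <- as.numeric(fp$presence)
  w <- fp$weight
  n <- length(y)
  stopifnot(valid_fraction >= 0, valid_fraction < 1)
  wdev <- function(yy, ww, pp) {
    -2 * sum(ww * (yy * log(pmax(pp, 1e-12)) +
      (1 - yy) * log(pmax(1 - pp, 1e-12))))
  }
  base_rate <- sum(w * y) / sum(w)
  f0 <- stats::qlogis(min(max(base_rate, 1e-6), 1 - 1e-6))
  trees <- vector("list", n_trees)
  deviance <- numeric(n_trees)
  valid_deviance <- rep(NA_real_, n_trees)
  withr::with_seed(seed, {
    valid <- if (valid_fraction > 0) {
      sort(sample.int(n, max(2, floor(valid_fraction * n))))
    } else {
      integer(0)
    }
    fit_rows <- setdiff(seq_len(n), valid)
    f_score <- rep(f0, n)
    for (t in seq_len(n_trees)) {
      p <- stats::plogis(f_score)
      r <- y - p
      h <- w * p * (1 - p)
      rows <- if (bag_fraction < 1) {
        sort(sample(fit_rows, max(2, floor(bag_fraction * length(fit_rows)))))
      } else {
        fit_rows
      }
      tree <- fit_gradient_tree(
        x[rows, , drop = FALSE], r[rows], w[rows], h[rows],
        depth = tree_depth, min_obs = min_obs, leaf_lambda = leaf_lambda
      )
      if (learning_rate > 0) {
        f_score <- f_score + learning_rate * predict_tree(tree, x)
      }
      trees[[t]] <- tree
      p_full <- stats::plogis(f_score)
      deviance[t] <- wdev(y[fit_rows], w[fit_rows], p_full[fit_rows])
      if (length(valid) > 0) {
        valid_deviance[t] <- wdev(y[valid], w[valid], p_full[valid])
      }
    }
  })
  best <- if (valid_fraction > 0) which.min(valid_deviance) else n_trees
  new_sdm_fit(
    "brt",
    params = list(
      f0 = f0, trees = trees[seq_len(best)], learning_rate = learning_rate,
      n_trees = best, tree_depth = tree_depth, bag_fraction = bag_fraction
    ),
    feature_meta = fp$meta, iterations = best,
    extra = list(
      train_deviance = deviance[seq_len(best)],
      valid_deviance = valid_deviance
    )
  )
}

# Score a standardized feature matrix with any fitted learner; output in [0,1].
predict_features <- function(fit, x) {
  switch(fit$kind,
    maxent = {
      eta <- as.vector(x[, names(fit$params$lambda), drop = FALSE] %*% fit$params$lambda)
      stats::plogis(eta - fit$params$alpha)
    },
    glm = {
      co <- fit$params$coefficients
      terms <- setdiff(names(co), "(Intercept)")
      eta <- rep(co[["(Intercept)"]], nrow(x))
      if (length(terms) > 0) {
        eta <- eta + as.vector(x[, terms, drop = FALSE] %*% co[terms])
      }
      stats::plogis(eta)
    },
    brt = {
      f_score <- rep(fit$params$f0, nrow(x))
      if (fit$params$learning_rate > 0) {
        for (tree in fit$params$trees) {
          f_score <- f_score + fit$params$learning_rate * predict_tree(tree, x)
        }
      }
      stats::plogis(f_score)
    },
    stop("unknown model kind: ", fit$kind, call. = FALSE)
  )
}

# Raw layer values -> standardized feature matrix using the fit's stored
# training standardization. No clamping: values outside the training range
# extrapolate.
features_from_raw <- function(fit, raw) {
  meta <- fit$feature_meta
  missing_layers <- setdiff(unique(meta$layer), colnames(raw))
  if (length(missing_layers) > 0) {
    stop("missing layer(s): ", paste(missing_layers, collapse = ", "),
      call. = FALSE
    )
  }
  x <- matrix(NA_real_, nrow(raw), nrow(meta),
    dimnames = list(NULL, meta$feature)
  )
  for (i in seq_len(nrow(meta))) {
    v <- raw[, meta$layer[i]]^meta$power[i]
    x[, i] <- (v - meta$center[i]) / meta$scale[i]
  }
  x
}

#' Predict a suitability surface from a fitted model
#'
#' Applies any `sdm_fit` to a climate stack, cell by cell. Features are
#' standardized with the training statistics and *not* clamped: cells whose
#' climate lies outside the training range are extrapolated, never
#' truncated. Masked cells stay masked.
#'
#' @param fit An `sdm_fit`.
#' @param stack A [climate_stack()] containing every layer the fit uses.
#' @return A [raster_grid()] of scores in \[0, 1\].
#' @export
predict_sdm <- function(fit, stack) {
  stopifnot(inherits(fit, "sdm_fit"), is_climate_stack(stack))
  g <- stack_geometry(stack)
  keep <- which(!as.vector(stack_mask(stack)))
  raw <- vapply(
    stack$layers, function(l) as.vector(l$values)[keep],
    numeric(length(keep))
  )
  if (length(keep) == 1) raw <- matrix(raw, nrow = 1, dimnames = list(NULL, names(stack)))
  x <- features_from_raw(fit, raw)
  scores <- predict_features(fit, x)
  out <- rep(NA_real_, g$n_rows * g$n_cols)
  out[keep] <- scores
  raster_grid(
    matrix(out, g$n_rows, g$n_cols),
    g$x_origin, g$y_origin, g$cell_size
  )
}

#' Score arbitrary points under a fitted model
#'
#' @param fit An `sdm_fit`.
#' @param stack The climate stack to read features from.
#' @param points Data frame with `longitude`, `latitude`.
#' @return Numeric scores in \[0, 1\]; `NA` for masked/out-of-bounds points.
#' @export
sdm_scores <- function(fit, stack, points) {
  ex <- extract_at(stack, points)
  ok <- !ex$out_of_bounds & !ex$masked
  raw <- as.matrix(ex[ok, names(stack), drop = FALSE])
  scores <- rep(NA_real_, nrow(ex))
  if (any(ok)) scores[ok] <- predict_features(fit, features_from_raw(fit, raw))
  scores
}
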