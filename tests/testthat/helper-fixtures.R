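# Small, fast synthetic worlds and hand-built fixtures shared across tests.

tiny_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, n_rows = 14L, n_cols = 18L, n_layers = 3L,
    layer_names = c("bio10", "bio11", "bio16"),
    true_coefficients = list(bio10 = c(6, -5), bio11 = c(4, -4)),
    true_intercept = -4, n_presence = 120L, mask_fraction = 0,
    spatial_range = 3
  )
  args <- list(...)
  defaults[names(args)] <- args
  do.call(synth_config, defaults)
}

tiny_world <- function(seed = 1, ...) {
  cfg <- tiny_config(seed, ...)
  stack <- gen_climate_stack(cfg)
  truth <- gen_true_suitability(stack, cfg)
  occ <- sample_occurrences(truth, cfg)
  list(cfg = cfg, stack = stack, truth = truth, occ = occ)
}

const_grid <- function(value, n_rows = 4, n_cols = 5,
                       x_origin = 0, y_origin = 0, cell_size = 1) {
  raster_grid(
    matrix(value, n_rows, n_cols),
    x_origin, y_origin, cell_size
  )
}

# Feature table built directly from a numeric matrix (features taken as-is,
# centers 0 / scales 1), mirroring build_feature_table's contract.
manual_features <- function(x, presence, weight = rep(1, nrow(x))) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  out <- tibble::as_tibble(as.data.frame(x))
  out$label <- ifelse(presence, "presence", "background")
  out$weight <- weight
  attr(out, "feature_meta") <- tibble::tibble(
    feature = colnames(x), layer = colnames(x), power = 1,
    center = 0, scale = 1
  )
  class(out) <- c("feature_table", class(out))
  out
}

# Independent penalized-maxent solver: L-BFGS-B on the bound-constrained
# lambda = lambda_plus - lambda_minus reformulation of the L1 problem.
maxent_lbfgs_oracle <- function(fb, mu, beta) {
  m <- ncol(fb)
  obj <- function(par) {
    lam <- par[1:m] - par[(m + 1):(2 * m)]
    eta <- as.vector(fb %*% lam)
    mx <- max(eta)
    -(sum(lam * mu) - (mx + log(sum(exp(eta - mx)))) - beta * sum(par))
  }
  gr <- function(par) {
    lam <- par[1:m] - par[(m + 1):(2 * m)]
    eta <- as.vector(fb %*% lam)
    p <- exp(eta - max(eta))
    p <- p / sum(p)
    g <- mu - as.vector(crossprod(fb, p))
    c(beta - g, beta + g)
  }
  o <- stats::optim(rep(0, 2 * m), obj, gr,
    method = "L-BFGS-B", lower = 0,
    control = list(maxit = 5000, factr = 1e3)
  )
  o$par[1:m] - o$par[(m + 1):(2 * m)]
}

# Brute-force max(sens + spec) scan used as the thresholding oracle.
max_ss_brute <- function(scores, labels) {
  cand <- sort(unique(scores))
  obj <- vapply(cand, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec
  }, numeric(1))
  list(threshold = cand[which.max(obj)], objective = max(obj))
}
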