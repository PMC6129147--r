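#' Pairwise Pearson correlation of climate layers
#'
#' Correlations are computed over all unmasked cells, or over supplied
#' sample points (e.g. presence + background locations) when the screening
#' should reflect the modelled environment rather than the whole map. A
#' zero-variance layer cannot carry a correlation; its row and column are
#' set to 0 with a warning.
#'
#' @param stack A [climate_stack()].
#' @param sample_points Optional data frame with `longitude`, `latitude`.
#' @return A symmetric correlation matrix (class `correlation_matrix`) with
#'   unit diagonal.
#' @export
pearson_matrix <- function(stack, sample_points = NULL) {
  stopifnot(is_climate_stack(stack))
  if (is.null(sample_points)) {
    keep <- !stack_mask(stack)
    if (sum(keep) < 3) stop("need at least 3 unmasked cells", call. = FALSE)
    mat <- vapply(
      stack$layers, function(l) l$values[keep],
      numeric(sum(keep))
    )
  } else {
    ex <- extract_at(stack, sample_points)
    ex <- ex[!ex$out_of_bounds & !ex$masked, names(stack), drop = FALSE]
    if (nrow(ex) < 3) stop("need at least 3 usable sample points", call. = FALSE)
    mat <- as.matrix(ex)
  }
  sds <- apply(mat, 2, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(mat))
  if (any(flat)) {
    warning(
      "zero-variance layer(s): ",
      paste(colnames(mat)[flat], collapse = ", "),
      "; their correlations are set to 0",
      call. = FALSE
    )
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  structure(r, class = c("correlation_matrix", "matrix"))
}

#' Default jackknife trainer: logistic regression
#'
#' The trainer contract: a function taking a feature data frame, a 0/1 label
#' vector and sample weights, returning a scoring function over new feature
#' data frames. Used by [jackknife_importance()]; any function with this
#' shape can replace it.
#'
#' @return A trainer function.
#' @export
trainer_glm <- function() {
  function(x, y, w) {
    df <- as.data.frame(x)
    df$.y <- y
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
      family = stats::binomial(),
      weights = w
    ))
    function(newdata) {
      as.numeric(suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(newdata), type = "response")
      ))
    }
  }
}

#' Jackknife variable importance
#'
#' For each variable, refits the model with that variable alone
#' (`gain_alone`: its training AUC) and with the variable left out
#' (`auc_without`; `loss_without` is the baseline AUC minus it), against the
#' all-variable baseline. High `gain_alone` marks variables informative on
#' their own; a near-zero `loss_without` marks variables whose information
#' is duplicated elsewhere. Trainer failures on a subset are recorded as
#' `NA` entries, not errors.
#'
#' @param features Data frame of predictor columns.
#' @param labels 0/1 vector (presence vs background).
#' @param weights Optional sample weights, default 1.
#' @param trainer A trainer as per [trainer_glm()].
#' @return A tibble with columns `variable`, `gain_alone`, `auc_without`,
#'   `loss_without`, plus attribute `baseline_auc`.
#' @export
jackknife_importance <- function(features, labels, weights = NULL,
                                 trainer = trainer_glm()) {
  features <- tibble::as_tibble(features)
  vars <- names(features)
  if (length(vars) < 1) stop("need at least one variable", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(features))
  train_auc <- function(cols) {
    tryCatch(
      {
        scorer <- trainer(features[, cols, drop = FALSE], labels, weights)
        auc(scorer(features[, cols, drop = FALSE]), labels)
      },
      error = function(e) NA_real_
    )
  }
  baseline <- train_auc(vars)
  rows <- purrr::map_dfr(vars, function(v) {
    alone <- train_auc(v)
    without <- if (length(vars) == 1) alone else train_auc(setdiff(vars, v))
    tibble::tibble(
      variable = v,
      gain_alone = alone,
      auc_without = without,
      loss_without = baseline - without
    )
  })
  attr(rows, "baseline_auc") <- baseline
  rows
}

#' Greedy importance-ranked selection under a correlation cap
#'
#' Implements the "keep the more important member of every correlated pair"
#' rule: variables are ranked by importance (ties broken by name order for
#' determinism) and accepted greedily iff their absolute Pearson correlation
#' with every already-accepted variable is below `r_max`. The absolute value
#' is used deliberately — anti-correlated predictors are equally redundant.
#'
#' @param corr A [pearson_matrix()] (or plain symmetric matrix with
#'   dimnames).
#' @param importance Either the tibble from [jackknife_importance()] (its
#'   `gain_alone` column is used) or a named numeric vector.
#' @param r_max Correlation cap, default 0.7.
#' @return Character vector of selected variable names, in acceptance order.
#' @export
select_uncorrelated <- function(corr, importance, r_max = 0.7) {
  r <- unclass(corr)
  nms <- colnames(r)
  if (is.data.frame(importance)) {
    imp <- stats::setNames(importance$gain_alone, importance$variable)
  } else {
    imp <- importance
  }
  if (!all(nms %in% names(imp))) {
    stop("importance is missing value(s) for: ",
      paste(setdiff(nms, names(imp)), collapse = ", "),
      call. = FALSE
    )
  }
  imp <- imp[nms]
  ord <- order(-imp, nms)
  selected <- character(0)
  for (v in nms[ord]) {
    if (all(abs(r[v, selected]) < r_max)) selected <- c(selected, v)
  }
  selected
}
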