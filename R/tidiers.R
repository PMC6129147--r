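#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an OLS fit
#'
#' @param x An [fit_ols()] result.
#' @param ... Unused.
#' @return One row per term: estimate, std.error, statistic, p.value and
#'   VIF (NA for the intercept).
#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  terms <- names(x$coefficients)
  tibble::tibble(
    term = terms,
    estimate = unname(x$coefficients),
    std.error = unname(x$std_error),
    statistic = unname(x$statistic),
    p.value = unname(x$p_value),
    vif = unname(c(NA_real_, x$vif))[seq_along(terms)]
  )
}

#' @rdname tidy.ols_fit
#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, AIC = x$aic, n = x$n,
    df.residual = x$n - length(x$coefficients)
  )
}

#' Tidy a geographically weighted regression
#'
#' @param x A [fit_gwr()] result.
#' @param ... Unused.
#' @return One row per term summarizing the spatial distribution of its
#'   local coefficients (min, quartiles, max). Per-location values live in
#'   `x$locations`.
#' @method tidy gwr_fit
#' @export
tidy.gwr_fit <- function(x, ...) {
  terms <- c("(Intercept)", x$predictors)
  purrr::map_dfr(terms, function(tm) {
    q <- stats::quantile(x$locations[[tm]], c(0, 0.25, 0.5, 0.75, 1))
    tibble::tibble(
      term = tm, minimum = q[[1]], q1 = q[[2]], median = q[[3]],
      q3 = q[[4]], maximum = q[[5]]
    )
  })
}

#' @rdname tidy.gwr_fit
#' @method glance gwr_fit
#' @export
glance.gwr_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$global_r_squared, AIC = x$aic,
    bandwidth = x$bandwidth, kernel = x$kernel,
    effective.params = x$effective_params, n = x$n
  )
}

#' Tidy a fitted distribution model
#'
#' @param x An `sdm_fit`.
#' @param ... Unused.
#' @return For MaxEnt, one row per feature with its lambda; for the GLM,
#'   the selected terms and coefficients; for the BRT, per-feature summed
#'   split gain (a relative influence measure).
#' @method tidy sdm_fit
#' @export
tidy.sdm_fit <- function(x, ...) {
  switch(x$kind,
    maxent = tibble::tibble(
      term = names(x$params$lambda),
      estimate = unname(x$params$lambda)
    ),
    glm = tibble::tibble(
      term = names(x$params$coefficients),
      estimate = unname(x$params$coefficients)
    ),
    brt = {
      gains <- stats::setNames(numeric(nrow(x$feature_meta)), x$feature_meta$feature)
      for (tree in x$params$trees) {
        for (nd in tree$nodes) {
          if (!is.na(nd$feature) && !is.null(nd$gain)) {
            gains[nd$feature] <- gains[nd$feature] + nd$gain
          }
        }
      }
      tibble::tibble(
        term = names(gains),
        estimate = unname(gains / max(sum(gains), .Machine$double.eps))
      )
    }
  )
}

#' @rdname tidy.sdm_fit
#' @method glance sdm_fit
#' @export
glance.sdm_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, n.features = nrow(x$feature_meta),
    converged = x$converged, iterations = x$iterations, AIC = x$aic
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return `tidy()`: metric/value rows; `glance()`: a one-row tibble.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    metric = c(
      "auc", "tss", "threshold", "sensitivity", "specificity",
      "a", "b", "c", "d"
    ),
    value = c(
      x$auc, x$tss, x$threshold, x$sensitivity, x$specificity,
      x$confusion$a, x$confusion$b, x$confusion$c, x$confusion$d
    )
  )
}

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, tss = x$tss, threshold = x$threshold,
    sensitivity = x$sensitivity, specificity = x$specificity
  )
}

#' Tidy an ensemble result
#'
#' @param x An [run_ensemble()] result.
#' @param ... Unused.
#' @return `tidy()`: the member table (model, replicate, AUC, TSS,
#'   consensus weight); `glance()`: the consensus evaluation plus member
#'   summary.
#' @method tidy ensemble_result
#' @export
tidy.ensemble_result <- function(x, ...) {
  x$members[, c("model", "replicate", "auc", "tss", "threshold", "weight")]
}

#' @rdname tidy.ensemble_result
#' @method glance ensemble_result
#' @export
glance.ensemble_result <- function(x, ...) {
  dplyr::bind_cols(
    glance.eval_report(x$consensus_eval),
    tibble::tibble(
      n.members = nrow(x$members), n.failures = nrow(x$failures),
      mean.member.tss = mean(x$members$tss)
    )
  )
}
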