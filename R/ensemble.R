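#' Confusion table for presence/absence predictions
#'
#' Counts `a` (presences predicted present), `b` (absences predicted
#' present), `c` (presences predicted absent) and `d` (absences predicted
#' absent). Sensitivity is `a/(a+c)`, specificity `d/(b+d)`.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A `confusion_table`.
#' @export
confusion_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_table")
}

#' @rdname confusion_table
#' @param ct A `confusion_table`.
#' @export
sensitivity <- function(ct) ct$a / (ct$a + ct$c)

#' @rdname confusion_table
#' @export
specificity <- function(ct) ct$d / (ct$b + ct$d)

#' True skill statistic
#'
#' `TSS = (ad - bc) / ((a + c)(b + d))`, the prevalence-independent skill of
#' a presence/absence prediction; algebraically identical to
#' `sensitivity + specificity - 1`. Both margins must be non-empty.
#'
#' @param ct A [confusion_table()].
#' @return TSS in \[-1, 1\].
#' @export
#' @examples
#' tss(confusion_table(40, 10, 10, 40)) # 0.6
tss <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  if ((ct$a + ct$c) == 0 || (ct$b + ct$d) == 0) {
    stop("TSS undefined: one class is empty", call. = FALSE)
  }
  (ct$a * ct$d - ct$b * ct$c) / ((ct$a + ct$c) * (ct$b + ct$d))
}

#' Rank-statistic AUC
#'
#' The probability that a random presence outscores a random background
#' point, ties counted one half (Mann-Whitney form via average ranks).
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

eval_report <- function(auc_value, threshold, ct, scores = NULL, labels = NULL) {
  structure(
    list(
      auc = auc_value, tss = tss(ct), threshold = threshold,
      sensitivity = sensitivity(ct), specificity = specificity(ct),
      confusion = ct, scores = scores, labels = labels
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> AUC = %.3f, TSS = %.3f at threshold %.3f (sens %.3f, spec %.3f)\n",
    x$auc, x$tss, x$threshold, x$sensitivity, x$specificity
  ))
  invisible(x)
}

confusion_at <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  confusion_table(
    a = sum(pred & labels == 1), b = sum(pred & labels == 0),
    c = sum(!pred & labels == 1), d = sum(!pred & labels == 0)
  )
}

#' Threshold maximizing sensitivity + specificity
#'
#' Scans the observed scores as candidate thresholds (prediction rule
#' `score >= threshold`) and returns the one maximizing
#' sensitivity + specificity; ties break toward the lowest threshold, i.e.
#' toward sensitivity. Returns the threshold together with the full
#' evaluation at it.
#'
#' @param scores,labels As in [auc()].
#' @return A list: `threshold` and `report` (an `eval_report`).
#' @export
max_ss_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("threshold undefined: both classes must be present", call. = FALSE)
  }
  cand <- sort(unique(scores))
  # at threshold t: sens = P(score >= t | 1), spec = P(score < t | 0)
  ord <- order(scores)
  s_sorted <- scores[ord]
  l_sorted <- labels[ord]
  idx <- findInterval(cand, s_sorted, left.open = TRUE) # strictly below t
  cum1 <- cumsum(l_sorted)
  cum0 <- cumsum(1 - l_sorted)
  below1 <- ifelse(idx == 0, 0, cum1[pmax(idx, 1)])
  below0 <- ifelse(idx == 0, 0, cum0[pmax(idx, 1)])
  sens <- (n1 - below1) / n1
  spec <- below0 / n0
  obj <- sens + spec
  best <- which.max(obj) # which.max takes the first (lowest) on ties
  thr <- cand[best]
  list(
    threshold = thr,
    report = eval_report(auc(scores, labels), thr,
      confusion_at(scores, labels, thr),
      scores = scores, labels = labels
    )
  )
}

evaluate_scores <- function(scores, labels) {
  max_ss_threshold(scores, labels)$report
}

derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

fit_one_model <- function(model, features,
                          maxent_args = list(), glm_args = list(),
                          brt_args = list(), seed = 1L) {
  switch(model,
    maxent = do.call(fit_maxent, c(list(features = features), maxent_args)),
    glm = do.call(fit_glm_stepwise, c(list(features = features), glm_args)),
    brt = do.call(
      fit_brt,
      c(list(features = features, seed = seed), brt_args)
    ),
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Replicated multi-model ensemble
#'
#' The consensus machinery: for each replicate a fresh bias-matched
#' background is drawn (sub-seed from a documented scheme: the master seed
#' seeds an RNG that draws one sub-seed per replicate), presences are
#' weighted by the inverse-density surface, each requested learner is
#' refitted, and its suitability raster predicted. Within each replicate a
#' fraction `member_holdout` of the presence and background rows is held
#' out of fitting and used to score the member (AUC, and TSS at the
#' max(sens + spec) threshold) — scoring members on their own training rows
#' would systematically over-weight the most flexible learner. The
#' consensus raster is the TSS-weighted mean of member rasters, members
#' with TSS <= 0 excluded (an unweighted mean is available via
#' `consensus = "mean"`). Member failures are logged and excluded; only the
#' failure of every member is an error. Fully deterministic given `seed`.
#'
#' @param stack A [climate_stack()].
#' @param occ_train Training occurrence tibble (>= 20 presences).
#' @param models Subset of `c("maxent", "glm", "brt")`.
#' @param replicates Replicates per model (the motivating analysis used 30).
#' @param n_background Background points per replicate.
#' @param seed Master seed.
#' @param quadratic Use quadratic features?
#' @param consensus `"tss_weighted"` or `"mean"`.
#' @param weight_sd Kernel sd for the weight surface (`NULL` = default rule).
#' @param member_holdout Fraction of rows held out per replicate for member
#'   scoring; 0 scores members on their training rows.
#' @param maxent_args,glm_args,brt_args Extra arguments per learner. The
#'   ensemble default for BRT (at most 200 trees at learning rate 0.05,
#'   tree count chosen on a 20 percent held-out deviance curve) is a
#'   compute-scaled version of the slow-learning single-fit default.
#' @return An `ensemble_result`: `members` tibble (fits, rasters,
#'   per-member evaluation, weights), `consensus` raster, `consensus_eval`,
#'   the weight surface and pooled background.
#' @export
run_ensemble <- function(stack, occ_train,
                         models = c("maxent", "glm", "brt"),
                         replicates = 30L, n_background = 1000L, seed = 1L,
                         quadratic = TRUE,
                         consensus = c("tss_weighted", "mean"),
                         weight_sd = NULL,
                         member_holdout = 0.25,
                         maxent_args = list(),
                         glm_args = list(),
                         brt_args = list(n_trees = 200L, learning_rate = 0.05,
                                         valid_fraction = 0.2)) {
  consensus <- match.arg(consensus)
  stopifnot(is_climate_stack(stack))
  occ_train <- as_occurrence_table(occ_train)
  occ_train <- occ_train[occ_train$presence == 1L, , drop = FALSE]
  if (nrow(occ_train) < 20) {
    stop("at least 20 training presences required", call. = FALSE)
  }
  models <- match.arg(models, several.ok = TRUE)
  geometry <- stack_geometry(stack)
  ws <- kernel_weight_surface(occ_train, geometry, sd = weight_sd)
  occ_w <- weight_occurrences(occ_train, ws)
  rep_seeds <- derive_seeds(seed, replicates)
  members <- list()
  failures <- list()
  bg_all <- list()
  stopifnot(member_holdout >= 0, member_holdout < 1)
  for (r in seq_len(replicates)) {
    bg <- sample_background(ws$density, n_background, seed = rep_seeds[r])
    bg_all[[r]] <- bg
    ft <- build_feature_table(stack, occ_w, bg, quadratic = quadratic)
    fp <- ft_parts(ft)
    n_rows_ft <- nrow(ft)
    holdout <- if (member_holdout > 0) {
      withr::with_seed(rep_seeds[r] + 1L, {
        idx_p <- which(fp$presence)
        idx_b <- which(!fp$presence)
        c(
          sample(idx_p, max(1L, floor(member_holdout * length(idx_p)))),
          sample(idx_b, max(2L, floor(member_holdout * length(idx_b))))
        )
      })
    } else {
      integer(0)
    }
    ft_fit <- if (length(holdout) > 0) ft[-holdout, , drop = FALSE] else ft
    attr(ft_fit, "feature_meta") <- attr(ft, "feature_meta")
    class(ft_fit) <- class(ft)
    eval_rows <- if (length(holdout) > 0) holdout else seq_len(n_rows_ft)
    for (m in models) {
      res <- tryCatch(
        {
          fit <- fit_one_model(m, ft_fit,
            maxent_args = maxent_args, glm_args = glm_args,
            brt_args = brt_args, seed = rep_seeds[r]
          )
          scores <- predict_features(fit, fp$x[eval_rows, , drop = FALSE])
          report <- evaluate_scores(scores, as.integer(fp$presence[eval_rows]))
          list(
            fit = fit, raster = predict_sdm(fit, stack), report = report
          )
        },
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- tibble::tibble(
          model = m, replicate = r, message = conditionMessage(res)
        )
      } else {
        members[[length(members) + 1]] <- tibble::tibble(
          model = m, replicate = r,
          auc = res$report$auc, tss = res$report$tss,
          threshold = res$report$threshold,
          fit = list(res$fit), raster = list(res$raster),
          report = list(res$report)
        )
      }
    }
  }
  if (length(members) == 0) {
    stop("all ensemble members failed to fit", call. = FALSE)
  }
  members <- dplyr::bind_rows(members)
  failures <- if (length(failures) > 0) {
    dplyr::bind_rows(failures)
  } else {
    tibble::tibble(model = character(), replicate = integer(), message = character())
  }
  members$weight <- consensus_weights(members$tss, consensus)
  cons <- consensus_raster(members$raster, members$weight, geometry)
  bg_pooled <- dplyr::bind_rows(bg_all)
  cons_eval <- evaluate_on_split(cons, occ_train, bg_pooled)
  structure(
    list(
      members = members, failures = failures, consensus = cons,
      consensus_eval = cons_eval, weight_surface = ws,
      background = bg_pooled, models = models, replicates = replicates,
      consensus_rule = consensus, seed = seed
    ),
    class = "ensemble_result"
  )
}

consensus_weights <- function(tss_values, rule) {
  if (rule == "mean") {
    return(rep(1 / length(tss_values), length(tss_values)))
  }
  w <- pmax(tss_values, 0)
  if (sum(w) <= 0) {
    warning("every member has TSS <= 0; falling back to unweighted mean",
      call. = FALSE
    )
    w <- rep(1, length(tss_values))
  }
  w / sum(w)
}

consensus_raster <- function(rasters, weights, geometry) {
  acc <- matrix(0, geometry$n_rows, geometry$n_cols)
  for (i in seq_along(rasters)) {
    acc <- acc + weights[i] * rasters[[i]]$values
  }
  raster_grid(acc, geometry$x_origin, geometry$y_origin, geometry$cell_size)
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble_result> %d member(s) (%s x %d replicates), consensus %s\n",
    nrow(x$members), paste(x$models, collapse = "/"), x$replicates,
    x$consensus_rule
  ))
  print(x$consensus_eval)
  invisible(x)
}

#' Evaluate a suitability surface on held-out presences
#'
#' Scores are read off the surface at the test presence locations (positive
#' class) and at the supplied background points (negative class — the
#' presence-background convention standing in for true absences), then
#' summarized by AUC and by TSS at the max(sensitivity + specificity)
#' threshold.
#'
#' @param surface A [raster_grid()] of suitability scores.
#' @param test_occ Occurrence tibble of test presences.
#' @param background Data frame of background points.
#' @return An `eval_report`.
#' @export
evaluate_on_split <- function(surface, test_occ, background) {
  stopifnot(is_raster_grid(surface))
  test_occ <- as_occurrence_table(test_occ)
  test_occ <- test_occ[test_occ$presence == 1L, , drop = FALSE]
  if (nrow(test_occ) == 0) stop("test set is empty", call. = FALSE)
  sp <- extract_at(surface, test_occ)$layer
  sb <- extract_at(surface, tibble::as_tibble(background))$layer
  if (all(is.na(sp))) {
    stop("all test presences fall on masked cells", call. = FALSE)
  }
  scores <- c(sp, sb)
  labels <- rep(c(1L, 0L), c(length(sp), length(sb)))
  keep <- !is.na(scores)
  evaluate_scores(scores[keep], labels[keep])
}

#' Classify a suitability surface into unsuitable/marginal/high
#'
#' Cells at or above `threshold` are `high`; cells in
#' `[marginal_fraction * threshold, threshold)` are `marginal`; the rest are
#' `unsuitable`. The marginal band's lower edge has no canonical value, so
#' it is an explicit parameter (default half the threshold).
#'
#' @param surface Suitability [raster_grid()] in \[0, 1\].
#' @param threshold Classification threshold in (0, 1) — typically the
#'   max(sensitivity + specificity) threshold from an `eval_report`.
#' @param marginal_fraction Fraction of `threshold` at which `marginal`
#'   begins; in (0, 1).
#' @return A list: `classes` (a [raster_grid()] coded 0 unsuitable,
#'   1 marginal, 2 high) and `areas` (tibble of class, cells, fraction,
#'   percent over unmasked cells).
#' @export
classify_suitability <- function(surface, threshold, marginal_fraction = 0.5) {
  stopifnot(is_raster_grid(surface))
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must be inside (0, 1)", call. = FALSE)
  }
  if (!(marginal_fraction > 0 && marginal_fraction < 1)) {
    stop("marginal_fraction must be inside (0, 1)", call. = FALSE)
  }
  v <- surface$values
  code <- matrix(NA_real_, surface$n_rows, surface$n_cols)
  code[v < marginal_fraction * threshold] <- 0
  code[v >= marginal_fraction * threshold & v < threshold] <- 1
  code[v >= threshold] <- 2
  n_tot <- sum(!is.na(v))
  areas <- tibble::tibble(
    class = c("unsuitable", "marginal", "high"),
    cells = vapply(0:2, function(k) sum(code == k, na.rm = TRUE), numeric(1))
  )
  areas$fraction <- areas$cells / n_tot
  areas$percent <- 100 * areas$fraction
  structure(
    list(
      classes = raster_grid(
        code, surface$x_origin, surface$y_origin,
        surface$cell_size
      ),
      areas = areas,
      threshold = threshold,
      marginal_fraction = marginal_fraction
    ),
    class = "suitability_classes"
  )
}
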