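#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map a raster grid
#'
#' @param object A [raster_grid()].
#' @param name Fill legend title.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot raster_grid
#' @export
autoplot.raster_grid <- function(object, name = "value", ...) {
  df <- as_tibble.raster_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = name) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Map the ensemble consensus suitability
#'
#' @param object An [run_ensemble()] result.
#' @param ... Passed on.
#' @method autoplot ensemble_result
#' @export
autoplot.ensemble_result <- function(object, ...) {
  autoplot.raster_grid(object$consensus, name = "suitability") +
    ggplot2::labs(title = "Ensemble consensus climatic suitability")
}

#' Map the suitability classes
#'
#' @param object A [classify_suitability()] result.
#' @param ... Unused.
#' @method autoplot suitability_classes
#' @export
autoplot.suitability_classes <- function(object, ...) {
  df <- as_tibble.raster_grid(object$classes)
  df$class <- factor(df$value,
    levels = 0:2,
    labels = c("unsuitable", "marginal", "high")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
    ggplot2::scale_fill_manual(
      values = c(
        unsuitable = "#f0f0f0", marginal = "#fdae61", high = "#d7191c"
      ),
      na.value = "grey85", na.translate = FALSE, name = "suitability"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' ROC curve of an evaluation report
#'
#' Uses the scores and labels stored in the report; the chosen
#' max(sensitivity + specificity) operating point is marked.
#'
#' @param object An `eval_report` carrying scores.
#' @param ... Unused.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$scores)) {
    stop("this eval_report carries no scores to plot", call. = FALSE)
  }
  thr <- sort(unique(object$scores))
  pts <- purrr::map_dfr(thr, function(t) {
    ct <- confusion_at(object$scores, object$labels, t)
    tibble::tibble(fpr = 1 - specificity(ct), tpr = sensitivity(ct))
  })
  pts <- dplyr::bind_rows(tibble::tibble(fpr = 1, tpr = 1), pts,
    tibble::tibble(fpr = 0, tpr = 0))
  op <- confusion_at(object$scores, object$labels, object$threshold)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = 3, colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point",
      x = 1 - specificity(op), y = sensitivity(op),
      colour = "#d7191c", size = 2
    ) +
    ggplot2::labs(
      x = "false positive rate", y = "sensitivity",
      title = sprintf("AUC = %.3f, TSS = %.3f", object$auc, object$tss)
    ) +
    ggplot2::theme_minimal()
}

#' Map the local R-squared of a geographically weighted fit
#'
#' @param object A [fit_gwr()] result.
#' @param ... Unused.
#' @method autoplot gwr_fit
#' @export
autoplot.gwr_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$locations,
    ggplot2::aes(.data$u, .data$v, colour = .data$local_r2)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = expression(local ~ R^2)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}
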