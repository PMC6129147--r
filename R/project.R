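#' Future climate scenario
#'
#' Labels an altered climate stack with its circulation model, concentration
#' pathway and horizon. The stack must share the current stack's geometry;
#' synthetic scenario stacks are typically built with [perturb_stack()].
#'
#' @param name Scenario label, e.g. `"HadGEM2_RCP2.6_2050"`.
#' @param stack A [climate_stack()].
#' @param horizon 2050 or 2070.
#' @param rcp One of 2.6, 4.5, 6.0, 8.5.
#' @return A `scenario`.
#' @export
scenario <- function(name, stack, horizon = 2050, rcp = 2.6) {
  stopifnot(is_climate_stack(stack))
  if (!horizon %in% c(2050, 2070)) {
    stop("horizon must be 2050 or 2070", call. = FALSE)
  }
  if (!rcp %in% c(2.6, 4.5, 6.0, 8.5)) {
    stop("rcp must be one of 2.6, 4.5, 6.0, 8.5", call. = FALSE)
  }
  structure(
    list(name = name, stack = stack, horizon = horizon, rcp = rcp),
    class = "scenario"
  )
}

#' Project a fitted ensemble onto a scenario
#'
#' Re-predicts every fitted ensemble member on the scenario's climate stack
#' — no refitting, no clamping, no randomness — and recombines them with the
#' stored consensus weights, then classifies the projected surface with the
#' same threshold rule as the current-climate map. The scenario stack must
#' carry every layer the members use and match the training geometry.
#'
#' @param ens An [run_ensemble()] result.
#' @param scn A [scenario()].
#' @param threshold Classification threshold (e.g. the current-climate
#'   max(sens + spec) threshold, reused for comparability).
#' @param marginal_fraction See [classify_suitability()].
#' @return A list: `name`, `consensus` raster, `classes`, `areas`.
#' @export
project_scenario <- function(ens, scn, threshold, marginal_fraction = 0.5) {
  stopifnot(inherits(ens, "ensemble_result"), inherits(scn, "scenario"))
  geometry <- stack_geometry(scn$stack)
  if (!same_geometry(geometry, ens$consensus)) {
    stop_geometry_mismatch(sprintf("scenario '%s' and training stacks", scn$name))
  }
  rasters <- vector("list", nrow(ens$members))
  for (i in seq_len(nrow(ens$members))) {
    rasters[[i]] <- tryCatch(
      predict_sdm(ens$members$fit[[i]], scn$stack),
      error = function(e) {
        stop(sprintf(
          "scenario '%s': %s", scn$name, conditionMessage(e)
        ), call. = FALSE)
      }
    )
  }
  cons <- consensus_raster(rasters, ens$members$weight, geometry)
  cls <- classify_suitability(cons, threshold, marginal_fraction)
  list(
    name = scn$name, horizon = scn$horizon, rcp = scn$rcp,
    consensus = cons, classes = cls$classes, areas = cls$areas,
    threshold = threshold
  )
}

#' Class-transition summary between two suitability maps
#'
#' Cross-tabulates the 3-class rasters (unsuitable/marginal/high) cell by
#' cell, and maps the cells entering (`gained`) and leaving (`lost`) the
#' high class. Row sums of the transition matrix equal the current class
#' areas; column sums equal the future ones.
#'
#' @param current,future Class [raster_grid()]s (codes 0/1/2) on one
#'   geometry.
#' @return A list: `transitions` (tibble `from`, `to`, `cells`), `matrix`
#'   (3x3), `gained` and `lost` (0/1 rasters).
#' @export
change_summary <- function(current, future) {
  stopifnot(is_raster_grid(current), is_raster_grid(future))
  if (!same_geometry(current, future)) stop_geometry_mismatch("class rasters")
  labels <- c("unsuitable", "marginal", "high")
  cu <- as.vector(current$values)
  fu <- as.vector(future$values)
  ok <- !is.na(cu) & !is.na(fu)
  tab <- matrix(0, 3, 3, dimnames = list(current = labels, future = labels))
  for (i in 0:2) {
    for (j in 0:2) {
      tab[i + 1, j + 1] <- sum(cu[ok] == i & fu[ok] == j)
    }
  }
  transitions <- tidyr::expand_grid(from = labels, to = labels)
  transitions$cells <- as.vector(t(tab)) # row-major: `to` varies fastest
  mk <- function(cond) {
    v <- rep(NA_real_, length(cu))
    v[ok] <- as.numeric(cond[ok])
    raster_grid(
      matrix(v, current$n_rows, current$n_cols),
      current$x_origin, current$y_origin, current$cell_size
    )
  }
  list(
    transitions = transitions,
    matrix = tab,
    gained = mk(cu != 2 & fu == 2),
    lost = mk(cu == 2 & fu != 2)
  )
}
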