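pipeline_schema <- function() list(
  seed = NULL,
  synth = names(formals(synth_config)),
  inputs = c("layers", "occurrences", "stations"),
  split = c("train_band", "test_bands"),
  selection = c("r_max", "n_background", "quadratic"),
  ensemble = c(
    "models", "replicates", "n_background", "quadratic", "consensus",
    "weight_sd", "maxent", "glm", "brt"
  ),
  threshold = c("marginal_fraction"),
  scenarios = NA, # free-form named list, validated per-entry
  hotspot = c("years", "high_quantile"),
  gwr = c("year", "factors", "vif_max", "kernel")
)

#' Assemble and validate a pipeline configuration
#'
#' The configuration is a nested list mirroring the stages of
#' [run_pipeline()]. Unknown keys anywhere are rejected before any
#' computation, so a typo cannot silently fall back to a default. Exactly
#' one of `synth` (parameters for [synth_config()]) or `inputs` (paths to a
#' named list of raster layers, an occurrences CSV and optionally a
#' stations CSV) must be given.
#'
#' @param seed Master seed; per-stage sub-seeds are drawn from it by the
#'   documented scheme in [run_ensemble()].
#' @param synth List of [synth_config()] arguments, or `NULL`.
#' @param inputs List with `layers` (named character vector of raster
#'   paths), `occurrences` (CSV path), optional `stations`; or `NULL`.
#' @param split List: `train_band`, `test_bands` (see
#'   [split_by_longitude()]). Defaults to the study's calibration bands,
#'   56°30'--59°00' for training and the flanking half-degree bands for
#'   testing.
#' @param selection List: `r_max` correlation cap, `n_background` points
#'   for the screening sample, `quadratic`.
#' @param ensemble List of [run_ensemble()] settings.
#' @param threshold List: `marginal_fraction`.
#' @param scenarios Named list; each entry a list with `offsets` (named
#'   additive layer shifts), `horizon`, `rcp`.
#' @param hotspot List: `years`, `high_quantile`; `NULL` disables the stage.
#' @param gwr List: `year`, `factors`, `vif_max`, `kernel`; `NULL` disables.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            synth = list(),
                            inputs = NULL,
                            split = list(
                              train_band = c(dms(56, 30), dms(59, 0)),
                              test_bands = list(
                                c(dms(56, 0), dms(56, 30)),
                                c(dms(59, 0), dms(59, 30))
                              )
                            ),
                            selection = list(r_max = 0.7),
                            ensemble = list(),
                            threshold = list(marginal_fraction = 0.5),
                            scenarios = list(),
                            hotspot = list(years = NULL, high_quantile = 0.9),
                            gwr = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ",
      paste(names(extra), collapse = ", "),
      call. = FALSE
    )
  }
  cfg <- list(
    seed = as.integer(seed), synth = synth, inputs = inputs, split = split,
    selection = selection, ensemble = ensemble, threshold = threshold,
    scenarios = scenarios, hotspot = hotspot, gwr = gwr
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  schema <- pipeline_schema()
  unknown_top <- setdiff(names(cfg), names(schema))
  if (length(unknown_top) > 0) {
    stop("unknown configuration key(s): ", paste(unknown_top, collapse = ", "),
      call. = FALSE
    )
  }
  for (section in names(cfg)) {
    allowed <- schema[[section]]
    if (is.null(allowed) || (length(allowed) == 1 && is.na(allowed))) next
    val <- cfg[[section]]
    if (is.null(val)) next
    bad <- setdiff(names(val), allowed)
    if (length(bad) > 0) {
      stop(sprintf(
        "unknown configuration key(s) in '%s': %s", section,
        paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  if (!is.null(cfg$inputs) && length(cfg$synth) > 0) {
    stop("give either 'synth' parameters or 'inputs' paths, not both",
      call. = FALSE
    )
  }
  for (nm in names(cfg$scenarios)) {
    bad <- setdiff(names(cfg$scenarios[[nm]]), c("offsets", "horizon", "rcp"))
    if (length(bad) > 0) {
      stop(sprintf(
        "unknown configuration key(s) in scenario '%s': %s", nm,
        paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
  }
  invisible(cfg)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null"
  )
}

eval_report_as_list <- function(report) {
  list(
    auc = report$auc, tss = report$tss, threshold = report$threshold,
    sensitivity = report$sensitivity, specificity = report$specificity,
    confusion = list(
      a = report$confusion$a, b = report$confusion$b,
      c = report$confusion$c, d = report$confusion$d
    )
  )
}

#' Run the full analysis pipeline
#'
#' Drives the stages in the order of the original workflow: synthesize (or
#' load) data, screen predictors, split occurrences geographically, fit the
#' replicated ensemble, threshold and classify the current-climate
#' consensus, project scenarios, and map hotspots and the station-climate
#' regression. Every stage logs its timing and seed to `log.txt`, a
#' resolved copy of the configuration is written for replay, and a stage
#' failure writes `failure.json` (stage + cause) before propagating the
#' error. Outputs are plain files (ASCII rasters, CSV, JSON) so any stage
#' can be re-run or inspected independently.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the key in-memory results (stack, splits,
#'   ensemble, evaluation, classification, scenario and hotspot summaries).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "log.txt")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      write_report_json(
        list(stage = name, error = conditionMessage(e)),
        file.path(outdir, "failure.json")
      )
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
    log_line("stage %-10s ok (%.2fs)", name, proc.time()[["elapsed"]] - t0)
    res
  }
  write_report_json(unclass(config), file.path(outdir, "resolved_config.json"))
  seeds <- derive_seeds(config$seed, 4L)
  log_line(
    "master seed %d; stage seeds synth=%d ensemble=%d eval=%d select=%d",
    config$seed, seeds[1], seeds[2], seeds[3], seeds[4]
  )

  data_dir <- file.path(outdir, "data")
  dir.create(data_dir, showWarnings = FALSE)
  dat <- stage("data", {
    if (is.null(config$inputs)) {
      scfg <- do.call(synth_config, c(list(seed = seeds[1]), config$synth))
      stack <- gen_climate_stack(scfg)
      truth <- gen_true_suitability(stack, scfg)
      occ <- sample_occurrences(truth, scfg)
      stations <- if (!is.null(config$gwr)) gen_station_series(scfg) else NULL
      for (nm in names(stack)) {
        write_raster(stack$layers[[nm]], file.path(data_dir, paste0(nm, ".asc")))
      }
      write_raster(truth, file.path(data_dir, "true_suitability.asc"))
      write_occurrences(occ, file.path(data_dir, "occurrences.csv"))
      if (!is.null(stations)) {
        utils::write.csv(stations$stations,
          file.path(data_dir, "stations.csv"),
          row.names = FALSE
        )
      }
      list(stack = stack, truth = truth, occ = occ, stations = stations)
    } else {
      layers <- lapply(config$inputs$layers, read_raster)
      names(layers) <- names(config$inputs$layers)
      occ <- read_occurrences(config$inputs$occurrences)
      stations <- if (!is.null(config$inputs$stations)) {
        list(stations = read_stations(config$inputs$stations), infestation = NULL)
      }
      list(
        stack = climate_stack(layers), truth = NULL, occ = occ,
        stations = stations
      )
    }
  })

  selected <- stage("select", {
    sel_cfg <- config$selection
    n_bg <- sel_cfg$n_background %||% 500L
    ws <- kernel_weight_surface(dat$occ, stack_geometry(dat$stack))
    bg <- sample_background(ws$density, n_bg, seed = seeds[4])
    pts <- dplyr::bind_rows(
      dat$occ[, c("longitude", "latitude")],
      bg
    )
    corr <- pearson_matrix(dat$stack, sample_points = pts)
    ft <- build_feature_table(dat$stack, dat$occ, bg, quadratic = FALSE)
    fp <- ft_parts(ft)
    imp <- jackknife_importance(
      tibble::as_tibble(as.data.frame(fp$x)),
      as.integer(fp$presence), fp$weight
    )
    keep <- select_uncorrelated(corr, imp, r_max = sel_cfg$r_max %||% 0.7)
    write_report_json(
      list(
        selected = keep,
        importance = as.data.frame(imp),
        baseline_auc = attr(imp, "baseline_auc")
      ),
      file.path(outdir, "selection.json")
    )
    keep
  })
  stack_sel <- climate_stack(dat$stack$layers[selected])

  splits <- stage("split", {
    split_by_longitude(dat$occ, config$split$train_band, config$split$test_bands)
  })
  log_line(
    "split: %d train / %d test of %d records",
    nrow(splits$train), nrow(splits$test), nrow(dat$occ)
  )

  ens_cfg <- config$ensemble
  ens <- stage("ensemble", {
    do.call(run_ensemble, c(
      list(
        stack = stack_sel, occ_train = splits$train,
        seed = seeds[2]
      ),
      ens_cfg[setdiff(names(ens_cfg), c("maxent", "glm", "brt"))],
      list(
        maxent_args = ens_cfg$maxent %||% list(),
        glm_args = ens_cfg$glm %||% list(),
        brt_args = ens_cfg$brt %||%
          list(n_trees = 200L, learning_rate = 0.05, valid_fraction = 0.2)
      )
    ))
  })

  evaluation <- stage("evaluate", {
    eval_bg <- sample_background(
      ens$weight_surface$density,
      nrow(ens$background) %/% max(1, ens$replicates),
      seed = seeds[3]
    )
    report <- if (nrow(splits$test) > 0) {
      evaluate_on_split(ens$consensus, splits$test, eval_bg)
    } else {
      ens$consensus_eval
    }
    write_report_json(
      list(
        consensus = eval_report_as_list(report),
        members = lapply(seq_len(nrow(ens$members)), function(i) {
          list(
            model = ens$members$model[i], replicate = ens$members$replicate[i],
            auc = ens$members$auc[i], tss = ens$members$tss[i],
            weight = ens$members$weight[i]
          )
        })
      ),
      file.path(outdir, "evaluation.json")
    )
    report
  })

  classification <- stage("classify", {
    cls <- classify_suitability(
      ens$consensus, evaluation$threshold,
      config$threshold$marginal_fraction %||% 0.5
    )
    write_raster(ens$consensus, file.path(outdir, "consensus.asc"))
    write_raster(cls$classes, file.path(outdir, "classes.asc"))
    utils::write.csv(cls$areas, file.path(outdir, "class_areas.csv"),
      row.names = FALSE
    )
    cls
  })

  scenario_results <- list()
  if (length(config$scenarios) > 0) {
    scen_dir <- file.path(outdir, "scenarios")
    dir.create(scen_dir, showWarnings = FALSE)
    scenario_results <- stage("project", {
      purrr::imap(config$scenarios, function(sc, nm) {
        offsets <- unlist(sc$offsets)
        dropped <- setdiff(names(offsets), selected)
        if (length(dropped) > 0) {
          log_line(
            "scenario %s: offset layer(s) %s not among selected predictors; ignored",
            nm, paste(dropped, collapse = ", ")
          )
          offsets <- offsets[names(offsets) %in% selected]
        }
        scn <- scenario(
          nm, perturb_stack(stack_sel, offsets),
          horizon = sc$horizon %||% 2050, rcp = sc$rcp %||% 2.6
        )
        proj <- project_scenario(
          ens, scn, evaluation$threshold,
          config$threshold$marginal_fraction %||% 0.5
        )
        chg <- change_summary(classification$classes, proj$classes)
        write_raster(proj$consensus, file.path(scen_dir, paste0(nm, "_consensus.asc")))
        write_raster(proj$classes, file.path(scen_dir, paste0(nm, "_classes.asc")))
        utils::write.csv(proj$areas, file.path(scen_dir, paste0(nm, "_areas.csv")),
          row.names = FALSE
        )
        utils::write.csv(chg$transitions,
          file.path(scen_dir, paste0(nm, "_transitions.csv")),
          row.names = FALSE
        )
        list(projection = proj, change = chg)
      })
    })
  }

  hotspots <- list()
  hs_years <- config$hotspot$years
  if (is.null(hs_years) && !is.null(dat$occ)) {
    hs_years <- sort(unique(dat$occ$year))
  }
  if (!is.null(config$hotspot) && length(hs_years) > 1) {
    hs_dir <- file.path(outdir, "hotspot")
    dir.create(hs_dir, showWarnings = FALSE)
    hotspots <- stage("hotspot", {
      geometry <- stack_geometry(dat$stack)
      surfaces <- lapply(hs_years, function(y) {
        s <- hotspot_surface(dat$occ, y, geometry)
        write_raster(s, file.path(hs_dir, paste0("hotspot_", y, ".asc")))
        s
      })
      names(surfaces) <- hs_years
      changes <- list()
      for (i in seq_len(length(hs_years) - 1)) {
        ch <- hotspot_change(
          surfaces[[i]], surfaces[[i + 1]],
          config$hotspot$high_quantile %||% 0.9
        )
        tag <- paste0(hs_years[i], "_", hs_years[i + 1])
        write_raster(ch$map, file.path(hs_dir, paste0("change_", tag, ".asc")))
        changes[[tag]] <- ch
      }
      list(surfaces = surfaces, changes = changes)
    })
  }

  gwr_results <- NULL
  if (!is.null(config$gwr) && !is.null(dat$stations)) {
    gwr_results <- stage("gwr", {
      inf <- dat$stations$infestation
      factors <- config$gwr$factors %||% c("dew_point", "min_temp", "wind_speed")
      if (is.null(inf)) {
        yr <- config$gwr$year %||% min(dat$occ$year)
        inf <- climate_to_locations(
          dat$stations$stations,
          dat$occ[dat$occ$year == yr, c("longitude", "latitude")], yr,
          factors = factors
        )
        inf$presence <- dat$occ$presence[dat$occ$year == yr]
      }
      screen <- screen_vif(inf, "presence", factors,
        vif_max = config$gwr$vif_max %||% 7.5
      )
      ols <- fit_ols(inf, "presence", screen$predictors)
      gwr <- fit_gwr(inf, "presence", screen$predictors,
        kernel = config$gwr$kernel %||% "gaussian"
      )
      summary_tab <- tibble::tibble(
        factors = paste(screen$predictors, collapse = "+"),
        ols_r2 = ols$r_squared, ols_aic = ols$aic,
        gwr_r2 = gwr$global_r_squared, gwr_aic = gwr$aic,
        bandwidth = gwr$bandwidth
      )
      utils::write.csv(summary_tab, file.path(outdir, "gwr_summary.csv"),
        row.names = FALSE
      )
      utils::write.csv(gwr$locations, file.path(outdir, "gwr_local.csv"),
        row.names = FALSE
      )
      list(screen = screen, ols = ols, gwr = gwr, summary = summary_tab)
    })
  }

  log_line("pipeline complete")
  invisible(list(
    stack = dat$stack, truth = dat$truth, occurrences = dat$occ,
    selected = selected, splits = splits, ensemble = ens,
    evaluation = evaluation, classification = classification,
    scenarios = scenario_results, hotspots = hotspots, gwr = gwr_results,
    outdir = outdir
  ))
}
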