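test_that("tss follows the quotient definition and its algebraic identity", {
  expect_equal(tss(confusion_table(10, 0, 0, 10)), 1)
  expect_equal(tss(confusion_table(25, 25, 25, 25)), 0)
  expect_equal(tss(confusion_table(40, 10, 10, 40)), 0.6)
  expect_error(tss(confusion_table(0, 5, 0, 5)), "empty")
  # identity with sensitivity + specificity - 1 over random tables
  withr::with_seed(51, {
    for (i in 1:50) {
      ct <- confusion_table(
        sample(0:60, 1), sample(0:60, 1), sample(0:60, 1), sample(0:60, 1)
      )
      if ((ct$a + ct$c) == 0 || (ct$b + ct$d) == 0) next
      expect_equal(tss(ct), sensitivity(ct) + specificity(ct) - 1,
        tolerance = 1e-12
      )
    }
  })
})

test_that("auc counts pairwise wins with half-ties and ignores monotone maps", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc(c(0.9, 0.6, 0.7, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
  withr::with_seed(52, {
    s <- rnorm(60)
    l <- rbinom(60, 1, 0.5)
    base <- auc(s, l)
    expect_equal(auc(exp(s), l), base, tolerance = 1e-12)
    expect_equal(auc(stats::qlogis(plogis(s)), l), base, tolerance = 1e-10)
  })
})

test_that("random labels give chance-level auc", {
  withr::with_seed(53, {
    aucs <- sapply(1:20, function(i) {
      auc(runif(1000), sample(rep(0:1, 500)))
    })
    expect_true(all(abs(aucs - 0.5) < 0.05))
  })
})

test_that("max(sens+spec) threshold matches a brute-force scan", {
  # perfectly separated scores reach sensitivity = specificity = 1
  ms <- max_ss_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(ms$report$sensitivity, 1)
  expect_equal(ms$report$specificity, 1)

  # all-identical scores: that score is returned, objective 1
  ms1 <- max_ss_threshold(rep(0.4, 8), rep(c(0, 1), 4))
  expect_equal(ms1$threshold, 0.4)
  expect_equal(ms1$report$sensitivity + ms1$report$specificity, 1)

  withr::with_seed(54, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      scores <- round(runif(n), sample(1:3, 1)) # force ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      got <- max_ss_threshold(scores, labels)
      want <- max_ss_brute(scores, labels)
      expect_equal(
        got$report$sensitivity + got$report$specificity,
        want$objective,
        tolerance = 1e-12
      )
      expect_equal(got$threshold, want$threshold)
    }
  })
})

test_that("consensus weighting follows tss with non-positive members excluded", {
  g <- function(v) const_grid(v, 2, 2)
  geometry <- g(0)
  w <- dubasclim:::consensus_weights(c(0.5, 0.5), "tss_weighted")
  cons <- dubasclim:::consensus_raster(list(g(0.2), g(0.6)), w, geometry)
  expect_true(all(abs(cons$values - 0.4) < 1e-12))

  w2 <- dubasclim:::consensus_weights(c(0.6, -0.1, 0.2), "tss_weighted")
  expect_equal(w2[2], 0)
  expect_equal(sum(w2), 1)
  expect_equal(w2[1] / w2[3], 3, tolerance = 1e-12)

  expect_warning(
    w3 <- dubasclim:::consensus_weights(c(-0.2, -0.1), "tss_weighted"),
    "TSS <= 0"
  )
  expect_equal(w3, c(0.5, 0.5))
  expect_equal(dubasclim:::consensus_weights(c(0.9, 0.1), "mean"), c(0.5, 0.5))
})

test_that("a small ensemble is deterministic and bounded by its members", {
  w <- tiny_world(8)
  ens1 <- suppressWarnings(run_ensemble(w$stack, w$occ,
    models = c("glm", "maxent"), replicates = 2, n_background = 150,
    seed = 99, brt_args = list()
  ))
  ens2 <- suppressWarnings(run_ensemble(w$stack, w$occ,
    models = c("glm", "maxent"), replicates = 2, n_background = 150,
    seed = 99, brt_args = list()
  ))
  expect_identical(ens1$consensus$values, ens2$consensus$values)
  expect_identical(tidy(ens1), tidy(ens2))

  lo <- Reduce(pmin, lapply(ens1$members$raster, function(r) r$values))
  hi <- Reduce(pmax, lapply(ens1$members$raster, function(r) r$values))
  expect_true(all(ens1$consensus$values >= lo - 1e-12, na.rm = TRUE))
  expect_true(all(ens1$consensus$values <= hi + 1e-12, na.rm = TRUE))
  expect_true(all(ens1$members$weight >= 0))
  expect_equal(sum(ens1$members$weight), 1, tolerance = 1e-12)
  expect_s3_class(glance(ens1), "tbl_df")

  expect_error(
    run_ensemble(w$stack, w$occ[1:5, ], models = "glm"),
    "at least 20"
  )
})

test_that("evaluation on a split extracts scores and summarizes them", {
  surf <- const_grid(0.05, 10, 10, x_origin = 56, y_origin = 22, cell_size = 0.1)
  surf$values[, 6:10] <- 0.95
  test_occ <- tibble::tibble(
    longitude = runif(20, 56.55, 56.95), latitude = runif(20, 22.05, 22.95),
    year = 2015L, presence = 1L
  )
  bg <- tibble::tibble(
    longitude = runif(200, 56.05, 56.45), latitude = runif(200, 22.05, 22.95)
  )
  ev <- evaluate_on_split(surf, test_occ, bg)
  expect_equal(ev$auc, 1)
  expect_equal(ev$tss, 1)
  expect_error(evaluate_on_split(surf, test_occ[0, ], bg), "empty")
})

test_that("suitability classification obeys the interval rule and a cell oracle", {
  surf <- const_grid(1, 6, 6)
  cls <- classify_suitability(surf, threshold = 0.4)
  expect_equal(cls$areas$percent[cls$areas$class == "high"], 100)

  vals <- matrix(c(0.3, 0.1, 0.45, 0.2, 0.39, 0.8), 2, 3)
  s2 <- raster_grid(vals, 0, 0, 1)
  cls2 <- classify_suitability(s2, threshold = 0.4, marginal_fraction = 0.5)
  expect_equal(cls2$classes$values[1, 1], 1) # 0.3 -> marginal
  expect_equal(cls2$classes$values[2, 1], 0) # 0.1 -> unsuitable
  expect_equal(cls2$classes$values[2, 3], 2) # 0.8 -> high

  withr::with_seed(55, {
    r <- raster_grid(matrix(runif(200), 10, 20), 0, 0, 1)
    r$values[sample(200, 15)] <- NA
    cls3 <- classify_suitability(r, 0.6, 0.5)
    oracle <- c(
      unsuitable = sum(r$values < 0.3, na.rm = TRUE),
      marginal = sum(r$values >= 0.3 & r$values < 0.6, na.rm = TRUE),
      high = sum(r$values >= 0.6, na.rm = TRUE)
    )
    expect_equal(
      stats::setNames(cls3$areas$cells, cls3$areas$class), oracle
    )
    expect_equal(sum(cls3$areas$cells), sum(!is.na(r$values)))
  })
  expect_error(classify_suitability(surf, 1.2), "threshold")
  expect_error(classify_suitability(surf, 0.5, 0), "marginal_fraction")
})
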