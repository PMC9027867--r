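separable_grid <- function(seed = 81, nr = 30, nc = 30) {
  g <- make_landscape(nr, nc, seed = seed, n_villages = 10)
  g
}

test_that("background sampling respects the buffer and determinism", {
  g <- separable_grid()
  pres <- g$cell_id[g$row == 15 & g$col == 15]
  occ <- sample_background(g, pres, buffer_km = 2.5, n_background = 2000,
                           seed = 1)
  # 2.5 km on a 250 m grid is a 10-cell Euclidean radius
  idx <- match(occ$background_cells, g$cell_id)
  d_cells <- sqrt((g$row[idx] - 15)^2 + (g$col[idx] - 15)^2)
  expect_true(all(d_cells <= 10 + 1e-9))
  expect_false(pres %in% occ$background_cells)
  # radius 10 around one cell holds at most the cells within the disc
  expect_lte(length(occ$background_cells), sum(
    sqrt(outer((1:30 - 15)^2, (1:30 - 15)^2, "+")) <= 10) - 1)
  occ2 <- sample_background(g, pres, 2.5, 2000, seed = 1)
  expect_identical(occ$background_cells, occ2$background_cells)

  expect_error(occurrence_set(pres, pres), "disjoint")
  g1 <- g[1, , drop = FALSE]
  expect_error(sample_background(g1, g1$cell_id, 2.5, 10, 1), "no eligible")
})

test_that("a perfectly separating covariate takes all the contribution", {
  g <- separable_grid()
  # presences in the warmest cells: bio01 separates them from background,
  # while the second covariate is independent noise
  set.seed(20)
  g$noise <- rnorm(nrow(g))
  ord <- order(-g$bio01)
  pres <- g$cell_id[ord[1:25]]
  bg <- g$cell_id[ord[200:500]]
  occ <- occurrence_set(pres, bg)
  fit <- fit_maxent(g, occ, c("bio01", "noise"), reg_multiplier = 1, seed = 2)
  expect_gt(fit$percent_contribution[["bio01"]], 95)
  expect_equal(sum(fit$percent_contribution), 100, tolerance = 0.01)
  expect_equal(sum(fit$permutation_importance), 100, tolerance = 0.01)
  expect_true(all(fit$percent_contribution >= 0))
  expect_true(all(fit$permutation_importance >= 0))
})

test_that("raw ROR is a normalized density; cloglog stays in [0, 1]", {
  g <- separable_grid(83)
  set.seed(84)
  pres <- sample(g$cell_id[g$pel_abu > 0], 20)
  occ <- sample_background(g, pres, 2.5, 400, seed = 5)
  fit <- fit_maxent(g, occ, c("bio01", "pel_abu", "pel_neigh"), seed = 6)
  norm_cells <- g[match(c(occ$presence_cells, occ$background_cells),
                        g$cell_id), ]
  raw <- predict_ror(fit, norm_cells, output = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  cl <- predict_ror(fit, g, output = "cloglog")
  expect_true(all(cl >= 0 & cl <= 1))
})

test_that("uniform covariates give the flat max-entropy solution", {
  g <- separable_grid(85)
  g$bio01 <- 5 # constant everywhere
  pres <- g$cell_id[1:10]
  bg <- g$cell_id[101:300]
  fit <- fit_maxent(g, occurrence_set(pres, bg), "bio01", seed = 7)
  raw <- predict_ror(fit, g[match(c(pres, bg), g$cell_id), ], "raw")
  expect_equal(raw, rep(1 / 210, 210), tolerance = 1e-9)
})

test_that("response curves reflect the fitted weights", {
  g <- separable_grid(86)
  ord <- order(-g$bio01)
  pres <- g$cell_id[ord[1:30]]
  bg <- g$cell_id[ord[101:600]]
  fit <- fit_maxent(g, occurrence_set(pres, bg), c("bio01", "bio04"),
                    features = "linear", seed = 8)
  rc <- response_curve(fit, "bio01", n_points = 50)
  expect_equal(nrow(rc), 50)
  w <- fit$feature_weights[["bio01"]]
  if (w > 0) expect_true(all(diff(rc$ror) >= -1e-12))
  # a zero-weight covariate yields a flat curve
  fit0 <- fit
  fit0$feature_weights[] <- 0
  rc0 <- response_curve(fit0, "bio04", n_points = 20)
  expect_equal(diff(range(rc0$ror)), 0, tolerance = 1e-12)
  expect_error(response_curve(fit, "wood"), "unknown covariate")
})

test_that("pure-noise covariates get low permutation importance", {
  g <- separable_grid(87)
  set.seed(88)
  g$noise <- rnorm(nrow(g))
  pres <- g$cell_id[order(-g$pel_abu)[1:30]]
  occ <- sample_background(g, pres, 2.5, 500, seed = 9)
  fit <- fit_maxent(g, occ, c("pel_abu", "noise"), seed = 10)
  expect_lt(fit$permutation_importance[["noise"]], 5)
})

test_that("dropping the L1 penalty never decreases training gain", {
  g <- separable_grid(89)
  set.seed(90)
  pres <- sample(g$cell_id[g$pel_abu > 0], 25)
  occ <- sample_background(g, pres, 2.5, 300, seed = 11)
  f_pen <- fit_maxent(g, occ, c("bio01", "pel_abu"), reg_multiplier = 1,
                      seed = 12)
  f_free <- fit_maxent(g, occ, c("bio01", "pel_abu"), reg_multiplier = 0,
                       seed = 12)
  expect_gte(f_free$training_gain, f_pen$training_gain - 1e-6)
})

test_that("TSS is 1 on separable data and near 0 without signal", {
  g <- separable_grid(91)
  # separable: presences are exactly the host-plant cells, and pel_abu
  # cleanly distinguishes them from plant-free background
  pres <- g$cell_id[g$pel_abu > 0]
  occ <- sample_background(g, pres, 5, 400, seed = 13)
  # linear features keep the score monotone in pel_abu, so the presence /
  # background separation is preserved exactly
  ev <- evaluate_tss(g, occ, c("pel_abu"), splits = 8, seed = 14,
                     features = "linear")
  expect_true(all(ev$tss_replicas == 1))
  expect_equal(ev$tss_full, 1)
  expect_true(all(ev$tss_replicas >= -1 & ev$tss_replicas <= 1))

  # no signal: presences drawn independently of the covariate
  set.seed(15)
  g$flat <- rnorm(nrow(g))
  pres2 <- sample(g$cell_id, 40)
  occ2 <- sample_background(g, pres2, 10, 400, seed = 16)
  ev2 <- evaluate_tss(g, occ2, "flat", splits = 10, seed = 17)
  expect_lt(abs(mean(ev2$tss_replicas)), 0.25)
})
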