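scenario_fixture <- function() {
  g <- tiny_landscape(seed = 92)
  d <- stratified_design(g, n_per_band = 20, visits = 3, seed = 93)
  cd <- standardize(simulate_counts(g, d, table_truth(), seed = 94))
  fit <- suppressWarnings(fit_nmix(cd, best_spec()))
  list(grid = g, fit = fit)
}

test_that("the null scenario is an exact identity with 100% no change", {
  fx <- scenario_fixture()
  base <- project_map(fx$fit, fx$grid)
  null <- project_map(fx$fit, fx$grid, scenario_spec(0, 1, label = "null"))
  expect_equal(base$E_N, null$E_N, tolerance = 1e-12)
  ch <- categorize_changes(base, null)
  expect_equal(ch$summary$percent[ch$summary$category == "no_change"], 100)
  expect_true(all(ch$cells$category == "no_change"))
})

test_that("change classification follows half-up integer rounding", {
  b <- data.frame(cell_id = c("a", "b"), E_N = c(1.2, 3.6))
  s <- data.frame(cell_id = c("a", "b"), E_N = c(1.4, 2.1))
  ch <- categorize_changes(b, s)
  # rounded baseline (1, 4) vs scenario (1, 2): one no_change, one decrease
  expect_equal(sort(ch$cells$category), c("decrease", "no_change"))
  expect_equal(ch$summary$percent[ch$summary$category == "no_change"], 50)
  expect_equal(ch$summary$percent[ch$summary$category == "decrease"], 50)

  # a 0 -> 3 cell among ten is a new infestation and an increase
  b2 <- data.frame(cell_id = sprintf("c%d", 1:10), E_N = c(0.2, rep(2, 9)))
  s2 <- data.frame(cell_id = sprintf("c%d", 1:10), E_N = c(2.9, rep(2, 9)))
  ch2 <- categorize_changes(b2, s2)
  sm <- ch2$summary
  expect_equal(sm$percent[sm$category == "new_infestation"], 10)
  expect_equal(sm$percent[sm$category == "increase"], 10)
  expect_true(all(ch2$cells$new_infestation ==
                    (ch2$cells$rounded_baseline == 0 &
                       ch2$cells$rounded_scenario >= 1)))

  # increases + decreases + no_change partition the cells
  expect_equal(sum(sm$n[sm$category %in% c("increase", "decrease", "no_change")]),
               ch2$n_cells)
  expect_error(categorize_changes(b, s2), "different cell sets")
})

test_that("round_half_up rounds .5 upward, unlike banker's rounding", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.49, -0.4)), c(1, 2, 2, 0))
})

test_that("warming raises expected abundance where the interaction allows", {
  fx <- scenario_fixture()
  fit <- fx$fit
  base <- project_map(fit, fx$grid)
  warm <- project_map(fit, fx$grid, scenario_spec(1.5, 1, label = "warm"))
  # cells whose scaled pel_abu exceeds -beta_bio01 / beta_int have a
  # positive temperature slope, so +1.5 degC strictly increases E[N]
  b_bio <- fit$beta_hat[["bio01"]]
  b_int <- fit$beta_hat[["bio01:pel_abu"]]
  sc <- fit$scaling$pel_abu
  pel_scaled <- (fx$grid$pel_abu[match(base$cell_id, fx$grid$cell_id)] -
                   sc["mean"]) / sc["sd"]
  pos <- b_bio + b_int * pel_scaled > 0
  expect_gt(sum(pos), 0)
  expect_true(all(warm$E_N[pos] > base$E_N[pos]))
})

test_that("scenario covariate transforms act on the raw scale", {
  fx <- scenario_fixture()
  g <- fx$grid
  sc <- scenario_spec(delta_bio01 = 2, pel_multiplier = 0.5)
  g2 <- cacyreus:::apply_scenario(as.data.frame(g), sc)
  expect_equal(g2$bio01, g$bio01 + 2)
  expect_equal(g2$pel_abu, g$pel_abu * 0.5)
  # neighbour counts recomputed from the halved pots over the topology
  expect_equal(g2$pel_neigh, compute_pel_neigh(g2))
  # multiplier zero flags a host-free landscape but still projects
  m0 <- project_map(fx$fit, g, scenario_spec(0, 0))
  expect_true(all(m0$host_free))
})

test_that("group summaries partition the global counts", {
  fx <- scenario_fixture()
  base <- project_map(fx$fit, fx$grid)
  warm <- project_map(fx$fit, fx$grid, scenario_spec(1.5, 0.5))
  ch <- categorize_changes(base, warm)
  by_muni <- summarize_by_group(ch, fx$grid)
  expect_equal(sum(by_muni$n_cells), ch$n_cells)
  expect_equal(sum(by_muni$n_decrease),
               sum(ch$cells$category == "decrease"))
  expect_equal(sum(by_muni$n_increase),
               sum(ch$cells$category == "increase"))
  expect_true(all(diff(by_muni$mean_elevation) >= 0))
  expect_error(summarize_by_group(ch, fx$grid, "region"), "not in grid")
})

test_that("elevation profiles bin means correctly", {
  fx <- scenario_fixture()
  base <- project_map(fx$fit, fx$grid)
  # a constant map has a flat profile
  flat <- base
  flat$E_N <- 2
  pr <- elevation_profile(list(flat = flat), fx$grid, n_bins = 5)
  expect_true(all(abs(pr$mean_E[pr$n_cells > 0] - 2) < 1e-12))
  expect_equal(sum(pr$n_cells), nrow(base))
  # a map strictly decreasing in elevation has non-increasing binned means
  dec <- base
  elev <- fx$grid$elevation[match(dec$cell_id, fx$grid$cell_id)]
  dec$E_N <- 1000 - elev
  pr2 <- elevation_profile(list(dec = dec), fx$grid, n_bins = 4)
  m <- pr2$mean_E[pr2$n_cells > 0]
  expect_true(all(diff(m) <= 0))
  expect_error(elevation_profile(list(base), fx$grid, n_bins = 1), "at least 2")
})
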