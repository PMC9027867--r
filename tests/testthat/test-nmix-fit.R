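test_that("AICc follows its closed form, limit and monotonicity", {
  # -2 loglik + 2K = 10 at K = 3, n = 75: AICc = 10 + 24/71
  ll <- -(10 - 2 * 3) / 2
  expect_equal(aicc(ll, 3, 75), 10 + 24 / 71, tolerance = 1e-12)
  # AICc -> AIC as n grows
  expect_lt(abs(aicc(-100, 4, 1e9) - (200 + 8)), 1e-6)
  # extra parameters cost more at equal likelihood
  expect_gt(aicc(-50, 3, 20), aicc(-50, 2, 20))
  expect_error(aicc(-50, 19, 20), "n > K")
})

test_that("perfect-detection single-visit Poisson MLE is the sample mean", {
  set.seed(31)
  y <- matrix(rpois(200, 6.3), 200, 1)
  cd <- count_data(y, data.frame(idx = seq_len(200)))
  fit <- fit_nmix(cd, nmix_spec(character(), character(), "P"), fix_p = 1)
  expect_equal(exp(fit$beta_hat[["(Intercept)"]]), mean(y), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the abundance linear predictor at the origin is the intercept", {
  # treating the published coefficient vector as fixed parameters, the
  # log-abundance at all-zero scaled covariates equals the intercept 3.095
  truth <- table_truth()
  zero <- data.frame(bio01 = 0, pel_abu = 0, pel_neigh = 0)
  eta <- cacyreus:::lin_pred(truth$beta, zero)
  expect_equal(unname(eta), 3.095, tolerance = 1e-12)
})

test_that("fitting recovers simulated parameters on one moderate dataset", {
  set.seed(41)
  M <- 250; J <- 3
  covs <- data.frame(x = rnorm(M))
  lam <- exp(1.5 + 0.6 * covs$x)
  p <- 0.45
  N <- rpois(M, lam)
  y <- matrix(rbinom(M * J, rep(N, J), p), M, J)
  cd <- count_data_std(y, covs, data.frame(v = rnorm(M)))
  fit <- fit_nmix(cd, nmix_spec("x", character(), "P"))
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta_hat[["(Intercept)"]] - 1.5), 4 * se[1])
  expect_lt(abs(fit$beta_hat[["x"]] - 0.6), 4 * se[2])
  # aicc slot consistent with the closed form
  expect_equal(fit$aicc, aicc(fit$loglik, fit$n_params, M), tolerance = 1e-12)
  # vcov symmetric positive definite for a converged fit
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-6)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > 0))
})

test_that("missing visits are skipped without breaking the fit", {
  set.seed(51)
  M <- 120; J <- 4
  N <- rpois(M, 5)
  y <- matrix(rbinom(M * J, rep(N, J), 0.5), M, J)
  y[sample(M * J, 60)] <- NA_integer_
  keep <- rowSums(!is.na(y)) > 0
  cd <- count_data_std(y[keep, ], data.frame(x = rnorm(sum(keep))),
                       data.frame(v = rnorm(sum(keep))))
  fit <- fit_nmix(cd, nmix_spec(character(), character(), "P"))
  expect_true(fit$converged)
  expect_lt(abs(exp(fit$beta_hat[[1]]) * plogis(fit$alpha_hat[[1]]) -
                  mean(y, na.rm = TRUE)), 0.5)
})

test_that("predictions follow the mixture algebra and monotonicity", {
  truth <- table_truth()
  set.seed(61)
  g <- tiny_landscape()
  d <- stratified_design(g, n_per_band = 20, visits = 3, seed = 62)
  cd <- standardize(simulate_counts(g, d, truth, seed = 63))
  fit <- suppressWarnings(fit_nmix(cd, best_spec()))

  zero <- data.frame(bio01 = 0, pel_abu = 0, pel_neigh = 0, pel_ava = 0)
  pr <- predict_abundance(fit, zero, rescale = FALSE)
  expect_equal(pr$E_N,
               (1 - fit$psi_hat) * exp(fit$beta_hat[["(Intercept)"]]),
               tolerance = 1e-10)

  # psi = 1 forces expected abundance to zero
  fit1 <- fit
  fit1$psi_hat <- 1
  expect_equal(predict_abundance(fit1, zero, rescale = FALSE)$E_N, 0)

  # E[N] increases in bio01 where beta_bio01 + beta_int * pel_abu_scaled > 0
  pel_hi <- 1.5
  slope <- fit$beta_hat[["bio01"]] + fit$beta_hat[["bio01:pel_abu"]] * pel_hi
  grid_b <- data.frame(bio01 = seq(-2, 2, length.out = 9), pel_abu = pel_hi,
                       pel_neigh = 0, pel_ava = 0)
  en <- predict_abundance(fit, grid_b, rescale = FALSE)$E_N
  if (slope > 0) expect_true(all(diff(en) > 0)) else expect_true(all(diff(en) < 0))

  expect_error(predict_abundance(fit, zero[c("bio01", "pel_ava")]),
               "missing covariate")
})

test_that("model selection tables rank, weight and resolve ties correctly", {
  mkfit <- function(ll, K, lab) {
    structure(list(spec = nmix_spec(character(), character(), "P"),
                   loglik = ll, n_params = as.integer(K), M = 75,
                   aicc = aicc(ll, K, 75), converged = TRUE), class = "nmix_fit")
  }
  # reproduce a published-style pair of AICc values exactly
  f1 <- mkfit(-(979.54 - 2 * 7 - 2 * 7 * 8 / 67) / 2, 7, "interaction")
  f2 <- mkfit(-(1099.16 - 2 * 6 - 2 * 6 * 7 / 68) / 2, 6, "additive")
  tab <- selection_table(list(f2, f1))
  expect_equal(tab$AICc, c(979.54, 1099.16), tolerance = 1e-9)
  expect_equal(tab$dAICc[1], 0)
  expect_equal(tab$dAICc[2], 1099.16 - 979.54, tolerance = 1e-9)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(tab$cum_weight) >= 0))
  expect_false(attr(tab, "tie"))
  # near-equal AICc flags a tie
  f3 <- mkfit(f1$loglik - 0.5, 7, "close")
  tab2 <- selection_table(list(f1, f3))
  expect_true(attr(tab2, "tie"))
})
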