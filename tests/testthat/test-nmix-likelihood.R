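test_that("likelihood matches brute-force enumeration on random instances", {
  # 12 fuzz cases x 3 mixtures here; the full 100-case sweep runs in the
  # acceptance suite
  for (seed in 1:12) {
    inst <- random_instance(seed)
    lam <- exp(inst$beta[1] + inst$beta[2] * inst$x)
    p <- plogis(inst$alpha[1] + inst$alpha[2] * inst$v)
    cd <- count_data_std(inst$y, data.frame(x = inst$x),
                         data.frame(v = inst$v))
    for (mix in c("P", "NB", "ZIP")) {
      spec <- nmix_spec("x", "v", mix)
      pars <- c(inst$beta, inst$alpha,
                if (mix %in% c("NB", "ZIP")) inst$extra)
      ours <- nmix_negloglik(pars, cd, spec, K_trunc = 1000)
      oracle <- brute_nll(inst$y, lam, p, mix,
                          psi = plogis(inst$extra),
                          theta = exp(inst$extra))
      expect_lt(abs(ours - oracle), 1e-10)
    }
  }
})

test_that("worked single-site example agrees with the enumeration oracle", {
  # one site, y = (1, 0), lambda = 2, p = 0.4, Poisson
  y <- matrix(c(1L, 0L), 1, 2)
  cd <- count_data_std(y, data.frame(x = 0), data.frame(v = 0))
  ours <- nmix_negloglik(c(log(2), 0, qlogis(0.4), 0), cd,
                         nmix_spec("x", "v", "P"), K_trunc = 100)
  oracle <- brute_nll(y, 2, 0.4, "P", Nmax = 1000)
  expect_lt(abs(ours - oracle), 1e-10)
})

test_that("an empty site under a vanishing rate carries no information", {
  y <- matrix(0L, 1, 3)
  cd <- count_data_std(y, data.frame(x = 0), data.frame(v = 0))
  nll <- nmix_negloglik(c(-30, 0, 0, 0), cd, nmix_spec("x", "v", "P"),
                        K_trunc = 100)
  expect_lt(abs(nll), 1e-8)
})

test_that("ZIP with psi = 0 collapses to the Poisson likelihood", {
  inst <- random_instance(99)
  cd <- count_data_std(inst$y, data.frame(x = inst$x), data.frame(v = inst$v))
  pars <- c(inst$beta, inst$alpha)
  nll_p <- nmix_negloglik(pars, cd, nmix_spec("x", "v", "P"), 500)
  nll_z <- nmix_negloglik(c(pars, qlogis(1e-300)), cd,
                          nmix_spec("x", "v", "ZIP"), 500)
  expect_equal(nll_z, nll_p, tolerance = 1e-12)
})

test_that("truncation is monotone: more latent classes never lose mass", {
  inst <- random_instance(17)
  cd <- count_data_std(inst$y, data.frame(x = inst$x), data.frame(v = inst$v))
  pars <- c(inst$beta, inst$alpha)
  spec <- nmix_spec("x", "v", "P")
  prev <- nmix_negloglik(pars, cd, spec, max(inst$y, na.rm = TRUE) + 2)
  for (K in c(20, 50, 200, 800)) {
    cur <- nmix_negloglik(pars, cd, spec, K)
    expect_lte(cur, prev + 1e-10)
    prev <- cur
  }
})

test_that("likelihood guards reject invalid inputs", {
  y <- matrix(5L, 1, 1)
  cd <- count_data_std(y, data.frame(x = 0), data.frame(v = 0))
  spec <- nmix_spec("x", "v", "P")
  expect_error(nmix_negloglik(c(0, 0, 0, 0), cd, spec, K_trunc = 3),
               "largest observed count")
  expect_error(nmix_negloglik(c(NA, 0, 0, 0), cd, spec, 100), "non-finite")
  expect_error(nmix_negloglik(c(0, 0, 0), cd, spec, 100), "expected 4")
})

test_that("NB with large dispersion reproduces the Poisson likelihood", {
  set.seed(21)
  M <- 40; J <- 3
  lam <- 4; p <- 0.5
  N <- rpois(M, lam)
  y <- matrix(rbinom(M * J, rep(N, J), p), M, J)
  cd <- count_data_std(y, data.frame(x = rnorm(M)), data.frame(v = rnorm(M)))
  pars_p <- c(log(lam), 0.1, qlogis(p), -0.1)
  nll_p <- nmix_negloglik(pars_p, cd, nmix_spec("x", "v", "P"), 500)
  nll_nb <- nmix_negloglik(c(pars_p, log(1e7)), cd,
                           nmix_spec("x", "v", "NB"), 500)
  expect_lt(abs(nll_nb - nll_p), 1e-4)
})
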