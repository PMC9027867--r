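# Shared fixtures and independent oracles.

# small landscape + design used across tests
tiny_landscape <- function(seed = 2, nr = 30, nc = 30, villages = 14) {
  make_landscape(nr, nc, seed = seed, n_villages = villages)
}

tiny_design <- function(grid, n = 5, visits = 3, seed = 3) {
  stratified_design(grid, n_per_band = n, visits = visits, seed = seed)
}

# count_data over externally supplied covariates already on the
# standardized scale (identity scaling record), for clean generative checks
count_data_std <- function(y, site_covs, obs_covs = NULL) {
  cd <- count_data(y, site_covs, obs_covs)
  vars <- c(names(site_covs), if (!is.null(obs_covs)) names(obs_covs))
  vars <- vars[vapply(c(site_covs, obs_covs)[vars], is.numeric, TRUE)]
  cd$scaling <- lapply(stats::setNames(nm = vars),
                       function(v) c(mean = 0, sd = 1))
  cd
}

# brute-force N-mixture negative log-likelihood: direct probability
# products enumerated over the latent abundance, independent of the
# package's log-space recurrence implementation
brute_nll <- function(y, lambda, p, mixture, psi = 0, theta = 1, Nmax = 1000) {
  Ns <- 0:Nmax
  ll <- 0
  for (i in seq_len(nrow(y))) {
    g <- switch(mixture,
      P = dpois(Ns, lambda[i]),
      NB = dnbinom(Ns, size = theta, mu = lambda[i]),
      ZIP = (Ns == 0) * psi + (1 - psi) * dpois(Ns, lambda[i])
    )
    pr <- g
    for (j in seq_len(ncol(y))) {
      if (!is.na(y[i, j])) pr <- pr * dbinom(y[i, j], Ns, p[i])
    }
    ll <- ll + log(sum(pr))
  }
  -ll
}

# random small N-mixture instance for likelihood fuzzing
random_instance <- function(seed) {
  set.seed(seed)
  M <- sample(1:5, 1)
  J <- sample(1:4, 1)
  y <- matrix(as.integer(sample(0:8, M * J, replace = TRUE)), M, J)
  if (M * J > 1 && runif(1) < 0.3) y[sample(M * J, 1)] <- NA_integer_
  if (any(rowSums(!is.na(y)) == 0)) y[cbind(1:M, 1)] <- 0L
  x <- rnorm(M)
  v <- rnorm(M)
  list(
    y = y, x = x, v = v,
    beta = rnorm(2, 0, 0.7), alpha = rnorm(2, 0, 0.7),
    extra = rnorm(1, 0, 0.8)
  )
}

# reference truth used in recovery-style tests
table_truth <- function(psi = 0.5) default_truth(psi = psi)

truth_vector <- function() {
  c(3.095, 0.446, 0.320, -0.343, 0.592, -2.632, 0.399, qlogis(0.5))
}

best_spec <- function(mixture = "ZIP") {
  nmix_spec(c("bio01", "pel_abu", "bio01:pel_abu", "pel_neigh"),
            "pel_ava", mixture)
}
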