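#' Generative parameters for the egg-count process
#'
#' Bundles the "truth" used by [simulate_counts()]: abundance coefficients
#' on the log scale, detection coefficients on the logit scale, and the
#' abundance mixture (Poisson `"P"`, negative binomial `"NB"` with
#' dispersion `theta`, or zero-inflated Poisson `"ZIP"` with zero-mass
#' `psi`). Coefficients are applied to covariates standardized over the
#' surveyed cells, matching how the models are fitted.
#'
#' @param beta named numeric: `(Intercept)` plus covariate names present in
#'   the landscape grid; interactions as `"a:b"`.
#' @param alpha named numeric: `(Intercept)` plus detection covariate names
#'   (typically `pel_ava`).
#' @param mixture one of `"P"`, `"NB"`, `"ZIP"`.
#' @param psi zero-inflation probability in `[0, 1]` (ZIP only).
#' @param theta negative-binomial dispersion > 0 (NB only).
#' @return a `truth_params` list.
#' @export
truth_params <- function(beta, alpha, mixture = c("P", "NB", "ZIP"),
                         psi = 0, theta = NULL) {
  mixture <- match.arg(mixture)
  stopifnot(is.numeric(beta), !is.null(names(beta)), "(Intercept)" %in% names(beta))
  stopifnot(is.numeric(alpha), !is.null(names(alpha)), "(Intercept)" %in% names(alpha))
  if (mixture == "ZIP") stopifnot(psi >= 0, psi <= 1)
  if (mixture == "NB") stopifnot(!is.null(theta), theta > 0)
  structure(list(beta = beta, alpha = alpha, mixture = mixture,
                 psi = if (mixture == "ZIP") psi else NULL,
                 theta = if (mixture == "NB") theta else NULL),
            class = "truth_params")
}

#' Default truth: the best-fitting egg-abundance model
#'
#' The package's reference parameter vector for fixtures and simulation
#' studies: a ZIP N-mixture with abundance driven by annual mean
#' temperature, host-plant pots, their interaction and neighbouring
#' host-plant abundance, and detection driven by host-plant availability.
#'
#' @param psi zero-inflation probability (default 0.5).
#' @return a [truth_params()] object.
#' @export
default_truth <- function(psi = 0.5) {
  truth_params(
    beta = c("(Intercept)" = 3.095, bio01 = 0.446, pel_abu = 0.320,
             pel_neigh = -0.343, "bio01:pel_abu" = 0.592),
    alpha = c("(Intercept)" = -2.632, pel_ava = 0.399),
    mixture = "ZIP", psi = psi
  )
}

# covariate names referenced by a coefficient vector (interactions split)
coef_covariates <- function(coefs) {
  nm <- setdiff(names(coefs), "(Intercept)")
  unique(unlist(strsplit(nm, ":", fixed = TRUE)))
}

# linear predictor of named coefficients over a standardized covariate table
lin_pred <- function(coefs, zcovs) {
  f <- if (length(names(coefs)) > 1)
    reformulate(setdiff(names(coefs), "(Intercept)")) else ~1
  X <- model.matrix(f, data = zcovs)
  # model.matrix writes interactions in its own order; match by sorted parts
  canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                              function(p) paste(sort(p), collapse = ":"), "")
  idx <- match(canon(names(coefs)), canon(colnames(X)))
  if (anyNA(idx)) stop_cfg("coefficient term(s) not found in covariates: ",
                           paste(names(coefs)[is.na(idx)], collapse = ", "))
  drop(X[, idx, drop = FALSE] %*% coefs)
}

# standardize selected columns; sd-0 columns pass through centred only
scale_block <- function(df, vars, scaling = NULL) {
  z <- df
  rec <- scaling %||% lapply(df[vars], function(x) {
    s <- sd(x)
    c(mean = mean(x), sd = if (is.na(s) || s == 0) 1 else s)
  })
  for (v in vars) z[[v]] <- (df[[v]] - rec[[v]]["mean"]) / rec[[v]]["sd"]
  attr(z, "scaling") <- rec
  z
}

#' Simulate repeated egg counts under the N-mixture process
#'
#' For every surveyed site the latent egg abundance `N_i` is drawn from the
#' truth's mixture with `log(lambda_i) = x_i' beta`, and each of the `J`
#' visits records `y_ij ~ Binomial(N_i, p_i)` with
#' `logit(p_i) = alpha0 + alpha_pel_ava * pel_ava_i`. The detection
#' covariate `pel_ava` (pots accessible during a survey) is site-level and
#' constant across visits, generated as a binomial thinning of `pel_abu`.
#' Covariates are standardized internally over the surveyed cells before
#' `beta`/`alpha` are applied.
#'
#' @param grid a `landscape_grid`.
#' @param design a `survey_design` over `grid`.
#' @param truth a [truth_params()] object.
#' @param seed integer seed.
#' @param pel_ava_rate thinning probability for accessible pots (default 0.8).
#' @param lambda_cap carrying-capacity ceiling on the per-cell expected egg
#'   abundance (default 5000): a loglinear rate extrapolated into an
#'   extreme covariate corner cannot exceed what the cell's plants can
#'   physically hold.
#' @return a [count_data()] object (raw covariates plus the y matrix).
#' @export
#' @examples
#' g <- make_landscape(30, 30, seed = 2)
#' d <- stratified_design(g, n_per_band = 5, seed = 3)
#' cd <- simulate_counts(g, d, default_truth(), seed = 4)
#' mean(cd$y == 0)
simulate_counts <- function(grid, design, truth, seed = 1, pel_ava_rate = 0.8,
                            lambda_cap = 5000) {
  stopifnot(inherits(truth, "truth_params"))
  idx <- match(design$sites$cell_id, grid$cell_id)
  if (anyNA(idx)) stop_cfg("design refers to cells absent from the grid")
  M <- length(idx)
  J <- design$visits_per_cell

  with_seed(seed, {
    covs <- as.data.frame(grid)[idx, , drop = FALSE]
    covs$pel_ava <- rbinom(M, covs$pel_abu, pel_ava_rate)
    rownames(covs) <- NULL

    abu_vars <- coef_covariates(truth$beta)
    det_vars <- coef_covariates(truth$alpha)
    miss <- setdiff(c(abu_vars, det_vars), names(covs))
    if (length(miss)) stop_cfg("truth covariate(s) not in grid: ",
                               paste(miss, collapse = ", "))
    z <- scale_block(covs, unique(c(abu_vars, det_vars)))

    eta <- lin_pred(truth$beta, z)
    v <- lin_pred(truth$alpha, z)
    if (any(!is.finite(eta)))
      stop_cfg("non-finite abundance linear predictor")
    if (anyNA(v))
      stop_cfg("non-finite detection linear predictor")
    lambda <- pmin(exp(pmin(eta, 35)), lambda_cap)
    p <- plogis(v)

    N <- switch(truth$mixture,
      P = rpois(M, lambda),
      NB = rnbinom(M, size = truth$theta, mu = lambda),
      ZIP = ifelse(runif(M) < truth$psi, 0L, rpois(M, lambda))
    )
    y <- matrix(rbinom(M * J, rep(N, J), rep(p, J)), M, J)
    colnames(y) <- sprintf("visit_%d", seq_len(J))

    count_data(
      y = y,
      site_covs = covs[setdiff(names(covs), "pel_ava")],
      obs_covs = covs["pel_ava"],
      band = design$sites$band
    )
  })
}

#' Simulate spatially biased opportunistic presence points
#'
#' Emulates citizen-science style presence-only records: cells are sampled
#' with probability proportional to their occupancy probability
#' `1 - exp(-E[N])` (a sighting requires the species to be there, but a
#' heavily infested cell does not yield proportionally more records) times
#' an accessibility bias factor that is higher in urban and low-elevation
#' cells (people record where people are). Cells without host plants never
#' yield records: the species is a strict Pelargonium obligate and every
#' census occurrence fell in a pot-holding cell. `bias_strength = 0`
#' removes the bias, leaving sampling driven by occupancy alone.
#'
#' @param grid a `landscape_grid`.
#' @param truth a [truth_params()] object (drives expected abundance;
#'   covariates standardized over the whole grid).
#' @param n_points number of presence points (>= 1).
#' @param bias_strength exponent on the accessibility factor (default 1).
#' @param seed integer seed.
#' @return data.frame `point_id, cell_id, x, y` (metric coordinates of a
#'   random location inside the cell).
#' @export
simulate_opportunistic <- function(grid, truth, n_points = 138,
                                   bias_strength = 1, seed = 1) {
  stopifnot(n_points >= 1)
  abu_vars <- coef_covariates(truth$beta)
  z <- scale_block(as.data.frame(grid), abu_vars)
  eta <- lin_pred(truth$beta, z)
  lambda <- exp(pmin(eta, 35))
  en <- if (identical(truth$mixture, "ZIP")) (1 - truth$psi) * lambda else lambda
  if (all(en <= 0) || !any(is.finite(en) & en > 0))
    stop_cfg("expected abundance is zero everywhere; cannot place presences")

  access <- exp(-(grid$elevation - min(grid$elevation)) / 500) *
    (1 + 2 * as.numeric(grid$urban))
  # host-plant obligate: records can only come from cells with Pelargonium
  w <- -expm1(-en) * access^bias_strength * (grid$pel_abu > 0)
  res <- attr(grid, "resolution_m") %||% 250

  with_seed(seed, {
    cells <- sample.int(nrow(grid), n_points, replace = TRUE, prob = w)
    xy <- grid_xy(grid)[cells, , drop = FALSE]
    data.frame(
      point_id = sprintf("p%04d", seq_len(n_points)),
      cell_id = grid$cell_id[cells],
      x = xy[, "x"] + runif(n_points, -res / 2, res / 2),
      y = xy[, "y"] + runif(n_points, -res / 2, res / 2),
      stringsAsFactors = FALSE
    )
  })
}
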