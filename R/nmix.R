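#' N-mixture model specification
#'
#' @param abundance character vector of abundance covariate names;
#'   interactions as `"a:b"` (main effects need not be included, but every
#'   referenced name must exist in the data). Empty = intercept-only.
#' @param detection character vector of detection covariate names
#'   (typically `"pel_ava"`); empty = intercept-only.
#' @param mixture abundance mixture: `"P"`, `"NB"` or `"ZIP"`.
#' @return an `nmix_spec` list.
#' @export
#' @examples
#' nmix_spec(c("bio01", "pel_abu", "bio01:pel_abu", "pel_neigh"), "pel_ava", "ZIP")
nmix_spec <- function(abundance = character(), detection = character(),
                      mixture = c("P", "NB", "ZIP")) {
  mixture <- match.arg(mixture)
  structure(list(abundance = abundance, detection = detection,
                 mixture = mixture), class = "nmix_spec")
}

spec_label <- function(spec) {
  lab <- function(x) if (length(x) == 0) "." else paste(x, collapse = " + ")
  sprintf("p(%s) lambda(%s) [%s]", lab(spec$detection), lab(spec$abundance),
          spec$mixture)
}

mixture_code <- function(mixture) match(mixture, c("P", "NB", "ZIP")) - 1L

design_matrix <- function(terms, covs) {
  if (length(terms) == 0)
    return(matrix(1, nrow(covs), 1, dimnames = list(NULL, "(Intercept)")))
  parts <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(parts, names(covs))
  if (length(miss))
    stop_cfg("model term covariate(s) not in data: ", paste(miss, collapse = ", "))
  model.matrix(reformulate(terms), data = covs)
}

build_matrices <- function(data, spec) {
  need_scale <- length(spec$abundance) > 0 || length(spec$detection) > 0
  if (need_scale && is.null(data$scaling))
    stop_cfg("data must be standardized (see standardize()) before fitting")
  covs <- all_covs(data)
  list(X = design_matrix(spec$abundance, covs),
       V = design_matrix(spec$detection, covs))
}

n_extra <- function(mixture) if (mixture %in% c("NB", "ZIP")) 1L else 0L

param_names <- function(spec, X, V, fix_p = NULL) {
  c(paste0("lam:", colnames(X)),
    if (is.null(fix_p)) paste0("det:", colnames(V)),
    switch(spec$mixture, ZIP = "psi(logit)", NB = "theta(log)", NULL))
}

#' Marginalized N-mixture negative log-likelihood
#'
#' Evaluates `-sum_i log sum_{N >= max_j y_ij}^{K_trunc} g(N; lambda_i)
#' prod_j Binom(y_ij; N, p_i)` in log space, where `g` is Poisson, negative
#' binomial (mean `lambda`, dispersion `theta`) or zero-inflated Poisson
#' (`psi` extra mass at 0), `log lambda_i = x_i' beta` and
#' `logit p_i = v_i' alpha`. Missing visits skip their binomial factor.
#'
#' @param params packed parameter vector: abundance coefficients, then
#'   detection coefficients (omitted when `fix_p` is given), then
#'   `qlogis(psi)` (ZIP) or `log(theta)` (NB).
#' @param data a standardized [count_data()] object.
#' @param spec an [nmix_spec()].
#' @param K_trunc upper truncation bound for the latent abundance sum; must
#'   be at least the largest observed count.
#' @param fix_p optional fixed detection probability (e.g. 1 for a
#'   perfect-detection reduction); replaces the detection submodel.
#' @return the negative log-likelihood (a single number).
#' @export
nmix_negloglik <- function(params, data, spec, K_trunc, fix_p = NULL) {
  stopifnot(inherits(data, "count_data"), inherits(spec, "nmix_spec"))
  if (any(!is.finite(params))) stop_cfg("non-finite parameter vector")
  maxy <- max(data$y, na.rm = TRUE)
  if (K_trunc < maxy)
    stop_cfg("K_trunc (", K_trunc, ") is below the largest observed count (", maxy, ")")
  mats <- build_matrices(data, spec)
  nb <- ncol(mats$X)
  na <- if (is.null(fix_p)) ncol(mats$V) else 0L
  ne <- n_extra(spec$mixture)
  if (length(params) != nb + na + ne)
    stop_cfg("expected ", nb + na + ne, " parameters, got ", length(params))
  beta <- params[seq_len(nb)]
  alpha <- if (na > 0) params[nb + seq_len(na)] else numeric()
  extra <- if (ne > 0) params[nb + na + 1] else 0
  nmix_nll_cpp(data$y, mats$X, mats$V, beta, alpha, extra,
               mixture_code(spec$mixture), as.integer(K_trunc),
               if (is.null(fix_p)) -1 else fix_p)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2K + 2K(K+1) / (n - K - 1)`. The sample size `n` is
#' the number of sites (the independent replicate in an N-mixture design).
#'
#' @param loglik maximized log-likelihood.
#' @param K number of free parameters.
#' @param n sample size (must exceed `K + 1`).
#' @return the AICc value.
#' @export
#' @examples
#' aicc(-2, 3, 75)
aicc <- function(loglik, K, n) {
  if (n - K - 1 <= 0)
    stop_cfg("AICc undefined: need n > K + 1 (n = ", n, ", K = ", K, ")")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Fit a binomial N-mixture model by maximum likelihood
#'
#' Maximizes the marginalized likelihood (see [nmix_negloglik()]) by BFGS
#' quasi-Newton iteration from documented starts (abundance intercept at
#' `log(mean site maximum + 0.5)`, all other coefficients 0). The latent-N
#' truncation bound is chosen adaptively: the smallest bound at which
#' adding 50 more latent classes changes the log-likelihood by less than
#' 1e-8 (capped at `K_max`); the optimum is re-polished whenever the bound
#' grows beyond the one used during optimization. The variance matrix is
#' the inverse observed information at the optimum.
#'
#' @param data a standardized [count_data()] object.
#' @param spec an [nmix_spec()].
#' @param K_trunc optional fixed truncation bound (default: adaptive).
#' @param K_max cap on the truncation bound (default 25000).
#' @param start optional start vector (packed as in [nmix_negloglik()]);
#'   used for warm starts in bootstrap refits.
#' @param fix_p optional fixed detection probability.
#' @param hessian compute the observed information and `vcov` (default
#'   TRUE). Bootstrap refits that only need fitted values set this to
#'   FALSE; `converged` then reflects optimizer success alone.
#' @param control passed to [stats::optim()] (defaults:
#'   `maxit = 500, reltol = 1e-10`).
#' @return an `nmix_fit`: coefficients, `vcov`, `loglik`, `aicc`,
#'   `converged`, `K_trunc`, the scaling record and bookkeeping needed by
#'   [predict_abundance()].
#' @export
fit_nmix <- function(data, spec, K_trunc = NULL, K_max = 25000L,
                     start = NULL, fix_p = NULL, hessian = TRUE,
                     control = list()) {
  stopifnot(inherits(data, "count_data"), inherits(spec, "nmix_spec"))
  mats <- build_matrices(data, spec)
  X <- mats$X; V <- mats$V
  nb <- ncol(X)
  na <- if (is.null(fix_p)) ncol(V) else 0L
  ne <- n_extra(spec$mixture)
  maxy <- max(data$y, na.rm = TRUE)
  ctl <- modifyList(list(maxit = 500, reltol = 1e-10), control)

  K_fit <- as.integer(K_trunc %||% min(K_max, max(300L, 5L * maxy + 200L)))
  if (K_fit < maxy) stop_cfg("K_trunc below the largest observed count")
  mc <- mixture_code(spec$mixture)
  obj_at <- function(par, K) {
    beta <- par[seq_len(nb)]
    alpha <- if (na > 0) par[nb + seq_len(na)] else numeric()
    extra <- if (ne > 0) par[nb + na + 1] else 0
    nmix_nll_cpp(data$y, X, V, beta, alpha, extra, mc, as.integer(K),
                 if (is.null(fix_p)) -1 else fix_p)
  }
  # value + analytic gradient, cached so optim's fn/gr pair costs one eval
  make_obj <- function(K) {
    cache <- new.env(parent = emptyenv())
    eval_at <- function(par) {
      key <- paste(par, collapse = ",")
      if (!identical(cache$key, key)) {
        beta <- par[seq_len(nb)]
        alpha <- if (na > 0) par[nb + seq_len(na)] else numeric()
        extra <- if (ne > 0) par[nb + na + 1] else 0
        cache$val <- nmix_nll_grad_cpp(
          data$y, X, V, beta, alpha, extra, mc, as.integer(K),
          if (is.null(fix_p)) -1 else fix_p)
        cache$key <- key
      }
      cache$val
    }
    list(fn = function(par) eval_at(par)$value,
         gr = function(par) eval_at(par)$gradient)
  }

  if (is.null(start)) {
    start <- c(log(mean(apply(data$y, 1, max, na.rm = TRUE)) + 0.5),
               rep(0, nb - 1), rep(0, na), rep(0, ne))
  }
  stopifnot(length(start) == nb + na + ne)

  ob <- make_obj(K_fit)
  opt <- optim(start, ob$fn, ob$gr, method = "BFGS", control = ctl)
  if (opt$convergence != 0)
    opt <- optim(opt$par, ob$fn, ob$gr, method = "BFGS", control = ctl)

  # adaptive truncation: smallest K where 50 more classes change loglik < 1e-8
  adaptive_K <- function(par, K0) {
    K <- max(K0, maxy)
    f <- obj_at(par, K)
    repeat {
      f2 <- obj_at(par, K + 50L)
      if (abs(f2 - f) < 1e-8 || K >= K_max) return(K)
      K <- min(K_max, K * 2L)
      f <- obj_at(par, K)
    }
  }
  K_ad <- adaptive_K(opt$par, min(K_fit, maxy + 50L))
  if (K_ad > K_fit) { # optimization ran truncated; re-polish at the wider bound
    K_fit <- K_ad
    ob <- make_obj(K_fit)
    opt <- optim(opt$par, ob$fn, ob$gr, method = "BFGS", control = ctl)
    K_ad <- adaptive_K(opt$par, K_fit)
  }

  vcov <- NULL
  if (hessian) {
    hess <- tryCatch(optimHess(opt$par, ob$fn, ob$gr, control = ctl),
                     error = function(e) NULL)
    if (!is.null(hess)) {
      vcov <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(vcov) && any(!is.finite(vcov))) vcov <- NULL
    }
  }
  pn <- param_names(spec, X, V, fix_p)
  par <- setNames(opt$par, pn)
  converged <- opt$convergence == 0 &&
    (!hessian || (!is.null(vcov) && all(diag(vcov) > 0)))
  if (!converged)
    warning("fit_nmix: model did not converge cleanly (",
            spec_label(spec), ")", call. = FALSE)
  if (!is.null(vcov)) dimnames(vcov) <- list(pn, pn)

  loglik <- -opt$value
  K_par <- length(par)
  structure(list(
    spec = spec,
    coef = par,
    beta_hat = setNames(par[seq_len(nb)], colnames(X)),
    alpha_hat = if (na > 0) setNames(par[nb + seq_len(na)], colnames(V)) else NULL,
    extra_hat = if (ne > 0) par[[nb + na + 1]] else NULL,
    psi_hat = if (spec$mixture == "ZIP") plogis(par[[nb + na + 1]]) else NULL,
    theta_hat = if (spec$mixture == "NB") exp(par[[nb + na + 1]]) else NULL,
    vcov = if (is.null(vcov)) NULL else vcov,
    c_hat_inflation = 1,
    loglik = loglik, n_params = K_par, M = nrow(data$y),
    aicc = aicc(loglik, K_par, nrow(data$y)),
    converged = converged, K_trunc = K_ad,
    scaling = data$scaling, fix_p = fix_p,
    idx = list(beta = seq_len(nb),
               alpha = if (na > 0) nb + seq_len(na) else integer(),
               extra = if (ne > 0) nb + na + 1L else integer())
  ), class = "nmix_fit")
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat("N-mixture fit:", spec_label(x$spec), "\n")
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, length(x$coef))
  print(round(data.frame(estimate = x$coef, se = se), 4))
  cat(sprintf("logLik %.3f | K %d | M %d | AICc %.2f | K_trunc %d | %s\n",
              x$loglik, x$n_params, x$M, x$aicc, x$K_trunc,
              if (x$converged) "converged" else "NOT converged"))
  if (x$c_hat_inflation > 1)
    cat(sprintf("(vcov inflated by c-hat = %.3f)\n", x$c_hat_inflation))
  invisible(x)
}

#' Predict expected abundance and detection probability
#'
#' Expected abundance is `lambda` for P/NB and `(1 - psi) lambda` for ZIP;
#' detection probability comes from the detection submodel. Standard errors
#' are delta-method, using the fit's (possibly c-hat-inflated) variance
#' matrix. New covariates are given on the raw scale and re-standardized
#' with the fit's scaling record.
#'
#' @param fit an `nmix_fit`.
#' @param newdata data.frame of raw covariates covering the fit's terms.
#' @param rescale apply the stored scaling record (default TRUE; set FALSE
#'   if `newdata` is already standardized).
#' @param detection also evaluate the detection submodel (default TRUE);
#'   set FALSE when `newdata` lacks the detection covariates, e.g. for
#'   landscape-wide abundance projections.
#' @return data.frame `E_N, se_E_N, p, se_p` (one row per `newdata` row;
#'   `p` columns are `NA` when `detection = FALSE`).
#' @export
predict_abundance <- function(fit, newdata, rescale = TRUE, detection = TRUE) {
  stopifnot(inherits(fit, "nmix_fit"))
  covs <- as.data.frame(newdata)
  need <- unique(unlist(strsplit(
    c(fit$spec$abundance, if (detection) fit$spec$detection),
    ":", fixed = TRUE)))
  miss <- setdiff(need, names(covs))
  if (length(miss))
    stop_cfg("newdata is missing covariate(s): ", paste(miss, collapse = ", "))
  if (rescale && !is.null(fit$scaling)) {
    for (v in intersect(names(fit$scaling), names(covs))) {
      rec <- fit$scaling[[v]]
      covs[[v]] <- (covs[[v]] - rec["mean"]) / rec["sd"]
    }
  }
  X <- design_matrix(fit$spec$abundance, covs)
  lam <- drop(exp(X %*% fit$beta_hat))
  psi <- fit$psi_hat %||% 0
  EN <- (1 - psi) * lam

  if (!detection) {
    p <- rep(NA_real_, nrow(covs)); Vm <- NULL
  } else if (!is.null(fit$fix_p)) {
    p <- rep(fit$fix_p, nrow(covs)); Vm <- NULL
  } else {
    Vm <- design_matrix(fit$spec$detection, covs)
    p <- drop(plogis(Vm %*% fit$alpha_hat))
  }

  se_EN <- se_p <- rep(NA_real_, nrow(covs))
  if (!is.null(fit$vcov)) {
    np <- length(fit$coef)
    G <- matrix(0, nrow(covs), np)
    G[, fit$idx$beta] <- EN * X
    if (fit$spec$mixture == "ZIP" && length(fit$idx$extra))
      G[, fit$idx$extra] <- -lam * psi * (1 - psi)
    se_EN <- sqrt(pmax(0, rowSums((G %*% fit$vcov) * G)))
    if (!is.null(Vm)) {
      Gp <- matrix(0, nrow(covs), np)
      Gp[, fit$idx$alpha] <- (p * (1 - p)) * Vm
      se_p <- sqrt(pmax(0, rowSums((Gp %*% fit$vcov) * Gp)))
    }
  }
  data.frame(E_N = EN, se_E_N = se_EN, p = p, se_p = se_p)
}
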