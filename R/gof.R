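#' @keywords internal
#' @noRd
fitted_rates <- function(fit, data) {
  mats <- build_matrices(data, fit$spec)
  lam <- drop(exp(mats$X %*% fit$beta_hat))
  p <- if (!is.null(fit$fix_p)) rep(fit$fix_p, nrow(data$y))
       else drop(plogis(mats$V %*% fit$alpha_hat))
  psi <- fit$psi_hat %||% 0
  list(lambda = lam, p = p, psi = psi, EN = (1 - psi) * lam)
}

# site-visit chi-square with epsilon-guarded denominator
chisq_stat <- function(y, fitted, eps = 1e-6) {
  ok <- !is.na(y)
  sum((y[ok] - fitted[ok])^2 / (fitted[ok] + eps))
}

#' Parametric-bootstrap goodness-of-fit test and overdispersion factor
#'
#' Computes the site-visit chi-square statistic
#' `sum (y_ij - yhat_ij)^2 / (yhat_ij + 1e-6)` with
#' `yhat_ij = E[N_i] * p_i`, then simulates `replicates` datasets from the
#' fitted model over the same design, refits the same specification to each
#' (warm-started at the parent estimates) and recomputes the statistic. The
#' bootstrap p-value is the proportion of replicate statistics at least as
#' large as the observed one, and the overdispersion factor is
#' `c_hat = chisq_obs / mean(chisq_boot)`. Replicates whose refit does not
#' converge are excluded from the null distribution; more than 20% of
#' exclusions flags the result unreliable.
#'
#' @param fit a converged `nmix_fit`.
#' @param data the standardized [count_data()] the model was fitted to.
#' @param replicates bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return a `gof_result`: `chisq_obs`, `chisq_boot`, `p_value`, `c_hat`,
#'   `replicates`, `seed`, `n_nonconverged`, `unreliable` (TRUE when more
#'   than 20% of replicate refits failed to converge).
#' @export
gof_bootstrap <- function(fit, data, replicates = 1000, seed = 1) {
  stopifnot(inherits(fit, "nmix_fit"), replicates >= 1)
  if (!fit$converged) stop_cfg("goodness of fit requires a converged fit")
  fr <- fitted_rates(fit, data)
  M <- nrow(data$y); J <- ncol(data$y)
  fit_mat <- matrix(rep(fr$EN * fr$p, J), M, J)
  obs <- chisq_stat(data$y, fit_mat)
  na_pat <- is.na(data$y)

  boot <- numeric(replicates)
  bad <- 0L
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      N <- switch(fit$spec$mixture,
        P = rpois(M, fr$lambda),
        NB = rnbinom(M, size = fit$theta_hat, mu = fr$lambda),
        ZIP = ifelse(runif(M) < fr$psi, 0L, rpois(M, fr$lambda))
      )
      yr <- matrix(rbinom(M * J, rep(N, J), rep(fr$p, J)), M, J)
      yr[na_pat] <- NA_integer_
      dr <- data
      dr$y <- yr
      Kr <- max(fit$K_trunc, max(yr, na.rm = TRUE) + 100L)
      fr2 <- suppressWarnings(
        fit_nmix(dr, fit$spec, K_trunc = Kr, start = unname(fit$coef),
                 fix_p = fit$fix_p, hessian = FALSE)
      )
      if (!fr2$converged) {
        # a failed refit yields arbitrary fitted values; its statistic is
        # not a draw from the null distribution, so it is excluded
        bad <- bad + 1L
        boot[r] <- NA_real_
        next
      }
      rates <- fitted_rates(fr2, dr)
      boot[r] <- chisq_stat(yr, matrix(rep(rates$EN * rates$p, J), M, J))
    }
  })
  boot <- boot[!is.na(boot)]
  if (length(boot) == 0)
    stop_cfg("no bootstrap replicate refit converged")

  unreliable <- bad / replicates > 0.2
  if (unreliable)
    warning("gof_bootstrap: ", bad, "/", replicates,
            " replicate refits did not converge; result flagged unreliable",
            call. = FALSE)
  structure(list(
    chisq_obs = obs, chisq_boot = boot,
    p_value = mean(boot >= obs),
    c_hat = obs / mean(boot),
    replicates = replicates, seed = seed,
    n_nonconverged = bad, unreliable = unreliable
  ), class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "parametric-bootstrap GOF: chisq = %.2f, p = %.3f, c-hat = %.3f (%d reps)%s\n",
    x$chisq_obs, x$p_value, x$c_hat, x$replicates,
    if (x$unreliable) " [UNRELIABLE: >20% refits non-converged]" else ""
  ))
  if (x$c_hat > 2)
    cat("warning: c-hat > 2 suggests substantial extra-model variance\n")
  invisible(x)
}

#' Inflate a fit's variance matrix by the overdispersion factor
#'
#' Multiplies the variance-covariance matrix by `c_hat` when `c_hat > 1`
#' (standard errors scale by `sqrt(c_hat)`); leaves it unchanged when
#' `c_hat <= 1` (no deflation). Point estimates are untouched.
#'
#' @param fit an `nmix_fit` with an available `vcov`.
#' @param c_hat overdispersion factor (> 0), e.g. from [gof_bootstrap()].
#' @return the fit with adjusted `vcov` and `c_hat_inflation` recorded.
#' @export
inflate_vcov <- function(fit, c_hat) {
  stopifnot(inherits(fit, "nmix_fit"), c_hat > 0)
  if (is.null(fit$vcov)) stop_cfg("fit has no variance matrix to inflate")
  if (c_hat > 1) {
    fit$vcov <- fit$vcov * c_hat
    fit$c_hat_inflation <- c_hat
  }
  fit
}

#' Observed, fitted and residual table for diagnostics
#'
#' @param fit a converged `nmix_fit`.
#' @param data the [count_data()] it was fitted to.
#' @return data.frame `site, visit, observed, fitted, raw_resid,
#'   pearson_resid` (one row per non-missing site-visit); Pearson residuals
#'   use the same epsilon-guarded denominator as the GOF statistic.
#' @export
residual_table <- function(fit, data) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (!fit$converged) stop_cfg("residuals require a converged fit")
  fr <- fitted_rates(fit, data)
  M <- nrow(data$y); J <- ncol(data$y)
  fitted <- rep(fr$EN * fr$p, J)
  df <- data.frame(
    site = rep(seq_len(M), J),
    visit = rep(seq_len(J), each = M),
    observed = as.vector(data$y),
    fitted = fitted
  )
  df <- df[!is.na(df$observed), , drop = FALSE]
  df$raw_resid <- df$observed - df$fitted
  df$pearson_resid <- df$raw_resid / sqrt(df$fitted + 1e-6)
  rownames(df) <- NULL
  df
}
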