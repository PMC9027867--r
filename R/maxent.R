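#' Presence/background occurrence set
#'
#' @param presence_cells cell ids with presences (duplicates collapsed).
#' @param background_cells pseudo-absence cell ids (disjoint from
#'   presences).
#' @param buffer_km background eligibility buffer around presences, km.
#' @return an `occurrence_set` list.
#' @export
occurrence_set <- function(presence_cells, background_cells, buffer_km = 2.5) {
  presence_cells <- unique(as.character(presence_cells))
  background_cells <- as.character(background_cells)
  if (length(intersect(presence_cells, background_cells)))
    stop_cfg("background cells must be disjoint from presence cells")
  structure(list(presence_cells = presence_cells,
                 background_cells = background_cells,
                 buffer_km = buffer_km),
            class = "occurrence_set")
}

#' Sample background (pseudo-absence) cells within a buffer
#'
#' Background cells are drawn uniformly without replacement from the cells
#' whose centres lie within `buffer_km` (Euclidean distance on the grid's
#' metric coordinates) of at least one presence cell centre, excluding the
#' presence cells themselves. This restricted background corrects for the
#' spatial bias of opportunistic sampling effort. If fewer eligible cells
#' exist than requested, all of them are taken (with a message).
#'
#' @param grid a `landscape_grid`.
#' @param presences presence cell ids (>= 1).
#' @param buffer_km buffer radius in km (default 2.5).
#' @param n_background requested number of background cells (>= 1).
#' @param seed integer seed.
#' @return an [occurrence_set()].
#' @export
sample_background <- function(grid, presences, buffer_km = 2.5,
                              n_background = 1000, seed = 1) {
  presences <- unique(as.character(presences))
  stopifnot(length(presences) >= 1, n_background >= 1)
  pidx <- match(presences, grid$cell_id)
  if (anyNA(pidx)) stop_cfg("presence cell(s) absent from the grid")
  xy <- grid_xy(grid)
  d2min <- rep(Inf, nrow(grid))
  for (i in pidx) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    d2min <- pmin(d2min, d2)
  }
  eligible <- which(d2min <= (buffer_km * 1000)^2)
  eligible <- setdiff(eligible, pidx)
  if (length(eligible) == 0)
    stop_cfg("no eligible background cells within the buffer")
  take <- min(n_background, length(eligible))
  if (take < n_background)
    message("only ", take, " eligible background cells; taking all of them")
  bg <- with_seed(seed, sample(eligible, take))
  occurrence_set(grid$cell_id[pidx], grid$cell_id[bg], buffer_km)
}

# rank AUC of positive vs negative scores
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# feature matrix over min-max scaled covariates; constant covariates map to 0.5
maxent_features <- function(covmat, scaling, features) {
  cols <- list()
  for (v in colnames(covmat)) {
    lo <- scaling[[v]]["min"]; hi <- scaling[[v]]["max"]
    z <- if (hi > lo) pmin(1, pmax(0, (covmat[, v] - lo) / (hi - lo)))
         else rep(0.5, nrow(covmat))
    if ("linear" %in% features) cols[[v]] <- z
    if ("quadratic" %in% features) cols[[paste0(v, "^2")]] <- z^2
  }
  do.call(cbind, cols)
}

#' Fit a maximum-entropy presence-background suitability model
#'
#' Estimates the relative occurrence rate (ROR) of the species over the
#' landscape from presence-only data: feature weights `w` maximize the
#' penalized log-likelihood of the Gibbs density
#' `q(c) = exp(f(c)'w) / Z` over the presence + background cells, with an
#' L1 penalty `reg_multiplier * sd(f_j) / sqrt(m)` per feature (m =
#' number of presence cells). Covariates are min-max scaled to `[0, 1]`;
#' feature classes are linear and quadratic. Training is coordinate-wise
#' proximal Newton; percent contribution accumulates each feature's
#' penalized-gain increments along the training path, and permutation
#' importance is the AUC drop when a covariate's values are permuted
#' across presence + background cells — both normalized to sum to 100.
#'
#' @param grid a `landscape_grid`.
#' @param occ an [occurrence_set()].
#' @param covariates covariate (column) names to use.
#' @param features feature classes, subset of `c("linear", "quadratic")`.
#' @param reg_multiplier L1 regularization multiplier (default 1; 0 =
#'   unpenalized).
#' @param maxit maximum coordinate-descent sweeps.
#' @param tol convergence tolerance on the largest coordinate step.
#' @param perm_reps permutations averaged per covariate for importance.
#' @param seed seed for the importance permutations.
#' @return a `maxent_fit` with `feature_weights`, `feature_scaling`,
#'   `percent_contribution`, `permutation_importance`, `training_gain`,
#'   `log_Z`, `entropy`, and the normalization set.
#' @export
fit_maxent <- function(grid, occ, covariates,
                       features = c("linear", "quadratic"),
                       reg_multiplier = 1, maxit = 2000, tol = 1e-7,
                       perm_reps = 5, seed = 1) {
  stopifnot(inherits(occ, "occurrence_set"))
  features <- match.arg(features, c("linear", "quadratic"), several.ok = TRUE)
  if (length(occ$presence_cells) < 5)
    stop_cfg("need at least 5 presence cells")
  cells <- c(occ$presence_cells, occ$background_cells)
  idx <- match(cells, grid$cell_id)
  if (anyNA(idx)) stop_cfg("occurrence cell(s) absent from the grid")
  miss <- setdiff(covariates, names(grid))
  if (length(miss)) stop_cfg("unknown covariate(s): ", paste(miss, collapse = ", "))
  covmat <- as.matrix(as.data.frame(grid)[idx, covariates, drop = FALSE])
  if (any(!is.finite(covmat))) stop_cfg("non-finite covariate values")

  scaling <- lapply(covariates, function(v)
    c(min = min(covmat[, v]), max = max(covmat[, v])))
  names(scaling) <- covariates
  F <- maxent_features(covmat, scaling, features)
  n <- nrow(F); nf <- ncol(F)
  m <- length(occ$presence_cells)
  is_pres <- seq_len(n) <= m
  feat_cov <- sub("\\^2$", "", colnames(F))

  lam <- reg_multiplier * apply(F, 2, sd) / sqrt(m)
  Fp_mean <- colMeans(F[is_pres, , drop = FALSE])

  pen_ll <- function(eta, w) {
    lz <- log(sum(exp(eta - max(eta)))) + max(eta)
    sum(eta[is_pres]) - m * lz - sum(lam * abs(w))
  }

  w <- numeric(nf)
  eta <- rep(0, n)
  contrib <- setNames(numeric(length(covariates)), covariates)
  ll <- pen_ll(eta, w)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    max_step <- 0
    for (j in seq_len(nf)) {
      me <- max(eta)
      q <- exp(eta - me); q <- q / sum(q)
      Eq <- sum(q * F[, j])
      grad <- m * (Fp_mean[j] - Eq)
      curv <- m * (sum(q * F[, j]^2) - Eq^2) + 1e-12
      z <- curv * w[j] + grad
      wj_new <- sign(z) * max(abs(z) - lam[j], 0) / curv
      d <- wj_new - w[j]
      d <- max(-1, min(1, d)) # step clip for exponential-model stability
      if (d == 0) next
      eta_new <- eta + d * F[, j]
      ll_new <- pen_ll(eta_new, `[<-`(w, j, w[j] + d))
      if (ll_new < ll) { # quadratic step overshot; halve until improving
        repeat {
          d <- d / 2
          if (abs(d) < 1e-12) { d <- 0; break }
          eta_new <- eta + d * F[, j]
          ll_new <- pen_ll(eta_new, `[<-`(w, j, w[j] + d))
          if (ll_new >= ll) break
        }
        if (d == 0) next
      }
      contrib[feat_cov[j]] <- contrib[feat_cov[j]] + max(0, ll_new - ll)
      w[j] <- w[j] + d
      eta <- eta_new
      ll <- ll_new
      max_step <- max(max_step, abs(d))
    }
    if (max_step < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop_cfg("maxent training did not converge in ", maxit,
             " sweeps (last max step ", signif(max_step, 3), ")")

  me <- max(eta)
  log_Z <- log(sum(exp(eta - me))) + me
  q <- exp(eta - log_Z)
  entropy <- -sum(q * log(pmax(q, 1e-300)))
  training_gain <- mean(eta[is_pres]) - log_Z + log(n)

  pct <- if (sum(contrib) > 0) 100 * contrib / sum(contrib)
         else setNames(rep(100 / length(covariates), length(covariates)),
                       covariates)

  auc0 <- auc_rank(eta[is_pres], eta[!is_pres])
  imp <- setNames(numeric(length(covariates)), covariates)
  with_seed(seed, {
    for (v in covariates) {
      jcols <- which(feat_cov == v)
      drop_v <- numeric(perm_reps)
      for (r in seq_len(perm_reps)) {
        perm <- sample.int(n)
        eta_p <- eta
        for (j in jcols) eta_p <- eta_p + (F[perm, j] - F[, j]) * w[j]
        drop_v[r] <- auc0 - auc_rank(eta_p[is_pres], eta_p[!is_pres])
      }
      imp[v] <- max(0, mean(drop_v))
    }
  })
  imp <- if (sum(imp) > 0) 100 * imp / sum(imp)
         else setNames(rep(100 / length(covariates), length(covariates)),
                       covariates)

  names(w) <- colnames(F)
  structure(list(
    feature_weights = w, feature_scaling = scaling,
    feature_classes = features, regularization = reg_multiplier,
    penalties = setNames(lam, colnames(F)),
    percent_contribution = pct, permutation_importance = imp,
    training_gain = training_gain,
    log_Z = log_Z, entropy = entropy, n_norm = n,
    cov_means = colMeans(covmat),
    presence_cells = occ$presence_cells,
    background_cells = occ$background_cells,
    covariates = covariates, converged = TRUE
  ), class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf("maxent_fit: %d presences, %d background cells, gain %.3f\n",
              length(x$presence_cells), length(x$background_cells),
              x$training_gain))
  ord <- order(-x$percent_contribution)
  print(round(data.frame(
    percent_contribution = x$percent_contribution[ord],
    permutation_importance = x$permutation_importance[ord]
  ), 1))
  invisible(x)
}

# linear predictor (eta) for arbitrary grid cells, clamped to training range
maxent_eta <- function(fit, grid, cells = NULL) {
  df <- as.data.frame(grid)
  if (!is.null(cells)) df <- df[match(cells, df$cell_id), , drop = FALSE]
  covmat <- as.matrix(df[fit$covariates])
  out_of_range <- 0L
  for (v in fit$covariates) {
    sc <- fit$feature_scaling[[v]]
    out_of_range <- out_of_range +
      sum(covmat[, v] < sc["min"] | covmat[, v] > sc["max"])
  }
  if (out_of_range > 0)
    message(out_of_range,
            " covariate value(s) outside the training range were clamped")
  F <- maxent_features(covmat, fit$feature_scaling, fit$feature_classes)
  drop(F %*% fit$feature_weights)
}

#' Predict the relative occurrence rate over a grid
#'
#' `raw` output is the Gibbs density relative to the training
#' normalization: it sums to exactly 1 over the presence + background
#' cells the model was trained on. `cloglog` output maps suitability to
#' `[0, 1]` via `1 - exp(-exp(eta - log Z + H))` with `H` the entropy of
#' the raw training distribution. Covariates outside the training range
#' are clamped (with a message).
#'
#' @param fit a `maxent_fit`.
#' @param grid a `landscape_grid` (or subset) carrying the fit covariates.
#' @param output `"cloglog"` (default) or `"raw"`.
#' @return numeric vector of per-cell ROR, in `grid` row order.
#' @export
predict_ror <- function(fit, grid, output = c("cloglog", "raw")) {
  output <- match.arg(output)
  eta <- maxent_eta(fit, grid)
  if (output == "raw") exp(eta - fit$log_Z)
  else 1 - exp(-exp(eta - fit$log_Z + fit$entropy))
}

#' Response curve of the suitability model along one covariate
#'
#' Sweeps the covariate over its training range at `n_points` values while
#' holding every other covariate at its presence + background mean, and
#' returns the cloglog ROR.
#'
#' @param fit a `maxent_fit`.
#' @param covariate covariate name present in the fit.
#' @param n_points number of sweep points (default 100).
#' @return data.frame `value, ror`.
#' @export
response_curve <- function(fit, covariate, n_points = 100) {
  if (!covariate %in% fit$covariates)
    stop_cfg("unknown covariate: ", covariate)
  sc <- fit$feature_scaling[[covariate]]
  vals <- seq(sc["min"], sc["max"], length.out = n_points)
  nd <- as.data.frame(lapply(fit$cov_means, rep, n_points))
  nd[[covariate]] <- vals
  nd$cell_id <- sprintf("sweep_%d", seq_len(n_points))
  F <- maxent_features(as.matrix(nd[fit$covariates]), fit$feature_scaling,
                       fit$feature_classes)
  eta <- drop(F %*% fit$feature_weights)
  data.frame(value = vals,
             ror = 1 - exp(-exp(eta - fit$log_Z + fit$entropy)))
}

# threshold maximizing TSS on (positive, negative) scores; candidate
# cutpoints are midpoints between adjacent unique scores (plus the scores
# themselves), ties resolved toward the smallest threshold
best_tss <- function(pos, neg) {
  u <- sort(unique(c(pos, neg)))
  cand <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  tss <- vapply(cand, function(t)
    mean(pos >= t) + mean(neg < t) - 1, 0)
  i <- which.max(tss)
  list(threshold = cand[i], tss = tss[i])
}

#' Evaluate discrimination with the true skill statistic
#'
#' Runs `splits` train-test replicas: presences are split
#' `train_fraction` / `1 - train_fraction` at random, a fresh background
#' sample is drawn for each replica (split the same way), the model is
#' fitted on the training portion, the threshold maximizing training TSS
#' is chosen, and the test TSS (sensitivity + specificity - 1 on held-out
#' presences vs held-out background) is recorded. A model fitted to all
#' data is also evaluated within-sample and reported as `tss_full`
#' (labelled as within-sample).
#'
#' @param grid a `landscape_grid`.
#' @param occ an [occurrence_set()] (all presences; its buffer and
#'   background size drive the per-replica background sampling).
#' @param covariates covariate names.
#' @param splits number of replicas (default 100).
#' @param train_fraction presence fraction used for training (default 0.8).
#' @param seed integer seed.
#' @param n_background background cells per replica (default: size of
#'   `occ$background_cells`).
#' @param ... passed to [fit_maxent()].
#' @return an `eval_result`: `tss_full`, `tss_replicas`, `threshold_rule`,
#'   `n_skipped`.
#' @export
evaluate_tss <- function(grid, occ, covariates, splits = 100,
                         train_fraction = 0.8, seed = 1,
                         n_background = NULL, ...) {
  stopifnot(inherits(occ, "occurrence_set"))
  pres <- occ$presence_cells
  np <- length(pres)
  n_train <- round(train_fraction * np)
  if (np - n_train < 1)
    stop_cfg("too few presences for a non-empty test split")
  n_background <- n_background %||% max(length(occ$background_cells), 100)

  tss <- rep(NA_real_, splits)
  skipped <- 0L
  for (r in seq_len(splits)) {
    sr <- sub_seed(seed, r)
    bg <- sample_background(grid, pres, occ$buffer_km, n_background,
                            seed = sr)$background_cells
    sp <- with_seed(sr + 1L, {
      list(p = sample(np, n_train), b = sample(length(bg), round(0.8 * length(bg))))
    })
    train_p <- pres[sp$p]; test_p <- pres[-sp$p]
    train_b <- bg[sp$b]; test_b <- bg[-sp$b]
    if (length(train_p) < 5 || length(test_b) < 1) {
      skipped <- skipped + 1L
      next
    }
    fr <- tryCatch(
      fit_maxent(grid, occurrence_set(train_p, train_b, occ$buffer_km),
                 covariates, seed = sr, ...),
      error = function(e) NULL
    )
    if (is.null(fr)) { skipped <- skipped + 1L; next }
    thr <- best_tss(maxent_eta(fr, grid, train_p),
                    maxent_eta(fr, grid, train_b))$threshold
    pos <- maxent_eta(fr, grid, test_p)
    neg <- maxent_eta(fr, grid, test_b)
    tss[r] <- mean(pos >= thr) + mean(neg < thr) - 1
  }
  if (skipped > 0)
    message(skipped, " replica(s) skipped (degenerate split or failed fit)")

  full <- fit_maxent(grid, occ, covariates, seed = seed, ...)
  sc <- best_tss(maxent_eta(full, grid, occ$presence_cells),
                 maxent_eta(full, grid, occ$background_cells))
  structure(list(
    tss_full = sc$tss, tss_replicas = tss[!is.na(tss)],
    threshold_rule = "max training TSS (tss_full is within-sample)",
    n_skipped = skipped
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "TSS: full model (within-sample) %.3f; %d replicas mean %.3f (sd %.3f)\n",
    x$tss_full, length(x$tss_replicas), mean(x$tss_replicas),
    sd(x$tss_replicas)
  ))
  invisible(x)
}
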