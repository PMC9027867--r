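#' Repeated-count survey data
#'
#' Container for site x visit egg counts with site covariates and the
#' detection covariate. Missing visits are `NA` in `y`; every site must
#' have at least one observed visit.
#'
#' @param y M x J matrix of non-negative integer counts (NA = missed visit).
#' @param site_covs data.frame of site-level covariates (M rows), typically
#'   including `cell_id` and the abundance covariates.
#' @param obs_covs data.frame of detection covariates (M rows; site-level,
#'   constant across visits), typically `pel_ava`.
#' @param band optional altitudinal band labels (length M).
#' @return a `count_data` list with fields `y`, `site_covs`, `obs_covs`,
#'   `band`, `scaling` (NULL until [standardize()] is applied).
#' @export
count_data <- function(y, site_covs, obs_covs = NULL, band = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (any(y < 0, na.rm = TRUE))
    stop_cfg("counts must be non-negative")
  if (any(rowSums(!is.na(y)) == 0))
    stop_cfg("every site needs at least one non-missing visit")
  stopifnot(nrow(site_covs) == nrow(y))
  if (!is.null(obs_covs)) stopifnot(nrow(obs_covs) == nrow(y))
  structure(
    list(y = y, site_covs = as.data.frame(site_covs),
         obs_covs = if (is.null(obs_covs)) NULL else as.data.frame(obs_covs),
         band = band, scaling = NULL),
    class = "count_data"
  )
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf(
    "count_data: %d sites x %d visits, %d eggs counted, %.0f%% zero counts%s\n",
    nrow(x$y), ncol(x$y), sum(x$y, na.rm = TRUE),
    100 * mean(x$y == 0, na.rm = TRUE),
    if (is.null(x$scaling)) "" else " (standardized)"
  ))
  invisible(x)
}

# combined covariate table (site + obs), standardized when available
all_covs <- function(data, standardized = TRUE) {
  covs <- data$site_covs
  if (!is.null(data$obs_covs) && ncol(data$obs_covs) > 0)
    covs <- cbind(covs, data$obs_covs)
  if (standardized && !is.null(data$scaling)) {
    for (v in names(data$scaling)) {
      rec <- data$scaling[[v]]
      covs[[v]] <- (covs[[v]] - rec["mean"]) / rec["sd"]
    }
  }
  covs
}

#' Scale and centre covariates
#'
#' Transforms each named covariate to `(x - mean) / sd` and records the
#' means and standard deviations in the data's `scaling` slot, so that
#' scenario projections can re-standardize shifted covariates with the
#' training statistics.
#'
#' @param data a [count_data()] object.
#' @param vars covariate names to standardize; default: every numeric
#'   covariate column (excluding identifiers).
#' @return the `count_data` with `scaling` filled in.
#' @export
standardize <- function(data, vars = NULL) {
  stopifnot(inherits(data, "count_data"))
  covs <- all_covs(data, standardized = FALSE)
  if (is.null(vars)) {
    vars <- names(covs)[vapply(covs, is.numeric, TRUE)]
    vars <- setdiff(vars, c("row", "col", "site_id"))
  }
  miss <- setdiff(vars, names(covs))
  if (length(miss)) stop_cfg("unknown covariate(s): ", paste(miss, collapse = ", "))
  rec <- list()
  for (v in vars) {
    s <- sd(covs[[v]])
    if (is.na(s) || s == 0)
      stop_cfg("covariate '", v, "' has zero variance; cannot standardize")
    rec[[v]] <- c(mean = mean(covs[[v]]), sd = s)
  }
  data$scaling <- rec
  data
}

#' Invert standardization
#'
#' @param data a standardized [count_data()] object.
#' @param z named list/data.frame of standardized columns to map back to the
#'   raw scale; default: all recorded covariates.
#' @return data.frame of unstandardized columns.
#' @export
unstandardize <- function(data, z = NULL) {
  stopifnot(inherits(data, "count_data"), !is.null(data$scaling))
  if (is.null(z)) z <- all_covs(data)[names(data$scaling)]
  out <- as.data.frame(z)
  for (v in intersect(names(out), names(data$scaling))) {
    rec <- data$scaling[[v]]
    out[[v]] <- out[[v]] * rec["sd"] + rec["mean"]
  }
  out
}

#' Pearson-correlation collinearity screen
#'
#' Greedy filter keeping only covariates whose pairwise Pearson
#' correlations satisfy `|r| < threshold`: while any pair violates the
#' bound, the member with the larger mean absolute correlation against all
#' remaining candidates is dropped (ties: the later one in input order).
#'
#' @param data a [count_data()] object (or data.frame of covariates).
#' @param candidates covariate names to screen (>= 2).
#' @param threshold drop threshold on `|r|` (default 0.7; pairs with
#'   `|r| >= threshold` are broken up).
#' @return list with `retained` (character), `dropped` (data.frame
#'   `dropped, against, r`).
#' @export
#' @examples
#' df <- data.frame(a = rnorm(50))
#' df$b <- df$a
#' df$c <- rnorm(50)
#' collinearity_filter(df, c("a", "b", "c"))$retained
collinearity_filter <- function(data, candidates, threshold = 0.7) {
  covs <- if (inherits(data, "count_data")) all_covs(data, standardized = FALSE)
          else as.data.frame(data)
  stopifnot(length(candidates) >= 2)
  miss <- setdiff(candidates, names(covs))
  if (length(miss)) stop_cfg("unknown covariate(s): ", paste(miss, collapse = ", "))
  bad <- candidates[!vapply(covs[candidates], is.numeric, TRUE)]
  if (length(bad)) stop_cfg("non-numeric covariate(s): ", paste(bad, collapse = ", "))

  keep <- candidates
  dropped <- data.frame(dropped = character(), against = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (length(keep) < 2) break
    r <- cor(covs[keep])
    diag(r) <- 0
    if (max(abs(r)) < threshold) break
    worst <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    # drop the pair member with larger mean |r| against the others;
    # ties -> the one later in input order
    score <- colMeans(abs(r))[pair]
    out <- if (score[1] > score[2]) pair[1]
           else if (score[2] > score[1]) pair[2]
           else pair[which.max(match(pair, candidates))]
    other <- setdiff(pair, out)
    dropped <- rbind(dropped, data.frame(
      dropped = out, against = other, r = r[pair[1], pair[2]],
      stringsAsFactors = FALSE
    ))
    keep <- setdiff(keep, out)
  }
  list(retained = keep, dropped = dropped)
}
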