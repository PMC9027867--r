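#' AICc model-selection table
#'
#' Ranks fitted models by AICc and reports Akaike weights, mirroring the
#' usual `K / AICc / dAICc / Wi / Cum.Wi` layout.
#'
#' @param fits list of `nmix_fit` objects.
#' @param labels optional model labels (default: generated from each spec).
#' @return a data.frame of class `nmix_selection`, sorted by AICc, with
#'   columns `model, K, AICc, dAICc, weight, cum_weight` and an attribute
#'   `tie` (TRUE when the top two models are within 2 AICc units).
#' @export
selection_table <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 1)
  labels <- labels %||% vapply(fits, function(f) spec_label(f$spec), "")
  tab <- data.frame(
    model = labels,
    K = vapply(fits, function(f) f$n_params, 0L),
    AICc = vapply(fits, function(f) f$aicc, 0),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  w <- exp(-0.5 * tab$dAICc)
  tab$weight <- w / sum(w)
  tab$cum_weight <- cumsum(tab$weight)
  rownames(tab) <- NULL
  attr(tab, "tie") <- nrow(tab) > 1 && tab$dAICc[2] <= 2
  class(tab) <- c("nmix_selection", "data.frame")
  tab
}

#' @export
print.nmix_selection <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$AICc <- round(df$AICc, digits)
  df$dAICc <- round(df$dAICc, digits)
  df$weight <- signif(df$weight, 3)
  df$cum_weight <- round(df$cum_weight, 3)
  print(df, row.names = FALSE)
  if (isTRUE(attr(x, "tie")))
    cat("note: top models within 2 AICc units (tie); parsimony rule applies\n")
  invisible(x)
}

# pick the best row's fit index honouring the dAICc<=2 parsimony tie rule
pick_best <- function(fits, tab) {
  contenders <- tab$model[tab$dAICc <= 2]
  labels <- vapply(fits, function(f) spec_label(f$spec), "")
  if (length(contenders) > 1) {
    ks <- tab$K[tab$dAICc <= 2]
    contenders <- contenders[order(ks, tab$AICc[tab$dAICc <= 2])]
  }
  match(contenders[1], labels)
}

#' Two-step covariate selection for N-mixture models
#'
#' Step 1 selects the detection structure: candidate detection covariate
#' sets are compared at null (intercept-only) abundance under a Poisson
#' mixture. Step 2 holds the winning detection structure fixed and ranks
#' candidate abundance structures by AICc. Step 3 refits the step-2 winner
#' under each requested mixture (P/NB/ZIP) and ranks again. A model is
#' declared best outright when it leads by more than 2 AICc units;
#' otherwise the tie is reported and the most parsimonious contender is
#' taken. Non-converged candidates are excluded from ranking (with a
#' message).
#'
#' @param data a standardized [count_data()] object.
#' @param detection_candidates list of character vectors of detection
#'   covariates (include `character(0)` for the null detection model).
#' @param abundance_candidates list of character vectors of abundance
#'   terms.
#' @param mixtures mixtures to compare in step 3 (default P, NB, ZIP).
#' @param ... passed to [fit_nmix()].
#' @return list with `detection`, `abundance`, `mixture` selection tables
#'   (class `nmix_selection`), `best_fit` (an `nmix_fit`), and `dropped`
#'   (labels of non-converged candidates).
#' @export
two_step_selection <- function(data,
                               detection_candidates = list(character(0), "pel_ava"),
                               abundance_candidates,
                               mixtures = c("P", "NB", "ZIP"), ...) {
  stopifnot(length(detection_candidates) >= 1, length(abundance_candidates) >= 1)
  dropped <- character()
  fit_all <- function(specs) {
    if (length(specs) == 0) return(list())
    fits <- lapply(specs, function(s) fit_nmix(data, s, ...))
    keep <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
    if (!all(keep)) {
      bad <- vapply(fits[!keep], function(f) spec_label(f$spec), "")
      dropped <<- c(dropped, bad)
      message("excluded non-converged model(s): ", paste(bad, collapse = "; "))
    }
    if (!any(keep)) stop_cfg("no candidate model converged")
    fits[keep]
  }

  # step 1: detection at null abundance, Poisson mixture
  det_fits <- fit_all(lapply(detection_candidates, function(d)
    nmix_spec(character(), d, "P")))
  det_tab <- selection_table(det_fits)
  best_det <- det_fits[[pick_best(det_fits, det_tab)]]$spec$detection

  # step 2: abundance structures with the winning detection held fixed
  abu_fits <- fit_all(lapply(abundance_candidates, function(a)
    nmix_spec(a, best_det, "P")))
  abu_tab <- selection_table(abu_fits)
  best_abu <- abu_fits[[pick_best(abu_fits, abu_tab)]]$spec$abundance

  # step 3: mixture comparison for the winning structure (the Poisson fit
  # is reused from step 2 rather than refitted)
  abu_winner <- abu_fits[[pick_best(abu_fits, abu_tab)]]
  mix_fits <- fit_all(lapply(setdiff(mixtures, "P"), function(m)
    nmix_spec(best_abu, best_det, m)))
  if ("P" %in% mixtures) mix_fits <- c(list(abu_winner), mix_fits)
  mix_tab <- selection_table(mix_fits)
  best_fit <- mix_fits[[pick_best(mix_fits, mix_tab)]]

  list(detection = det_tab, abundance = abu_tab, mixture = mix_tab,
       best_fit = best_fit, dropped = dropped)
}
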