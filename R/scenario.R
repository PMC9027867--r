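#' Climate / host-plant scenario specification
#'
#' @param delta_bio01 additive shift on annual mean temperature, degrees C
#'   on the unscaled scale (default +1.5, the mid-century warming
#'   projection for the Alps under a low-emission pathway).
#' @param pel_multiplier factor applied to host-plant pot counts (default
#'   0.5, a 50% reduction campaign); must be >= 0.
#' @param label scenario label for tables and profiles.
#' @param recompute_neigh recompute `pel_neigh` from the multiplied
#'   `pel_abu` over the grid topology (default TRUE); if FALSE,
#'   `pel_neigh` is multiplied directly.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(delta_bio01 = 1.5, pel_multiplier = 0.5,
                          label = NULL, recompute_neigh = TRUE) {
  stopifnot(pel_multiplier >= 0)
  label <- label %||% sprintf("dT=%+g, pel x%g", delta_bio01, pel_multiplier)
  structure(list(delta_bio01 = delta_bio01, pel_multiplier = pel_multiplier,
                 label = label, recompute_neigh = recompute_neigh),
            class = "scenario_spec")
}

# apply a scenario to raw grid covariates
apply_scenario <- function(grid, scenario) {
  if (is.null(scenario)) return(grid)
  g <- grid
  g$bio01 <- g$bio01 + scenario$delta_bio01
  g$pel_abu <- g$pel_abu * scenario$pel_multiplier
  if (scenario$recompute_neigh && all(c("row", "col") %in% names(g)))
    g$pel_neigh <- compute_pel_neigh(g)
  else
    g$pel_neigh <- g$pel_neigh * scenario$pel_multiplier
  g
}

#' Project expected egg abundance over the landscape
#'
#' Applies a scenario on the unscaled covariates (temperature shift;
#' host-plant multiplication with `pel_neigh` recomputed from the modified
#' counts when the grid topology is available), re-standardizes with the
#' fit's training scaling record, and evaluates the fitted model's
#' expected abundance per cell. By default the projection is restricted to
#' cells holding host plants at baseline (`pel_abu > 0`): the butterfly is
#' a host-plant obligate.
#'
#' @param fit an `nmix_fit` with a scaling record.
#' @param grid a `landscape_grid`.
#' @param scenario a [scenario_spec()] or NULL for the baseline.
#' @param host_cells_only restrict to baseline `pel_abu > 0` cells
#'   (default TRUE).
#' @return data.frame `cell_id, E_N, se_E_N` plus a `host_free` flag when
#'   the scenario removes all host plants.
#' @export
project_map <- function(fit, grid, scenario = NULL, host_cells_only = TRUE) {
  stopifnot(inherits(fit, "nmix_fit"))
  if (is.null(fit$scaling))
    stop_cfg("fit carries no scaling record; fit on standardized data")
  g <- as.data.frame(grid)
  keep <- if (host_cells_only) g$pel_abu > 0 else rep(TRUE, nrow(g))
  if (!any(keep)) stop_cfg("no host-plant cells to project on")
  # scenario applied over the full grid so pel_neigh recomputation sees
  # the whole topology, then restricted to the projection cells
  g2 <- apply_scenario(g, scenario)[keep, , drop = FALSE]
  pr <- predict_abundance(fit, g2, detection = FALSE)
  out <- data.frame(cell_id = g$cell_id[keep], E_N = pr$E_N,
                    se_E_N = pr$se_E_N, stringsAsFactors = FALSE)
  if (!is.null(scenario) && scenario$pel_multiplier == 0)
    out$host_free <- TRUE
  out
}

#' Classify per-cell abundance changes between two maps
#'
#' Expected abundances are rounded half-up to whole eggs before
#' comparison, so sub-egg drifts never register as change. Categories:
#' `increase`, `decrease`, `no_change`, and `new_infestation` (rounded
#' baseline 0 to rounded scenario >= 1), which is a sub-category of
#' increase and is also counted among increases in the percentage summary.
#'
#' @param baseline,scenario maps from [project_map()] over identical cell
#'   sets.
#' @return a `scenario_result`: `cells` (per-cell table with categories)
#'   and `summary` (percentages with counts; increases + decreases +
#'   no_change = 100).
#' @export
categorize_changes <- function(baseline, scenario) {
  if (!setequal(baseline$cell_id, scenario$cell_id) ||
      nrow(baseline) != nrow(scenario))
    stop_cfg("baseline and scenario maps cover different cell sets")
  s <- scenario[match(baseline$cell_id, scenario$cell_id), , drop = FALSE]
  rb <- round_half_up(baseline$E_N)
  rs <- round_half_up(s$E_N)
  category <- ifelse(rs > rb, "increase", ifelse(rs < rb, "decrease", "no_change"))
  new_inf <- rb == 0 & rs >= 1
  cells <- data.frame(
    cell_id = baseline$cell_id,
    baseline_E = baseline$E_N, scenario_E = s$E_N,
    rounded_baseline = rb, rounded_scenario = rs,
    category = category, new_infestation = new_inf,
    stringsAsFactors = FALSE
  )
  n <- nrow(cells)
  cnt <- c(
    changed = sum(category != "no_change"),
    increase = sum(category == "increase"),
    decrease = sum(category == "decrease"),
    new_infestation = sum(new_inf),
    no_change = sum(category == "no_change")
  )
  summary <- data.frame(
    category = names(cnt), n = as.integer(cnt),
    percent = round(100 * cnt / n, 1), row.names = NULL
  )
  structure(list(cells = cells, summary = summary, n_cells = n),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("scenario change summary over", x$n_cells, "cells:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Summarize scenario changes by grouping field
#'
#' Per group (default: municipality) reports the mean elevation and the
#' percentage (and count) of cells with decreases and increases, sorted by
#' mean elevation ascending — the layout used to read altitudinal
#' countertrends off a management scenario.
#'
#' @param result a `scenario_result`.
#' @param grid the `landscape_grid` the maps came from.
#' @param group grouping column in `grid` (default `"municipality"`).
#' @return data.frame `group, mean_elevation, n_cells, pct_decrease,
#'   n_decrease, pct_increase, n_increase`, sorted by elevation.
#' @export
summarize_by_group <- function(result, grid, group = "municipality") {
  stopifnot(inherits(result, "scenario_result"))
  if (!group %in% names(grid)) stop_cfg("grouping field '", group, "' not in grid")
  idx <- match(result$cells$cell_id, grid$cell_id)
  df <- data.frame(
    group = as.data.frame(grid)[idx, group],
    elevation = grid$elevation[idx],
    category = result$cells$category
  )
  agg <- do.call(rbind, lapply(split(df, df$group), function(d) {
    data.frame(
      group = d$group[1],
      mean_elevation = mean(d$elevation),
      n_cells = nrow(d),
      pct_decrease = round(100 * mean(d$category == "decrease"), 1),
      n_decrease = sum(d$category == "decrease"),
      pct_increase = round(100 * mean(d$category == "increase"), 1),
      n_increase = sum(d$category == "increase")
    )
  }))
  agg <- agg[order(agg$mean_elevation), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Binned elevation profile of projected abundance
#'
#' Bins cells into `n_bins` equal-width elevation bins and reports the
#' mean projected abundance (and cell count) per bin for each map — a
#' robust alternative to a smoothed elevation trend line. Extreme values
#' are retained.
#'
#' @param maps named list of maps from [project_map()] (names = scenario
#'   labels), or a single map.
#' @param grid the `landscape_grid`.
#' @param n_bins number of elevation bins (>= 2).
#' @return data.frame `scenario, bin_low, bin_high, bin_mid, n_cells,
#'   mean_E`.
#' @export
elevation_profile <- function(maps, grid, n_bins = 10) {
  if (n_bins < 2) stop_cfg("n_bins must be at least 2")
  if (is.data.frame(maps)) maps <- list(map = maps)
  stopifnot(length(maps) >= 1)
  if (is.null(names(maps))) names(maps) <- sprintf("map_%d", seq_along(maps))
  elev_all <- grid$elevation[match(
    unique(unlist(lapply(maps, `[[`, "cell_id"))), grid$cell_id)]
  brk <- seq(min(elev_all), max(elev_all), length.out = n_bins + 1)
  out <- do.call(rbind, lapply(names(maps), function(nm) {
    mp <- maps[[nm]]
    elev <- grid$elevation[match(mp$cell_id, grid$cell_id)]
    bin <- pmin(n_bins, pmax(1, findInterval(elev, brk, rightmost.closed = TRUE)))
    do.call(rbind, lapply(seq_len(n_bins), function(b) {
      sel <- bin == b
      data.frame(
        scenario = nm, bin_low = brk[b], bin_high = brk[b + 1],
        bin_mid = (brk[b] + brk[b + 1]) / 2,
        n_cells = sum(sel),
        mean_E = if (any(sel)) mean(mp$E_N[sel]) else NA_real_
      )
    }))
  }))
  rownames(out) <- NULL
  out
}
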