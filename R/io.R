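#' Read / write a landscape grid as CSV
#'
#' The canonical grid schema is `cell_id, row, col, elevation, bio01,
#' bio04, pel_abu, pel_neigh, wood, eco, grass, municipality, urban`.
#' Unknown extra columns round-trip untouched.
#'
#' @param path CSV file path.
#' @return [read_grid()]: a `landscape_grid`; [write_grid()]: the path,
#'   invisibly.
#' @export
read_grid <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("cell_id", "row", "col", "elevation", "bio01", "bio04",
              "pel_abu", "pel_neigh", "wood", "eco", "grass",
              "municipality", "urban")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop_cfg("grid file lacks mandatory column(s): ", paste(miss, collapse = ", "))
  if (any(df$pel_abu != round(df$pel_abu)))
    stop_cfg("pel_abu must be integer counts")
  df$pel_abu <- as.integer(df$pel_abu)
  df$urban <- as.logical(df$urban)
  as_landscape_grid(df)
}

#' @param grid a `landscape_grid`.
#' @rdname read_grid
#' @export
write_grid <- function(grid, path) {
  write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' Read / write repeated-count survey data as wide CSV
#'
#' Wide schema: `site_id, cell_id, visit_1 .. visit_J, pel_ava`; missing
#' visits are empty cells.
#'
#' @param path CSV file path.
#' @param grid optional `landscape_grid` to join site covariates from (by
#'   `cell_id`); without it only `pel_ava` is available as a covariate.
#' @return [read_counts()]: a [count_data()]; [write_counts()]: the path,
#'   invisibly.
#' @export
read_counts <- function(path, grid = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  vcols <- grep("^visit_\\d+$", names(df), value = TRUE)
  need <- c("site_id", "cell_id", "pel_ava")
  miss <- setdiff(need, names(df))
  if (length(miss) || length(vcols) == 0)
    stop_cfg("counts file lacks column(s): ",
             paste(c(miss, if (!length(vcols)) "visit_*"), collapse = ", "))
  y <- as.matrix(df[vcols])
  site_covs <- df[c("site_id", "cell_id")]
  if (!is.null(grid)) {
    idx <- match(df$cell_id, grid$cell_id)
    if (anyNA(idx)) stop_cfg("counts refer to cells absent from the grid")
    site_covs <- cbind(site_covs,
                       as.data.frame(grid)[idx, setdiff(names(grid), "cell_id")])
  }
  count_data(y, site_covs, obs_covs = df["pel_ava"])
}

#' @param data a [count_data()] object.
#' @rdname read_counts
#' @export
write_counts <- function(data, path) {
  df <- data.frame(
    site_id = data$site_covs$site_id %||% seq_len(nrow(data$y)),
    cell_id = data$site_covs$cell_id %||% NA
  )
  df <- cbind(df, as.data.frame(data$y))
  df$pel_ava <- data$obs_covs$pel_ava
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write presence points as CSV (`point_id, cell_id, x, y`)
#' @param path CSV file path.
#' @return [read_points()]: data.frame; [write_points()]: the path,
#'   invisibly.
#' @export
read_points <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("point_id", "cell_id", "x", "y"), names(df))
  if (length(miss))
    stop_cfg("points file lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @param points data.frame of presence points.
#' @rdname read_points
#' @export
write_points <- function(points, path) {
  write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Default end-to-end pipeline configuration
#'
#' A demo-scale configuration: a 30 x 30 grid, the standard 3-band x
#' 25-cell x 3-visit survey, the package's reference truth, the usual
#' candidate model set, and both warming and host-plant-reduction
#' scenarios. Every stage derives its seed from the single top-level seed.
#'
#' @param seed master seed.
#' @return nested configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    # ~8% urban cells, matching the host-plant census's footprint
    landscape = list(n_rows = 30, n_cols = 30, n_villages = 8),
    design = list(n_per_band = 25, visits = 3),
    truth = default_truth(),
    screen = c("bio01", "bio04", "pel_abu", "pel_neigh",
               "wood", "eco", "grass"),
    model = list(
      detection_candidates = list(character(0), "pel_ava"),
      abundance_candidates = list(
        "bio01",
        c("bio01", "pel_abu"),
        c("bio01", "pel_abu", "pel_neigh"),
        c("bio01", "pel_abu", "bio01:pel_abu", "pel_neigh")
      ),
      mixtures = c("P", "NB", "ZIP")
    ),
    gof = list(replicates = 200),
    maxent = list(n_points = 138, bias_strength = 1, buffer_km = 2.5,
                  n_background = 500, splits = 20,
                  covariates = c("bio01", "bio04", "pel_abu", "pel_neigh")),
    scenario = list(delta_bio01 = 1.5, pel_multiplier = 0.5)
  )
}

#' Run the full simulate / fit / diagnose / project pipeline
#'
#' Orchestrates every stage end-to-end: landscape + survey simulation,
#' collinearity screening and standardization, two-step N-mixture
#' selection, bootstrap goodness of fit with c-hat inflation, the
#' presence-only suitability model with TSS evaluation, and the warming /
#' host-plant-reduction scenario projections. All artifacts are written as
#' CSV into `out_dir` together with a machine-readable `manifest.json`
#' (seeds, settings, package version). Deterministic given `config$seed`.
#'
#' @param config configuration list, see [pipeline_config()]; a path to a
#'   YAML file is also accepted (requires the `yaml` package).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run_")) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_cfg("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
    config$truth <- do.call(truth_params, config$truth)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_cfg("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  out <- function(name) file.path(out_dir, name)

  grid <- stage("landscape", do.call(make_landscape,
    c(config$landscape, list(seed = sub_seed(seed, 1)))))
  write_grid(grid, out("grid.csv"))

  design <- stage("design", do.call(stratified_design,
    c(list(grid = grid), config$design, list(seed = sub_seed(seed, 2)))))

  counts <- stage("counts", simulate_counts(grid, design, config$truth,
                                            seed = sub_seed(seed, 3)))
  counts$site_covs$site_id <- seq_len(nrow(counts$y))
  write_counts(counts, out("counts.csv"))

  points <- stage("opportunistic", simulate_opportunistic(
    grid, config$truth, n_points = config$maxent$n_points,
    bias_strength = config$maxent$bias_strength, seed = sub_seed(seed, 4)))
  write_points(points, out("points.csv"))

  screen <- stage("collinearity", collinearity_filter(counts, config$screen))
  write.csv(screen$dropped, out("collinearity_dropped.csv"), row.names = FALSE)

  counts <- stage("standardize", standardize(counts))

  sel <- stage("selection", two_step_selection(
    counts,
    detection_candidates = config$model$detection_candidates,
    abundance_candidates = config$model$abundance_candidates,
    mixtures = config$model$mixtures))
  write.csv(as.data.frame(sel$detection), out("selection_detection.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(sel$abundance), out("selection_abundance.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(sel$mixture), out("selection_mixture.csv"),
            row.names = FALSE)

  gof <- stage("gof", gof_bootstrap(sel$best_fit, counts,
                                    replicates = config$gof$replicates,
                                    seed = sub_seed(seed, 5)))
  fit <- inflate_vcov(sel$best_fit, gof$c_hat)
  write.csv(data.frame(chisq_boot = gof$chisq_boot), out("gof_boot.csv"),
            row.names = FALSE)
  write.csv(data.frame(
    parameter = names(fit$coef), estimate = unname(fit$coef),
    se = if (is.null(fit$vcov)) NA else sqrt(diag(fit$vcov))
  ), out("coefficients.csv"), row.names = FALSE)

  mx <- stage("maxent", {
    occ <- sample_background(grid, unique(points$cell_id),
                             buffer_km = config$maxent$buffer_km,
                             n_background = config$maxent$n_background,
                             seed = sub_seed(seed, 6))
    fitm <- fit_maxent(grid, occ, config$maxent$covariates,
                       seed = sub_seed(seed, 7))
    tss <- evaluate_tss(grid, occ, config$maxent$covariates,
                        splits = config$maxent$splits,
                        seed = sub_seed(seed, 8))
    list(occ = occ, fit = fitm, tss = tss)
  })
  write.csv(data.frame(
    variable = names(mx$fit$percent_contribution),
    percent_contribution = unname(mx$fit$percent_contribution),
    permutation_importance = unname(mx$fit$permutation_importance)
  )[order(-mx$fit$percent_contribution), ],
  out("maxent_contributions.csv"), row.names = FALSE)
  write.csv(data.frame(cell_id = grid$cell_id,
                       ror_cloglog = predict_ror(mx$fit, grid)),
            out("ror_map.csv"), row.names = FALSE)
  write.csv(data.frame(tss_replica = mx$tss$tss_replicas),
            out("tss_replicas.csv"), row.names = FALSE)

  scen <- stage("scenario", {
    baseline <- project_map(fit, grid)
    warming <- project_map(fit, grid, scenario_spec(config$scenario$delta_bio01, 1,
                                                    label = "warming"))
    mitig <- project_map(fit, grid,
                         scenario_spec(config$scenario$delta_bio01,
                                       config$scenario$pel_multiplier,
                                       label = "warming+reduction"))
    ch_warm <- categorize_changes(baseline, warming)
    ch_mitig <- categorize_changes(warming, mitig)
    list(baseline = baseline, warming = warming, mitig = mitig,
         change_warming = ch_warm, change_mitigation = ch_mitig,
         by_muni = summarize_by_group(ch_mitig, grid),
         profile = elevation_profile(
           list(baseline = baseline, warming = warming,
                `warming+reduction` = mitig), grid))
  })
  write.csv(scen$change_warming$summary, out("scenario_warming_summary.csv"),
            row.names = FALSE)
  write.csv(scen$change_mitigation$summary,
            out("scenario_mitigation_summary.csv"), row.names = FALSE)
  write.csv(scen$by_muni, out("municipality_summary.csv"), row.names = FALSE)
  write.csv(scen$profile, out("elevation_profile.csv"), row.names = FALSE)

  manifest <- list(
    package = "cacyreus",
    version = as.character(utils::packageVersion("cacyreus")),
    r_version = R.version.string,
    seed = seed,
    stage_seeds = setNames(as.list(vapply(1:8, sub_seed, 0L, seed = seed)),
                           c("landscape", "design", "counts", "opportunistic",
                             "gof", "background", "maxent", "tss")),
    settings = config[setdiff(names(config), "truth")],
    truth = list(beta = as.list(config$truth$beta),
                 alpha = as.list(config$truth$alpha),
                 mixture = config$truth$mixture,
                 psi = config$truth$psi, theta = config$truth$theta),
    best_model = spec_label(fit$spec),
    c_hat = gof$c_hat
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(grid = grid, design = design, counts = counts,
                 points = points, screen = screen, selection = sel,
                 gof = gof, fit = fit, maxent = mx, scenario = scen,
                 out_dir = out_dir))
}
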