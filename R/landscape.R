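#' Generate a synthetic Alpine landscape grid
#'
#' Builds a 250 m resolution grid emulating the structure of an Alpine valley
#' study area: an elevation gradient with smooth topographic noise, annual
#' mean temperature (`bio01`) decreasing with elevation at a fixed lapse
#' rate, temperature seasonality (`bio04`) with a mild elevation trend,
#' host-plant (Pelargonium) pot counts confined to clustered urban
#' "village" patches spread along the altitudinal gradient with a
#' valley-floor preference, the 8-neighbour host-plant sum (`pel_neigh`),
#' and woodland/ecotone/grassland cover fractions. Village pot abundance
#' rises with elevation, mirroring the census pattern in which the
#' heaviest Pelargonium displays were found in high mountain villages.
#'
#' Host plants only occur in urban cells: ornamental Pelargonium does not
#' naturalise in these landscapes, so every cell with `pel_abu > 0` carries
#' the `urban` flag. `bio01` is by default a deterministic lapse function of
#' elevation (`sea_level_temp - lapse_rate * elevation / 1000`), so it is
#' strictly decreasing in elevation; spatial roughness enters through the
#' elevation field itself. Set `bio01_noise_sd > 0` to add independent
#' temperature noise.
#'
#' @param n_rows,n_cols grid dimensions (each at least 3).
#' @param seed integer seed; the grid is deterministic given the seed.
#' @param elev_range numeric length-2, low < high elevation in metres.
#' @param lapse_rate temperature lapse rate in degrees C per km (default 6.5).
#' @param sea_level_temp annual mean temperature at 0 m, degrees C.
#' @param bio01_noise_sd sd of optional additive noise on `bio01` (default 0).
#' @param elev_noise_sd amplitude (m) of the smooth topographic noise.
#' @param n_villages number of urban village patches; default scales with
#'   grid area (about one per 80 cells).
#' @param village_radius Chebyshev radius of each urban patch, in cells.
#' @param pel_mean,pel_size negative-binomial mean and size for pot counts
#'   in urban cells (zeros allowed); the per-village mean is `pel_mean`
#'   scaled by an elevation-dependent factor in `[0.25, 1.75]`.
#' @param urban_open_frac,rural_open_frac total wood+eco+grass cover in
#'   urban and non-urban cells; both must lie in `[0, 1]`.
#' @return a `landscape_grid`: a data.frame with columns `cell_id, row, col,
#'   elevation, bio01, bio04, pel_abu, pel_neigh, wood, eco, grass,
#'   municipality, urban` and attributes `resolution_m`, `n_rows`, `n_cols`.
#' @export
#' @examples
#' g <- make_landscape(12, 12, seed = 1)
#' summary(g$bio01)
#' sum(g$pel_abu > 0)
make_landscape <- function(n_rows = 20, n_cols = 20, seed = 1,
                           elev_range = c(500, 2000),
                           lapse_rate = 6.5, sea_level_temp = 14,
                           bio01_noise_sd = 0, elev_noise_sd = 60,
                           n_villages = NULL, village_radius = 1,
                           pel_mean = 25, pel_size = 5,
                           urban_open_frac = 0.4, rural_open_frac = 0.95) {
  if (n_rows < 3 || n_cols < 3)
    stop_cfg("grid dimensions must be at least 3x3")
  if (length(elev_range) != 2 || elev_range[1] >= elev_range[2])
    stop_cfg("elev_range must be (low, high) with low < high")
  if (urban_open_frac < 0 || urban_open_frac > 1 ||
      rural_open_frac < 0 || rural_open_frac > 1)
    stop_cfg("invalid cover fractions: open fractions must lie in [0, 1]")
  n_villages <- n_villages %||% max(1L, round(n_rows * n_cols / 80))

  with_seed(seed, {
    rows <- rep(seq_len(n_rows), each = n_cols)
    cols <- rep(seq_len(n_cols), times = n_rows)
    n <- n_rows * n_cols

    # valley-to-ridge gradient along rows + smooth sinusoidal roughness
    base <- elev_range[1] +
      (elev_range[2] - elev_range[1]) * (rows - 1) / (n_rows - 1)
    ph <- runif(3, 0, 2 * pi)
    fr <- runif(3, 0.5, 2)
    noise <- elev_noise_sd * (
      sin(2 * pi * fr[1] * rows / n_rows + ph[1]) +
        sin(2 * pi * fr[2] * cols / n_cols + ph[2]) +
        0.5 * sin(2 * pi * fr[3] * (rows + cols) / (n_rows + n_cols) + ph[3])
    ) / 1.5
    elevation <- pmin(elev_range[2], pmax(elev_range[1], base + noise))

    bio01 <- sea_level_temp - lapse_rate * elevation / 1000
    if (bio01_noise_sd > 0) bio01 <- bio01 + rnorm(n, 0, bio01_noise_sd)
    bio04 <- 55 + 0.004 * elevation + rnorm(n, 0, 1)

    # village centres span the altitudinal gradient with a valley-floor
    # preference (Alpine municipalities sit from the valley bottom up to
    # ~1700 m, not only at the lowest elevations)
    eligible_centres <- which(elevation <= quantile(elevation, 0.85))
    wv <- exp(-(elevation[eligible_centres] -
                  min(elevation[eligible_centres])) / 500)
    centres <- sample(eligible_centres, min(n_villages, length(eligible_centres)),
                      prob = wv)
    urban <- logical(n)
    for (ct in centres) {
      sel <- abs(rows - rows[ct]) <= village_radius &
        abs(cols - cols[ct]) <= village_radius
      urban <- urban | sel
    }

    # each cell belongs to the municipality of its nearest village centre
    d2 <- outer(rows, rows[centres], "-")^2 + outer(cols, cols[centres], "-")^2
    municipality <- sprintf("muni_%02d", max.col(-d2, ties.method = "first"))

    # pot abundance rises with village elevation: high mountain resort
    # villages garden far more heavily than valley-floor towns (the
    # largest census counts came from the highest municipalities)
    vil_ez <- (elevation[centres] - elev_range[1]) / diff(elev_range)
    vil_mult <- 0.25 + 1.5 * vil_ez
    cell_vil <- max.col(-d2, ties.method = "first")
    pel_abu <- integer(n)
    pel_abu[urban] <- rnbinom(sum(urban),
                              mu = pel_mean * vil_mult[cell_vil[urban]],
                              size = pel_size)

    # land cover: elevation-dependent propensities, scaled by open fraction
    ez <- (elevation - elev_range[1]) / diff(elev_range)
    prop <- cbind(
      wood  = pmax(0.05, 1.2 * ez * (1 - ez) * 4 * 0.5 + 0.1),
      eco   = pmax(0.05, 0.3 - 0.1 * ez),
      grass = pmax(0.05, 0.15 + 0.6 * ez)
    )
    w <- prop * matrix(rgamma(3 * n, shape = 4, rate = 4), n, 3)
    frac <- w / rowSums(w) * ifelse(urban, urban_open_frac, rural_open_frac)

    grid <- data.frame(
      cell_id = sprintf("c%05d", seq_len(n)),
      row = rows, col = cols,
      elevation = elevation, bio01 = bio01, bio04 = bio04,
      pel_abu = pel_abu, pel_neigh = 0L,
      wood = frac[, "wood"], eco = frac[, "eco"], grass = frac[, "grass"],
      municipality = municipality, urban = urban,
      stringsAsFactors = FALSE
    )
    grid$pel_neigh <- compute_pel_neigh(grid)
    as_landscape_grid(grid, n_rows = n_rows, n_cols = n_cols)
  })
}

#' Recompute the neighbouring host-plant sum
#'
#' For every cell, sums `pel_abu` over the 8 cells of the 3x3 Moore
#' neighbourhood, excluding the focal cell and truncating at grid edges.
#'
#' @param grid a `landscape_grid` (or data.frame with `row`, `col`,
#'   `pel_abu`).
#' @return integer vector of neighbour sums, in `grid` row order.
#' @export
compute_pel_neigh <- function(grid) {
  nr <- max(grid$row)
  nc <- max(grid$col)
  m <- matrix(0L, nr, nc)
  m[cbind(grid$row, grid$col)] <- grid$pel_abu
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  as.integer(out[cbind(grid$row, grid$col)])
}

as_landscape_grid <- function(df, n_rows = max(df$row), n_cols = max(df$col),
                              resolution_m = 250) {
  validate_grid(df)
  structure(df,
    class = c("landscape_grid", "data.frame"),
    resolution_m = resolution_m, n_rows = n_rows, n_cols = n_cols
  )
}

validate_grid <- function(df) {
  needed <- c(
    "cell_id", "row", "col", "elevation", "bio01", "bio04",
    "pel_abu", "pel_neigh", "wood", "eco", "grass", "municipality", "urban"
  )
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop_cfg("grid is missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("row", "col")]))
    stop_cfg("grid (row, col) indices must be unique")
  if (any(df$pel_abu < 0) || any(df$pel_abu != round(df$pel_abu)))
    stop_cfg("pel_abu must be non-negative integers")
  if (any(df$pel_abu > 0 & !df$urban))
    stop_cfg("host plants outside urban cells: pel_abu > 0 requires urban = TRUE")
  cover <- df$wood + df$eco + df$grass
  if (any(df$wood < 0 | df$eco < 0 | df$grass < 0 | cover > 1 + 1e-9))
    stop_cfg("invalid cover fractions: wood/eco/grass must be >= 0 and sum to <= 1")
  invisible(df)
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "landscape_grid: %d x %d cells at %g m (%d urban, %d with host plants)\n",
    attr(x, "n_rows"), attr(x, "n_cols"), attr(x, "resolution_m"),
    sum(x$urban), sum(x$pel_abu > 0)
  ))
  cat(sprintf(
    "  elevation %.0f-%.0f m, bio01 %.1f-%.1f degC, %d pots total\n",
    min(x$elevation), max(x$elevation), min(x$bio01), max(x$bio01),
    sum(x$pel_abu)
  ))
  invisible(x)
}

# metric cell-centre coordinates (m), used for buffer distances
grid_xy <- function(grid) {
  res <- attr(grid, "resolution_m") %||% 250
  cbind(x = (grid$col - 0.5) * res, y = (grid$row - 0.5) * res)
}
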