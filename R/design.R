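#' Stratified random survey design over altitudinal bands
#'
#' Emulates the standardised egg-count protocol: the grid is split into
#' altitudinal bands (default 500-1000, 1000-1500, 1500-2000 m), a fixed
#' number of cells is drawn uniformly without replacement within each band,
#' and each selected cell receives the same number of repeat visits.
#'
#' @param grid a `landscape_grid`.
#' @param bands list (or 2-column matrix) of `(low_m, high_m)` elevation
#'   bands; a cell belongs to a band when `low <= elevation < high` (the
#'   last band is closed above).
#' @param n_per_band number of cells sampled in each band (default 25).
#' @param visits repeat visits per selected cell (default 3).
#' @param seed integer seed.
#' @param eligible optional logical vector (length `nrow(grid)`) or a
#'   function `grid -> logical` restricting the sampling frame, emulating
#'   the open-area/urban eligibility filter of the field protocol. Default:
#'   all cells eligible.
#' @return a `survey_design`: list with `sites` (data.frame `cell_id`,
#'   `band`), `bands`, `cells_per_band`, `visits_per_cell`, `seed`.
#' @export
#' @examples
#' g <- make_landscape(30, 30, seed = 2)
#' d <- stratified_design(g, n_per_band = 5, visits = 3, seed = 9)
#' table(d$sites$band)
stratified_design <- function(grid,
                              bands = list(c(500, 1000), c(1000, 1500), c(1500, 2000)),
                              n_per_band = 25, visits = 3, seed = 1,
                              eligible = NULL) {
  if (is.matrix(bands)) bands <- split(bands, seq_len(nrow(bands)))
  stopifnot(length(bands) >= 1, n_per_band >= 1, visits >= 1)
  ok <- if (is.null(eligible)) rep(TRUE, nrow(grid))
        else if (is.function(eligible)) eligible(grid)
        else as.logical(eligible)
  stopifnot(length(ok) == nrow(grid))

  with_seed(seed, {
    sites <- do.call(rbind, lapply(seq_along(bands), function(b) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      last <- b == length(bands)
      in_band <- ok & grid$elevation >= lo &
        (if (last) grid$elevation <= hi else grid$elevation < hi)
      idx <- which(in_band)
      if (length(idx) < n_per_band)
        stop_cfg(sprintf(
          "band %d (%g-%g m) has only %d eligible cell(s), need %d",
          b, lo, hi, length(idx), n_per_band
        ))
      data.frame(
        cell_id = grid$cell_id[sample(idx, n_per_band)],
        band = b, stringsAsFactors = FALSE
      )
    }))
    structure(
      list(
        sites = sites, bands = bands, cells_per_band = n_per_band,
        visits_per_cell = visits, seed = seed
      ),
      class = "survey_design"
    )
  })
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf(
    "survey_design: %d bands x %d cells x %d visits = %d sites, %d site-visits\n",
    length(x$bands), x$cells_per_band, x$visits_per_cell,
    nrow(x$sites), n_site_visits(x)
  ))
  invisible(x)
}

#' Total number of site-visits in a survey design
#' @param design a `survey_design`.
#' @return integer: sites times visits per site.
#' @export
n_site_visits <- function(design) nrow(design$sites) * design$visits_per_cell
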