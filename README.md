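# cacyreus

Distribution modelling for the geranium bronze (*Cacyreus marshalli*), the
only alien butterfly established in Europe. The species is strictly
dependent on ornamental *Pelargonium* pots, so in Alpine valleys it lives
in villages: its spread is driven by host-plant availability but capped by
cold temperatures at high elevation. `cacyreus` implements the full
analysis chain used to study such an invasion in a protected Alpine area,
for ecologists who want to fit these models to survey data or to stress
them on synthetic landscapes:

* **Synthetic landscapes and surveys** — a 250 m grid over a 500–2000 m
  elevation gradient, temperature from a lapse rate (6.5 °C/km), pot
  counts confined to clustered urban village patches, stratified random
  sampling of cells in altitudinal bands with repeat visits, egg counts
  generated by a zero-inflated N-mixture process, and spatially biased
  presence-only records.
* **Binomial N-mixture models** for repeated egg counts with imperfect
  detection. The latent egg abundance N_i of site i follows a Poisson (P),
  negative binomial (NB) or zero-inflated Poisson (ZIP) mixture with
  log λ_i = x_i′β, and each visit records y_ij ~ Binomial(N_i, p_i) with
  logit p_i = α0 + α1·pel_ava_i. The likelihood marginalizes N_i up to an
  adaptive truncation bound; fitting is by BFGS with analytic gradients
  (compiled core).
* **Model selection** by AICc (small-sample corrected), following the
  two-step workflow: detection structure first (at null abundance), then
  abundance covariates, then the abundance mixture.
* **Diagnostics** — parametric-bootstrap χ² goodness of fit, the
  overdispersion factor ĉ = χ²_obs / mean(χ²_boot), ĉ-inflated variance
  matrices, and residual tables.
* **Presence-only suitability** — a maximum-entropy (Gibbs density)
  model over presence + buffered background cells with linear/quadratic
  features and L1 regularization, reporting the relative occurrence rate
  (ROR), percent contributions, permutation importances, response curves
  and true-skill-statistic (TSS) evaluation under repeated 80/20 splits.
* **Scenario projection** — expected egg abundance per cell under a
  climate-warming shift (+1.5 °C) and/or a host-plant reduction (e.g.
  −50% pots), with per-cell change categories (increase / decrease /
  no change / new infestation), municipality summaries and elevation
  profiles.

## Worked example

```r
library(cacyreus)

# a 30 x 30 synthetic Alpine valley with villages and Pelargonium pots
grid <- make_landscape(30, 30, seed = 42, n_villages = 8)
grid
#> landscape_grid: 30 x 30 cells at 250 m (66 urban, 66 with host plants)
#>   elevation 500-2000 m, bio01 1.0-10.8 degC, 1193 pots total

# stratified egg-count survey: 3 altitudinal bands x 25 cells x 3 visits
design <- stratified_design(grid, n_per_band = 25, visits = 3, seed = 42)
counts <- simulate_counts(grid, design, default_truth(), seed = 42)
counts
#> count_data: 75 sites x 3 visits, 1584 eggs counted, 58% zero counts

# fit the egg-abundance model with imperfect detection
counts <- standardize(counts)
fit <- fit_nmix(counts, nmix_spec(
  abundance = c("bio01", "pel_abu", "bio01:pel_abu", "pel_neigh"),
  detection = "pel_ava", mixture = "ZIP"))
fit
#> N-mixture fit: p(pel_ava) lambda(bio01 + pel_abu + bio01:pel_abu + pel_neigh) [ZIP]
#>                   estimate     se
#> lam:(Intercept)     2.6853 0.5812
#> lam:bio01           0.4176 0.0845
#> lam:pel_abu         0.6289 0.1232
#> lam:pel_neigh      -0.3833 0.0780
#> lam:bio01:pel_abu   0.6559 0.0798
#> det:(Intercept)    -2.1319 0.6272
#> det:pel_ava        -0.0003 0.1002
#> psi(logit)         -0.2173 0.2425
#> logLik -256.750 | K 8 | M 75 | AICc 531.68 | K_trunc 5776 | converged

# parametric-bootstrap goodness of fit and overdispersion
gof <- gof_bootstrap(fit, counts, replicates = 200, seed = 42)
gof
#> parametric-bootstrap GOF: chisq = 869.04, p = 0.657, c-hat = 0.000 (200 reps)
fit <- inflate_vcov(fit, gof$c_hat)

# project a +1.5 degC scenario over the host-plant cells
baseline <- project_map(fit, grid)
warming  <- project_map(fit, grid, scenario_spec(1.5, 1, label = "+1.5 degC"))
categorize_changes(baseline, warming)
#> scenario change summary over 66 cells:
#>         category  n percent
#>          changed 65    98.5
#>         increase 65    98.5
#>         decrease  0     0.0
#>  new_infestation  6     9.1
#>        no_change  1     1.5
```

Reading the output: temperature (`bio01`), host-plant pots (`pel_abu`) and
their synergy raise expected egg abundance, while pots in neighbouring
cells (`pel_neigh`) pull eggs away from the focal cell; `pel_ava` drives
how detectable the eggs are on a visit. The bootstrap p-value (0.657) says
the ZIP model is consistent with its own data-generating assumptions here;
a p-value near 0 would flag lack of fit. With a +1.5 °C warming nearly all
host-plant cells gain eggs, and a handful of previously egg-free cells
become newly infested — the same qualitative pattern reported for the real
system. (At this small scale mean-based ĉ is dominated by the bootstrap's
heavy tail and no variance inflation is applied; see the methods
vignette.)

The presence-only side is driven the same way:

```r
pts <- simulate_opportunistic(grid, default_truth(), n_points = 138, seed = 1)
occ <- sample_background(grid, unique(pts$cell_id), buffer_km = 2.5,
                         n_background = 500, seed = 2)
mx <- fit_maxent(grid, occ, c("bio01", "bio04", "pel_abu", "pel_neigh"))
evaluate_tss(grid, occ, c("bio01", "bio04", "pel_abu", "pel_neigh"),
             splits = 20, seed = 3)
```

`run_pipeline(pipeline_config(seed = 1))` chains every stage —
simulate → screen → select → diagnose → suitability → scenarios — and
writes all tables (selection tables, coefficients, GOF, contributions,
ROR map, change summaries, elevation profiles) plus a manifest as CSV/JSON
into a run directory.

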