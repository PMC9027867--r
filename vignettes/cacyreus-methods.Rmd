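---
title: "Models and methods in cacyreus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cacyreus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cacyreus` models the distribution of a host-plant-obligate alien
butterfly in Alpine valleys from two kinds of data: repeated egg counts
collected under a stratified survey protocol, and opportunistic
presence-only records. This vignette is the package's account of the
models, the synthetic data they are exercised on, and the numerical and
design choices behind the implementation.

## The N-mixture model

Egg counts are modelled hierarchically. Site $i$ holds a latent egg
abundance $N_i$ drawn from an abundance mixture with mean
$\log \lambda_i = x_i'\beta$; visit $j$ records
$y_{ij} \sim \mathrm{Binomial}(N_i, p_i)$ with
$\mathrm{logit}\, p_i = w_i'\alpha$. Three mixtures are supported for
$N_i$: Poisson (P), negative binomial (NB; mean $\lambda$, dispersion
$\theta$, variance $\lambda + \lambda^2/\theta$, $\theta$ estimated on the
log scale), and zero-inflated Poisson (ZIP; extra mass $\psi$ at zero,
$\psi$ a scalar on the logit scale with no covariates — the conventional
choice, since nothing in the data motivates structured zero inflation).

The likelihood marginalizes $N_i$ from $\max_j y_{ij}$ up to a truncation
bound $K$. The implementation (compiled, with analytic gradients) uses
one-step recurrences in $N$ and a streaming log-sum-exp that stops once
terms fall 46 nats below the running maximum; because the summand is
log-concave in $N$ (apart from the ZIP spike at zero), the neglected tail
is bounded by $K e^{-46}$ in relative terms. $K$ is chosen adaptively as
the smallest bound at which 50 additional latent classes change the
log-likelihood by less than $10^{-8}$ (cap 25 000), and the optimum is
re-polished if the bound grows past the one used during optimization.

Key model assumptions — population closure across the repeat visits
within a flight generation, no false positives, independent and
homogeneous detection of individual eggs — are properties of the survey
protocol, not of the code; when closure is doubtful the estimates read as
"eggs present during the sampling period" rather than absolute abundance.

**Fitting.** BFGS from documented starts (abundance intercept at
$\log(\overline{\max_j y_{ij}} + 0.5)$, everything else at 0), relative
tolerance $10^{-10}$, at most 500 iterations; the variance matrix is the
inverse observed information at the optimum. A fit is `converged` when
the optimizer reports success and the information matrix is positive
definite. Bootstrap refits skip the information matrix (`hessian =
FALSE`): they only need fitted values, and a ridge-flat Hessian does not
invalidate those.

**Selection.** Models are ranked by AICc,
$-2\ell + 2K + 2K(K+1)/(n-K-1)$, with $n$ equal to the number of sites —
the site is the independent replicate. The two-step workflow first tests
detection structures at null abundance (Poisson), then ranks abundance
structures with the winning detection held fixed, then refits the winner
under P/NB/ZIP. A lead of more than 2 AICc units decides outright; closer
calls are reported as ties and resolved by parsimony (fewest parameters).
Candidates whose fit does not converge are excluded from ranking, with a
message. Before any fitting, covariates are screened by pairwise Pearson
correlation (drop threshold $|r| \ge 0.7$; greedy removal of the member
with the larger mean $|r|$, ties to the later candidate) and then scaled
and centred; the means and standard deviations are recorded so that
scenario projections can re-standardize shifted covariates with the
training statistics.

## Goodness of fit and overdispersion

The fit statistic is the site-visit chi-square
$\sum_{ij} (y_{ij} - \hat y_{ij})^2 / (\hat y_{ij} + 10^{-6})$ with
$\hat y_{ij} = \widehat{E}[N_i]\,\hat p_i$; the $10^{-6}$ guard keeps
near-zero fitted cells finite, and the statistic is kept at the
site-visit level so that it decomposes into the Pearson residuals of the
diagnostic table. A parametric bootstrap (default 1000 replicates;
package tests use 200) simulates data from the fitted model over the same
design, refits the same specification warm-started at the parent
estimates, and recomputes the statistic. The p-value is the proportion of
replicate statistics at least as large as the observed one, and
$\hat c = \chi^2_{\mathrm{obs}} / \mathrm{mean}(\chi^2_{\mathrm{boot}})$.
Replicates whose refit fails outright are excluded — their fitted values
are arbitrary, so their statistic is not a draw from the null — and more
than 20% exclusions flags the whole result unreliable. When
$\hat c > 1$, the variance matrix may be multiplied by $\hat c$
(standard errors scale by $\sqrt{\hat c}$); $\hat c \le 1$ never
deflates. A warning is printed when $\hat c > 2$, a conventional marker
of substantial extra-model variance.

A caveat the package makes visible rather than hides: at small $M$ with a
ZIP mixture and strong covariate effects, the bootstrap null distribution
of this chi-square is heavy-tailed (occasional replicates place enormous
mass on a near-empty cell), so the *mean*-based $\hat c$ can collapse
toward zero even when the rank-based p-value is well behaved. Read
$\hat c$ together with the p-value, and at demo scales trust the p-value.

## The presence-only suitability model

Presence-only records are modelled as a maximum-entropy (Gibbs) density
over cells: $q(c) \propto \exp(f(c)'w)$, normalized over the presence +
background set, with features the min–max-scaled covariates and their
squares (hinge features are deliberately omitted: linear + quadratic keeps
the small-sample fits deterministic and stable). Background cells are
drawn uniformly within 2.5 km (Euclidean, cell centres, 250 m pitch) of a
presence — a restricted background that mirrors the accessibility bias of
opportunistic recording. Weights maximize the presence log-likelihood
penalized by $\mathrm{reg} \times \mathrm{sd}(f_j)/\sqrt{m}$ per feature
(L1), trained by coordinate-wise proximal Newton steps with halving line
search. Percent contribution accumulates each feature's penalized-gain
increments along the training path; permutation importance is the AUC
drop when a covariate's values are permuted across presence + background
(averaged over 5 permutations); both are normalized to sum to 100, giving
the two conventional columns of a contributions table.

The raw output (relative occurrence rate, ROR) sums to one over the
training normalization set; the cloglog transform
$1 - \exp(-e^{\eta - \log Z + H})$ (with $H$ the entropy of the raw
density) maps suitability to $[0,1]$ for mapping. Covariates outside the
training range are clamped, with a message. Evaluation runs repeated
train–test replicas: presences split 80/20, a fresh background sample per
replica (the natural reading of an ambiguous protocol), threshold chosen
to maximize training TSS over midpoint candidates (ties to the smallest
threshold, which maximizes the margin on the low side), and TSS =
sensitivity + specificity − 1 scored on held-out presences versus held-out
background. The full-data TSS is evaluated within-sample and labelled as
such. Scenario projection through the suitability model is deliberately
out of scope: with a host-obligate species the suitability surface is
dominated by the host covariate and adds no scenario information beyond
the abundance model.

## Scenario engine

Scenarios act on the *unscaled* covariates — an additive temperature
shift (default +1.5 °C, the mid-century Alpine projection under a
low-emission pathway) and a host-plant multiplier (default 0.5, an
awareness-campaign reduction) — after which covariates are re-standardized
with the training scaling record and pushed through the fitted model.
When the multiplier changes pot counts and the grid topology is loaded,
the neighbour sum is recomputed from the modified counts (halving pots
halves what neighbours see); a flag allows plain multiplication instead,
since the corresponding field protocol is ambiguous on this point.
Projections default to cells holding host plants at baseline — the
butterfly is a strict Pelargonium obligate — with a switch to project
everywhere.

Change classification first rounds expected abundances half-up to whole
eggs (eggs are integers; sub-egg float drift must not register as
change), then compares: increase, decrease, no change, and — as a
sub-category of increase — "new infestation" when a rounded baseline of 0
becomes at least 1. Increases, decreases and no-change partition the
cells; new infestations are reported separately and also counted among
increases. Summaries by municipality are sorted by mean elevation so
altitudinal countertrends are visible at a glance; elevation profiles use
equal-width binned means (a smoother would add tuning without adding
information at these cell counts) and retain extreme values.

## What the synthetic landscape emulates — and what it does not

The generator reproduces the statistical structure the analysis assumes:
a 250 m grid over a 500–2000 m gradient; temperature as a deterministic
lapse (6.5 °C/km from a 14 °C sea-level mean) of a smoothly noisy
elevation field, so temperature is strictly decreasing in elevation while
remaining spatially smooth (an optional independent temperature noise
term exists, default off); seasonality with a mild elevation trend;
urban village patches spread along the gradient with a valley-floor
preference, pot counts only in urban cells, and per-village pot abundance
*rising* with elevation — high mountain resort villages garden most
heavily, which is also what keeps the warm-and-pot-rich corner of
covariate space rare, as it is in the real census. Within a village, pot
counts are negative binomial with moderate dispersion (size 5, mean 25
scaled by the elevation factor in [0.25, 1.75]); cover fractions come
from elevation-dependent propensities scaled to the open fraction of the
cell. Surveys draw a fixed number of cells uniformly within each
altitudinal band (default 3 bands × 25 cells × 3 visits); an eligibility
filter (e.g. open-area or urban-only frames) is available as a
configuration hook rather than an exact reproduction of any field rule.

Egg counts follow the ZIP N-mixture process exactly, with one biological
guard: the expected abundance is capped at 5000 eggs per cell, because a
loglinear rate extrapolated into an extreme covariate corner would
otherwise predict tens of thousands of eggs in a 250 m cell — more than
its plants could carry. The default "truth" is the package's reference
coefficient vector (`default_truth()`): abundance intercept 3.095,
temperature 0.446, pots 0.320, neighbouring pots −0.343,
temperature×pots 0.592 on the log scale over standardized covariates;
detection intercept −2.632 and pot availability 0.399 on the logit scale;
zero inflation 0.5 (a fixture choice; nothing pins it). The detection
covariate (pots accessible during a survey) is a site-level binomial
thinning of the cell's pots, constant across visits.

Opportunistic presences are sampled with probability proportional to the
occupancy probability $1 - e^{-E[N]}$ times an accessibility factor
(higher in urban and low-elevation cells), restricted to pot-holding
cells. Two deliberate departures from a literal
"proportional-to-abundance" sampler are worth recording: expected
abundance spans many orders of magnitude under the reference
coefficients, so a literal sampler collapses every record onto one or two
super-infested cells, whereas sightings of a butterfly saturate once the
species is present at all — the occupancy link restores the realistic
spread of records across many cells; and the host restriction reflects
that every real occurrence fell in a pot-holding cell.

What passing tests on these landscapes does **not** show: robustness to
spatial autocorrelation in the counts beyond what covariates induce, to
visit-varying detection, to open populations (births/deaths between
visits), to false positives, or to observer heterogeneity — none of which
the generator produces, because none are in the model.

## Simulation evidence and its limits

The test suite runs, at fixed seeds, the studies a reviewer would ask
for, scaled to a single CPU: likelihood agreement with a brute-force
enumeration oracle on 100 random small instances (tolerance $10^{-10}$;
the oracle multiplies raw probabilities, the implementation works in log
space with recurrences); a 200-replicate parameter-recovery study at 300
sites × 3 visits from the reference ZIP truth; a 500-simulation
calibration of the bootstrap GOF test (200 replicates each, 40 sites,
Poisson); 50 replicates of the two-step selection at 300 sites; and the
separability, normalization and monotonicity checks of the suitability
and scenario modules. Sizes were chosen so each study carries real Monte
Carlo resolution while the whole suite stays a desk-scale run.

One recovery result deserves its own paragraph. With detection around
$p \approx 0.07$ and three visits, the abundance and detection
*intercepts* of an N-mixture model sit on a nearly flat likelihood ridge
(raising $\lambda$ while lowering $p$ changes the likelihood little);
this is a documented property of binomial N-mixture models at low
detection, not an optimizer artifact — restarting at the generating
values finds the same optimum, and the generating values score several
log-likelihood units worse than the MLE on typical replicates. In the
package's recovery study the slope coefficients and $\psi$ recover with
small median bias and honest interval coverage, while the two intercepts
are median-biased on the order of a quarter of a unit with coverage still
near nominal. Users who need absolute abundance at the covariate origin
should treat it with corresponding caution; effects and scenario
*contrasts*, which depend on the slopes, are the reliable outputs.

## Interfaces

All functionality is exposed as documented R functions;
`run_pipeline()` orchestrates the full chain from one seeded
configuration (each stage derives its own seed from the master seed, and
no stage touches the global RNG state) and writes every table as CSV plus
a JSON manifest recording versions, seeds and settings.
`scripts/acceptance.R` is the command-line entry point for reproducing
the headline numbers; a shell-level subcommand interface would add
surface without adding capability for an analysis package whose users
work in R.

## Known limitations

* No spatial autocorrelation terms, no open-population dynamics, no
  Bayesian fitting.
* $\hat c$ is mean-based by construction and unstable at small scales
  (see above); no alternative GOF statistics are offered.
* The maxent implementation restricts itself to linear + quadratic
  features; background size, regularization and feature defaults are
  package choices where the original protocols are silent.
* The landscape generator is a statistical emulator, not a GIS: no real
  habitat maps, no georeferencing beyond grid indices.
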