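---
title: "Estimating spatial synchrony in fitness-related traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spatial synchrony in fitness-related traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitsync)
```

## The problem

Long-term nest-box monitoring of hole-nesting passerines (blue tit, great
tit, pied flycatcher) yields, for each population and breeding season,
annual average values of fitness-related traits: median laying date, mean
clutch size, mean fledgling number. Year-to-year fluctuations of these
values are often correlated between populations hundreds of kilometres
apart. Quantifying that *spatial synchrony* — how strong it is at short
distances, whether a region-wide component remains at long distances, and
over what spatial scale it decays — is the goal of this package, together
with measuring how much of it a climatic driver (spring temperature or
precipitation) can account for: a Moran effect acting on trait values
rather than on abundances.

## The model

Let $\tilde{y}_{it}$ be the detrended, normalized annual average trait
value of population $i$ in year $t$. We assume the vector of values
available in year $t$ follows a zero-mean multivariate normal
distribution, $\tilde{Y}_t \sim \mathrm{MVN}(0, \Sigma_t)$, with unit
variances and pairwise correlations given by a Gaussian correlogram in the
inter-population distance $d_{ij}$ (km):

$$\rho(d) = \rho_\infty + (\rho_0 - \rho_\infty)\, e^{-d^2 / (2\,l^2)}.$$

* $\rho_0 \in [0, 1]$ — correlation as distance approaches zero. With
  unit diagonals, $1 - \rho_0$ is a nugget: purely local variability
  (measurement noise, micro-habitat) that is not shared even by adjacent
  populations.
* $\rho_\infty \in [0, \rho_0]$ — correlation at infinite distance: a
  fully regional shared component (e.g. continent-scale weather indices).
* $l > 0$ (km) — the standard deviation of the Gaussian decay kernel: the
  characteristic distance over which fluctuations remain correlated.

The correlation matrix decomposes as $\rho_\infty J + (\rho_0 -
\rho_\infty) K + (1 - \rho_0) I$ with $J$ the all-ones matrix and $K$ a
Gaussian kernel matrix, so it is positive semidefinite for every valid
parameter set and site layout — the property tests assert this on
randomized draws.

Monitoring schemes start and stop in different years, so the set of
available populations varies by year. The total log-likelihood is the sum
of annual log-likelihoods, each evaluated on that year's availability
subset of $\Sigma$. No explicit overlap weighting is needed: pairs of
populations with long joint coverage simply contribute more annual terms,
which is how overlap earns its influence on the estimates. Years with a
single available population contribute a parameter-free standard-normal
term; we include it (rather than skipping the year) so that total
log-likelihoods are comparable across parameter values, which leaves the
maximizer unchanged.

## Preprocessing

Brood records enter the analysis only if they are first clutches, were not
experimentally manipulated, and carry the target trait; for the fledgling
traits, broods with zero fledglings are excluded so that fledgling number
reflects parental effort rather than complete brood loss. Population-years
with fewer than 2 remaining broods are dropped (re-checked *after* the
row-level exclusions), and populations with fewer than 9 observed years
are excluded (both thresholds configurable). Laying date is aggregated by
the annual median — within-year laying-date distributions are typically
right-skewed — with the even-count median taken as the mean of the two
middle values; the other traits use arithmetic means, and fledgling
success is the mean of per-brood `fledglings / clutch size`.

Each population's series is then detrended by ordinary least squares
against calendar year and scaled to unit sample standard deviation
(`n - 1` denominator throughout), so synchrony reflects shared
year-to-year fluctuation, not shared long-term trends or level
differences. Detrending needs at least 3 observed years and fails loudly
on exactly-linear (zero-residual-variance) series. We normalize by the
*residual* SD, the standard reading of "detrended and normalized";
normalizing by the pre-detrending SD would only shrink all values of a
population by a common factor and reintroduce trend-size dependence.

Daily climate series are collapsed to annual means over a February–May
window (the period before and during breeding), 120 calendar days in
ordinary years and 121 in leap years. Because real station series have
gaps — the original gridded product did not — a year is kept if at most
10% of its window days are missing.

## Estimation

`fit_synchrony()` maximizes the total log-likelihood over $0 \le
\rho_\infty \le \rho_0 \le 1$, $0 < l \le l_{\max}$. The optimizer works
in unconstrained coordinates — $\rho_0 = \mathrm{logit}^{-1}(u_1)$,
$\rho_\infty = \rho_0\,\mathrm{logit}^{-1}(u_2)$ (enforcing the ordering),
$l = l_{\max}\,\mathrm{logit}^{-1}(u_3)$ — and runs derivative-free
Nelder–Mead searches from 10 Latin-hypercube starting points, because the
surface can be multimodal when few site pairs are informative about $l$.
The default $l_{\max}$ is 5 times the maximum pairwise distance: beyond
that the data cannot distinguish a large $l$ from a flat correlogram, and
unbounded $l$ diverges on flat surfaces. Boundary estimates are legitimate
and reported as-is; in practice $\hat\rho_\infty = 0$ occurs regularly
(the logistic transform saturates to exact 0 in double precision).
Numerically singular year covariances (co-located sites with $\rho_0 \to
1$) get a $10^{-8}$ ridge and a warning. Each year-specific likelihood
term is computed from one Cholesky factorization per distinct availability
pattern, so complete panels cost a single factorization per evaluation.

Identifiability caveat: for data with no synchrony the likelihood is flat
in $\rho_0$ once $l$ falls below the smallest pairwise distance (any
$\rho_0$ with tiny $l$ yields the identity correlation at all observed
distances). Statements about "no synchrony" should therefore be read off
the fitted correlogram at observed distances, not off $\hat\rho_0$ alone.

## Uncertainty: parametric bootstrap

`parametric_bootstrap()` simulates each replicate dataset from the fitted
model, year by year, restricted to the *observed* annual availability
sets, and refits it with the same multi-start protocol. Medians and
percentile 2.5/97.5 intervals over replicates summarize the distribution
(percentile, not BCa — the plain quantiles of the replicate distribution
are what the method's users report, and the bootstrap median doubles as
the headline estimate). The full protocol uses $B = 2000$ replicates; the
examples and tests scale $B$ down. All randomness flows from one master
seed: $B$ sub-seeds are drawn once, and replicate $b$ uses sub-seed $b$
for both its data simulation and its refit start design, so results are
reproducible and independent of evaluation order. Replicates whose refit
fails are dropped and counted; more than 20% failures aborts with an
error rather than reporting a silently biased interval.

## Climate adjustment

`residualize_on_climate()` regresses, per population, the annual average
trait values on the population's seasonal climate means (OLS, intercept +
slope; climate z-scored per population first) and normalizes the
residuals. `compare_synchrony()` fits the synchrony model before and after
this adjustment on the identical population set and distance matrix, and
reports the drop in fitted correlation across a distance grid with a
bootstrap band (raw minus adjusted, paired by replicate index). If a
spatially autocorrelated climate field drives the trait, the adjusted
correlogram drops toward the synchrony of the residual field.

The source material describes detrending for the raw synchrony analysis
and regression *on climate* for the adjusted one, leaving open whether the
climate regression also included a year term. The default follows the
literal reading (climate only); `include_year = TRUE` runs the joint
regression instead. The choice matters whenever trait trends and climate
trends diverge. The raw fit always sees detrended series, but a
climate-only regression cannot remove a trait trend the climate variable
does not carry — and populations of the same species tend to share their
trend direction (e.g. advancing laying dates), so the leftover trend acts
as a *shared* component that re-synchronizes the adjusted panel and masks
the climate contribution. The synthetic-study analysis script demonstrates
this: with identical trends across populations and a trend-free climate
field, the climate-only adjustment removes almost nothing while the joint
regression recovers the residual field's synchrony. Conversely, with a
strongly trending climate (warming springs) the joint regression is the
more conservative attribution, since the year term can absorb trend-borne
covariation that the climate slope would otherwise claim.

## Synthetic data

`simulation_scenario()` + `generate_panel()` generate studies with known
truth: sites uniform in a planar region or lat/lon box, annual latent
fields drawn i.i.d. across years from the model (matching the model's
assumption for detrended series; an AR(1) knob is deliberately absent —
temporal autocorrelation beyond a linear trend is a known limitation, see
below), per-population means, linear trends and SDs, independent thinning
plus per-population observation windows for missingness, and optionally a
spatially autocorrelated climate field with per-population slopes
(`trait = mean + trend + beta * C + sd * e`). Trait-unit defaults used in
the analysis scripts (laying-date SD ≈ 3–5 days, trends ≈ −0.15 days/yr)
are realistic magnitudes for these species, chosen once; they are inputs,
not estimates. The latent field is returned complete even where the
observable panel is masked, enabling exact oracle comparisons, and the raw
panel's mask is exactly the mask handed to the bootstrap (round-trip
identity, tested). `simulate_broods()` additionally expands annual values
into a minimal brood table (no within-season skew, no brood-level
covariance) solely to exercise the record-level filters.

What passing tests on these data do *not* show about real data: real
trait panels have right-skewed within-year distributions entering the
annual medians, temporally autocorrelated climate drivers, observation
error that varies with brood counts, and non-Gaussian tails — none of
which the generator emulates. The recovery results establish correctness
of the estimator under its own assumptions, not robustness to their
violation.

## Numerical choices and problem sizes

* Nelder–Mead relative tolerance $10^{-8}$, max 500 iterations, 10 starts
  (6 or fewer in some scaled-down tests); fits are deterministic given the
  start seed.
* Ridge $10^{-8}$ on singular year covariances, with a warning.
* Sample SD with $n - 1$ denominator everywhere.
* Distances: great-circle (haversine) on a 6371.0 km radius sphere for
  lat/lon coordinates; Euclidean km for planar simulated layouts.
* The test suite runs recovery at 60 replicates per regime (31–35 sites,
  30 complete years) and interval coverage at 24 outer replicates with
  $B = 80$; `scripts/acceptance.R` runs the recovery protocol at 200
  replicates. These sizes keep the whole suite at a few minutes while
  leaving Monte-Carlo error well inside the asserted tolerances.

## Worked example

```{r example, eval = FALSE}
layout <- generate_sites(25, c(2000, 2000), seed = 1)
panel <- simulate_mvn_panel(synchrony_params(0.8, 0.26, 250),
                            matrix(TRUE, 25, 30), layout$D)
fit <- fit_synchrony(panel, layout$D)
boot <- parametric_bootstrap(fit$params, panel$mask, layout$D,
                             B = 200, seed = 2)
boot
plot_correlogram(boot, pairwise_empirical_correlations(panel, layout$D))
```

## Known limitations

* Temporal structure beyond a linear trend (AR(1) year effects, decadal
  cycles) is neither modelled nor removed; shared smooth variation
  inflates apparent synchrony.
* The correlogram is isotropic and restricted to non-negative
  correlations; genuinely negative long-distance correlations are
  truncated at $\rho_\infty = 0$.
* One climate variable per adjustment; joint multi-variable attribution is
  out of scope.
* The annual cross-sections are treated as independent given the model,
  so the likelihood ignores estimation error in the annual averages
  themselves (a population-year built from 2 broods counts as much as one
  built from 200).
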