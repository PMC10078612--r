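# traitsync

Spatial synchrony in fitness-related traits of long-term monitored bird
populations.

Populations of hole-nesting passerines (blue tits, great tits, pied
flycatchers) monitored in nest-box schemes across Europe show correlated
year-to-year fluctuations in laying date, clutch size and fledgling
number, even when separated by hundreds of kilometres. `traitsync`
estimates that synchrony, its spatial scale, and how much of it a climatic
driver (mean spring temperature or precipitation) accounts for — a Moran
effect acting on trait values. It is aimed at ecologists working with
multi-population, multi-decade breeding records.

## The model

Detrended, normalized annual average trait values of the populations
available in year *t* are modelled as

&nbsp;&nbsp;&nbsp;&nbsp;*Ỹ<sub>t</sub>* ~ MVN(0, Σ<sub>t</sub>),

with unit diagonal and pairwise correlations following a Gaussian
correlogram in distance *d* (km):

&nbsp;&nbsp;&nbsp;&nbsp;ρ(d) = ρ<sub>∞</sub> + (ρ<sub>0</sub> − ρ<sub>∞</sub>) · exp(−d² / 2l²)

* **ρ<sub>0</sub>** — correlation at zero distance (1 − ρ<sub>0</sub> is a
  local nugget);
* **ρ<sub>∞</sub>** — region-wide correlation floor at large distance;
* **l** — spatial scale (km): the SD of the Gaussian decay kernel, the
  characteristic distance over which fluctuations stay correlated.

The total log-likelihood sums the annual MVN log-densities over each
year's availability subset (schemes start and stop in different years) and
is maximized under 0 ≤ ρ<sub>∞</sub> ≤ ρ<sub>0</sub> ≤ 1 with multi-start
Nelder–Mead. Uncertainty comes from a parametric bootstrap that re-simulates
data from the fitted model on the observed availability pattern and refits.
Climate contribution is measured by regressing each population's annual
trait values on its seasonal (February–May) climate means, normalizing the
residuals, and refitting the synchrony model.

## Worked example

Simulate a complete 25-site, 30-year study from a known correlogram and
recover it:

```r
library(traitsync)
layout <- generate_sites(25, c(2000, 2000), seed = 1)
panel  <- withr::with_seed(2, simulate_mvn_panel(
  synchrony_params(0.8, 0.26, 250), matrix(TRUE, 25, 30), layout$D))
fit  <- fit_synchrony(panel, layout$D)
boot <- parametric_bootstrap(fit$params, panel$mask, layout$D, B = 200, seed = 3)
boot
#> Synchrony fit (parametric bootstrap, 200/200 replicates)
#>         rho0 rho_inf    l_km
#> point  0.786   0.294 254.840
#> median 0.789   0.292 255.787
#> 2.5%   0.719   0.205 216.049
#> 97.5%  0.845   0.369 301.538
```

The point estimates (ρ̂<sub>0</sub> = 0.786, ρ̂<sub>∞</sub> = 0.294,
l̂ = 255 km) sit close to the generating truth (0.8, 0.26, 250 km), and the
bootstrap 95% intervals bracket all three. `plot_correlogram(boot, ...)`
draws the fitted decay curve with its band over the model-free pairwise
correlations.

For real data, `run_pipeline(pipeline_config(...))` drives the whole
chain from brood CSVs (record filtering → annual aggregation → detrending
→ fit → bootstrap → climate comparison) and writes fit JSONs, correlogram
and pairwise CSVs, figures and a manifest.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the study design on synthetic
data end to end:

1. `01_simulate_study.R` — a 31-population European-layout study with a
   temperature-driven laying-date-like trait, emitted as brood/site/climate
   CSVs plus the generating truth.
2. `02_fit_synchrony.R` — the full pipeline on those files, including the
   before/after-temperature comparison.
3. `03_parameter_recovery.R` — recovery table across the four published
   parameter regimes (`results/parameter_recovery.csv`).

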