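# flptools

Tools for analysing **food-loss percentages (FLP)** — the share of available
food lost in a (country, year, commodity, supply-chain activity) cell, on a
0–100 scale — across countries at different development levels.

Food loss concentrates at different supply-chain stages depending on a
country's economic and institutional capacity: downstream (retail,
consumption) in high-income economies, upstream (harvest, storage,
transport) in lower-income ones. Quantifying that pattern requires (a) a
defensible, data-driven split of countries into "developed" and
"developing" rather than an off-the-shelf income class, and (b) models of
FLP that separate development effects and time trends from persistent
country-level idiosyncrasies. `flptools` provides both, for analysts
working with World-Bank-style indicator panels and FAO-style food-loss
records, plus a seeded synthetic-data generator so the whole pipeline is
testable offline.

## The method

**Stage 1 — temporally weighted typology.** Each country's history of GDP
per capita, GDP growth rate and health expenditure per capita is collapsed
to an exponentially weighted mean over its observed years $T$:

$$w_t = \frac{e^{\lambda [t - \min(T)]}}{\sum_{s \in T} e^{\lambda [s - \min(T)]}},$$

so larger decay $\lambda$ emphasizes recent years ($\lambda = 0$ is the
uniform limit). The weighted, z-standardized profiles are clustered by
restarted K-means (k-means++ seeding, best of 50 by WCSS); the cluster with
the higher GDP-per-capita centroid is always labelled *developed*. The
decay parameter is chosen by a sensitivity analysis over
$\lambda \in \{0, 0.05, \dots, 0.5\}$: per $\lambda$ the mean silhouette
width and suggested optimal $k$ (argmax silhouette over $k = 2,\dots,6$)
are computed, label agreement against a reference $\lambda$ is measured,
and countries whose label flips anywhere on the grid are reported as
*borderline* (hybrid) economies. An elbow (WCSS) curve provides a second
check on the cluster count.

**Stage 2 — random-intercept mixed models.** Within each commodity group
and each supply-chain stage,

$$\mathrm{FLP}_{c,t} = \beta_0 + \beta_1 D_c + \beta_2 (t - 2000) + u_c + \varepsilon_{c,t},$$

with $D_c = 1$ for developing countries, $u_c \sim N(0, \sigma_u^2)$ a
country random intercept and $\varepsilon \sim N(0, \sigma_e^2)$, fitted by
maximum likelihood (profiled over the variance ratio; see the vignette).
The package reports Wald tests of the development contrast ($\beta_1$) and
the year trend ($\beta_2$), variance components, and Nakagawa-style
marginal / conditional R². Descriptive group means and per-group OLS
trends complete the reporting surface.

## Worked example

```r
library(flptools)

# 105 synthetic countries (13 developed / 92 developing by construction)
sim  <- generate_indicator_panel(indicator_sim_config(seed = 20))
prof <- weighted_profiles(sim$panel, lambda = 0.2)
fit  <- kmeans_fit(prof, k = 2, restarts = 50, seed = 1)
print(fit)
#> K-means typology (k = 2, lambda = 0.2)
#>   WCSS 87.5925, mean silhouette 0.7650
#>
#>  developed developing
#>         13         92
round(fit$centroids, 1)
#>             gdp_pc health_pc growth
#> developed  56071.5    5205.2    1.1
#> developing  5083.5     274.8    3.2
```

The two-cluster solution separates cleanly (mean silhouette 0.77) and
recovers the generative 13/92 split exactly; the centroid table shows the
developed cluster's much higher GDP and health expenditure and lower growth
rate. Food-loss records are then screened and modelled:

```r
rec <- generate_flp_panel(flp_sim_config(seed = 21), sim$labels)
scr <- apply_exclusions(categorize(rec$records)$records)
print(scr)
#> Screening result
#>   input records    : 3159
#>   retained         : 1886
#>   excluded         : 1273
#>   commodity groups dropped: beverages

lmm <- fit_all_strata(scr$records, fit$labels, by = "commodity")
print(lmm$fits[["grains"]])
#> Random-intercept LMM (ML) - grains
#>   n = 183 observations, 98 countries
#>           term estimate      se      t         p
#>    (Intercept)  19.2153 1.25554 15.304 7.136e-53
#>     developing  -8.0002 1.15407 -6.932 4.144e-12
#>  year_centered   0.1041 0.05082  2.049 4.051e-02
#>   sigma_u = 2.7811, sigma_e = 3.6636, logLik = -532.1147
#>   marginal R2 = 0.275, conditional R2 = 0.540
```

Screening drops the chronically under-reported `beverages` group (11
commodity groups in, 10 out) and listwise-deletes records missing a
modelling variable, with every drop counted. In the grains stratum the
developing-country contrast is estimated at −8.0 FLP points (truth −6 with
this seed's noise; the 95% interval covers it), the year trend at +0.10
points/year, and the conditional R² (0.54) far exceeds the marginal (0.28):
persistent country differences, not the fixed effects, carry most of the
variance — the generator builds that structure in, as real food-loss data
show.

The full pipeline (simulate → screen → classify → sensitivity → mixed
models → trends → report) runs as one call:

```r
manifest <- run_pipeline(run_config(out_dir = "flp_run", seed = 1))
```

writing tidy CSV/JSON artifacts, a text report and a run manifest, with
byte-identical outputs for identical config and seed. A thin CLI wrapper
ships in `inst/cli/flp_pipeline.R`. Real data enter through
`read_indicator_panel()` (long or wide World-Bank-style CSV),
`read_flp_records()`, `harmonize_countries()` and
`build_unified_dataset()`.

## Package layout

- `R/io.R` — readers/writers, country harmonization, unified dataset
- `R/simulate.R` — seeded indicator-panel and FLP-record generators
- `R/screening.R` — categorization, missingness report, exclusion rules
- `R/typology.R` — temporal weights, K-means typology, silhouette/elbow,
  λ-sensitivity, borderline report
- `R/lmm.R` — profiled-ML random-intercept model, Nakagawa R², per-stratum
  batches, hypothesis report
- `R/trends.R` — group means, OLS trends, borderline profiles
- `R/pipeline.R` — orchestration, manifest, text report
- `vignettes/food-loss-typology.Rmd` — the methods vignette (model,
  assumptions, design choices, limitations)
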