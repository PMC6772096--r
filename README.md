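# neonicbirds

An analysis pipeline linking spatio-temporal neonicotinoid seed-treatment
usage to farmland bird population growth, with a synthetic-data generator
standing in for the licensed survey sources (bird counts, pesticide usage
surveys, agricultural census).

It is aimed at ecotoxicologists and population ecologists who want to
reproduce, stress-test or adapt this class of exposure–response analysis:
regional usage surveys are disaggregated to 5×5 km grid squares in
proportion to cropped area, weighted by avian toxicity equivalency
factors, and entered as a cumulative covariate in a per-species log-linear
mixed model whose exposure coefficient is then compared across dietary
exposure groups.

## The model

For counts μ of one species at survey site *s* (grid *g*, region *r*) in
year *t*:

    ln μ(g,t,s,r) = β₀ + β₁ Σ_{j≤t−1} P(g,j) + Σ_{j≤t} β₂(j) + x_g + y_s + z_r

* `P(g,j)` — TEF-adjusted neonicotinoid mass (kg) applied in grid *g* in
  year *j*, built from the allocation identities `Z = 100·x/y`,
  `B = (A/100)·Z`, `C = Σ_crops B` (mass conserved exactly within every
  region × crop × compound × year);
* `β₁` — change in annual log population growth per TEF-adjusted kg
  (reported as `100·(exp(β₁) − 1)` percent);
* `β₂` — per-year background growth rates, entered through a binary year
  matrix;
* `x, y, z` — zero-mean Gaussian random intercepts for grid square,
  site and region (fitted by Laplace-approximate maximum likelihood via
  glmmTMB; Poisson, quasi-Poisson or negative binomial).

Species are assigned to high / medium / low dietary exposure groups from
the summed proportion of high-residue food items (treated crop seed and
seedlings) at three life stages, and the per-species β₁ estimates are
compared across groups (Kruskal–Wallis) and regressed on diet proportions
(inverse-variance weighted least squares).

## Worked example

Simulate a small landscape bundle (3 regions, 12 grid squares, 10 years,
biennial usage surveys with a compound changeover in 1998) and run the full
pipeline on four species with known exposure coefficients:

```r
library(neonicbirds)

cfg <- pipeline_config(
  out_dir = file.path(tempdir(), "bundle"), rng_seed = 1,
  landscape = landscape_config(n_regions = 3, grids_per_region = 4,
                               years = 1994:2003, changeover_year = 1998,
                               missing_census_years = c(1997, 1999),
                               rng_seed = 1),
  n_species = 4, true_beta1 = c(-0.01, -0.003, 0, 0.01), sites_per_grid = 3)

run_simulate(cfg)         # writes crop_areas/usage/jsa/tef/counts/diet CSVs
res <- run_pipeline(cfg)  # allocate -> classify -> fit -> synthesize

res$fits[, c("species", "beta1_hat", "se", "p", "pct_change", "family", "converged")]
#>   species beta1_hat      se        p pct_change  family converged
#> 1   sp001   -0.0146 0.00484 2.61e-03      -1.45 poisson      TRUE
#> 2   sp002   -0.0125 0.00476 8.54e-03      -1.25 poisson      TRUE
#> 3   sp003    0.0012 0.00411 7.71e-01       0.12 poisson      TRUE
#> 4   sp004    0.0144 0.00364 7.85e-05       1.45 poisson      TRUE
```

Each row is one species' fitted exposure coefficient: `beta1_hat` is the
change in log population growth per TEF-adjusted kg applied in the
species' grid squares (so sp001, generated with a true coefficient of
−0.01, is estimated at −0.0146 ± 0.0048 — a −1.45% change in annual
growth per kg), with the Wald test against zero alongside. The species
generated with no effect (sp003) is correctly non-significant. The
cross-species synthesis in `res$synthesis` then asks whether these
coefficients differ between dietary exposure groups; here
`res$synthesis$kw` gives chi-squared = 2.7 on 2 df, p = 0.26 — no group
effect, as generated.

The `analysis/` directory contains the same workflow as numbered stage
scripts (`01_simulate.R` … `05_synthesize.R`, run from the repository
root), writing their tables under `results/`. The two published
sensitivity analyses are one flag away: `usage_interpolation = "stepped"`
and `tef_mode = "chronic"`.

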