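---
title: "Modelling neonicotinoid exposure and farmland bird population growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neonicotinoid exposure and farmland bird population growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonicbirds)
```

## The problem

Neonicotinoid insecticides (imidacloprid, clothianidin, thiamethoxam) are
applied in arable systems overwhelmingly as seed coatings. Granivorous
farmland birds can ingest treated seed and seedlings directly, so a
long-standing question is whether spatio-temporal variation in
neonicotinoid use is associated with changes in farmland bird populations,
and whether any association tracks how much high-residue food a species
eats. Answering it requires stitching together three data sources with
incompatible resolutions: bird counts at individual survey sites, pesticide
usage reported per region every other year, and cropped areas per 5×5 km
grid square with long runs of missing census years.

This package implements that analysis as a tested pipeline, together with
a synthetic-data generator that reproduces the statistical structure of
each source, so every stage can be verified without the licensed survey
data.

## Spatial disaggregation of usage

Usage surveys report the mass $A$ (kg) of each compound applied to each
crop in each region. A grid square holding a fraction of the region's crop
receives that fraction of the mass:

$$Z = 100\,\frac{x}{y}, \qquad B = \frac{A}{100}\,Z, \qquad
  C = \sum_{\text{crops}} B,$$

with $x$ the grid's cropped area (ha), $y$ the regional cropped area, $B$
the per-crop allocated mass and $C$ the grid total. The allocation is a
partition of mass: for every region × crop × compound × year,
$\sum_{\text{grids}} B = A$ exactly, and the package treats any violation
(for example usage recorded against a region with zero cropped area) as a
hard error rather than silently dropping mass.

Two interpolation layers precede allocation:

* **Usage surveys are biennial.** Gap years are filled per region × crop ×
  compound with the mean of the bracketing surveys (primary rule) or by
  carrying the preceding survey forward (the published sensitivity rule).
  Years after the last survey can only use the stepped rule, under either
  method. A combination absent from a survey year is treated as zero mass,
  not as missing.
* **Census years are missing in blocks.** Grid-level crop areas in a
  missing year are filled per crop by one of three rules: linear
  interpolation within each grid's own series; the grid's share of the
  regional crop in the nearest census year scaled to that year's regional
  June-survey total; or the same against national totals. 1998, which has
  neither census nor survey totals, stays absent and is flagged.

## Toxicity equivalency

Compounds differ sharply in avian toxicity, so masses are scaled to the
toxicity of imidacloprid before being summed. The acute basis uses oral
LD50s for bobwhite quail (152, 2000, 2716 ng/kg bw), giving factors 1,
152/2000 = 0.076 and 152/2716 = 0.056 (displayed 0.08 and 0.06); the
chronic basis uses LOAELs (2820, 7380, 12660 ng/kg bw/day), giving 1, 0.38
and 0.22. Factors are carried at full precision and rounded only for
display. The acute basis is the primary analysis; the chronic basis is one
of the two sensitivity analyses.

```{r tef}
default_tef_table()
```

## The per-species model

For species counts $\mu$ at site $s$ (grid $g$, region $r$) in year $t$:

$$\ln \mu_{g,t,s,r} = \beta_0
  + \beta_1 \sum_{j \le t-1} P_{g,j}
  + \sum_{j \le t} \beta_{2,j}
  + x_g + y_s + z_r,$$

where $P_{g,j}$ is the grid's TEF-adjusted application in year $j$, the
$\beta_{2,j}$ are per-year background log growth rates entered through a
binary year matrix (the row for year $t$ has ones in all columns up to
$t$), and $x, y, z$ are independent zero-mean Gaussian random intercepts.
$\beta_0$ is the log abundance in the baseline year (cumulative exposure
zero, year row all zeros), and $\beta_1$ is the change in annual log
population growth per TEF-adjusted kg — displayed as a percentage via
$100(e^{\beta_1} - 1)$.

The "cumulative" covariate is a design device for tracking year-on-year
change in use, not a claim of multi-year environmental accumulation. Two
readings of its upper limit are defensible — through $t-1$ (the harvest
preceding the breeding-season count) or through $t$ — and the prose and
displayed formula of the source analysis differ on this point. The package
defaults to $j \le t-1$ and exposes `lag_mode = "through_t"` rather than
silently resolving the ambiguity.

Data preparation follows the survey conventions: the site-year count is
the maximum over the two visits; 1998 (no cropping data) and 2001
(foot-and-mouth access restrictions) are dropped; sites that never carried
farmland habitat code `"E"` are excluded unless explicitly exempted
(mirroring a surveyed block whose habitat was never recorded). Exposure
recorded in bird-excluded years still feeds later cumulative sums — those
exclusions reflect count quality, not absence of pesticide — while years
absent from the exposure surface contribute zero.

Fitting is maximum likelihood with a Laplace approximation (glmmTMB).
Three families are exposed: Poisson; quasi-Poisson as the classical
quasi-likelihood contract (Poisson point estimates, all standard errors
inflated by $\sqrt{\hat\phi}$ with $\hat\phi$ the Pearson dispersion);
and negative binomial with quadratic mean–variance. The pipeline's
`family = "auto"` follows the published decision rule: fit Poisson, refit
quasi-Poisson when the Pearson ratio exceeds 1.5. Non-convergence (including
a non-positive-definite Hessian or non-finite standard errors) is flagged
on the result and such species are excluded from the synthesis with a
warning, never silently.

Zero inflation is assessed by simulation: `n_sim` response vectors are
drawn from the fitted model conditional on the estimated random effects,
and the observed number of zeros is placed in the simulated distribution
(two-sided tail, with a $+1$ continuity correction so $p$ is never exactly
zero).

## Dietary exposure groups

Food items are classed by residue concentration relative to treated crop
seed (555,600 ng/g): items below a threshold percentage of that maximum
are "low". The threshold defaults to 0.011% rather than a literal 0.01%
because the most contaminated low item (prey birds, 56 ng/g) sits at
0.0101% — the published labels, which place it in the low class, are
treated as authoritative, and the threshold is configurable.

Species carry the summed proportion of high-residue items (treated seed
and seedlings) in the diet at three life stages. Groups: **high** if any
stage reaches 50% (inclusive — the published table labels a species
peaking at exactly 50 as high, so the table wins over the prose rule
">50%"); **low** if every recorded stage is zero; **medium** otherwise,
including proportions below 1% (any non-zero presence implies at least
medium). Species with only qualitative diet evidence can carry a direct
group override, mirroring two corvid/sturnid species assigned medium by
judgement. The packaged 22-species table reproduces the published 8/9/5
high/medium/low split exactly.

## Cross-species synthesis

Per-species $\hat\beta_1$ values are compared across the three diet
groups with the tie-corrected Kruskal–Wallis test (chi-squared reference;
an exhaustive permutation reference is available for $n \le 10$), and
regressed on each life-stage proportion and on an optional external
population trend by weighted least squares. Weights default to
$1/\mathrm{SE}^2$ — the standard reading of "weighted by their standard
errors" — with $1/\mathrm{SE}$ exposed as an option since the phrase is
ambiguous. Species missing a predictor are dropped from that regression
only, and each regression reports its degrees of freedom so the sample
composition is auditable (19 complete cases among 22 species gives the
$F_{1,17}$ bookkeeping).

## The synthetic-data generator

The generator is the package's substitute for the licensed sources and
defines the conditions under which the pipeline is verified:

* **Crop areas** are gamma draws (shape 2) per grid × crop — non-negative
  with a heavy right tail, mimicking the concentration of arable land —
  multiplied by a persistent grid × crop propensity so squares keep their
  cropping character across years. Regional June-survey totals are exact
  regional sums for *all* years, so the JSA-based census fill rules are
  exactly checkable; census years are then removed per configuration.
* **Usage** exists only in survey years (biennial by default) and equals
  regional cropped area × an application rate of about 0.02 kg active
  substance per hectare, split across compounds with the dominant share
  (0.75) moving from the first compound to the second at the changeover
  year (2008 by default).
* **Counts** are drawn per visit from Poisson or negative binomial with
  mean $\exp(\beta_0 + \beta_1 \cdot \text{cumP} + \sum\beta_2 + x + y +
  z)$, using the same cumulative-exposure rule as the estimator. All sites
  default to farmland habitat, with configurable fractions of non-farmland
  and habitat-unrecorded sites to exercise the filter.
* **Diet profiles** are generated group-first, with stage proportions
  consistent with the assigned group by construction, so classification
  round-trips exactly.
* Every table draws from its own stream, derived from the master seed by a
  fixed label: adding species never perturbs the landscape draws, and
  identical seeds give byte-identical bundles.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spatial autocorrelation in cropping or in bird
abundance, migratory phenology, observer effects, density dependence, and
cross-species correlation in counts at shared sites.

## Verification experiments and their scales

The package's operating characteristics are measured by three experiment
functions, at scales chosen to be informative on a single desktop core:

* `recovery_experiment()`: 200 datasets over a fixed 4-region, 40-grid,
  80-site, 19-year exposure surface with $\beta_1 = -0.005$; the mean
  estimate falls within two Monte-Carlo standard errors of the truth and
  95% Wald coverage lands in [0.91, 0.99].
* `null_calibration_experiment()`: 400 datasets with $\beta_1 = 0$ at the
  same design scale; the Wald rejection rate at $\alpha = 0.05$ stays
  within the binomial 99% band [0.028, 0.075]. Calibration is assessed at
  this scale deliberately: on much smaller designs (few regions, tens of
  sites) the Wald z-test in this model is visibly anticonservative and the
  region variance weakly identified — a known small-sample property worth
  keeping in mind when fitting sparse species.
* `sensitivity_experiment()`: one fixed 10-species bundle re-estimated
  under stepped (vs mean) usage interpolation and chronic (vs acute)
  TEFs; coefficient vectors correlate above 0.99 across settings,
  mirroring the published finding that these choices barely move the
  estimates.

Two protocol details are deliberate. The recovery experiments draw one
realised count per site-year from the generative family, because the
max-of-two-visits extraction rule shifts the mean by a non-proportional
amount ($E[\max(X_1,X_2)] \approx \lambda(1 + 1/\sqrt{\pi\lambda})$ for
Poisson visits): that shift is a property of the extraction convention,
not of the model, and it shows up in practice as mild *under*-dispersion
of max-counts relative to Poisson. The two-visit layer is exercised
separately by the pipeline tests. And the random intercepts are treated
as three independent crossed effects even though the grouping is
physically nested (sites within grids within regions), because the model
writes them additively with globally unique identifiers; with nested data
the crossed parameterisation is equivalent up to how variance is
apportioned between levels.

## Numerical choices and degenerate inputs

* TEFs at full precision internally; 2 d.p. display via `format_tef()`.
* Residue threshold 0.011% of maximum (configurable), for the reason above.
* High-group boundary at exactly 50, inclusive.
* An empty set of high-residue plant families sums to 0% (informative
  absence), while a species with no recorded stage at all and no override
  is an error.
* Usage years before the first survey are an error (nothing to fill
  from); trailing years use the stepped rule under both methods.
* Missing JSA totals for a fill year degrade to a warning and an absent
  year; usage against zero cropped area is a hard error by default.
* Convergence requires the optimiser to report success *and* a positive
  definite Hessian *and* finite positive standard errors. A single
  optimiser start is used: across the verification experiments the
  default initialisation converged in effectively all replicates, so
  multi-start machinery was judged unnecessary; failures are flagged, not
  retried.
* Year-effect columns with no variation (a year nobody observed) are
  dropped from the fixed-effect matrix rather than left collinear.
* Region schemes that change over the study period (five broad regions in
  the early survey era, nine statistical regions later) are represented by
  carrying the region label per grid × year row of the census table — the
  allocation keys on whatever label a row carries, so an era switch needs
  no separate lookup structure.

## Limitations

Beyond the generator's idealisations listed above: the pipeline assumes
birds respond only to applications within their own 5×5 km square; spray
(non-seed) applications are out of scope; there is no correction for
detectability; and the quasi-Poisson family is a variance contract, not a
likelihood, so its "dispersion" is diagnostic rather than generative. The
harvest-year convention of the usage surveys leaves the mapping of autumn
sowings onto the bird-observation calendar genuinely ambiguous; the
`lag_mode` switch exposes both readings rather than resolving them.
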