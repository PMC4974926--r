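---
title: "Piecewise SEM for bee reproduction and floral resources: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise SEM for bee reproduction and floral resources: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(beesem)
library(dplyr)
```

## The scientific problem

Cavity-nesting solitary bees provision each brood cell with pollen, so the
number of brood cells a female builds is a direct proxy of her reproductive
output. Whether richer and more temporally stable flower communities let
bees build more cells is an open question: flower richness could shorten
foraging trips and broaden the phenological window of resource supply, but
richness covaries with abundance, elevation and disturbance history, so the
raw correlations are confounded. The package analyses this question the way
it is analysed in the field: a trap-nest survey of a bee assemblage along
an elevation gradient (the reference design has fourteen 100 × 200 m sites
at 1,100–1,500 m in the Monte desert, with weekly floral censuses over one
flowering season), turned into site-level covariates and per-species
reproduction summaries, and fitted with piecewise structural equation
models compared by information criteria.

Three reproductive responses are analysed per bee species and, summed over
species, at the community level: the mean number of brood cells per nest
(defined only at sites where the species nested), the total number of brood
cells per site, and the total number of nests per site (absence counts as
zero for the totals). Species with fewer than 30 occupied trap nests over
the whole survey are excluded as statistically unreliable
(`filter_focal_species()`); in the reference census of 598 nests and 11
species this keeps 7 focal species. For species that build no discrete
brood cells (bare pollen masses), the occupied cavity length stands in for
the cell count via `pollen_length_proxy()`; with the default conversion of
1 the raw length is the response, which suffices because only standardized
(correlation-scale) effects enter the models.

## Site covariates

* **Flower abundance** is the seasonal flower density of a site: per taxon,
  mean flowers per flowering individual × number of flowering individuals
  (`flower_density()`), or a direct count where individuals cannot be
  distinguished; the site-week totals are summed over the season. Weekly
  counts from the four plots and two transects of a site are pooled into
  one site-week total before any further computation; plot-level analysis
  is out of scope.
* **Flower richness** is rarefied to remove sampling-effort bias:
  `rarefied_richness()` computes the hypergeometric expectation
  E[S~n~] = Σ~i~ (1 − C(N−N~i~, n)/C(N, n)) via `vegan::rarefy()`. The
  default rarefaction depth is the minimum seasonal flower total across
  sites — the standard choice when no depth is prescribed — and is
  configurable.
* **Temporal stability** of floral resources is the inverse coefficient of
  variation of the weekly abundance series, mean/sd with the sample (n−1)
  standard deviation (`temporal_stability()`); the sample form matches the
  default of the statistical environments used in this literature and a
  population-sd variant is available. A constant non-zero series yields an
  `Inf` sentinel with a warning (never a silent drop); an all-zero series
  errors. At least two weeks are required, and stability is invariant to
  rescaling the whole series.

Whether stability should be computed on raw weekly totals or on per-area
densities is not fixed by the design; since the two differ by a constant
factor per site and stability is scale-invariant, the distinction only
matters if the sampled area varies within a season, and the weekly series
interface accepts either.

## Diet generalization

Diet breadth per bee species is measured on pooled pollen-grain counts
(pooling across nests and sites is the default; per-nest rarefaction with
averaging is a deliberate non-default because grain totals per nest are
highly variable). Two indices are rarefied to a common depth of grains so
species are comparable:

* **rarefied degree** — expected number of plant species in a random
  subsample of n grains; analytic, same hypergeometric expectation as
  flower richness;
* **rarefied inverse Simpson** — expected 1/Σp~i~² of a subsample. No
  simple closed form exists, so it is estimated by Monte-Carlo
  hypergeometric subsampling with an explicit seed; the Monte-Carlo
  standard error is attached to the result. The inverse (effective-number)
  form of Simpson's index is the default because it shares the
  species-count scale of the degree; the Gini–Simpson complement can be
  derived from it directly.

The default depth is the minimum pooled grain total across the focal
species.

## The causal models and the d-separation test

A candidate model is a DAG over observed site-level variables
(`causal_model()`). The complete structure routes elevation to richness and
abundance, richness to stability, and all five covariates to the response;
the simplified nested structure keeps richness, stability and elevation as
direct causes, with the richness and elevation edges on a keep-list so
model pruning retains them even when non-significant — their trends are the
scientific target, and automatic pruning should not silence them.

Each model is tested locally rather than through a global covariance fit:

1. `basis_set()` lists one conditional-independence claim per non-adjacent
   variable pair, conditioning on the union of the parents of both
   variables. Claims are ordered lexicographically by the sorted pair, so
   output is deterministic. The test suite verifies the construction
   against an independent path-blocking d-separation oracle, exhaustively
   over every 5-vertex DAG (all upper-triangular edge sets, which covers
   all DAGs up to the vertex relabelling both routines ignore).
2. Each claim is evaluated with a Pearson partial correlation
   (`partial_correlation()`), computed from the precision matrix of
   (x, y, Z); the p-value is two-sided from the t distribution on
   n − 2 − |Z| degrees of freedom. The implementation route differs
   deliberately from the textbook residual-regression definition, which
   serves as the test oracle (agreement to 1e−12). Complete-case filtering
   is applied first; zero variance after residualisation is a
   degenerate-input error, and a constant conditioning variable is dropped
   as uninformative.
3. `fisher_c()` combines the claim p-values: C = −2 Σ ln p~i~, chi-square
   with df = 2k under the model. A zero p-value propagates as an infinite-C
   sentinel with a warning (decisive rejection). A saturated model (empty
   basis set) gets C = 0, df = 0, p = 1 by convention and is flagged.

The df = 2k convention is the standard one for Fisher's C. Printed triples
of (C, df, p) in the applied literature are not always jointly consistent
with it; no alternative convention reproduces such triples either, so the
package reports df = 2k and leaves claim-level p-values in the output for
audit.

### AIC and model ranking

`model_aic()` offers three formulas:

* `shipley` — AIC = C + 2K, the large-sample form;
* `shipley_corrected` — AIC = C + 2K·n/(n − K − 1), the small-sample
  correction and the default (appropriate for tens of sites);
* `as_printed` — AIC = 2 ln C + 2K, a formula that circulates in applied
  papers. It is dimensionally inconsistent with the chi-square scale of C,
  undefined for C ≤ 0, and ignores n even where the surrounding text
  mentions it; it is provided strictly as an audit option and errors
  loudly on C ≤ 0.

K counts free parameters. The package's general default is one coefficient
per edge plus one variance per variable; the pipeline, however, counts
edges only (`K_rule = "edges"`), because with the variance-inclusive count
the corrected denominator n − K − 1 is non-positive for the complete model
at 14 sites. Both rules are exposed, and rankings are insensitive to the
shared variance count when models span the same variables.

ΔAIC support classes follow the conventional thresholds: below 3,
substantial support; above 10, essentially none. Published wordings leave
the 7–10 band unlabelled; the package classifies the whole 3–10 interval as
"less" support rather than inventing a fourth class. AIC ties are broken
lexicographically by model name.

### Path coefficients

The coefficient of an edge X → Y is the partial correlation of X and Y
given Y's *other* parents — the same routine that supplies independence
p-values, applied per edge; a sole-parent edge reduces to the plain Pearson
r. This piecewise estimator targets a population partial correlation, which
equals the generating standardized coefficient for sole-parent edges but
deviates slightly (up to ~0.05 at moderate effect sizes) when co-parents
are correlated. The generator therefore exposes
`implied_path_coefficients()`, the exact population value of this estimand
under a configured linear system, and parameter-recovery tests compare
estimates to it rather than to the raw coefficients — the statistically
correct target for this estimator.

## Cross-species meta-analysis

For each simplified-model edge, the per-species coefficients r~s~ are
combined with Fisher's z transform, z = 0.5 ln[(1+r)/(1−r)], and
inverse-variance weights w = N − 3 (the sampling variance of z is
approximately 1/(N−3)): z~w~ = Σ w~s~z~s~ / Σ w~s~. N per species is the
number of sites contributing to that species' coefficient — 14 for the
totals, fewer for mean cells per nest where the species was absent
somewhere. Confidence limits are percentile bootstrap: species' (z, w)
pairs are resampled with replacement B = 100,000 times (seed-reproducible)
and the 2.5/97.5 percentiles reported, mapped back to the correlation scale
with tanh. Percentile — not BCa — intervals are used, matching standard
practice for this design. With as few as seven species the percentile
bootstrap is known to undercover somewhat relative to the nominal 95%;
this is a property of the method at small k, not of the implementation,
whose two-species case is verified exactly against the enumerable 3-point
resample distribution.

The relationship between the flower-richness effect and diet
generalization is tested with Spearman rank correlations. For tie-free
samples of up to 9 species the two-sided p-value is exact, from full
enumeration of all n! rank permutations (5,040 permutations at n = 7);
ties or larger n fall back to the t approximation
t = ρ√((n−2)/(1−ρ²)).

## The synthetic survey generator

The generator exists so that every stage is testable without field data; it
emulates the sampling design, not any particular realised data set. Its
defaults are fixed to the reference study conditions: 14 sites uniform on
1,100–1,500 m; time since fire uniform on 1–40 years (disturbance history
"varies substantially" across such sites; the range brackets recent burns
through mature shrubland); 8 weekly censuses (a 15 Oct–8 Dec season at
weekly intervals); 7 focal bee species; about 6 expected nests per species
per site (≈ 600 nests over the survey); cells per nest 1 + Poisson(2);
pollen loads of ~200 counted grains from a 25-species plant pool.

Site covariates follow a configurable standardized linear causal model
with Gaussian noise; the default structure and effects encode the system's
known pattern — elevation raises rarefied richness (0.39) and lowers
abundance (−0.51), richness lowers stability (−0.54) — and are mapped to
natural units by configurable mean/sd scales (richness 10 ± 2 species,
abundance 5,000 ± 1,000 flowers per season, stability 2 ± 0.4). Noise
variances are set analytically so every variable has unit population
variance, which makes edge coefficients standardized and lets
`implied_covariance()` return the exact correlation matrix.

Weekly counts are realised by splitting a site's seasonal total across
weeks with a symmetric Dirichlet draw; the concentration α = 1/cv² − 1/W
makes the expected sample CV across the W weeks equal the target CV (the
weekly *shape* is nuisance; stability is the modelled quantity). A W-week
non-negative series cannot have CV above √W, so configured stability means
at or below 1/√W are a configuration error, while rare tail draws below
the floor are clamped just above it with a warning. The realised series'
stability is a noisy measurement of the target at W = 8 (sampling error of
a CV over 8 observations is large); analyses run on the generated site
table use the target values, and `floral_metrics()` recomputes the noisy
version the way a field pipeline would.

Nest counts per species × site are Poisson (negative binomial optional)
with log mean linear in the standardized covariates; defaults give
elevation a negative effect on nest numbers and stability a small negative
effect on cells per nest, the direction of the system's published pattern.
Pollen composition per individual is multinomial with use weights decaying
geometrically in a species-specific preference order; the decay scale sets
diet breadth, and the default gradient (1 → 8 across the seven species)
spans oligolectic to polylectic behaviour.

What the generator does **not** emulate: spatial autocorrelation among
sites, within-season phenological structure beyond the CV target,
overdispersion by default, parasitism, and any nonlinearity. Passing tests
on synthetic data therefore demonstrate the correctness and calibration of
the machinery under the assumed linear-Gaussian/Poisson sampling structure,
not the field validity of the ecological conclusions.

## Numerical choices and degenerate inputs

* Partial correlations clip to [−1, 1] before the t statistic; |r| = 1
  maps to p = 0.
* `fisher_c` rejects p-values outside [0, 1]; zero gives Inf + warning.
* Rarefaction requires 1 ≤ n ≤ N and a non-empty community; depth defaults
  are minima across units, never maxima.
* Bootstrap and Simpson rarefaction take explicit seeds and restore the
  caller's RNG state; the pipeline derives stage seeds deterministically
  from the single configured seed, so a config + seed reproduces the
  report bundle byte for byte.
* Quantiles in the bootstrap use R's default (type 7) definition.
* Pruning removes an edge only when it is both non-significant and below
  the magnitude threshold, never an edge on the keep-list; pruning to an
  edgeless model warns.

## Problem sizes used by the test suite

The suite checks calibration at desk scale, chosen to give tight Monte
Carlo bounds while keeping a laptop run comfortable: the exhaustive
5-vertex DAG sweep (1,024 graphs); 1,000 random partial-correlation
instances at 1e−12 tolerance; 1,000 simulated surveys of 50 sites for the
type-I error of the d-sep test (binomial 99% band around α = 0.05); 5,000
synthetic sites for coefficient recovery within ±0.05; 100 study-scale
(n = 14) replicates for model-selection consistency; B = 100,000 bootstrap
replicates against the exact two-species resample distribution.

## Known limitations

* Estimation is fully piecewise: no global covariance fit, no latent
  variables, no non-Gaussian independence tests, no mixed models.
* The partial-correlation path estimator is consistent for its population
  partial correlation, not for the generating standardized regression
  coefficient when co-parents correlate (see above).
* Percentile-bootstrap coverage at k = 7 species is below nominal; treat
  the limits as approximate.
* The mean-cells response conditions on presence, so its per-species
  sample sizes vary and can get small; the pipeline propagates the per-fit
  n into the meta-analysis weights accordingly.
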