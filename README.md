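# beesem

Piecewise structural equation models for the reproduction of cavity-nesting
solitary bees along floral-resource gradients.

## The problem

Does a richer, more temporally stable flower community let solitary bees
produce more offspring? Trap-nest surveys measure bee reproduction as brood
cells and nests per site, but flower richness is confounded with flower
abundance, elevation and fire history, so the question needs a causal-model
treatment rather than raw correlations. `beesem` implements the full
analysis chain for this design, aimed at pollination ecologists working
with trap-nest + floral-census data:

* per-site covariates: flower density, rarefied flower richness
  (hypergeometric expectation, via vegan), and temporal stability of weekly
  flower production (inverse coefficient of variation);
* per-species reproduction summaries (mean cells per nest, total cells,
  total nests; absence = zero for totals) with the ≥ 30-nest focal-species
  filter and a cavity-length proxy for species without discrete brood
  cells;
* piecewise SEM: candidate DAGs are tested through their d-separation
  basis set — one Pearson partial-correlation test per non-adjacent
  variable pair given the parents of both — combined by Fisher's C,

  C = −2 Σ ln p_i ~ χ²(2k),

  and ranked by AIC (default small-sample form C + 2K·n/(n−K−1); the
  large-sample C + 2K and an audit-only 2 ln C + 2K variant are
  selectable). Path coefficients are partial correlations of each edge
  given the response's other parents;
* cross-species meta-analysis of any path: Fisher z transform
  z = ½ ln[(1+r)/(1−r)], inverse-variance weights w = N − 3, and
  percentile bootstrap confidence limits (default B = 100,000,
  seed-reproducible);
* Spearman rank correlations (exact permutation p at n ≤ 9) between the
  flower-richness effect and rarefied diet-generalization indices (degree
  and inverse Simpson);
* a synthetic survey generator that emulates the whole sampling design
  (14 sites on a 1,100–1,500 m gradient, weekly floral censuses, 7 focal
  bee species, pollen loads) from a configurable standardized linear
  causal model, so every stage is testable without field data.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

```r
library(beesem)

census <- monte_nest_census()          # packaged survey census
sum(census$total_nests)
#> [1] 598
filter_focal_species(census, min_nests = 30)
#> [1] "Anthidium decaspilum"       "Anthidium rubripes"
#> [3] "Anthidium vigintipunctatum" "Megachile leucographa"
#> [5] "Megachile ctenophora"       "Trichothurgus laticeps"
#> [7] "Xylocopa atamisquensis"

# full analysis on a seeded synthetic survey (or pass input = list(nests=,
# sites=, pollen=) with CSV paths to analyse field data)
res <- run_pipeline(list(generator = list(), seed = 1,
                         bootstrap_reps = 10000, simpson_reps = 500))

res$fits$community$total_cells$ranking
#> # A tibble: 2 × 8
#>   model          C     K     n   AIC formula           delta_AIC support
#>   <chr>      <dbl> <int> <int> <dbl> <chr>                 <dbl> <chr>
#> 1 simplified  1.07     5    14  18.6 shipley_corrected       0   substantial
#> 2 complete   16.7      8    14  61.5 shipley_corrected      42.9 none

res$meta[["stability -> mean_cells_per_nest"]]
#> <meta_fit> 7 species, B = 10000
#>   weighted mean r = -0.3517, 95% CI (-0.5047, -0.1683)
```

The ranking says the simplified causal structure (richness, stability and
elevation acting directly on reproduction) is consistent with the
d-separation test (small Fisher's C) and decisively out-ranks the complete
model once the AIC penalty for its extra paths is paid. The meta-analysis
row combines the stability → mean-cells path across the seven species into
a weighted mean coefficient with bootstrap percentile limits — here
negative, reflecting the generator's built-in weak negative stability
effect on cells per nest. `res$spearman` holds the rank correlations
between each species' richness effect and its diet-generalization indices,
and `res$generalization` the rarefied degree / inverse-Simpson values
themselves.

Single pieces are available directly, e.g.:

```r
temporal_stability(c(10, 20, 30))      # mean/sd = 2
rarefied_richness(c(2, 2), n = 2)      # 5/3
fisher_c(c(0.5, 0.5))                  # 2.7726
basis_set(causal_model(c("A -> B", "B -> C")))   # A ⊥ C | B
```

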