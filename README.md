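# phylograd

Geographic patterns of insect diversity across reserve networks: community
phylogenetic structure, latitudinal gradients, and the relative importance of
contemporary versus historical climate.

## The problem

Species richness of insects across a large latitudinal span (e.g. China's
nature reserves, 19–52 °N) often does not decline monotonically toward the
poles: it can peak at midlatitudes, where faunas of tropical (Oriental) and
temperate (Palearctic) biogeographic affinity overlap. Under phylogenetic
niche conservatism (PNC), lineages retain their ancestral climatic
tolerances, so winter coldness — in particular the coldest-month temperature
of the Last Glacial Maximum (LGM_MTCM) — filters which clades reach which
latitudes. Two testable signatures follow:

1. assemblages at higher latitudes should be dominated by evolutionarily
   *derived* clades (cold-adapted, younger), and
2. winter-coldness variables should rank among the strongest predictors of
   both richness and phylogenetic structure.

`phylograd` implements the full analysis chain for these questions, plus a
generative simulator that produces reserve networks with exactly these
mechanisms built in, so every stage can be validated against known truth.

## The statistics at its core

**Mean root distance (MRD).** For a rooted order-level phylogeny, the root
distance RD of an order is the number of nodes separating it from the root
(root counted, so the tips of a star tree have RD 1; branch lengths are
ignored). For an assemblage *S* of species with order assignments,

    MRD(S) = (1/|S|) * sum over species i of RD(order_i)

High MRD marks assemblages dominated by derived orders. Orders are further
grouped by geohistorical origin: "cold clades" arose in the Late
Carboniferous–Early Permian (320–274 Ma: Hemiptera, Coleoptera), "warm
clades" in the Triassic–Jurassic (250–145 Ma: Hymenoptera, Orthoptera,
Diptera, Lepidoptera).

**Gradients.** Richness (natural-log) and MRD are regressed on latitude by
OLS, linear and quadratic; a concave quadratic `y = a·lat² + b·lat + c` with
`a < 0` yields a peak latitude at `−b/(2a)` when the vertex lies inside the
data range. Bivariate predictor screens report 100·R² per predictor with
significance codes.

**Importance stage.** Candidate predictors (climate indices, LGM analogues,
NDVI, terrain roughness TR = 1/cos(slope), area, habitat heterogeneity,
human disturbance) are pruned by backward AIC elimination and then by
variance inflation factor (VIF = 1/(1−R²) > 10); a seeded random forest of
200 bootstrap regression trees scores the survivors by out-of-bag
permutation importance, normalised so the strongest predictor is exactly 1;
Moran's I correlograms (equal-count great-circle distance classes, 999
permutations) check the forest's out-of-bag residuals for spatial
autocorrelation.

## Worked example

```r
library(phylograd)

ds  <- simulate_dataset(sim_config(seed = 7))   # 110 reserves, 500 species
sm  <- dataset_summaries(ds)

fit <- fit_latitudinal(sm$richness, sm$lat, "quadratic",
                       log_y = TRUE, response = "richness")
fit
#> gradient_fit: richness ~ lat (quadratic), n = 110, R2 = 0.816, p = 5.03e-40
#> intercept         b         a
#>  2.301046  0.221544 -0.003516
peak_latitude(fit)$peak
#> [1] 31.50697

expected_patterns(ds)
#>                              property    value  p_value pass
#> 1         oriental_richness_decreases -0.96332 1.59e-63 TRUE
#> 2       palearctic_richness_increases  0.65510 8.21e-15 TRUE
#> 3 total_richness_humped_interior_peak -0.00352 5.03e-40 TRUE
#> 4         mrd_increases_with_latitude  0.04073 6.09e-38 TRUE
#> 5         warm_mrd_slope_exceeds_cold  0.03797 1.30e-13 TRUE
```

Total richness is hump-shaped and peaks at ~31.5 °N; Oriental richness falls
and Palearctic richness rises with latitude; MRD increases northward
(+0.041 nodes/degree) and does so faster in the warm-originated clades —
the full PNC signature, recovered from simulated occurrences by the same
code paths that would process real species lists.

The end-to-end pipeline (species lists + covariates + tree in, tables and
JSON reports out) runs from the shell:

```sh
Rscript scripts/run_pipeline.R --simulate --seed 3 --out runs/demo
```

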