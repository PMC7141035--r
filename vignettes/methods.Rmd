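---
title: "Models and methods behind phylograd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylograd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylograd)
```

# What the package computes

`phylograd` analyses insect diversity across a network of nature reserves
spanning a large latitudinal gradient. Its chain has four stages: (i)
community phylogenetic structure via mean root distance, (ii) per-reserve
environmental covariates, (iii) latitudinal gradient fits with quadratic
peak estimation, and (iv) a multivariate variable-importance stage. A fifth
module, the synthetic-data generator, encodes the causal mechanisms the
analysis is meant to detect and provides ground truth for validation.

# Mean root distance

## Definition and conventions

The root distance (RD) of a tip in a rooted tree is a pure node count:
branch lengths never enter. We count the internal nodes on the root-to-tip
path *including the root*, so the tips of a star tree have RD 1 and RD is
always at least 1. The alternative root-exclusive convention (available via
`root_distances(..., convention = "edge-count")`) is exactly one lower for
every tip. Because the two conventions differ by a constant, MRD
*differences* between assemblages and latitudinal *slopes* of MRD are
identical under either; only intercepts shift. This is why the choice of
convention, which the literature rarely states, cannot affect any
comparative conclusion drawn from this package.

Polytomies are kept as single nodes. Resolving them at random would add
nodes on some paths nondeterministically and inflate RD; a node count should
count the nodes that are actually supported.

MRD weights *species*, not orders: an assemblage of 90 beetle species and 10
fly species has MRD dominated by the beetles. Species whose order is absent
from the RD table are excluded with a warning and a reported count — never
imputed — and an assemblage with no scorable species is an error.

## Warm and cold clades

Six species-rich orders are classified by the thermal character of their
origination window: Hemiptera (~310 Ma) and Coleoptera (~282 Ma) arose in
the cold Late Carboniferous–Early Permian (320–274 Ma window); Hymenoptera
(~250 Ma), Orthoptera (~215 Ma), Diptera (~170 Ma) and Lepidoptera
(~156 Ma) in the warm Triassic–Jurassic (250–145 Ma window). The class
column of `clade_origin_table()` is derived from the ages and the windows,
so an edited table stays internally consistent; orders outside both windows
are "unclassified" and reported separately by `group_richness()`.

# Environmental covariates

Terrain roughness is TR = 1/cos(slope), evaluated with full machine
precision for pi; the relative difference against a truncated 5-decimal pi
is below 1e-6 and has no practical effect, but there is no reason to carry
it. Slope comes from Horn's 3×3 weighted finite differences — the algorithm
standard GIS packages use — with border cells handled by edge replication
and no-data neighbours replaced by the centre value, so every valid cell
gets a slope.

Climate indices follow the WorldClim conventions: MAP is the *sum* of
twelve monthly precipitation values (not their mean), MTCM the minimum
monthly mean temperature, MAT the mean. The glacial–interglacial anomaly is
current MAT minus LGM MAT, so positive values mean warming since the LGM.
NDVI uses the monthly maximum-value composite: per cell, the maximum over
each month's dekadal layers (suppressing cloud contamination), then the
mean of the twelve monthly composites, then the mean over cells and years.
Reserve-level aggregation of any grid is the arithmetic mean over valid
cells.

PET has no canonical formula at this level of description; it is accepted
as a per-reserve input, and a clearly labelled Thornthwaite helper
(`pet_thornthwaite()`) is available for users who have only temperature.
Rasters are exchanged as ESRI ASCII grids, a plain-text format that
round-trips bit-exactly in tests; the reader honours the header's no-data
sentinel.

# Gradient fits

Richness responses are analysed on the natural-log scale (the standard
power-law linearisation for richness), MRD raw. Reserves with zero richness
in a group are dropped from that group's log fit with a recorded count —
they reflect presence-only species lists, not true absences of information.
A constant response returns a null fit (slope 0, R² 0, p 1) rather than an
error, so degenerate simulations remain comparable; a constant *latitude*
is always an error.

The quadratic peak is the vertex −b/(2a), reported only when the fit is
concave (a < 0) and the vertex falls inside the observed latitude range;
otherwise the reason (upward parabola, degenerate quadratic, vertex outside
data) is returned instead of a number. Model significance is the F test of
the full model; per-coefficient t tests are not used for significance
codes. Note that estimating the peak on log richness is exact for the
log-quadratic model but only approximately the peak of raw richness; all
peak estimates in this package are on the log scale.

The bivariate screen reports 100·R² per single-predictor OLS with the
conventional code thresholds (' < .1, * < .05, ** < .01, *** < .001) and
flags the top three predictors per response. AREA enters as its natural
log; since only Ln(AREA) is modelled, the unit of area affects intercepts
only.

# The importance stage

Pruning runs AIC first, then VIF, matching the order in which the two
criteria are conventionally listed; the order can be flipped in
`model_spec()`. AIC backward elimination removes single predictors while
any removal lowers AIC; ties break by declaration order, making the
procedure fully deterministic. The VIF stage then iteratively removes the
largest-VIF survivor until all VIFs are ≤ 10. VIF is computed from the
diagonal of the inverse correlation matrix, with a per-column
auxiliary-regression fallback when that matrix is singular; exact
collinearity reports as infinite rather than erroring, because dropping the
offender is precisely the stage's job. Worth knowing: plain AIC backward
elimination retains a pure-noise predictor whenever its squared t statistic
exceeds 2, i.e. in roughly 16% of random datasets — this is a property of
AIC, not a defect of the implementation, and the tests assert the drop rate
accordingly.

The forest is 200 bootstrap regression trees (`randomForest`, the seed
recorded in every report). Importance is out-of-bag *permutation*
importance, unscaled — more robust to predictor scale than node-impurity —
with negative raw values floored at zero before dividing by the maximum, so
reported importances lie in (0, 1] with the maximum exactly 1. If no
predictor beats the permutation null (a pure-noise response), the
normalised scale degenerates; the stage then reports an all-way tie at 1
with a warning rather than failing, so null simulations can still proceed
to the residual diagnostics. A predictor numerically identical to the
response triggers a leakage warning.

Moran's I uses great-circle (haversine) distances between reserve
centroids — the reserve is the unit of analysis, WGS84 decimal degrees
assumed — split into distance classes of approximately equal pair counts
(default 10), binary weights within a class, and 999 seeded permutations
for two-sided p values. The expectation under randomisation is −1/(n−1).
The residuals-independent flag uses a Bonferroni-corrected alpha across
classes (the standard correlogram-wide test): with ten classes each tested
at raw alpha = .05, about 40% of genuinely independent datasets would show
at least one "significant" class by chance alone, which would make the flag
useless; the corrected test keeps its false-alarm rate near the nominal 5%.
Raw per-class p values are always reported alongside.

# The synthetic-data generator

The generator is a first-class module: it encodes, in the simplest
functional forms consistent with the mechanisms above, the structure the
analysis assumes, and it records every equation and parameter in the
dataset's truth record.

* **Reserves.** Latitudes uniform on 19.1–51.5 °N, longitudes uniform on
  82–130 °E (no east–west structure; longitude exists to exercise the
  great-circle code). Winter coldness declines linearly with latitude
  (MTCM = 42 − 1.4·lat + noise, spanning roughly +15 to −30 °C), and the
  LGM analogue subtracts a cooling offset that grows northward
  (4 °C + 0.15 °C per degree), so LGM_MTCM spans about +11 to −39 °C.
  Precipitation, PET, NDVI follow their own declining gradients; elevation,
  habitat heterogeneity, terrain roughness, GDP, POP and area are drawn
  independently of latitude. A single `noise` multiplier scales all
  covariate noise; at zero the climate collapses exactly onto the declared
  gradients.
* **Species pool.** 150 Oriental, 150 Palearctic and 200 widespread
  species, each affinity spread evenly over the six modelled orders
  (balanced composition, so affinity MRD baselines differ only through the
  tolerance draws, not sampling noise). Tolerance limits are Gaussian:
  Oriental species have high cold limits (mean −2 °C — intolerant of
  glacial cold), Palearctic species low cold limits (−35) *and* low warm
  limits (−8, the competition-proxy exclusion from the warm south),
  widespread species a midlatitude band (−20 to +8). The cold limit is
  lowered by `cold_shift[clade] · (RD − 6)` — 4 °C per node in warm clades,
  3 °C per node in cold clades — so derived orders are stochastically more
  cold-tolerant, with the steeper coupling in the warm-originated clades.
* **Occupancy.** Deterministic interval filter: species *i* occurs at
  reserve *r* iff `cold_limit(i) ≤ LGM_MTCM(r) ≤ warm_limit(i)`. The filter
  is keyed to glacial (not current) winter coldness by default — the
  historical-signal hypothesis — switchable to current MTCM for contrast
  experiments. A `"random"` occupancy mode draws seeded Bernoulli presences
  with no geographic signal, the null used in validation.

The default phylogeny places the six modelled orders at node depths 4
(Orthoptera), 5 (Hemiptera), 6 (Hymenoptera), 7 (Coleoptera) and 9
(Lepidoptera, Diptera), the usual apterygote-to-holometabolan ladder with
Hymenoptera branching earliest within Holometabola. The cold clade then
spans depths {5, 7} and the warm clade {4, 6, 9, 9}; combined with the
per-clade coupling this yields positive MRD–latitude slopes in both clades
with the warm slope distinctly steeper — the qualitative contrast the
analysis is designed to detect.

Under these defaults (seeds 1–20, n = 110): Oriental richness declines and
Palearctic richness rises with latitude, total richness is concave with an
interior peak near 31 °N, MRD rises at roughly 0.02–0.04 nodes per degree
overall, warm-clade slopes are ~3–5× cold-clade slopes, and the importance
stage ranks LGM_MTCM at 1.0 for the Oriental-richness response in ≥ 95% of
replicates. The effect sizes (niche-limit means and sds, pool sizes, the
coupling strengths) are not derivable from any field estimate; they were
fixed once, sized so the patterns are detectable at n = 110 reserves, and
are recorded in the truth object. The driver-recovery check is run on the
*Oriental richness* response deliberately: the filter makes richness a
monotone function of glacial coldness for that group, whereas total
richness is hump-shaped, and a hump defeats the *linear* AIC screen that
precedes the forest — with a humped response the screen can discard the
true driver before the forest ever sees it. That behaviour is a real
property of linear-screen-then-forest pipelines and is preserved, not
patched around.

## What the simulator does not emulate

No dispersal limitation, speciation, competition dynamics (beyond the
Palearctic warm-limit proxy), sampling effort variation, spatial
autocorrelation in the covariate noise, or real geography. Passing tests on
synthetic data therefore demonstrate that the pipeline recovers the
mechanisms *it assumes*, under clean conditions — they say nothing about
detection sensitivity under sampling noise or confounded gradients in real
reserve data.

# Numerical choices and degenerate inputs

* Ties everywhere break by declaration order; a single recorded seed
  governs bootstrap and permutation draws, making every report bitwise
  reproducible.
* Equal-count Moran distance classes come from quantile breaks of the
  pairwise distances; heavily tied distances merge classes rather than
  producing empty ones, and genuinely empty classes are reported as such.
* The problem sizes used by the validation suite — 200 random trees up to
  12 tips, 100 random VIF designs, 1,000 random concave quadratics against
  a 0.001° grid argmax, 20 replicate simulations of 110 reserves for
  driver recovery — were chosen as the sizes at which each check is
  decisive for this design.
* Grids must be at least 3×3 for slope; months with no dekadal layers,
  tables with missing or non-numeric required columns, duplicate species
  within a reserve, one species in two orders, and constant values fed to
  Moran's I are all hard errors naming the offender.

# Known limitations

* MRD resolution is the order: within-order evolutionary structure is
  invisible, and order-level RD treats all species in an order as
  exchangeable.
* OLS gradient fits carry no spatial error structure; the package's
  position is the diagnostic one (fit, then test residuals for spatial
  autocorrelation), not the corrective one (SAR/GWR), and datasets whose
  residuals fail the Moran screen need methods beyond this package.
* Peak latitudes are estimated on log richness; for strongly skewed humps
  the raw-scale peak can sit elsewhere.
* The AIC screen is linear; genuinely hump-shaped predictor–response
  relationships can eliminate a true driver before the forest stage (see
  above). Quadratic terms for specific predictors (as done for PET via
  PET²) are the standard mitigation and are supported as ordinary columns.
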