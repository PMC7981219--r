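---
title: "Methods: occurrence-based sympatry, bioregions and body-size divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occurrence-based sympatry, bioregions and body-size divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sympatria)
```

# The question and the pipeline

When congeners meet, do they diverge? In species-rich clades such as
*Sceloporus* (spiny lizards), competition theory predicts that sympatric
congeners should differ in body size more often than chance would allow,
while phylogenetic conservatism pulls the other way: close relatives tend
to live near one another and to look alike. `sympatria` turns point
occurrence records, a dated phylogeny and a table of adult male
snout-to-vent lengths (SVL, mm) into the statistics that separate these
forces:

1. **Cleaning** — occurrences falling clearly outside a species' range
   polygon are removed (boundary-inclusive point-in-polygon, so a record
   on the range edge survives).
2. **Bioregions** — occurrences are binned on an adaptive quadtree grid,
   the species-by-cell bipartite network is built, and its cells are
   partitioned into bioregions; each region is summarised by richness,
   spherical area, centroid northing, elevation heterogeneity and biome
   count, and richness is correlated with those covariates.
3. **Sympatry** — a directed rule: species *a* is sympatric with *b* when
   at least `min_points` (default 10) of *a*'s occurrence points lie
   within `threshold_km` (default 5, inclusive) of some point of *b*.
4. **Divergent sympatry** — for each focal species the size-class counts
   of its sympatric congeners, O, are compared with expectations E from
   genus-wide class frequencies: χ² = Σ (O−E)²/E, multiplied by −1 when
   the focal's own class is over-represented (convergent sympatry).
5. **Comparative layer** — BM/OU/EB maximum-likelihood fits to SVL,
   Pagel's λ, GLS ancestral states, intercept-only PGLS residuals, and
   per-region MPD with standardized effect sizes under a tip-shuffling
   null.

Every stage is exercised end to end on synthetic data by
`simulate_and_run()`, so the whole analysis is testable without any
external occurrence snapshot.

# Models and their assumptions

## Trait evolution

All trait models are multivariate normal, `x ~ N(μ1, σ²W)`, differing in
the structure matrix built from the shared root-to-MRCA path lengths C:

* **BM**: `W = C`. σ² (mm² per unit branch length) and the root state μ
  have exact GLS closed forms; no optimisation is involved.
* **OU**: a non-stationary Ornstein–Uhlenbeck process conditioned on the
  root, `W_ij = exp(−2αT)(exp(2αC_ij) − 1)/(2α)` on an ultrametric tree
  of depth T. At α = 0 this is exactly BM, so the models are nested and
  the BM log-likelihood is always a candidate during profiling.
  Non-ultrametric input is an error, never a silent approximation.
* **EB** (early burst): rate decays as `σ² e^{rt}` with r ≤ 0, giving
  `W = (e^{rC} − 1)/r`, again nesting BM at r = 0.
* **Pagel's λ**: off-diagonal entries of C scaled by λ ∈ [0, 1]; λ = 1
  recovers BM and λ = 0 phylogenetic independence.

OU, EB and λ each profile a single parameter with σ² and μ concentrated
out analytically; the 1-D profile is searched from five deterministic
starting intervals and the nested null is always evaluated, so the
reported optimum can never fall below the BM likelihood by more than
round-off. `converged` is reported honestly: a degenerate optimum or
multi-start disagreement flags the fit rather than being hidden (an EB
fit on data without an early burst typically sits on the r = 0 boundary).

Ancestral states are the GLS conditional expectations of internal nodes
given the tips under the fitted BM model; the root estimate coincides
with the GLS root. Intercept-only PGLS (the trait regressed on a grand
mean under BM covariance) yields residuals interpretable as
phylogenetically detrended size; their C⁻¹-weighted sum is zero by
construction.

## Dispersion

MPD is the mean patristic distance over unordered pairs in an
assemblage. The null model shuffles tip labels across the pool of
species occurring in at least one assemblage ("taxa-labels" style),
recomputing every assemblage's MPD per draw with one shared permutation,
999 draws by default. SES = (obs − null mean)/null SD; negative SES means
clustering (closely related species share regions). The p-value quantile
uses the (r+1)/(n+1) rank convention, so it never reaches 0 or 1; an
assemblage equal to the whole pool has a constant null and is flagged
degenerate rather than scored.

## Sympatry geometry

Distances are haversine great-circle distances on a sphere of mean
radius 6371.0088 km; the ellipsoidal error is far below the 5 km
threshold granularity. "5 km or closer" is inclusive (≤). Each focal
point supports at most one count per partner species no matter how many
partner points are nearby, while a single partner point may support many
focal points — the rule counts the *focal's* occurrence points. The
matrix implementation buckets points on a threshold-sized grid and only
evaluates distances between neighbouring buckets; the test suite holds
it to exact equality with a brute-force all-pairs oracle. The rule is
directional by default (`N[a,b]` and `N[b,a]` may differ); an optional
`symmetrize` flag ORs the two calls and is recorded in the run manifest.

## Bioregions

The quadtree starts from 4° cells anchored at integer multiples of 4°
from (−180, −90), splits any cell holding more than `max_capacity = 100`
points while its side exceeds `min_deg = 2°`, and undoes a split whose
non-empty children fall below `min_capacity = 10` (empty children are
simply dropped). A forced merge can leave a leaf above capacity; that is
the intended fixed point of the split/merge rules, and the reference
oracle in the tests encodes the same behaviour.

Community detection is two-mode label propagation on the weighted
bipartite graph: cells start with unique labels, species and cells
alternately adopt the weighted-majority label of their neighbours with
lowest-id tie-breaking, and the update order is a seeded permutation, so
the partition is deterministic given the seed. The published analyses in
this area delegate this step to an external map-equation service; here
the clustering sits behind a single `detect_bioregions()` interface so a
different optimizer can be substituted without touching the rest of the
pipeline. The phylogeny is deliberately not used in clustering: no
published description of how it would enter exists, and downstream
stages only need a partition of cells by species composition.

Region area sums exact spherical quadrilateral areas
R²·Δλ·(sin φ₂ − sin φ₁); the centroid latitude is area-weighted (a
choice — the alternative, unweighted cell means, is not materially
different at these cell sizes) and northing is lat × πR/180 ≈ 111.195
km/degree. Raster cells are attributed to regions by cell-centre
containment. Missing rasters produce `NA` covariates, never zeros, and
the corresponding correlations are flagged undefined.

## Size classes and composition tests

The three SVL classes come from Fisher–Jenks optimal natural breaks: a
dynamic program over the distinct sorted values minimising total
within-class sum of squares (equal values always share a class; boundary
values classify into the lower class). Visual breaks from a histogram
can be supplied through `breaks =` and override the optimiser. The
goodness-of-fit tests are standard Pearson χ² with df = (categories with
positive expectation) − 1; for the three sign categories against a
uniform expectation that is df = 2. The genus pool behind the
expectations excludes the focal species by default (no self-counting);
`include_focal = TRUE` reproduces the inclusive convention, and the
choice is logged. The near-neutral sign category has half-width
`neutral_band`, default 0 — any three-way partition of scores requires
an explicit band, which is recorded in the report.

# The synthetic-data generator

`sim_config()` defaults define the study conditions: 69 congeners on a
Yule tree (rate 1 per unit time, the classic epoch construction whose
expected depth is Σ₂ⁿ 1/k), SVL evolving by BM with σ² = 8.07 mm² per
unit branch length around a 76 mm root, disc ranges of radius 100 km in
a Mexico-to-southern-US-sized domain (−125…−80°E, 8…42°N), 200 uniform
occurrence points per species, a 0.5° raster with five latitudinal-band
biomes and a smoothed Gaussian elevation field (mean 1000 m, SD 600 m).
The per-species point count and domain are desk-scale choices: they keep
an end-to-end run in seconds while leaving every rule (the 10-point,
5 km sympatry rule especially) well inside its operating regime.

Ranges are 64-vertex discs (area error below 0.5% of the true circle)
placed on a slot grid via the equirectangular approximation at the
domain centre; pairs named in `cooccurrence_pairs` are separated by the
centre distance that yields the requested overlap area fraction
(circle–circle intersection inverted numerically), all other discs are
disjoint with a guaranteed gap, and an overfull domain raises a packing
error rather than silently overlapping. A species may appear in at most
one pair — chains of overlap constraints are not representable by
independent disc placements. `cooccurrence_design()` builds the two
designs the tests plant: *divergent* (each small species overlaps a
large one) and *assorted* (adjacent sizes overlap).

What the generator does **not** emulate: niche- or climate-driven range
shapes, spatial sampling bias, observation error, coordinate
uncertainty, or intraspecific size variation. Passing tests therefore
demonstrate that the statistics recover planted structure under clean
sampling — not that any particular empirical data set is free of the
biases real occurrence archives carry.

Randomness is controlled by one root seed; each stage derives a child
seed from its name (`child_seed()`), so regenerating one artifact never
perturbs the others and every generator is bit-reproducible.

# Numerical choices

* Likelihoods use Cholesky factorisations throughout; a non-positive
  quadratic form (all tip values equal) is flagged `degenerate`, not
  propagated as −∞.
* OU/EB near their nulls switch to the exact BM limit below 10⁻¹⁰/T to
  avoid 0/0.
* Label propagation breaks ties toward the lowest label id and caps at
  100 sweeps (fixed points are reached in a handful).
* Point-in-polygon is even-odd ray casting with an explicit on-edge
  check, so boundary points are inside.
* Quadtree cell membership is half-open `[min, max)`; occurrences on the
  domain's extreme eastern/northern edge would fall into the next cell,
  which the generator's interior domains never produce.
* Species centroids are arithmetic lon/lat means with no antimeridian
  unwrapping — correct for an Americas-scale domain and documented as a
  caveat elsewhere.
* Duplicate occurrence records are retained; deduplication is an
  explicit, visible cleaning decision left to the user.

# Problem sizes in the test suite

The property tests run at sizes chosen to make their statistics sharp:
100 random instances against the brute-force sympatry oracle (3–10
species, ≤600 points each); 50 random vectors against exhaustive
natural-breaks enumeration; 200 replicates of σ² recovery and 100 of λ
recovery/destruction on a 200-tip tree (the ML σ̂² carries the (n−1)/n
factor, so the recovery check compares the bias-corrected replicate mean
to the truth within a 99% CI); 1000 replicates of MPD-SES calibration at
199 null draws each (the calibration criterion fixes the replicate
count; the null count per replicate is the package's choice); and
end-to-end planted-design recovery at 12–16 species × 150 points.

# Known limitations

* The bioregion partition is a deterministic label-propagation
  surrogate, not a map-equation optimizer; region counts on sparse or
  disconnected networks tend to be finer than a flow-based method would
  produce.
* Intercept-only PGLS detrends size but cannot adjust for unmeasured
  predictors; the residual–divergence correlation inherits whatever
  structure the sympatry rule's threshold imposes.
* The arithmetic-mean centroid and equirectangular range placement are
  adequate for mid-latitude continental domains only.
* MPD/SES uses unrestricted tip shuffling; richness and occupancy
  structure are preserved, but spatial autocorrelation in sampling is
  not part of the null.
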