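# sympatria

Occurrence-based analysis of congeneric sympatry and body-size divergence
in species-rich clades.

Competition between close relatives should favour coexistence of species
that differ in body size, while phylogenetic conservatism keeps relatives
both nearby and similar. Given three inputs a herpetologist or
macroecologist can actually assemble — a table of point occurrences
(species, longitude, latitude), a rooted phylogeny with branch lengths,
and mean adult male snout-to-vent lengths (SVL, mm) — `sympatria`
computes the statistics that separate those forces:

* **Directed sympatry rule.** Species *a* is sympatric with *b* when at
  least `min_points` (default 10) of *a*'s occurrence points lie within
  `threshold_km` (default 5, inclusive) of some point of *b*, with
  great-circle (haversine) distances on a sphere of radius 6371.0088 km.
* **Divergent sympatry.** For each focal species with sympatric-congener
  size-class counts O = (O_s, O_m, O_l) and genus-frequency expectations
  E, the signed statistic is

  χ² = Σ_c (O_c − E_c)² / E_c, negated when the focal's own size class
  is over-represented (convergent sympatry). Size classes are
  Fisher–Jenks natural breaks (optimal 1-D classification minimising
  within-class SS).
* **Bioregions.** Occurrences binned on an adaptive quadtree grid
  (4° → 2° cells, capacities 100/10); the species-by-cell bipartite
  network is partitioned by seeded two-mode label propagation; regions
  are summarised (richness, spherical area, centroid northing, elevation
  SD, biome count) and richness is correlated with each covariate
  (Spearman and Pearson, plus an OLS of richness on biome count).
* **Phylogenetic layer.** BM / OU / early-burst maximum-likelihood fits
  to SVL, Pagel's λ, GLS ancestral states, intercept-only PGLS
  residuals, and per-region MPD (mean pairwise patristic distance) with
  standardized effect sizes, SES = (MPD_obs − MPD_null)/SD_null, under a
  tip-shuffling null — negative SES means phylogenetic clustering.

A synthetic-data generator (Yule trees, Brownian SVL, disc ranges with a
controllable co-occurrence design, occurrence clouds, elevation and
biome rasters) makes the entire pipeline testable end to end without
external data.

## Worked example

Simulate 16 species under a planted *size-divergent* design (each small
species' range overlaps a large species' range) and run the full
pipeline:

```r
library(sympatria)
sim <- sim_config(n_species = 16, n_points_per_species = 150,
                  domain_bbox = c(-115, 12, -85, 38), range_radius_km = 110,
                  raster_resolution_deg = 1, n_biomes = 3, seed = 11)
res <- simulate_and_run(sim, dir = "run1", design = "divergent", n_null = 199)

print(res$classification)
#> Size classification: 16 species in 3 classes
#>   breaks (mm): 70.680, 78.043
#>   counts: small=3, medium=5, large=8
print(res$sympatry)
#> Directed sympatry matrix: 16 species, threshold 5 km, min 10 points
#>   6 directed sympatry calls
print(res$fits$bm)
#> BM fit: logLik = -42.8972, sigma2 = 11.91, root = 76.55 mm
print(res$fits$lambda)
#> Pagel's lambda: 0.9823 (logLik = -42.6302, sigma2 = 10.08)
```

The three small species all co-occur with a larger congener, so every
defined small-species score is positive (divergent sympatry):

```r
res$divergence[res$divergence$defined,
               c("focal", "class", "chi2", "sign", "signed_score")]
#>  focal class  chi2 sign signed_score
#>  sp001 large 4.000    1        4.000
#>  sp002 small 0.875    1        0.875
#>  sp004 large 4.000    1        4.000
#>  sp007 small 0.875    1        0.875
#>  sp008 small 0.875    1        0.875
#>  sp010 large 4.000    1        4.000
```

`sigma2 = 11.91` is the ML Brownian rate (mm² per unit branch length;
the generating value was 8.07 — a 16-species realisation is noisy),
`root = 76.55 mm` the GLS root state (generated at 76 mm), and λ close
to 1 says size carries strong phylogenetic signal, as expected for BM
data. Per-region dispersion (`res$dispersion`) reports observed MPD,
the null mean, SES and p-quantile per bioregion; negative SES rows are
regions whose species are closer on the tree than random pool draws.

All stage tables (cells, network edges, region summaries, sympatry,
divergence, fits, MPD, correlates) are written as CSV to the output
directory together with `manifest.json` — configuration echo, per-stage
seeds and content digests; re-running the same configuration reproduces
byte-identical outputs.

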