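# Synthetic-data generators: tree shape, Brownian increments, range
# overlap design, occurrence sampling, rasters, and determinism.

test_that("two-tip Yule tree is a cherry with equal positive tip branches", {
  tr <- simulate_yule_tree(2, 1.0, seed = 42)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 2)
  expect_equal(tr$Nnode, 1)
  expect_true(all(tr$edge.length > 0))
  expect_equal(tr$edge.length[1], tr$edge.length[2])
})

test_that("Yule simulation is deterministic under a fixed seed and ultrametric", {
  t1 <- simulate_yule_tree(50, 1.0, seed = 7)
  t2 <- simulate_yule_tree(50, 1.0, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  depths <- ape::node.depth.edgelength(t1)[1:50]
  expect_lt(diff(range(depths)), 1e-9)
  expect_true(ape::is.binary(t1))
  expect_error(simulate_yule_tree(1, 1.0), "n_tips")
})

test_that("mean Yule depth matches the analytic expectation", {
  # E[depth] = sum_{k=2}^{50} 1/k for birth rate 1
  expected <- sum(1 / (2:50))
  depths <- vapply(1:1000, function(s) {
    tr <- simulate_yule_tree(50, 1.0, seed = 20000 + s)
    max(ape::node.depth.edgelength(tr))
  }, 0)
  # MC standard error ~ sqrt(sum 1/k^2)/sqrt(1000) ~ 0.025
  expect_lt(abs(mean(depths) - expected), 0.085)
})

test_that("Brownian trait simulation has the right degenerate and diffusive behaviour", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(simulate_bm_trait(tr, 50, 0, seed = 1)), c(50, 50))
  expect_error(simulate_bm_trait(tr, 50, -1), "sigma2")
  x1 <- simulate_bm_trait(tr, 50, 4, seed = 9)
  expect_identical(x1, simulate_bm_trait(tr, 50, 4, seed = 9))
  # var(x1 - x2) = 2 sigma2 t on a two-tip star
  diffs <- vapply(1:10000, function(s) {
    x <- simulate_bm_trait(tr, 0, 3, seed = s)
    x[[1]] - x[[2]]
  }, 0)
  expect_lt(abs(var(diffs) - 6) / 6, 0.06)
})

test_that("range generation honours the co-occurrence design", {
  cfg <- sim_config(n_species = 8, n_points_per_species = 10,
                    domain_bbox = c(-110, 15, -90, 35), range_radius_km = 80,
                    seed = 3,
                    cooccurrence_pairs = list(list("sp001", "sp002", 0.5),
                                              list("sp003", "sp004", 1.0)))
  rg <- generate_ranges(cfg)
  a <- polygon_area(rg[["sp001"]])
  f_half <- convex_intersection_area(rg[["sp001"]], rg[["sp002"]]) / a
  expect_gte(f_half, 0.45); expect_lte(f_half, 0.55)
  f_full <- convex_intersection_area(rg[["sp003"]], rg[["sp004"]]) /
    polygon_area(rg[["sp003"]])
  expect_equal(f_full, 1, tolerance = 1e-9)
  # all non-designed pairs disjoint
  others <- c("sp005", "sp006", "sp007", "sp008")
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(convex_intersection_area(rg[[others[i]]], rg[[others[j]]]), 0)
  # paired discs do not leak into other species' discs
  expect_equal(convex_intersection_area(rg[["sp001"]], rg[["sp005"]]), 0)
})

test_that("disjoint-design ranges are pairwise disjoint and packing failures are loud", {
  cfg <- sim_config(n_species = 6, domain_bbox = c(-105, 18, -92, 30),
                    range_radius_km = 50, seed = 5)
  rg <- generate_ranges(cfg)
  sp <- names(rg)
  for (i in seq_along(sp)) for (j in seq_len(i - 1))
    expect_equal(convex_intersection_area(rg[[sp[i]]], rg[[sp[j]]]), 0)
  tight <- sim_config(n_species = 60, domain_bbox = c(-105, 18, -92, 30),
                      range_radius_km = 50, seed = 5)
  expect_error(generate_ranges(tight), "packing")
})

test_that("occurrence sampling stays inside ranges with exact counts", {
  cfg <- sim_config(n_species = 5, domain_bbox = c(-110, 15, -90, 35),
                    range_radius_km = 100, seed = 4)
  rg <- generate_ranges(cfg)
  occ <- sample_occurrences(rg, 37, seed = 8)
  expect_true(all(table(occ$species) == 37))
  for (s in names(rg))
    expect_true(all(points_in_polygon(occ$longitude[occ$species == s],
                                      occ$latitude[occ$species == s],
                                      rg[[s]])))
  expect_identical(occ, sample_occurrences(rg, 37, seed = 8))
})

test_that("a near-point polygon collapses sampling onto its centroid", {
  theta <- 2 * pi * (0:63) / 64
  tiny <- cbind(-100 + 1e-8 * cos(theta), 30 + 1e-8 * sin(theta))
  occ <- sample_occurrences(list(dot = tiny), 1, seed = 1)
  expect_lt(abs(occ$longitude - (-100)), 1e-6)
  expect_lt(abs(occ$latitude - 30), 1e-6)
  expect_error(sample_occurrences(list(bad = tiny[1:2, ]), 1), "polygon")
})

test_that("rasters honour biome counts, flatness, and determinism", {
  cfg <- sim_config(n_species = 5, domain_bbox = c(-110, 15, -90, 35),
                    raster_resolution_deg = 1, n_biomes = 4, seed = 6)
  ras <- generate_rasters(cfg)
  expect_equal(sort(unique(as.vector(ras$biome$values))), 1:4)
  flat <- sim_config(n_species = 5, domain_bbox = c(-110, 15, -90, 35),
                     raster_resolution_deg = 1, n_biomes = 1, elev_sd = 0,
                     seed = 6)
  fras <- generate_rasters(flat)
  expect_equal(length(unique(as.vector(fras$biome$values))), 1)
  expect_true(all(fras$elevation$values == flat$elev_mean))
  ras2 <- generate_rasters(cfg)
  expect_identical(ras$elevation$values, ras2$elevation$values)
  bad <- sim_config(n_species = 5, domain_bbox = c(-110, 15, -90, 35),
                    raster_resolution_deg = 0.7, seed = 6)
  expect_error(generate_rasters(bad), "divide")
})

test_that("generated artifacts round-trip through their interchange formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_species = 6, n_points_per_species = 15,
                    domain_bbox = c(-110, 15, -90, 35), range_radius_km = 80,
                    raster_resolution_deg = 1, seed = 11)
  dat <- simulate_dataset(cfg, dir = dir)
  tr2 <- read_tree(dat$files$tree)
  expect_equal(sort(tr2$tip.label), sort(dat$tree$tip.label))
  expect_equal(ape::cophenetic.phylo(tr2)[dat$tree$tip.label, dat$tree$tip.label],
               ape::cophenetic.phylo(dat$tree), tolerance = 1e-9)
  expect_equal(read_traits(dat$files$traits), dat$traits, tolerance = 1e-9)
  occ2 <- read_occurrences(dat$files$occurrences)
  expect_equal(occ2$longitude, dat$occurrences$longitude, tolerance = 1e-9)
  rg2 <- read_ranges(dat$files$ranges)
  expect_equal(rg2[["sp001"]][, 1], dat$ranges[["sp001"]][, 1], tolerance = 1e-9)
  el2 <- read_raster(dat$files$elevation)
  expect_equal(el2$values, dat$rasters$elevation$values, tolerance = 1e-9)
  expect_equal(el2$origin, dat$rasters$elevation$origin)
})
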