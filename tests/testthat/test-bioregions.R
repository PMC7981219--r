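# Adaptive quadtree binning, the species-by-cell network, label-propagation
# bioregions, and per-region summaries and correlates.

unit_occ <- function(lon, lat, species = "a")
  data.frame(species = species, longitude = lon, latitude = lat)

test_that("a below-capacity cell stays a single 4-degree leaf", {
  set.seed(1)
  occ <- unit_occ(runif(50, -100, -96.01), runif(50, 26, 29.99))
  q <- quadtree_bin(occ)
  expect_equal(nrow(q$cells), 1)
  expect_equal(q$cells$side, 4)
  expect_equal(q$cells$count, 50L)
  expect_equal(q$cells$lon_min, -100)
  expect_equal(q$cells$lat_min, 26)
})

test_that("an over-capacity cell splits once down to the 2-degree floor", {
  set.seed(2)
  occ <- unit_occ(runif(400, -100, -96.001), runif(400, 26, 29.999))
  q <- quadtree_bin(occ)
  expect_true(all(q$cells$side == 2))
  expect_equal(nrow(q$cells), 4)
  expect_equal(sum(q$cells$count), 400L)
  # min-size leaves may exceed capacity; here they are all near 100
  expect_true(all(q$cells$count > 10))
})

test_that("corner-concentrated points leave one min-size leaf; empties drop", {
  set.seed(3)
  occ <- unit_occ(runif(101, -100, -98.01), runif(101, 26, 27.99))
  q <- quadtree_bin(occ)
  expect_equal(nrow(q$cells), 1)
  expect_equal(q$cells$side, 2)
  expect_equal(q$cells$count, 101L)
})

test_that("a sparse sibling forces the split to be undone", {
  set.seed(4)
  occ <- rbind(unit_occ(runif(95, -100, -98.01), runif(95, 26, 27.99)),
               unit_occ(runif(6, -98, -96.01), runif(6, 28, 29.99)))
  q <- quadtree_bin(occ)
  expect_equal(nrow(q$cells), 1)
  expect_equal(q$cells$side, 4)
  expect_equal(q$cells$count, 101L)
})

test_that("leaves match the independent recursive oracle on random instances", {
  for (seed in 1:10) {
    occ <- random_occ_instance(3, 150, c(-104, 26, -96, 34), seed = seed,
                               cluster_sd = 1.5)
    q <- quadtree_bin(occ)
    got <- q$cells[c("lon_min", "lat_min", "side", "count")]
    names(got) <- c("x0", "y0", "side", "count")
    got <- got[order(got$x0, got$y0, got$side), ]
    oracle <- quadtree_oracle(occ)
    expect_equal(got, oracle, ignore_attr = TRUE)
    # tiling: every point in exactly one leaf
    expect_equal(sum(q$cells$count), nrow(occ))
    expect_equal(sort(unname(unlist(q$points))), seq_len(nrow(occ)))
  }
})

test_that("halving max_capacity never coarsens any leaf", {
  occ <- random_occ_instance(4, 200, c(-104, 26, -96, 34), seed = 77,
                             cluster_sd = 1.5)
  q_loose <- quadtree_bin(occ, max_capacity = 100)
  q_tight <- quadtree_bin(occ, max_capacity = 50)
  side_at <- function(q, lon, lat) {
    hit <- q$cells$lon_min <= lon & lon < q$cells$lon_max &
      q$cells$lat_min <= lat & lat < q$cells$lat_max
    q$cells$side[hit]
  }
  for (i in sample(nrow(occ), 50))
    expect_lte(side_at(q_tight, occ$longitude[i], occ$latitude[i]),
               side_at(q_loose, occ$longitude[i], occ$latitude[i]))
  expect_error(quadtree_bin(occ, max_deg = 4, min_deg = 3), "2\\^k")
})

test_that("the bipartite network conserves occurrence weight", {
  occ <- rbind(unit_occ(rep(-99, 7), rep(29, 7), "a"),
               unit_occ(rep(-91, 4), rep(29, 4), "b"))
  q <- quadtree_bin(occ)
  net <- build_bipartite(q, occ)
  expect_equal(nrow(net$edges), 2)
  expect_equal(sum(net$edges$weight), nrow(occ))
  expect_equal(net$edges$weight[net$edges$species == "a"], 7L)
  expect_length(intersect(net$edges$cell_id[net$edges$species == "a"],
                          net$edges$cell_id[net$edges$species == "b"]), 0)
})

test_that("label propagation merges a single species' cells into one region", {
  occ <- unit_occ(c(-99, -95, -91), c(29, 29, 29))
  q <- quadtree_bin(occ)
  net <- build_bipartite(q, occ)
  asg <- detect_bioregions(net, seed = 1)
  expect_equal(asg$n_regions, 1)
})

test_that("disconnected blocks become distinct regions, deterministically", {
  occ <- rbind(
    unit_occ(c(-99, -95), c(29, 29), "A"), unit_occ(c(-99, -95), c(29, 29), "B"),
    unit_occ(c(-79, -75), c(9, 9), "C"), unit_occ(c(-79, -75), c(9, 9), "D"))
  q <- quadtree_bin(occ)
  net <- build_bipartite(q, occ)
  asg <- detect_bioregions(net, seed = 5)
  expect_equal(asg$n_regions, 2)
  blocks <- split(names(asg$cell_region), asg$cell_region)
  # the two 2-cell blocks are exactly the detected regions
  lon_of <- function(cells) sort(as.numeric(sub("c_(-?[0-9.]+)_.*", "\\1", cells)))
  expect_setequal(lapply(blocks, lon_of), list(c(-100, -96), c(-80, -76)))
  expect_identical(asg$cell_region, detect_bioregions(net, seed = 5)$cell_region)
})

test_that("planted two-block networks are recovered under dominant within-block weight", {
  for (seed in 1:20) {
    set.seed(seed)
    # two blocks of 4 species x 3 cells; heavy within, light across
    edges <- rbind(
      expand.grid(species = paste0("a", 1:4), cell_id = paste0("cellA", 1:3),
                  stringsAsFactors = FALSE),
      expand.grid(species = paste0("b", 1:4), cell_id = paste0("cellB", 1:3),
                  stringsAsFactors = FALSE))
    edges$weight <- sample(20:40, nrow(edges), replace = TRUE)
    cross <- data.frame(species = "a1", cell_id = "cellB1",
                        weight = sample(1:2, 1))
    net <- structure(list(edges = rbind(edges, cross),
                          species = sort(unique(c(edges$species))),
                          cells = sort(unique(edges$cell_id))),
                     class = "bipartite_network")
    asg <- detect_bioregions(net, seed = seed)
    expect_equal(asg$n_regions, 2)
    grp <- split(names(asg$cell_region), asg$cell_region)
    expect_setequal(lapply(grp, sort),
                    list(paste0("cellA", 1:3), paste0("cellB", 1:3)))
  }
})

test_that("region summaries compute spherical areas and raster covariates", {
  # one-degree cell at the equator: R^2 * (pi/180) * sin(1 deg)
  expect_equal(cell_area_km2(0, 0, 1, 1), 12363.6, tolerance = 1e-4)
  occ <- unit_occ(c(-99.5, -99.4, -99.3), c(29.5, 29.4, 29.3))
  q <- quadtree_bin(occ)
  net <- build_bipartite(q, occ)
  asg <- detect_bioregions(net, seed = 1)
  flat <- raster_grid(matrix(500, 8, 8), origin = c(-104, 26), cellsize = 1)
  onebiome <- raster_grid(matrix(3, 8, 8), origin = c(-104, 26), cellsize = 1,
                          categorical = TRUE)
  s <- summarize_bioregions(asg, q, flat, onebiome)
  expect_equal(s$elevation_sd_m, 0)
  expect_equal(s$n_biomes, 1)
  expect_equal(s$area_km2, cell_area_km2(-100, 26, -96, 30))
  expect_equal(s$centroid_lat, 28)
  expect_equal(s$centroid_northing_km, 28 * pi * 6371.0088 / 180)
  # absent rasters give NA fields, not zeros
  s0 <- summarize_bioregions(asg, q)
  expect_true(is.na(s0$elevation_sd_m) && is.na(s0$n_biomes))
})

test_that("richness correlates flag degenerate covariates and find exact fits", {
  summ <- data.frame(region = 1:5, richness = c(2, 4, 6, 8, 10),
                     area_km2 = c(5, 3, 8, 1, 9) * 1e4,
                     centroid_northing_km = c(1000, 2000, 1500, 800, 2500),
                     elevation_sd_m = rep(100, 5),
                     n_biomes = c(1, 2, 3, 4, 5))
  # perfect collinearity by construction triggers lm's perfect-fit warning
  res <- suppressWarnings(richness_correlates(summ))
  ols <- res[res$statistic == "ols_F", ]
  expect_equal(ols$r_squared, 1, tolerance = 1e-12)
  expect_equal(ols$df2, 3L)
  elev <- res[res$covariate == "elevation_sd_m", ]
  expect_true(all(!elev$defined))
  expect_error(richness_correlates(summ[1:2, ]), "3 regions")
})

test_that("correlation p-values are calibrated under a permutation null", {
  set.seed(123)
  p_vals <- replicate(1000, {
    x <- rnorm(16); y <- rnorm(16)
    correlate(x, y, "pearson")$p_value
  })
  expect_gt(mean(p_vals <= 0.05), 0.03)
  expect_lt(mean(p_vals <= 0.05), 0.07)
})
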