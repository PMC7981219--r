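# Adaptive-resolution binning of occurrences, the species-by-cell bipartite
# network, bioregion detection by two-mode label propagation, and per-region
# summaries and richness correlates.

#' Adaptive quadtree binning of occurrences
#'
#' Starts from a lattice of `max_deg` cells anchored at integer multiples of
#' `max_deg` from (-180, -90) and recursively quarters any cell holding more
#' than `max_capacity` points while its side exceeds `min_deg`. After a
#' split, if any resulting non-empty leaf holds fewer than `min_capacity`
#' points the split is undone and the parent becomes the leaf (so sparse
#' corners are not shattered); empty cells are simply dropped.
#'
#' @param occ occurrence data.frame.
#' @param max_deg maximum (starting) cell side, degrees.
#' @param min_deg minimum cell side; `max_deg` must be `min_deg * 2^k`.
#' @param max_capacity split cells holding more points than this.
#' @param min_capacity merge back splits that produce non-empty leaves
#'   smaller than this.
#' @return object of class `grid_cells`: data.frame of leaves (`cell_id`,
#'   bbox, `side`, `count`) plus a list mapping cell id to point indices.
#' @export
quadtree_bin <- function(occ, max_deg = 4, min_deg = 2, max_capacity = 100,
                         min_capacity = 10) {
  occ <- .as_occurrences(occ)
  k <- log2(max_deg / min_deg)
  if (max_deg <= 0 || min_deg <= 0 || abs(k - round(k)) > 1e-9 || k < 0)
    stop("max_deg must be min_deg * 2^k for integer k >= 0", call. = FALSE)

  # top-level lattice anchored at multiples of max_deg from (-180, -90)
  ix <- floor((occ$longitude + 180) / max_deg)
  iy <- floor((occ$latitude + 90) / max_deg)
  tops <- split(seq_len(nrow(occ)), paste(ix, iy, sep = "_"))

  recurse <- function(idx, x0, y0, side) {
    n <- length(idx)
    if (n == 0) return(NULL)
    leaf <- list(list(x0 = x0, y0 = y0, side = side, idx = idx))
    if (n <= max_capacity || side <= min_deg + 1e-12) return(leaf)
    half <- side / 2
    lon <- occ$longitude[idx]; lat <- occ$latitude[idx]
    right <- lon >= x0 + half; top <- lat >= y0 + half
    children <- list(
      recurse(idx[!right & !top], x0, y0, half),
      recurse(idx[right & !top], x0 + half, y0, half),
      recurse(idx[!right & top], x0, y0 + half, half),
      recurse(idx[right & top], x0 + half, y0 + half, half)
    )
    leaves <- do.call(c, children)
    if (any(vapply(leaves, function(l) length(l$idx), 0L) < min_capacity))
      return(leaf)   # undo the split: parent becomes the leaf
    leaves
  }

  leaves <- list()
  for (key in sort(names(tops))) {
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    x0 <- -180 + ij[1] * max_deg
    y0 <- -90 + ij[2] * max_deg
    leaves <- c(leaves, recurse(tops[[key]], x0, y0, max_deg))
  }
  cells <- data.frame(
    cell_id = vapply(leaves, function(l)
      sprintf("c_%g_%g_%g", l$x0, l$y0, l$side), ""),
    lon_min = vapply(leaves, function(l) l$x0, 0),
    lat_min = vapply(leaves, function(l) l$y0, 0),
    side = vapply(leaves, function(l) l$side, 0),
    count = vapply(leaves, function(l) length(l$idx), 0L),
    stringsAsFactors = FALSE
  )
  cells$lon_max <- cells$lon_min + cells$side
  cells$lat_max <- cells$lat_min + cells$side
  ord <- order(cells$cell_id)
  cells <- cells[ord, , drop = FALSE]
  rownames(cells) <- NULL
  points <- lapply(leaves[ord], function(l) l$idx)
  names(points) <- cells$cell_id
  structure(list(cells = cells, points = points,
                 max_deg = max_deg, min_deg = min_deg,
                 max_capacity = max_capacity, min_capacity = min_capacity),
            class = "grid_cells")
}

#' @export
print.grid_cells <- function(x, ...) {
  cat(sprintf("Adaptive grid: %d leaf cells (sides %s deg), %d points\n",
              nrow(x$cells),
              paste(sort(unique(x$cells$side)), collapse = "/"),
              sum(x$cells$count)))
  invisible(x)
}

#' Species-by-cell bipartite network
#'
#' One weighted edge per (species, cell) pair, weight = number of that
#' species' occurrences in the cell; total edge weight equals the number of
#' binned occurrences.
#'
#' @param cells a [quadtree_bin()] result.
#' @param occ the occurrence data.frame the cells were built from.
#' @return object of class `bipartite_network`: edge data.frame (`species`,
#'   `cell_id`, `weight`) plus node lists.
#' @export
build_bipartite <- function(cells, occ) {
  stopifnot(inherits(cells, "grid_cells"))
  occ <- .as_occurrences(occ)
  covered <- sum(lengths(cells$points))
  if (covered != nrow(occ))
    stop("cells do not cover all occurrences", call. = FALSE)
  rows <- lapply(names(cells$points), function(cid) {
    tab <- table(occ$species[cells$points[[cid]]])
    data.frame(species = names(tab), cell_id = cid,
               weight = as.integer(tab), stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  edges <- edges[order(edges$cell_id, edges$species), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 species = sort(unique(edges$species)),
                 cells = sort(unique(edges$cell_id))),
            class = "bipartite_network")
}

#' Detect bioregions by two-mode label propagation
#'
#' Partitions the cells of the species-by-cell network into bioregions:
#' every cell starts with a unique label, then species and cells
#' alternately adopt the weighted-majority label of their neighbours (ties
#' broken by the lowest label id) until a fixed point. The node update
#' order is a seeded permutation, so the result is deterministic given the
#' seed. Regions are the distinct final cell labels, renumbered in cell-id
#' order.
#'
#' @param net a [build_bipartite()] network.
#' @param seed integer seed.
#' @param max_iter iteration cap (a fixed point is normally reached in a
#'   handful of sweeps).
#' @return object of class `bioregion_assignment`: `cell_region` (named
#'   region id per cell), `region_species` (species set per region, union
#'   over member cells), `n_regions`.
#' @export
detect_bioregions <- function(net, seed = 1, max_iter = 100) {
  stopifnot(inherits(net, "bipartite_network"))
  if (nrow(net$edges) == 0) stop("empty network", call. = FALSE)
  cells <- net$cells
  species <- net$species
  cell_lab <- seq_along(cells); names(cell_lab) <- cells
  sp_lab <- rep(NA_integer_, length(species)); names(sp_lab) <- species

  by_sp <- split(net$edges[c("cell_id", "weight")], net$edges$species)
  by_cell <- split(net$edges[c("species", "weight")], net$edges$cell_id)
  majority <- function(labels, weights) {
    agg <- tapply(weights, labels, sum)
    best <- names(agg)[agg == max(agg)]
    as.integer(min(as.integer(best)))   # lowest-id tie-break
  }

  set.seed(seed)
  sp_order <- sample(species)
  cell_order <- sample(cells)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (s in sp_order) {
      e <- by_sp[[s]]
      new <- majority(cell_lab[e$cell_id], e$weight)
      if (is.na(sp_lab[s]) || new != sp_lab[s]) { sp_lab[s] <- new; changed <- TRUE }
    }
    for (cc in cell_order) {
      e <- by_cell[[cc]]
      new <- majority(sp_lab[e$species], e$weight)
      if (new != cell_lab[cc]) { cell_lab[cc] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  # renumber regions 1..K by first appearance in sorted cell-id order
  uniq <- unique(cell_lab[sort(cells)])
  region <- match(cell_lab, uniq)
  names(region) <- names(cell_lab)
  region_species <- lapply(seq_along(uniq), function(r) {
    member_cells <- names(region)[region == r]
    sort(unique(net$edges$species[net$edges$cell_id %in% member_cells]))
  })
  names(region_species) <- as.character(seq_along(uniq))
  structure(list(cell_region = region, region_species = region_species,
                 n_regions = length(uniq), seed = seed),
            class = "bioregion_assignment")
}

#' @export
print.bioregion_assignment <- function(x, ...) {
  cat(sprintf("Bioregion assignment: %d regions over %d cells\n",
              x$n_regions, length(x$cell_region)))
  rich <- vapply(x$region_species, length, 0L)
  cat(sprintf("  richness per region: %s\n", paste(rich, collapse = ", ")))
  invisible(x)
}

#' Per-bioregion summaries
#'
#' Computes, for each region: species richness; area as the sum of member
#' cells' spherical quadrilateral areas; area-weighted centroid latitude
#' and its northing (great-circle distance from the equator); the standard
#' deviation of elevation over raster cells whose centres fall in the
#' region; the number of distinct biome labels among those cells; and
#' size-class counts of the region's species. Raster-derived fields are
#' `NA` (not zero) when the corresponding raster is absent.
#'
#' @param assignment a [detect_bioregions()] result.
#' @param cells the [quadtree_bin()] result the assignment was built on.
#' @param elevation optional elevation `raster_grid` (metres).
#' @param biome optional categorical biome `raster_grid`.
#' @param cls optional [classify_sizes()] result.
#' @return data.frame, one row per region.
#' @export
summarize_bioregions <- function(assignment, cells, elevation = NULL,
                                 biome = NULL, cls = NULL) {
  stopifnot(inherits(assignment, "bioregion_assignment"),
            inherits(cells, "grid_cells"))
  cdf <- cells$cells
  cdf$region <- assignment$cell_region[cdf$cell_id]
  if (anyNA(cdf$region))
    stop("assignment inconsistent with cells", call. = FALSE)
  cdf$area <- cell_area_km2(cdf$lon_min, cdf$lat_min, cdf$lon_max, cdf$lat_max)
  cdf$clat <- (cdf$lat_min + cdf$lat_max) / 2

  in_region_cells <- function(pts, sub) {
    hit <- rep(FALSE, nrow(pts))
    for (i in seq_len(nrow(sub)))
      hit <- hit | (pts$longitude >= sub$lon_min[i] &
                      pts$longitude < sub$lon_max[i] &
                      pts$latitude >= sub$lat_min[i] &
                      pts$latitude < sub$lat_max[i])
    hit
  }
  elev_pts <- if (!is.null(elevation)) raster_cell_centers(elevation)
  biome_pts <- if (!is.null(biome)) raster_cell_centers(biome)

  rows <- lapply(sort(unique(cdf$region)), function(r) {
    sub <- cdf[cdf$region == r, , drop = FALSE]
    sp <- assignment$region_species[[as.character(r)]]
    area <- sum(sub$area)
    clat <- sum(sub$clat * sub$area) / area
    elev_sd <- n_biomes <- NA_real_
    if (!is.null(elev_pts)) {
      v <- elev_pts$value[in_region_cells(elev_pts, sub)]
      v <- v[v != elevation$nodata]
      elev_sd <- if (length(v) > 1) stats::sd(v) else if (length(v) == 1) 0 else NA_real_
    }
    if (!is.null(biome_pts)) {
      v <- biome_pts$value[in_region_cells(biome_pts, sub)]
      v <- v[v != biome$nodata]
      n_biomes <- if (length(v)) length(unique(v)) else NA_real_
    }
    counts <- if (!is.null(cls)) {
      as.numeric(table(factor(cls$class[intersect(sp, names(cls$class))],
                              levels = cls$class_names)))
    } else rep(NA_real_, 3)
    data.frame(region = r, richness = length(sp), n_cells = nrow(sub),
               area_km2 = area, centroid_lat = clat,
               centroid_northing_km = clat * KM_PER_DEG,
               elevation_sd_m = elev_sd, n_biomes = n_biomes,
               n_small = counts[1], n_medium = counts[2], n_large = counts[3])
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Richness correlates across bioregions
#'
#' Spearman and Pearson correlations of species richness against area,
#' centroid northing and elevation SD (two-sided p, df = n - 2), and an
#' ordinary least-squares fit of richness on the number of biomes with
#' F(1, n-2), R-squared and p. Covariates with zero variance (or absent)
#' give a flagged undefined result rather than an error.
#'
#' @param summaries the [summarize_bioregions()] data.frame.
#' @return data.frame of statistic rows (`statistic`, `covariate`,
#'   `estimate`, `df`/`df2`, `p_value`, `r_squared`, `defined`).
#' @export
richness_correlates <- function(summaries) {
  if (nrow(summaries) < 3)
    stop("need at least 3 regions with complete covariates", call. = FALSE)
  rich <- summaries$richness
  covs <- list(area_km2 = summaries$area_km2,
               centroid_northing_km = summaries$centroid_northing_km,
               elevation_sd_m = summaries$elevation_sd_m)
  rows <- list()
  for (nm in names(covs)) {
    x <- covs[[nm]]
    for (method in c("spearman", "pearson")) {
      if (anyNA(x) || stats::sd(x) == 0 || stats::sd(rich) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          statistic = method, covariate = nm, estimate = NA_real_,
          df = length(rich) - 2L, df2 = NA_integer_, p_value = NA_real_,
          r_squared = NA_real_, defined = FALSE)
      } else {
        ct <- correlate(rich, x, method = method)
        rows[[length(rows) + 1]] <- data.frame(
          statistic = method, covariate = nm, estimate = ct$estimate,
          df = ct$df, df2 = NA_integer_, p_value = ct$p_value,
          r_squared = NA_real_, defined = TRUE)
      }
    }
  }
  nb <- summaries$n_biomes
  if (anyNA(nb) || stats::sd(nb) == 0) {
    rows[[length(rows) + 1]] <- data.frame(
      statistic = "ols_F", covariate = "n_biomes", estimate = NA_real_,
      df = 1L, df2 = length(rich) - 2L, p_value = NA_real_,
      r_squared = NA_real_, defined = FALSE)
  } else {
    fit <- stats::lm(rich ~ nb)
    sm <- summary(fit)
    rows[[length(rows) + 1]] <- data.frame(
      statistic = "ols_F", covariate = "n_biomes",
      estimate = unname(sm$fstatistic[1]), df = 1L,
      df2 = as.integer(sm$fstatistic[3]),
      p_value = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                          sm$fstatistic[3], lower.tail = FALSE),
      r_squared = sm$r.squared, defined = TRUE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
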