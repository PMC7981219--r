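# Synthetic-data generators: Yule trees, Brownian traits, disc ranges with a
# controllable co-occurrence design, occurrence clouds, and elevation/biome
# rasters. These supply inputs with the statistical structure the analysis
# assumes, so every downstream stage is testable without external data.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study system: 69 congeners, a Brownian snout-to-vent length (SVL) process
#' with rate 8.07 mm^2 per unit branch length around a 76 mm root, disc
#' ranges over a Mexico/southern-US-sized domain, and a 0.5-degree raster
#' with five biomes.
#'
#' @param n_species number of species (>= 2).
#' @param birth_rate Yule speciation rate per unit time.
#' @param root_svl root SVL in mm.
#' @param sigma2 Brownian rate, mm^2 per unit branch length.
#' @param domain_bbox c(lon_min, lat_min, lon_max, lat_max) in degrees.
#' @param range_radius_km radius of each species' disc range.
#' @param n_points_per_species occurrence points sampled per species.
#' @param cooccurrence_pairs list of `list(a, b, f)` triples: species `a` and
#'   `b` get discs overlapping with area fraction `f` in `[0, 1]`; a species
#'   may appear in at most one pair; unlisted species get disjoint discs.
#' @param raster_resolution_deg raster cell size in degrees; must divide the
#'   bbox extents.
#' @param n_biomes number of distinct biome labels (>= 1).
#' @param elev_mean,elev_sd mean and spatial standard deviation of the
#'   elevation field, metres; `elev_sd = 0` gives a flat raster.
#' @param elev_smooth Gaussian smoothing length of the elevation field, in
#'   cells; 0 leaves white noise.
#' @param species optional character vector of species names.
#' @param seed root seed; every generator derives its own child seed from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 69, birth_rate = 1, root_svl = 76,
                       sigma2 = 8.07, domain_bbox = c(-125, 8, -80, 42),
                       range_radius_km = 100, n_points_per_species = 200,
                       cooccurrence_pairs = list(),
                       raster_resolution_deg = 0.5, n_biomes = 5,
                       elev_mean = 1000, elev_sd = 600, elev_smooth = 2,
                       species = NULL, seed = 1) {
  .assert_count(n_species, "n_species", 2)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  stopifnot(length(domain_bbox) == 4)
  if (domain_bbox[1] >= domain_bbox[3] || domain_bbox[2] >= domain_bbox[4])
    stop("domain_bbox must satisfy min < max", call. = FALSE)
  .assert_count(n_biomes, "n_biomes", 1)
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(n_species))
  if (length(species) != n_species || anyDuplicated(species))
    stop("species names must be unique and of length n_species", call. = FALSE)
  for (p in cooccurrence_pairs) {
    if (length(p) < 3) stop("each cooccurrence pair is list(a, b, f)", call. = FALSE)
    f <- as.numeric(p[[3]])
    if (!is.finite(f) || f < 0 || f > 1)
      stop("overlap fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_species = as.integer(n_species), birth_rate = birth_rate,
    root_svl = root_svl, sigma2 = sigma2, domain_bbox = domain_bbox,
    range_radius_km = range_radius_km,
    n_points_per_species = as.integer(n_points_per_species),
    cooccurrence_pairs = cooccurrence_pairs,
    raster_resolution_deg = raster_resolution_deg,
    n_biomes = as.integer(n_biomes), elev_mean = elev_mean,
    elev_sd = elev_sd, elev_smooth = elev_smooth,
    species = species, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Classic epoch construction: starting from two lineages, the waiting time
#' while k lineages exist is exponential with rate `k * birth_rate`; at each
#' event a uniformly chosen lineage splits, and the process stops at the end
#' of the n-lineage epoch. The tree is therefore ultrametric with expected
#' depth \eqn{\sum_{k=2}^{n} 1/(k\lambda)}.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param tip_labels optional character vector of tip labels.
#' @return an [ape::phylo] object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               tip_labels = NULL) {
  .assert_count(n_tips, "n_tips", 2)
  if (birth_rate <= 0) stop("birth_rate must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  root <- n + 1L
  # growing edge arrays; child is NA while the lineage is active
  e_parent <- c(root, root)
  e_start <- c(0, 0)
  e_end <- c(NA_real_, NA_real_)
  e_child <- c(NA_integer_, NA_integer_)
  active <- c(1L, 2L)
  internal_next <- n + 2L
  t <- 0
  k <- 2L
  repeat {
    t <- t + stats::rexp(1, rate = k * birth_rate)
    if (k == n) break
    pick <- active[sample.int(length(active), 1L)]
    node <- internal_next
    internal_next <- internal_next + 1L
    e_child[pick] <- node
    e_end[pick] <- t
    e_parent <- c(e_parent, node, node)
    e_start <- c(e_start, t, t)
    e_end <- c(e_end, NA_real_, NA_real_)
    e_child <- c(e_child, NA_integer_, NA_integer_)
    active <- c(active[active != pick],
                length(e_parent) - 1L, length(e_parent))
    k <- k + 1L
  }
  e_child[active] <- seq_len(n)
  e_end[active] <- t
  if (is.null(tip_labels)) tip_labels <- sprintf("sp%03d", seq_len(n))
  stopifnot(length(tip_labels) == n)
  tr <- structure(list(
    edge = cbind(e_parent, e_child, deparse.level = 0),
    edge.length = e_end - e_start,
    tip.label = tip_labels,
    Nnode = n - 1L
  ), class = "phylo", order = NULL)
  stats::reorder(tr, "cladewise")
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Accumulates independent Gaussian increments with variance
#' `sigma2 * branch length` along each edge from the root state.
#'
#' @param tree an [ape::phylo] tree.
#' @param root_state trait value at the root (mm).
#' @param sigma2 Brownian rate (mm^2 per unit branch length, >= 0).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return named numeric vector of tip trait values.
#' @export
simulate_bm_trait <- function(tree, root_state = 76, sigma2 = 8.07,
                              seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")
  n <- length(tree$tip.label)
  states <- numeric(n + tree$Nnode)
  states[n + 1L] <- root_state
  inc <- stats::rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  for (e in seq_len(nrow(tree$edge)))
    states[tree$edge[e, 2]] <- states[tree$edge[e, 1]] + inc[e]
  out <- states[seq_len(n)]
  names(out) <- tree$tip.label
  out
}

# centre separation giving overlap-area fraction f for equal discs of radius r
.disc_separation <- function(r, f) {
  if (f >= 1) return(0)
  if (f <= 0) return(2 * r)
  area <- function(d) 2 * r^2 * acos(pmin(1, d / (2 * r))) -
    (d / 2) * sqrt(pmax(0, 4 * r^2 - d^2))
  stats::uniroot(function(d) area(d) / (pi * r^2) - f,
                 c(0, 2 * r), tol = 1e-10)$root
}

#' Generate synthetic species ranges as overlapping or disjoint discs
#'
#' Each species gets a disc of radius `range_radius_km`, discretized as a
#' 64-vertex polygon in lon/lat via the local equirectangular scaling at the
#' domain centre. Species named in `cooccurrence_pairs` are placed so their
#' discs overlap with the requested area fraction; all other disc pairs are
#' disjoint with a positive gap. Discs are laid out on a slot grid; if the
#' domain cannot hold them, a packing-failure error is raised.
#'
#' @param config a [sim_config()].
#' @return a named list of 64x2 vertex matrices (class `species_ranges`),
#'   with attributes `radius_km` and `gap_km` (guaranteed minimum edge gap
#'   between non-paired discs).
#' @export
generate_ranges <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "ranges"))
  bb <- config$domain_bbox
  r <- config$range_radius_km
  lat0 <- (bb[2] + bb[4]) / 2
  km_lon <- KM_PER_DEG * cos(lat0 * pi / 180)
  km_lat <- KM_PER_DEG

  species <- config$species
  pairs <- config$cooccurrence_pairs
  paired <- unlist(lapply(pairs, function(p) c(p[[1]], p[[2]])))
  if (anyDuplicated(paired))
    stop("a species may appear in at most one cooccurrence pair", call. = FALSE)
  if (!all(paired %in% species))
    stop("cooccurrence pair names a species not in the config", call. = FALSE)
  unpaired <- setdiff(species, paired)

  gap <- max(10, 0.1 * r)
  pitch <- 4 * r + gap              # slot pitch: worst-case disc extent is 2r
  width <- (bb[3] - bb[1]) * km_lon - 4 * r
  height <- (bb[4] - bb[2]) * km_lat - 4 * r
  if (width <= 0 || height <= 0)
    stop("packing failure: domain smaller than one range", call. = FALSE)
  ncol_s <- floor(width / pitch) + 1
  nrow_s <- floor(height / pitch) + 1
  n_slots <- length(pairs) + length(unpaired)
  if (ncol_s * nrow_s < n_slots)
    stop(sprintf(
      "packing failure: %d slots needed but only %d fit in the domain",
      n_slots, ncol_s * nrow_s), call. = FALSE)

  slot_xy <- function(i) {          # slot centre in km from bbox SW corner
    row <- (i - 1) %/% ncol_s
    col <- (i - 1) %% ncol_s
    c(2 * r + col * pitch, 2 * r + row * pitch)
  }
  theta <- 2 * pi * (seq_len(64) - 1) / 64
  disc <- function(cx, cy) {        # km centre -> lon/lat polygon
    cbind(bb[1] + (cx + r * cos(theta)) / km_lon,
          bb[2] + (cy + r * sin(theta)) / km_lat)
  }

  out <- vector("list", length(species))
  names(out) <- species
  slot <- 1
  for (p in pairs) {
    d <- .disc_separation(r, as.numeric(p[[3]]))
    c0 <- slot_xy(slot); slot <- slot + 1
    out[[p[[1]]]] <- disc(c0[1] - d / 2, c0[2])
    out[[p[[2]]]] <- disc(c0[1] + d / 2, c0[2])
  }
  for (s in unpaired) {
    c0 <- slot_xy(slot); slot <- slot + 1
    out[[s]] <- disc(c0[1], c0[2])
  }
  structure(out, class = "species_ranges", radius_km = r, gap_km = gap)
}

#' Sample uniform occurrence points inside species ranges
#'
#' Rejection sampling within each polygon's bounding box, boundary-inclusive.
#'
#' @param ranges a `species_ranges` list (or any named list of lon/lat
#'   polygon matrices).
#' @param n_points_per_species points per species (>= 1).
#' @param seed integer seed.
#' @return occurrence data.frame with columns `species`, `longitude`,
#'   `latitude`.
#' @export
sample_occurrences <- function(ranges, n_points_per_species, seed = NULL) {
  .assert_count(n_points_per_species, "n_points_per_species", 1)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(names(ranges), function(s) {
    poly <- ranges[[s]]
    if (is.null(poly) || !is.matrix(poly) || nrow(poly) < 3 ||
        any(!is.finite(poly)))
      stop(sprintf("empty polygon for species %s", s), call. = FALSE)
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    got_x <- numeric(0); got_y <- numeric(0)
    tries <- 0
    while (length(got_x) < n_points_per_species) {
      m <- 2 * (n_points_per_species - length(got_x)) + 8
      x <- stats::runif(m, xr[1], xr[2])
      y <- stats::runif(m, yr[1], yr[2])
      keep <- points_in_polygon(x, y, poly)
      got_x <- c(got_x, x[keep]); got_y <- c(got_y, y[keep])
      tries <- tries + 1
      if (tries > 1000)
        stop(sprintf("cannot sample inside polygon for species %s", s),
             call. = FALSE)
    }
    data.frame(species = s,
               longitude = got_x[seq_len(n_points_per_species)],
               latitude = got_y[seq_len(n_points_per_species)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Generate elevation and biome rasters
#'
#' Elevation is a smoothed Gaussian random field rescaled to the configured
#' mean and spatial standard deviation (metres). Biomes are contiguous
#' latitudinal bands, one band per label, so exactly `n_biomes` distinct
#' labels are present.
#'
#' @param config a [sim_config()].
#' @return list with elements `elevation` and `biome`, each a `raster_grid`.
#' @export
generate_rasters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "rasters"))
  bb <- config$domain_bbox
  res <- config$raster_resolution_deg
  nc <- (bb[3] - bb[1]) / res
  nr <- (bb[4] - bb[2]) / res
  if (abs(nc - round(nc)) > 1e-9 || abs(nr - round(nr)) > 1e-9)
    stop("raster_resolution_deg must divide the bbox extents", call. = FALSE)
  nc <- as.integer(round(nc)); nr <- as.integer(round(nr))
  if (nr < config$n_biomes)
    stop("raster has fewer rows than biomes", call. = FALSE)

  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (config$elev_smooth > 0) {
    w <- stats::dnorm(seq(-3, 3, length.out = 2 * ceiling(3 * config$elev_smooth) + 1))
    w <- w / sum(w)
    smooth1 <- function(v) stats::filter(c(rev(v), v, rev(v)), w,
                                         sides = 2)[length(v) + seq_along(v)]
    z <- apply(z, 2, smooth1)
    z <- t(apply(z, 1, smooth1))
  }
  if (config$elev_sd > 0 && stats::sd(as.vector(z)) > 0) {
    z <- (z - mean(z)) / stats::sd(as.vector(z)) * config$elev_sd + config$elev_mean
  } else {
    z <- matrix(config$elev_mean, nr, nc)
  }
  elevation <- raster_grid(values = z, origin = c(bb[1], bb[2]),
                           cellsize = res)

  band <- ceiling(seq_len(nr) / nr * config$n_biomes)  # row 1 = north
  biome <- raster_grid(values = matrix(rep(band, nc), nr, nc),
                       origin = c(bb[1], bb[2]), cellsize = res,
                       categorical = TRUE)
  list(elevation = elevation, biome = biome)
}

#' Build a co-occurrence pair design from traits
#'
#' Pairs species so that range overlap is size-divergent (each small species
#' overlaps a large one), size-assorted (similar sizes overlap), or absent.
#' Used to plant the effects the divergence statistic should recover.
#'
#' @param traits named SVL vector.
#' @param type `"divergent"`, `"assorted"` or `"none"`.
#' @param overlap overlap area fraction for each pair.
#' @param k number of size classes used to define small/large.
#' @return list of `list(a, b, f)` pairs suitable for [sim_config()].
#' @export
cooccurrence_design <- function(traits, type = c("divergent", "assorted", "none"),
                                overlap = 0.6, k = 3) {
  type <- match.arg(type)
  if (type == "none") return(list())
  traits <- .as_traits(traits)
  cls <- classify_sizes(traits, k = k)
  sm <- names(cls$class)[cls$class == "small"]
  lg <- names(cls$class)[cls$class == "large"]
  if (type == "divergent") {
    m <- min(length(sm), length(lg))
    lapply(seq_len(m), function(i) list(sm[i], lg[i], overlap))
  } else {
    ord <- names(sort(traits))
    m <- floor(length(ord) / 2)
    lapply(seq_len(m), function(i) list(ord[2 * i - 1], ord[2 * i], overlap))
  }
}

#' Generate a complete synthetic data set
#'
#' Runs every generator under per-stage child seeds and (optionally) writes
#' the artifacts in their interchange formats: Newick tree, trait CSV, range
#' GeoJSON, occurrence CSV, and two ESRI ASCII grid rasters.
#'
#' @param config a [sim_config()].
#' @param dir output directory; `NULL` skips writing.
#' @param design optional co-occurrence design type passed to
#'   [cooccurrence_design()] when `config$cooccurrence_pairs` is empty;
#'   `NULL` leaves the configured pairs.
#' @return list with `tree`, `traits`, `ranges`, `occurrences`, `rasters`,
#'   `config`, and `files` (paths, when written).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL, design = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_yule_tree(config$n_species, config$birth_rate,
                             seed = child_seed(config$seed, "tree"),
                             tip_labels = config$species)
  traits <- simulate_bm_trait(tree, config$root_svl, config$sigma2,
                              seed = child_seed(config$seed, "traits"))
  if (!is.null(design) && length(config$cooccurrence_pairs) == 0)
    config$cooccurrence_pairs <- cooccurrence_design(traits, design)
  ranges <- generate_ranges(config)
  occ <- sample_occurrences(ranges, config$n_points_per_species,
                            seed = child_seed(config$seed, "occurrences"))
  rasters <- generate_rasters(config)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      tree = file.path(dir, "tree.nwk"),
      traits = file.path(dir, "traits.csv"),
      ranges = file.path(dir, "ranges.geojson"),
      occurrences = file.path(dir, "occurrences.csv"),
      elevation = file.path(dir, "elevation.asc"),
      biome = file.path(dir, "biomes.asc")
    )
    ape::write.tree(tree, files$tree)
    write_traits(traits, files$traits)
    write_ranges(ranges, files$ranges)
    write_occurrences(occ, files$occurrences)
    write_raster(rasters$elevation, files$elevation)
    write_raster(rasters$biome, files$biome)
  }
  list(tree = tree, traits = traits, ranges = ranges, occurrences = occ,
       rasters = rasters, config = config, files = files)
}
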