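# Independent reference implementations used to check the package's
# optimized code paths. These deliberately share no code with R/.

# all-pairs directed sympatry counts via geosphere's haversine
brute_force_sympatry <- function(occ, threshold_km = 5, min_points = 10) {
  species <- sort(unique(occ$species))
  n_sp <- length(species)
  N <- matrix(0L, n_sp, n_sp, dimnames = list(species, species))
  pts <- split(occ[c("longitude", "latitude")], occ$species)
  for (a in species) for (b in species) {
    if (a == b) next
    pa <- as.matrix(pts[[a]])
    pb <- as.matrix(pts[[b]])
    d <- geosphere::distm(pa, pb, fun = geosphere::distHaversine) / 1000
    d <- d * (6371.0088 / 6378.137)  # rescale to the mean-radius sphere
    N[a, b] <- sum(apply(d <= threshold_km, 1, any))
  }
  S <- N >= min_points
  diag(S) <- NA
  diag(N) <- NA_integer_
  list(N = N, S = S)
}

# reference recursive quadtree following the stated split/merge rules,
# written independently of the package implementation
quadtree_oracle <- function(occ, max_deg = 4, min_deg = 2,
                            max_capacity = 100, min_capacity = 10) {
  descend <- function(lon, lat, x0, y0, side) {
    n <- length(lon)
    if (n == 0) return(list())
    this_leaf <- list(list(x0 = x0, y0 = y0, side = side, count = n))
    if (n <= max_capacity || side <= min_deg) return(this_leaf)
    h <- side / 2
    quads <- list(c(0, 0), c(h, 0), c(0, h), c(h, h))
    kids <- list()
    for (q in quads) {
      sel <- lon >= x0 + q[1] & lon < x0 + q[1] + h &
        lat >= y0 + q[2] & lat < y0 + q[2] + h
      kids <- c(kids, descend(lon[sel], lat[sel], x0 + q[1], y0 + q[2], h))
    }
    counts <- vapply(kids, function(l) l$count, 0)
    if (any(counts < min_capacity)) return(this_leaf)
    kids
  }
  leaves <- list()
  gx <- floor((occ$longitude + 180) / max_deg)
  gy <- floor((occ$latitude + 90) / max_deg)
  for (key in unique(paste(gx, gy))) {
    sel <- paste(gx, gy) == key
    ij <- as.numeric(strsplit(key, " ")[[1]])
    leaves <- c(leaves, descend(occ$longitude[sel], occ$latitude[sel],
                                -180 + ij[1] * max_deg, -90 + ij[2] * max_deg,
                                max_deg))
  }
  df <- do.call(rbind, lapply(leaves, function(l)
    data.frame(x0 = l$x0, y0 = l$y0, side = l$side, count = l$count)))
  df[order(df$x0, df$y0, df$side), , drop = FALSE]
}

# exhaustive Fisher-Jenks by enumerating all 2-break partitions of the
# sorted distinct values
jenks_exhaustive_3 <- function(values) {
  v <- sort(unique(values))
  m <- length(v)
  ss <- function(x) if (length(x) < 2) 0 else sum((x - mean(x))^2)
  grp <- function(lo, hi) values[values >= v[lo] & values <= v[hi]]
  best <- NULL
  for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) {
    tot <- ss(grp(1, i)) + ss(grp(i + 1, j)) + ss(grp(j + 1, m))
    if (is.null(best) || tot < best$ss - 1e-12)
      best <- list(ss = tot, breaks = c(v[i], v[j]))
  }
  best
}

# explicit GLS ancestral-state oracle for a 3-tip tree via dense inverses
gls_anc_oracle <- function(tree, x) {
  x <- x[tree$tip.label]
  C <- ape::vcv(tree)
  Ci <- solve(C)
  one <- rep(1, length(x))
  root <- as.numeric((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
  n <- length(tree$tip.label)
  dn <- ape::dist.nodes(tree)
  depth <- dn[n + 1, ]
  nodes <- (n + 1):(n + tree$Nnode)
  est <- vapply(nodes, function(nd) {
    cv <- vapply(seq_len(n), function(tp) (depth[nd] + depth[tp] - dn[nd, tp]) / 2, 0)
    root + as.numeric(t(cv) %*% Ci %*% (x - root))
  }, 0)
  list(root = root, estimates = est, nodes = nodes)
}

# small clustered occurrence generator for sympatry/quadtree stress cases
random_occ_instance <- function(n_species, pts_per_species, bbox, seed,
                                cluster_sd = 0.3) {
  set.seed(seed)
  rows <- lapply(seq_len(n_species), function(i) {
    cx <- runif(1, bbox[1], bbox[3])
    cy <- runif(1, bbox[2], bbox[4])
    data.frame(species = sprintf("sp%02d", i),
               longitude = pmin(bbox[3], pmax(bbox[1], rnorm(pts_per_species, cx, cluster_sd))),
               latitude = pmin(bbox[4], pmax(bbox[2], rnorm(pts_per_species, cy, cluster_sd))))
  })
  do.call(rbind, rows)
}
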