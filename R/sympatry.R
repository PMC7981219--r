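# Directed congeneric sympatry from occurrence points: species a is
# sympatric with species b when at least `min_points` of a's occurrence
# points lie within `threshold_km` (inclusive) of some occurrence point of
# b. Each of a's points counts at most once per b, however many b points
# are nearby; one b point may support many of a's points.

# distance from each row-point to each col-point, returned as a logical
# "any column within threshold" per row; chunked to bound memory
.any_within <- function(lon1, lat1, lon2, lat2, threshold_km, chunk = 2000L) {
  n1 <- length(lon1)
  out <- logical(n1)
  to_rad <- pi / 180
  la2 <- lat2 * to_rad; lo2 <- lon2 * to_rad
  for (s in seq(1, n1, by = chunk)) {
    e <- min(n1, s + chunk - 1L)
    la1 <- lat1[s:e] * to_rad; lo1 <- lon1[s:e] * to_rad
    a <- outer(la1, la2, function(x, y) sin((y - x) / 2)^2) +
      outer(cos(la1), cos(la2)) *
      outer(lo1, lo2, function(x, y) sin((y - x) / 2)^2)
    d <- 2 * EARTH_RADIUS_KM * asin(sqrt(pmin(pmax(a, 0), 1)))
    out[s:e] <- apply(d <= threshold_km, 1, any)
  }
  out
}

#' Sympatric congeners of a focal species
#'
#' Applies the directed sympatry rule to one focal species: every other
#' species b is listed when at least `min_points` of the focal's occurrence
#' points are within `threshold_km` (inclusive) of at least one b point.
#'
#' @param occ occurrence data.frame (`species`, `longitude`, `latitude`).
#' @param focal focal species id (must be present).
#' @param threshold_km distance threshold, km; the rule is `<=`.
#' @param min_points minimum number of supporting focal points.
#' @return data.frame `species`, `supporting_points` for qualifying species.
#' @export
sympatric_congeners <- function(occ, focal, threshold_km = 5, min_points = 10) {
  occ <- .as_occurrences(occ)
  if (!focal %in% occ$species)
    stop(sprintf("focal species %s absent from occurrences", focal),
         call. = FALSE)
  f <- occ[occ$species == focal, ]
  others <- setdiff(sort(unique(occ$species)), focal)
  counts <- vapply(others, function(b) {
    bp <- occ[occ$species == b, ]
    sum(.any_within(f$longitude, f$latitude, bp$longitude, bp$latitude,
                    threshold_km))
  }, 0L)
  keep <- counts >= min_points
  data.frame(species = others[keep],
             supporting_points = unname(counts[keep]),
             stringsAsFactors = FALSE)
}

#' Directed sympatry matrix over all species
#'
#' Computes the supporting-point count matrix `N[a, b]` (number of a's
#' points with at least one b point within the threshold) for every ordered
#' species pair, and the boolean call matrix `S = (N >= min_points)`. A
#' spatial bucket grid at the threshold scale restricts distance evaluation
#' to neighbouring buckets; the counts are identical to the all-pairs
#' computation.
#'
#' @param occ occurrence data.frame.
#' @param threshold_km distance threshold, km (inclusive).
#' @param min_points minimum supporting points for a sympatry call.
#' @param symmetrize logical; if TRUE, `S` is replaced by `S | t(S)` (the
#'   counts `N` stay directional).
#' @return object of class `sympatry_matrix`: list with `species`, logical
#'   matrix `S`, integer matrix `N`, and the rule parameters. Diagonals are
#'   `NA` (self-sympatry is undefined).
#' @export
sympatry_matrix <- function(occ, threshold_km = 5, min_points = 10,
                            symmetrize = FALSE) {
  occ <- .as_occurrences(occ)
  species <- sort(unique(occ$species))
  if (length(species) < 2) stop("need at least 2 species", call. = FALSE)
  n_sp <- length(species)
  sp_idx <- match(occ$species, species)
  n_pts <- nrow(occ)

  dlat <- threshold_km / KM_PER_DEG
  coslat <- cos(min(89.9, max(abs(occ$latitude))) * pi / 180)
  dlon <- dlat / max(coslat, 1e-3)
  bi <- floor((occ$latitude + 90) / dlat)
  bj <- floor((occ$longitude + 180) / dlon)
  keys <- paste(bi, bj, sep = "_")
  buckets <- split(seq_len(n_pts), keys)

  N <- matrix(0L, n_sp, n_sp, dimnames = list(species, species))
  to_rad <- pi / 180
  lon_r <- occ$longitude * to_rad
  lat_r <- occ$latitude * to_rad
  for (key in names(buckets)) {
    idx <- buckets[[key]]
    ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1]])
    neigh <- as.vector(outer(ij[1] + (-1:1), ij[2] + (-1:1),
                             function(a, b) paste(a, b, sep = "_")))
    cand <- unlist(buckets[intersect(neigh, names(buckets))], use.names = FALSE)
    a <- outer(lat_r[idx], lat_r[cand], function(x, y) sin((y - x) / 2)^2) +
      outer(cos(lat_r[idx]), cos(lat_r[cand])) *
      outer(lon_r[idx], lon_r[cand], function(x, y) sin((y - x) / 2)^2)
    d <- 2 * EARTH_RADIUS_KM * asin(sqrt(pmin(pmax(a, 0), 1)))
    hit <- d <= threshold_km
    for (r in seq_along(idx)) {
      sp_hit <- unique(sp_idx[cand[hit[r, ]]])
      sp_hit <- sp_hit[sp_hit != sp_idx[idx[r]]]
      if (length(sp_hit))
        N[sp_idx[idx[r]], sp_hit] <- N[sp_idx[idx[r]], sp_hit] + 1L
    }
  }
  S <- N >= min_points
  if (symmetrize) S <- S | t(S)
  diag(S) <- NA
  diag(N) <- NA_integer_
  structure(list(species = species, S = S, N = N,
                 threshold_km = threshold_km, min_points = min_points,
                 symmetrized = symmetrize),
            class = "sympatry_matrix")
}

#' @export
print.sympatry_matrix <- function(x, ...) {
  calls <- sum(x$S, na.rm = TRUE)
  cat(sprintf(
    "Directed sympatry matrix: %d species, threshold %.3g km, min %d points\n",
    length(x$species), x$threshold_km, x$min_points))
  cat(sprintf("  %d directed sympatry calls%s\n", calls,
              if (isTRUE(x$symmetrized)) " (symmetrized)" else ""))
  invisible(x)
}

#' Export a sympatry matrix as a long table
#' @param x a `sympatry_matrix`.
#' @return data.frame `focal`, `other`, `supporting_points`, `sympatric`.
#' @export
sympatry_table <- function(x) {
  stopifnot(inherits(x, "sympatry_matrix"))
  sp <- x$species
  grid <- expand.grid(focal = sp, other = sp, stringsAsFactors = FALSE)
  grid <- grid[grid$focal != grid$other, ]
  grid$supporting_points <- x$N[cbind(grid$focal, grid$other)]
  grid$sympatric <- x$S[cbind(grid$focal, grid$other)]
  grid[order(grid$focal, grid$other), , drop = FALSE]
}
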