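# Spherical and planar geometry primitives shared across the pipeline.

#' Mean Earth radius (km) used everywhere distances or areas are computed
#' @keywords internal
EARTH_RADIUS_KM <- 6371.0088

#' Kilometres per degree of latitude (and of longitude at the equator)
#' @keywords internal
KM_PER_DEG <- pi * EARTH_RADIUS_KM / 180

.check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(lon < -180 | lon > 180))
    stop("longitude outside [-180, 180]", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km. Inputs are
#' decimal-degree longitudes and latitudes and are recycled; the result is
#' symmetric, non-negative and zero only for identical points.
#'
#' @param lon1,lat1 coordinates of the first point(s), decimal degrees.
#' @param lon2,lat2 coordinates of the second point(s), decimal degrees.
#' @return numeric vector of distances in km.
#' @examples
#' geodesic_distance_km(0, 0, 0, 1)   # one degree of meridian, ~111.195 km
#' @export
geodesic_distance_km <- function(lon1, lat1, lon2, lat2) {
  .check_lonlat(lon1, lat1)
  .check_lonlat(lon2, lat2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Boundary-inclusive point-in-polygon test
#'
#' Even-odd ray casting with an explicit on-boundary check: points lying on an
#' edge or vertex are counted as inside (cleaning removes only points clearly
#' outside a range).
#'
#' @param lon,lat point coordinates (vectors, recycled together).
#' @param poly two-column matrix of polygon vertices (lon, lat), open ring
#'   (first vertex not repeated).
#' @return logical vector.
#' @export
points_in_polygon <- function(lon, lat, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  px <- poly[, 1]; py <- poly[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  inside <- logical(n)
  onedge <- logical(n)
  eps <- 1e-12 * max(1, max(abs(poly)))
  for (e in seq_along(px)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
    # collinear and within the segment's bounding box => on boundary
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    onseg <- abs(cross) <= eps * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      lon >= pmin(x1, x2) - eps & lon <= pmax(x1, x2) + eps &
      lat >= pmin(y1, y2) - eps & lat <= pmax(y1, y2) + eps
    onedge <- onedge | onseg
    crosses <- ((y1 > lat) != (y2 > lat)) &
      (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

#' Shoelace area of a simple polygon (planar, in the units of its vertices)
#' @param poly two-column matrix, open ring.
#' @return non-negative area.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Intersection area of two convex polygons (Sutherland-Hodgman clipping)
#'
#' Used to verify the co-occurrence design of synthetic ranges. Both polygons
#' must be convex; vertices may wind either way.
#'
#' @param a,b two-column vertex matrices, open rings.
#' @return planar intersection area (same units as the inputs).
#' @export
convex_intersection_area <- function(a, b) {
  a <- .ccw(as.matrix(a)); b <- .ccw(as.matrix(b))
  subject <- a
  nb <- nrow(b)
  for (e in seq_len(nb)) {
    if (nrow(subject) == 0) return(0)
    p1 <- b[e, ]; p2 <- b[if (e == nb) 1 else e + 1, ]
    subject <- .clip_halfplane(subject, p1, p2)
  }
  if (nrow(subject) < 3) return(0)
  polygon_area(subject)
}

.ccw <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  if (sum(x * ys - xs * y) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# keep the part of convex polygon `s` left of the directed line p1 -> p2
.clip_halfplane <- function(s, p1, p2) {
  n <- nrow(s)
  side <- (p2[1] - p1[1]) * (s[, 2] - p1[2]) - (p2[2] - p1[2]) * (s[, 1] - p1[1])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ci <- side[i] >= 0; cj <- side[j] >= 0
    if (ci) out <- rbind(out, s[i, ])
    if (ci != cj) {
      t <- side[i] / (side[i] - side[j])
      out <- rbind(out, s[i, ] + t * (s[j, ] - s[i, ]))
    }
  }
  out
}

#' Area of a grid cell on the sphere
#'
#' Exact spherical-quadrilateral area of a degree-aligned cell,
#' \eqn{R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)}.
#'
#' @param lon_min,lat_min,lon_max,lat_max cell bounds in degrees (vectorized).
#' @return area in km^2.
#' @export
cell_area_km2 <- function(lon_min, lat_min, lon_max, lat_max) {
  to_rad <- pi / 180
  EARTH_RADIUS_KM^2 * (lon_max - lon_min) * to_rad *
    (sin(lat_max * to_rad) - sin(lat_min * to_rad))
}
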