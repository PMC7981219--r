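# Readers, writers and validators for the interchange formats: occurrence
# CSV, range GeoJSON, Newick trees, trait CSV, and ESRI ASCII grid rasters.
# All delimited readers accept comma or tab, UTF-8.

.read_delim <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, encoding = "UTF-8",
                    check.names = FALSE)
}

#' Read an occurrence table
#'
#' Reads a delimited file of point occurrences (Darwin-Core-style columns),
#' validates coordinate bounds row by row, and preserves row order. Extra
#' columns are ignored.
#'
#' @param path CSV/TSV file.
#' @param dialect named character vector mapping the standard names
#'   `species`, `longitude`, `latitude` to the file's column names.
#' @return data.frame with columns `species`, `longitude`, `latitude`.
#' @export
read_occurrences <- function(path,
                             dialect = c(species = "species",
                                         longitude = "longitude",
                                         latitude = "latitude")) {
  raw <- .read_delim(path)
  need <- dialect[c("species", "longitude", "latitude")]
  missing_cols <- setdiff(unname(need), names(raw))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  occ <- data.frame(species = as.character(raw[[need[["species"]]]]),
                    longitude = as.numeric(raw[[need[["longitude"]]]]),
                    latitude = as.numeric(raw[[need[["latitude"]]]]),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(occ$longitude) | !is.finite(occ$latitude) |
                 occ$longitude < -180 | occ$longitude > 180 |
                 occ$latitude < -90 | occ$latitude > 90)
  if (length(bad))
    stop(sprintf("invalid coordinates at row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  if (nrow(occ) == 0 || !length(unique(occ$species)))
    stop("occurrence table is empty", call. = FALSE)
  occ
}

#' Write an occurrence table as CSV
#' @param occ occurrence data.frame.
#' @param path output file.
#' @export
write_occurrences <- function(occ, path) {
  occ <- .as_occurrences(occ)
  utils::write.csv(occ[c("species", "longitude", "latitude")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trait table (species, svl_mm)
#' @param path CSV/TSV file with columns `species` and `svl_mm`.
#' @return named numeric vector of SVL in mm.
#' @export
read_traits <- function(path) .as_traits(.read_delim(path))

#' Write a trait table as CSV
#' @param traits named numeric vector.
#' @param path output file.
#' @export
write_traits <- function(traits, path) {
  traits <- .as_traits(traits)
  utils::write.csv(data.frame(species = names(traits),
                              svl_mm = unname(traits)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' Wraps [ape::read.tree] with validation: the tree must parse, be rooted,
#' and carry unique tip labels and branch lengths.
#'
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop(sprintf("malformed Newick in %s: %s", path, conditionMessage(e)),
         call. = FALSE))
  if (is.null(tr)) stop(sprintf("malformed Newick in %s", path), call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in tree", call. = FALSE)
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (!ape::is.rooted(tr)) stop("tree is not rooted", call. = FALSE)
  tr
}

#' Read species range polygons from GeoJSON
#'
#' Expects a FeatureCollection with one polygon Feature per species and a
#' `species` property. Only simple (single-ring) polygons are supported.
#'
#' @param path GeoJSON file.
#' @return named list of lon/lat vertex matrices (class `species_ranges`).
#' @export
read_ranges <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  out <- list()
  for (f in gj$features) {
    sp <- f$properties$species
    if (is.null(sp)) stop("feature without species property", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    # drop the closing vertex of the ring
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    if (nrow(m) < 3) stop(sprintf("degenerate ring for %s", sp), call. = FALSE)
    out[[sp]] <- m
  }
  structure(out, class = "species_ranges")
}

#' Write species ranges as a GeoJSON FeatureCollection
#' @param ranges named list of lon/lat polygon matrices.
#' @param path output file.
#' @export
write_ranges <- function(ranges, path) {
  feats <- lapply(names(ranges), function(s) {
    m <- ranges[[s]]
    ring <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    ring[[length(ring) + 1]] <- ring[[1]]
    list(type = "Feature",
         properties = list(species = s),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a raster grid
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param origin c(lon, lat) of the lower-left corner.
#' @param cellsize cell size in degrees (> 0).
#' @param nodata sentinel for missing cells.
#' @param categorical logical; labels rather than a continuous field.
#' @return a `raster_grid` list.
#' @export
raster_grid <- function(values, origin, cellsize, nodata = -9999,
                        categorical = FALSE) {
  stopifnot(is.matrix(values), cellsize > 0, length(origin) == 2)
  structure(list(values = values, origin = as.numeric(origin),
                 cellsize = cellsize, n_rows = nrow(values),
                 n_cols = ncol(values), nodata = nodata,
                 categorical = categorical),
            class = "raster_grid")
}

#' Read an ESRI ASCII grid raster
#' @param path `.asc` file with the 6-line header dialect.
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII grid header", call. = FALSE)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("raster value count does not match header", call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  raster_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner),
              cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' Write a raster as an ESRI ASCII grid
#' @param raster a `raster_grid`.
#' @param path output `.asc` file.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "raster_grid"))
  hdr <- c(sprintf("ncols %d", raster$n_cols),
           sprintf("nrows %d", raster$n_rows),
           sprintf("xllcorner %.10g", raster$origin[1]),
           sprintf("yllcorner %.10g", raster$origin[2]),
           sprintf("cellsize %.10g", raster$cellsize),
           sprintf("NODATA_value %.10g", raster$nodata))
  rows <- apply(raster$values, 1, function(r)
    paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Centres of raster cells
#' @param raster a `raster_grid`.
#' @return data.frame with `longitude`, `latitude`, `value` per cell.
#' @export
raster_cell_centers <- function(raster) {
  stopifnot(inherits(raster, "raster_grid"))
  cs <- raster$cellsize
  lon <- raster$origin[1] + (seq_len(raster$n_cols) - 0.5) * cs
  # row 1 is the top (north) row
  lat <- raster$origin[2] + (raster$n_rows - seq_len(raster$n_rows) + 0.5) * cs
  data.frame(longitude = rep(lon, each = raster$n_rows),
             latitude = rep(lat, times = raster$n_cols),
             value = as.vector(raster$values))
}

#' Clean occurrences against range polygons
#'
#' Removes records clearly outside their species' range polygon
#' (boundary-inclusive, so points on an edge or vertex are kept). Species
#' without a polygon are routed to the report as unfilterable rather than
#' silently kept or dropped.
#'
#' @param occ occurrence data.frame.
#' @param ranges named list of lon/lat polygon matrices.
#' @return list with `occurrences` (retained records, original order),
#'   `unfilterable` (records of species lacking a polygon) and `report`
#'   (per-species retained/removed/unfilterable counts).
#' @export
filter_by_range <- function(occ, ranges) {
  occ <- .as_occurrences(occ)
  keep <- logical(nrow(occ))
  unfilt <- logical(nrow(occ))
  for (s in unique(occ$species)) {
    idx <- which(occ$species == s)
    if (is.null(ranges[[s]])) {
      unfilt[idx] <- TRUE
    } else {
      keep[idx] <- points_in_polygon(occ$longitude[idx], occ$latitude[idx],
                                     ranges[[s]])
    }
  }
  sp <- unique(occ$species)
  report <- data.frame(
    species = sp,
    retained = vapply(sp, function(s) sum(keep & occ$species == s), 0L),
    removed = vapply(sp, function(s)
      sum(!keep & !unfilt & occ$species == s), 0L),
    unfilterable = vapply(sp, function(s) sum(unfilt & occ$species == s), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(occurrences = occ[keep, , drop = FALSE],
       unfilterable = occ[unfilt, , drop = FALSE],
       report = report)
}

#' Arithmetic-mean range centroids per species
#'
#' Mean longitude and latitude of each species' occurrence records. Plain
#' arithmetic means in decimal degrees: no antimeridian unwrapping, which is
#' adequate for a study domain away from the 180th meridian.
#'
#' @param occ occurrence data.frame.
#' @param species optional species subset; requesting an absent species is
#'   an error rather than a zero.
#' @return data.frame `species`, `longitude`, `latitude`.
#' @export
species_centroids <- function(occ, species = NULL) {
  occ <- .as_occurrences(occ)
  if (is.null(species)) species <- unique(occ$species)
  absent <- setdiff(species, occ$species)
  if (length(absent))
    stop(sprintf("no occurrences for: %s", paste(absent, collapse = ", ")),
         call. = FALSE)
  data.frame(
    species = species,
    longitude = vapply(species, function(s)
      mean(occ$longitude[occ$species == s]), 0),
    latitude = vapply(species, function(s)
      mean(occ$latitude[occ$species == s]), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Reconcile species names across occurrence, tree and trait inputs
#'
#' @param occ occurrence data.frame (or NULL).
#' @param tree phylo (or NULL).
#' @param traits named trait vector (or NULL).
#' @return list with the `shared` species set and each input's orphans.
#' @export
reconcile_species <- function(occ = NULL, tree = NULL, traits = NULL) {
  sets <- list()
  if (!is.null(occ)) sets$occurrences <- unique(.as_occurrences(occ)$species)
  if (!is.null(tree)) sets$tree <- tree$tip.label
  if (!is.null(traits)) sets$traits <- names(.as_traits(traits))
  if (!length(sets)) stop("nothing to reconcile", call. = FALSE)
  shared <- Reduce(intersect, sets)
  orphans <- lapply(sets, function(s) setdiff(s, shared))
  list(shared = shared, orphans = orphans)
}
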