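# Small shared helpers.

#' Derive a deterministic per-stage seed from a root seed
#'
#' One root seed drives the whole pipeline; each stage re-seeds from a child
#' seed hashed from the stage name, so stages are individually reproducible
#' and inserting a stage does not perturb the randomness of the others.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729L
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2039 + h)
}

.assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("%s must be an integer >= %s", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# named-vector trait table coercion: accepts a named numeric vector or a
# data.frame with species/svl_mm columns; positivity is a trait-table
# (SVL) constraint, relaxed where any real-valued trait is admissible
.as_traits <- function(traits, positive = TRUE) {
  if (is.data.frame(traits)) {
    cols <- intersect(c("species", "svl_mm"), names(traits))
    if (length(cols) < 2) stop("trait table needs species and svl_mm columns", call. = FALSE)
    out <- traits$svl_mm
    names(out) <- as.character(traits$species)
    traits <- out
  }
  if (is.null(names(traits)) || anyNA(names(traits)) || any(names(traits) == ""))
    stop("traits must be a named numeric vector", call. = FALSE)
  if (anyDuplicated(names(traits))) stop("duplicate species in trait table", call. = FALSE)
  if (any(!is.finite(traits)))
    stop("trait values must be finite", call. = FALSE)
  if (positive && any(traits <= 0))
    stop("svl_mm must be positive and finite", call. = FALSE)
  traits
}

.as_occurrences <- function(occ) {
  stopifnot(is.data.frame(occ))
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(occ)))
    stop("occurrence table needs columns species, longitude, latitude", call. = FALSE)
  occ$species <- as.character(occ$species)
  .check_lonlat(occ$longitude, occ$latitude)
  occ
}
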