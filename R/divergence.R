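# Body-size classification and the signed "divergent sympatry" statistic:
# a Pearson chi-squared comparing a focal species' sympatric congeners'
# size-class counts with genus-wide expectations, negated when the focal
# co-occurs with its own size class more than expected (convergent sympatry).

#' Fisher-Jenks natural-breaks size classification
#'
#' Optimal k-class partition of a 1-D trait minimizing the total
#' within-class sum of squared deviations, by dynamic programming over the
#' distinct sorted values (so equal values always share a class).
#' Classification is by upper-break thresholds, ties assigned to the lower
#' class. With `k = 3` the classes are named small/medium/large.
#'
#' @param traits named numeric vector (SVL in mm) or data.frame with
#'   `species`, `svl_mm`.
#' @param k number of classes (default 3).
#' @param breaks optional two (or `k-1`) explicit strictly increasing upper
#'   thresholds, overriding the optimisation (e.g. visually chosen breaks).
#' @return object of class `size_classification`: list with `breaks` (k-1
#'   upper thresholds of the lower classes), `class` (named factor),
#'   `counts`, and `within_ss`.
#' @export
classify_sizes <- function(traits, k = 3, breaks = NULL) {
  traits <- .as_traits(traits)
  .assert_count(k, "k", 2)
  v <- sort(unique(traits))
  class_names <- if (k == 3) c("small", "medium", "large")
                 else paste0("class", seq_len(k))
  if (is.null(breaks)) {
    if (length(v) < k)
      stop(sprintf("need at least %d distinct trait values", k), call. = FALSE)
    w <- vapply(v, function(x) sum(traits == x), 0)
    m <- length(v)
    # prefix sums for O(1) weighted SS of any value interval
    cw <- cumsum(w); cwx <- cumsum(w * v); cwx2 <- cumsum(w * v^2)
    seg_ss <- function(i, j) {
      W <- cw[j] - if (i > 1) cw[i - 1] else 0
      S <- cwx[j] - if (i > 1) cwx[i - 1] else 0
      S2 <- cwx2[j] - if (i > 1) cwx2[i - 1] else 0
      S2 - S^2 / W
    }
    dp <- matrix(Inf, k, m)
    back <- matrix(0L, k, m)
    for (j in 1:m) dp[1, j] <- seg_ss(1, j)
    for (c in 2:k) for (j in c:m) {
      for (i in c:j) {
        val <- dp[c - 1, i - 1] + seg_ss(i, j)
        if (val < dp[c, j] - 1e-12) { dp[c, j] <- val; back[c, j] <- i }
      }
    }
    # recover class upper boundaries
    cuts <- integer(k)  # index of last distinct value in each class
    j <- m
    for (c in k:2) { cuts[c] <- j; j <- back[c, j] - 1L }
    cuts[1] <- j
    breaks <- v[cuts[seq_len(k - 1)]]
    within_ss <- dp[k, m]
  } else {
    if (length(breaks) != k - 1 || any(diff(breaks) <= 0))
      stop(sprintf("breaks must be %d strictly increasing values", k - 1),
           call. = FALSE)
    within_ss <- NA_real_
  }
  cls <- cut(traits, c(-Inf, breaks, Inf), labels = class_names, right = TRUE)
  names(cls) <- names(traits)
  counts <- table(cls)
  structure(list(breaks = breaks, class = cls,
                 counts = as.integer(counts), class_names = class_names,
                 within_ss = within_ss, traits = traits),
            class = "size_classification")
}

#' @export
print.size_classification <- function(x, ...) {
  cat(sprintf("Size classification: %d species in %d classes\n",
              length(x$class), length(x$class_names)))
  cat(sprintf("  breaks (mm): %s\n",
              paste(format(x$breaks, digits = 5), collapse = ", ")))
  cat(sprintf("  counts: %s\n",
              paste(sprintf("%s=%d", x$class_names, x$counts), collapse = ", ")))
  invisible(x)
}

# genus-pool proportions over classes; pool optionally excludes the focal
.pool_proportions <- function(cls, focal = NULL, include_focal = FALSE) {
  members <- names(cls$class)
  if (!include_focal && !is.null(focal)) members <- setdiff(members, focal)
  pool <- cls$class[members]
  tab <- table(factor(pool, levels = cls$class_names))
  list(counts = as.numeric(tab), size = length(pool))
}

#' Signed divergent-sympatry statistic for one focal species
#'
#' Counts the focal's sympatric congeners per size class (O), forms the
#' expectation from genus-wide class frequencies scaled to the number of
#' sympatric congeners (E), and computes the Pearson chi-squared
#' \eqn{\sum (O-E)^2/E} over classes with positive expectation. The value
#' is multiplied by -1 when the focal's own size class is over-represented
#' among its sympatric congeners (convergent sympatry); otherwise the sign
#' is +1 (divergent sympatry).
#'
#' @param focal focal species id (must be classified).
#' @param symp a [sympatry_matrix()].
#' @param cls a [classify_sizes()] result.
#' @param include_focal logical: keep the focal species in the genus pool
#'   used for the expectations (default FALSE, avoiding self-counting).
#' @return object of class `divergent_sympatry`: observed/expected per
#'   class, `chi2`, `sign`, `signed_score`, `n_sympatric`, and `defined`
#'   (FALSE when the focal has no sympatric congeners; such species are
#'   excluded from downstream tests, not scored 0).
#' @export
divergent_sympatry <- function(focal, symp, cls, include_focal = FALSE) {
  stopifnot(inherits(symp, "sympatry_matrix"),
            inherits(cls, "size_classification"))
  if (!focal %in% names(cls$class))
    stop(sprintf("focal species %s not classified", focal), call. = FALSE)
  if (!focal %in% symp$species)
    stop(sprintf("focal species %s not in sympatry matrix", focal),
         call. = FALSE)
  congeners <- symp$species[which(symp$S[focal, ])]
  congeners <- intersect(congeners, names(cls$class))
  n_symp <- length(congeners)
  O <- as.numeric(table(factor(cls$class[congeners],
                               levels = cls$class_names)))
  pool <- .pool_proportions(cls, focal, include_focal)
  E <- n_symp * pool$counts / pool$size
  if (n_symp == 0) {
    return(structure(list(focal = focal, observed = O, expected = E,
                          chi2 = NA_real_, sign = NA_integer_,
                          signed_score = NA_real_, n_sympatric = 0L,
                          defined = FALSE, class_names = cls$class_names),
                     class = "divergent_sympatry"))
  }
  pos <- E > 0
  chi2 <- sum((O[pos] - E[pos])^2 / E[pos])
  own <- match(as.character(cls$class[focal]), cls$class_names)
  sgn <- if (O[own] > E[own]) -1L else 1L
  structure(list(focal = focal, observed = O, expected = E, chi2 = chi2,
                 sign = sgn, signed_score = sgn * chi2,
                 n_sympatric = as.integer(n_symp), defined = TRUE,
                 class_names = cls$class_names),
            class = "divergent_sympatry")
}

#' @export
print.divergent_sympatry <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("Divergent sympatry for %s: undefined (no sympatric congeners)\n",
                x$focal))
    return(invisible(x))
  }
  cat(sprintf("Divergent sympatry for %s: chi2 = %.4g, sign %+d, score %+.4g\n",
              x$focal, x$chi2, x$sign, x$signed_score))
  cat(sprintf("  observed %s | expected %s (n = %d)\n",
              paste(x$observed, collapse = ":"),
              paste(format(x$expected, digits = 4), collapse = ":"),
              x$n_sympatric))
  invisible(x)
}

#' Divergent sympatry for every classified species
#' @inheritParams divergent_sympatry
#' @return data.frame with one row per species: per-class observed and
#'   expected counts, `chi2`, `sign`, `signed_score`, `n_sympatric`,
#'   `defined`.
#' @export
divergent_sympatry_all <- function(symp, cls, include_focal = FALSE) {
  sp <- intersect(symp$species, names(cls$class))
  rows <- lapply(sp, function(s) {
    r <- divergent_sympatry(s, symp, cls, include_focal)
    data.frame(focal = s, class = as.character(cls$class[s]),
               O_small = r$observed[1], O_medium = r$observed[2],
               O_large = r$observed[3],
               E_small = r$expected[1], E_medium = r$expected[2],
               E_large = r$expected[3],
               chi2 = r$chi2, sign = r$sign, signed_score = r$signed_score,
               n_sympatric = r$n_sympatric, defined = r$defined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Pearson goodness of fit against given expectations
.pearson_gof <- function(observed, expected, unit = NA_character_) {
  pos <- expected > 0
  chi2 <- sum((observed[pos] - expected[pos])^2 / expected[pos])
  df <- sum(pos) - 1L
  structure(list(unit = unit, observed = observed, expected = expected,
                 chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("Composition test (%s): chi2 = %.4g, df = %d, p = %.4g\n",
              x$unit, x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Goodness-of-fit of sign categories within one size class
#'
#' Partitions the species of a size class into three categories by signed
#' divergent-sympatry score: divergent (`score > neutral_band`),
#' near-neutral (`|score| <= neutral_band`), convergent
#' (`score < -neutral_band`), and tests the category counts against a
#' uniform expectation (Pearson, df = 2). Undefined results (species with
#' no sympatric congeners) are excluded.
#'
#' @param results data.frame from [divergent_sympatry_all()].
#' @param size_class class to test (e.g. "small").
#' @param neutral_band non-negative score half-width of the near-neutral
#'   category; the default 0 sends every nonzero score to the divergent or
#'   convergent category.
#' @return a `composition_test` with `counts = (divergent, neutral,
#'   convergent)`.
#' @export
sign_category_test <- function(results, size_class, neutral_band = 0) {
  stopifnot(neutral_band >= 0)
  sub <- results[results$defined & results$class == size_class, , drop = FALSE]
  if (nrow(sub) == 0)
    stop(sprintf("no defined results in class %s", size_class), call. = FALSE)
  s <- sub$signed_score
  counts <- c(divergent = sum(s > neutral_band),
              neutral = sum(abs(s) <= neutral_band),
              convergent = sum(s < -neutral_band))
  out <- .pearson_gof(as.numeric(counts), rep(nrow(sub) / 3, 3),
                      unit = sprintf("sign categories, %s", size_class))
  out$counts <- counts
  out$neutral_band <- neutral_band
  out
}

#' Size-class composition test per bioregion
#'
#' For each bioregion, compares the observed number of small, medium and
#' large species with the expectation from genus-wide class frequencies
#' scaled to the region's richness (Pearson chi-squared, df = classes with
#' positive expectation minus 1). Regions with fewer than two species are
#' flagged untested.
#'
#' @param assignment a [detect_bioregions()] result.
#' @param cls a [classify_sizes()] result.
#' @return list of `composition_test` objects (untested regions carry
#'   `tested = FALSE`), one per region.
#' @export
bioregion_size_composition <- function(assignment, cls) {
  stopifnot(inherits(assignment, "bioregion_assignment"),
            inherits(cls, "size_classification"))
  genus <- .pool_proportions(cls, focal = NULL, include_focal = TRUE)
  lapply(names(assignment$region_species), function(rid) {
    sp <- intersect(assignment$region_species[[rid]], names(cls$class))
    O <- as.numeric(table(factor(cls$class[sp], levels = cls$class_names)))
    if (length(sp) < 2) {
      out <- structure(list(unit = sprintf("bioregion %s", rid),
                            observed = O, expected = rep(NA_real_, 3),
                            chi2 = NA_real_, df = NA_integer_,
                            p_value = NA_real_),
                       class = "composition_test")
      out$tested <- FALSE
      return(out)
    }
    E <- length(sp) * genus$counts / genus$size
    out <- .pearson_gof(O, E, unit = sprintf("bioregion %s", rid))
    out$tested <- TRUE
    out
  })
}
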