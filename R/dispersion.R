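# Assemblage phylogenetic dispersion: mean pairwise patristic distance
# (MPD) and its standardized effect size under a tip-label-shuffling null.
# Negative SES indicates phylogenetic clustering (underdispersion): the
# assemblage's species are closer on the tree than random draws from the
# pool.

#' Mean pairwise phylogenetic distance of an assemblage
#'
#' Mean of the patristic (branch-length) distances over all unordered pairs
#' of assemblage members. Duplicate names and ordering are irrelevant.
#'
#' @param assemblage character vector of species (tree tips).
#' @param tree rooted [ape::phylo].
#' @param dist optional precomputed cophenetic distance matrix (for reuse
#'   across many assemblages).
#' @return the MPD, or `NA` with a warning-free flag for assemblages of
#'   fewer than 2 distinct members.
#' @export
mpd <- function(assemblage, tree, dist = NULL) {
  assemblage <- unique(as.character(assemblage))
  if (is.null(dist)) dist <- ape::cophenetic.phylo(tree)
  bad <- setdiff(assemblage, rownames(dist))
  if (length(bad))
    stop(sprintf("not tree tips: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (length(assemblage) < 2) return(NA_real_)
  sub <- dist[assemblage, assemblage]
  mean(sub[upper.tri(sub)])
}

#' MPD standardized effect sizes under a tip-shuffling null
#'
#' For each assemblage, compares the observed MPD with a null distribution
#' obtained by shuffling tip labels across the species pool (the union of
#' all assemblage members present in the tree) and recomputing every
#' assemblage's MPD per draw; one permutation is shared by all assemblages
#' within a draw. SES = (observed - null mean) / null SD; the p-value
#' quantile uses the (r + 1)/(n + 1) rank convention. Assemblages equal to
#' the whole pool have a constant null and are flagged degenerate rather
#' than scored 0.
#'
#' @param assemblages named list of species vectors (one per region).
#' @param tree rooted [ape::phylo].
#' @param n_null number of null draws (default 999).
#' @param seed integer seed.
#' @return data.frame of class `mpd_ses`: per region `observed_mpd`,
#'   `null_mean`, `null_sd`, `ses`, `p_quantile`, `n_species`, `n_null`,
#'   `degenerate`.
#' @export
mpd_ses <- function(assemblages, tree, n_null = 999, seed = 1) {
  stopifnot(is.list(assemblages), length(assemblages) >= 1)
  if (is.null(names(assemblages)))
    names(assemblages) <- as.character(seq_along(assemblages))
  assemblages <- lapply(assemblages, function(a)
    unique(intersect(as.character(a), tree$tip.label)))
  pool <- sort(unique(unlist(assemblages)))
  if (length(pool) < 2) stop("species pool has fewer than 2 tips", call. = FALSE)
  dist <- ape::cophenetic.phylo(tree)[pool, pool]

  idx_sets <- lapply(assemblages, function(a) match(a, pool))
  obs <- vapply(idx_sets, function(ix) {
    if (length(ix) < 2) return(NA_real_)
    sub <- dist[ix, ix]
    mean(sub[upper.tri(sub)])
  }, 0)

  set.seed(seed)
  np <- length(pool)
  nulls <- matrix(NA_real_, n_null, length(assemblages))
  for (b in seq_len(n_null)) {
    perm <- sample.int(np)
    for (j in seq_along(idx_sets)) {
      ix <- perm[idx_sets[[j]]]
      if (length(ix) < 2) next
      sub <- dist[ix, ix]
      nulls[b, j] <- mean(sub[upper.tri(sub)])
    }
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  degenerate <- !is.finite(obs) | !is.finite(null_sd) | null_sd < 1e-12
  ses <- ifelse(degenerate, NA_real_, (obs - null_mean) / null_sd)
  p_q <- vapply(seq_along(obs), function(j) {
    if (degenerate[j]) return(NA_real_)
    (sum(nulls[, j] < obs[j]) + 1) / (n_null + 1)
  }, 0)
  out <- data.frame(region = names(assemblages),
                    n_species = lengths(idx_sets),
                    observed_mpd = obs, null_mean = null_mean,
                    null_sd = null_sd, ses = ses, p_quantile = p_q,
                    n_null = n_null, degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("mpd_ses", class(out))
  out
}

#' @export
print.mpd_ses <- function(x, ...) {
  cat(sprintf("MPD dispersion for %d assemblages (%d null draws)\n",
              nrow(x), x$n_null[1]))
  print.data.frame(x[c("region", "n_species", "observed_mpd", "null_mean",
                       "ses", "p_quantile")], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Correlation with a two-sided test
#'
#' Pearson (t transform, df = n - 2) or Spearman (t approximation on the
#' rank correlation) correlation between two numeric vectors.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @param method "pearson" or "spearman".
#' @return list of class `stat_result`: `statistic`, `estimate`, `df`,
#'   `p_value`, `defined`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must be equal-length vectors of length >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(statistic = method, estimate = NA_real_,
                          df = length(x) - 2L, p_value = NA_real_,
                          defined = FALSE), class = "stat_result"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(statistic = method, estimate = unname(ct$estimate),
                 df = length(x) - 2L, p_value = ct$p.value, defined = TRUE),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s correlation: rho = %.4g, df = %d, p = %.4g%s\n",
              x$statistic, x$estimate, x$df, x$p_value,
              if (!x$defined) " [undefined: zero variance]" else ""))
  invisible(x)
}
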