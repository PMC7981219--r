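# Continuous-trait evolution on a phylogeny: Brownian motion (BM),
# Ornstein-Uhlenbeck (OU) and early-burst (EB) maximum likelihood, Pagel's
# lambda, GLS ancestral states, and intercept-only PGLS residuals. All
# models are multivariate normal with covariance sigma2 * W, where W is a
# structure matrix built from shared root-to-MRCA path lengths C:
#   BM: W = C
#   OU (ultrametric, depth T): W_ij = exp(-2 a T) (exp(2 a C_ij) - 1) / (2 a)
#   EB: W_ij = (exp(r C_ij) - 1) / r, r <= 0
#   lambda: off-diagonal of C scaled by lambda in [0, 1]
# sigma2 and the root state are concentrated out analytically, leaving at
# most one profiled parameter.

.match_traits_tree <- function(tree, traits) {
  traits <- .as_traits(traits, positive = FALSE)
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing))
    stop(sprintf("no trait value for tip(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  traits[tree$tip.label]
}

# profile log-likelihood of x ~ N(mu 1, sigma2 W) with mu, sigma2 at their
# conditional ML values
.gls_profile <- function(W, x) {
  n <- length(x)
  L <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(L)) return(list(ok = FALSE))
  logdet <- 2 * sum(log(diag(L)))
  Wi1 <- backsolve(L, backsolve(L, rep(1, n), transpose = TRUE))
  Wix <- backsolve(L, backsolve(L, x, transpose = TRUE))
  mu <- sum(Wix) / sum(Wi1)
  q <- sum((x - mu) * (Wix - mu * Wi1))
  sigma2 <- q / n
  if (sigma2 <= 0)
    return(list(ok = TRUE, mu = mu, sigma2 = 0, logLik = Inf,
                degenerate = TRUE, logdet = logdet, Wi1 = Wi1))
  logLik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(ok = TRUE, mu = mu, sigma2 = sigma2, logLik = logLik,
       degenerate = FALSE, logdet = logdet, Wi1 = Wi1)
}

.tree_depth <- function(tree) {
  nd <- ape::node.depth.edgelength(tree)
  max(nd[seq_along(tree$tip.label)])
}

.check_ultrametric <- function(tree, tol = 1e-6) {
  nd <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(nd)) > tol * max(nd))
    stop("tree is not ultrametric", call. = FALSE)
  invisible(max(nd))
}

#' Maximum-likelihood Brownian-motion fit
#'
#' Exact closed-form GLS: root state is the GLS mean under covariance
#' proportional to the shared-path-length matrix, and sigma2 is the ML
#' quadratic form divided by n. No iterative optimisation is involved.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param traits named trait vector covering every tip.
#' @return object of class `comparative_fit` with `model = "BM"`,
#'   `sigma2`, `root_state`, `log_likelihood`, `converged`, `degenerate`.
#' @export
bm_fit <- function(tree, traits) {
  x <- .match_traits_tree(tree, traits)
  C <- ape::vcv(tree)
  g <- .gls_profile(C, x)
  if (!g$ok) stop("phylogenetic covariance is singular", call. = FALSE)
  structure(list(model = "BM", sigma2 = g$sigma2, alpha = NA_real_,
                 r = NA_real_, root_state = g$mu,
                 log_likelihood = if (g$degenerate) NA_real_ else g$logLik,
                 converged = TRUE, degenerate = g$degenerate,
                 n = length(x)),
            class = "comparative_fit")
}

# shared 1-D profile optimiser over a transform parameter; 5 deterministic
# starting intervals, best local optimum wins
.profile_fit <- function(x, Wfun, lower, upper, null_at) {
  obj <- function(p) {
    g <- .gls_profile(Wfun(p), x)
    if (!g$ok || !is.finite(g$logLik)) return(1e10)
    -g$logLik
  }
  grid <- seq(lower, upper, length.out = 6)
  best <- NULL
  agree <- c()
  for (i in 1:5) {
    o <- stats::optimize(obj, c(grid[i], grid[i + 1]), tol = 1e-8)
    agree <- c(agree, o$objective)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  # the nested null (BM) is always a candidate
  f0 <- obj(null_at)
  if (f0 <= best$objective) best <- list(minimum = null_at, objective = f0)
  p_hat <- best$minimum
  g <- .gls_profile(Wfun(p_hat), x)
  converged <- g$ok && is.finite(g$logLik) &&
    (min(agree) - best$objective) < 1e-2 + abs(best$objective) * 1e-6
  list(p = p_hat, g = g, converged = converged)
}

#' Maximum-likelihood Ornstein-Uhlenbeck fit
#'
#' Non-stationary OU conditioned on the root state, on an ultrametric tree
#' (checked; non-ultrametric input is an error, not silently accepted).
#' The constraint strength alpha is profiled over a bounded interval from
#' five deterministic starts with sigma2 and the root concentrated out; at
#' alpha = 0 the model reduces exactly to BM.
#'
#' @inheritParams bm_fit
#' @param alpha_max upper bound for alpha, in units of 1/tree depth
#'   (default 50).
#' @param fixed optional fixed alpha (skips profiling; `fixed = 0`
#'   reproduces the BM likelihood exactly).
#' @return a `comparative_fit` with `model = "OU"` and `alpha`.
#' @export
ou_fit <- function(tree, traits, alpha_max = 50, fixed = NULL) {
  x <- .match_traits_tree(tree, traits)
  T_depth <- .check_ultrametric(tree)
  C <- ape::vcv(tree)
  Wfun <- function(a) {
    if (a < 1e-10 / T_depth) return(C)
    (exp(-2 * a * T_depth) * (exp(2 * a * C) - 1)) / (2 * a)
  }
  fit <- if (!is.null(fixed)) {
    list(p = fixed, g = .gls_profile(Wfun(fixed), x), converged = TRUE)
  } else .profile_fit(x, Wfun, 0, alpha_max / T_depth, null_at = 0)
  structure(list(model = "OU", sigma2 = fit$g$sigma2, alpha = fit$p,
                 r = NA_real_, root_state = fit$g$mu,
                 log_likelihood = if (fit$g$degenerate) NA_real_ else fit$g$logLik,
                 converged = fit$converged, degenerate = fit$g$degenerate,
                 n = length(x)),
            class = "comparative_fit")
}

#' Maximum-likelihood early-burst fit
#'
#' Early-burst rescales the Brownian rate through time as
#' `sigma2 * exp(rt)` with a nonpositive decay; integrating along shared
#' paths gives `W = (exp(rC) - 1) / r`, reducing to BM at zero decay. It is
#' profiled over `[-r_bound/T, 0]` from five deterministic starts; an
#' honest `converged` flag reports multi-start disagreement or a
#' degenerate optimum.
#'
#' @inheritParams bm_fit
#' @param r_bound magnitude bound for the decay, in units of 1/tree depth
#'   (default 10).
#' @param fixed optional fixed decay (skips profiling; `fixed = 0`
#'   reproduces the BM likelihood exactly).
#' @return a `comparative_fit` with `model = "EB"` and `r`.
#' @export
eb_fit <- function(tree, traits, r_bound = 10, fixed = NULL) {
  x <- .match_traits_tree(tree, traits)
  T_depth <- .tree_depth(tree)
  C <- ape::vcv(tree)
  Wfun <- function(r) {
    if (abs(r) < 1e-10 / T_depth) return(C)
    (exp(r * C) - 1) / r
  }
  fit <- if (!is.null(fixed)) {
    list(p = fixed, g = .gls_profile(Wfun(fixed), x), converged = TRUE)
  } else .profile_fit(x, Wfun, -r_bound / T_depth, 0, null_at = 0)
  structure(list(model = "EB", sigma2 = fit$g$sigma2, alpha = NA_real_,
                 r = fit$p, root_state = fit$g$mu,
                 log_likelihood = if (fit$g$degenerate) NA_real_ else fit$g$logLik,
                 converged = fit$converged, degenerate = fit$g$degenerate,
                 n = length(x)),
            class = "comparative_fit")
}

#' @export
print.comparative_fit <- function(x, ...) {
  extra <- switch(x$model,
                  OU = sprintf(", alpha = %.4g", x$alpha),
                  EB = sprintf(", r = %.4g", x$r), "")
  cat(sprintf("%s fit: logLik = %.4f, sigma2 = %.4g, root = %.4g mm%s%s\n",
              x$model, x$log_likelihood, x$sigma2, x$root_state, extra,
              if (!x$converged) " [did not converge]" else ""))
  invisible(x)
}

#' Pagel's lambda for a continuous trait
#'
#' Profiles lambda over the unit interval (off-diagonal covariance scaled
#' by lambda) with sigma2 and the root concentrated out; endpoints are
#' always evaluated, so the reported optimum is never worse than lambda = 0
#' or lambda = 1.
#'
#' @inheritParams bm_fit
#' @return object of class `lambda_fit`: `lambda`, `log_likelihood`,
#'   `sigma2`, `root_state`, plus the endpoint log-likelihoods.
#' @export
pagels_lambda <- function(tree, traits) {
  x <- .match_traits_tree(tree, traits)
  C <- ape::vcv(tree)
  D <- diag(diag(C))
  Wfun <- function(lam) lam * (C - D) + D
  obj <- function(lam) {
    g <- .gls_profile(Wfun(lam), x)
    if (!g$ok || !is.finite(g$logLik)) return(1e10)
    -g$logLik
  }
  o <- stats::optimize(obj, c(0, 1), tol = 1e-8)
  cand <- c(o$minimum, 0, 1)
  vals <- c(o$objective, obj(0), obj(1))
  lam <- cand[which.min(vals)]
  g <- .gls_profile(Wfun(lam), x)
  structure(list(lambda = lam, log_likelihood = g$logLik,
                 sigma2 = g$sigma2, root_state = g$mu,
                 logLik_lambda0 = -vals[2], logLik_lambda1 = -vals[3],
                 n = length(x)),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda: %.4g (logLik = %.4f, sigma2 = %.4g)\n",
              x$lambda, x$log_likelihood, x$sigma2))
  invisible(x)
}

#' GLS ancestral states under Brownian motion
#'
#' Conditional expectations of internal-node states given the tips under
#' the fitted BM model: `a = root + Cov(node, tips) C^{-1} (x - root)`,
#' with prediction variances that include root-estimation uncertainty.
#' The root estimate equals the BM GLS root.
#'
#' @inheritParams bm_fit
#' @return object of class `ancestral_states`: data.frame with `node`
#'   (ape node number), `estimate`, `variance`; plus the underlying
#'   `comparative_fit`.
#' @export
ancestral_states_bm <- function(tree, traits) {
  x <- .match_traits_tree(tree, traits)
  fit <- bm_fit(tree, traits)
  n <- length(tree$tip.label)
  root <- n + 1L
  dn <- ape::dist.nodes(tree)
  depth <- dn[root, ]
  nodes <- root:(n + tree$Nnode)
  # shared path length between any node pair from depths and patristic dist
  shared <- function(i, j) (depth[i] + depth[j] - dn[i, j]) / 2
  C <- ape::vcv(tree)
  L <- chol(C)
  solveC <- function(v) backsolve(L, backsolve(L, v, transpose = TRUE))
  xc <- x - fit$root_state
  Ci_x <- solveC(xc)
  Ci_1 <- solveC(rep(1, n))
  s11 <- sum(Ci_1)
  tips <- seq_len(n)
  est <- var <- numeric(length(nodes))
  for (idx in seq_along(nodes)) {
    nd <- nodes[idx]
    cv <- vapply(tips, function(tp) shared(nd, tp), 0)
    est[idx] <- fit$root_state + sum(cv * Ci_x)
    Ci_cv <- solveC(cv)
    base <- depth[nd] - sum(cv * Ci_cv)
    rootadj <- (1 - sum(Ci_1 * cv))^2 / s11
    var[idx] <- fit$sigma2 * (base + rootadj)
  }
  structure(list(states = data.frame(node = nodes, estimate = est,
                                     variance = pmax(var, 0)),
                 fit = fit),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  rt <- x$states$estimate[1]
  cat(sprintf("BM ancestral states for %d internal nodes; root = %.4g mm\n",
              nrow(x$states), rt))
  invisible(x)
}

#' Intercept-only PGLS residuals
#'
#' Generalized least squares of the trait on an intercept under BM
#' covariance: the residuals are the trait values minus the GLS grand mean
#' (the BM root state), i.e. phylogenetically detrended size. Residuals
#' weighted by the row sums of C^{-1} sum to zero.
#'
#' @inheritParams bm_fit
#' @return named numeric vector of residuals (mm) per tip.
#' @export
pgls_residuals <- function(tree, traits) {
  x <- .match_traits_tree(tree, traits)
  fit <- bm_fit(tree, traits)
  x - fit$root_state
}
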