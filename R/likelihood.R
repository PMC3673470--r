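# Felsenstein pruning for site-class mixture codon models.
#
# A "class specification" is a data frame with one row per omega class:
# columns weight, omega_back, omega_fore.  Site models have
# omega_fore == omega_back everywhere; branch models give foreground
# branches their own omega.  All class matrices are divided by one shared
# scale factor so branch lengths keep a single interpretation across the
# mixture (expected substitutions per codon under the weighted model).

# internal: shared mixture-level scale factor.  calibration = "mixture"
# uses the weighted expected rate over classes (background omegas);
# a numeric calibration freezes the factor (e.g. at an M0 fit's value).
mixture_scale_factor <- function(classes, kappa, pi, code, calibration) {
  if (is.numeric(calibration)) {
    if (calibration <= 0) stop("calibration factor must be positive")
    return(calibration)
  }
  r <- unscaled_rates(kappa, pi, code)
  sum(classes$weight * (r["syn"] + classes$omega_back * r["ns"]))
}

# internal: per-(edge, class) transition matrices for a tagged tree.
# Returns list(P = list over classes of list over postorder edge index,
#              tv = traversal, classes, scale)
build_engine <- function(tp, classes, kappa, pi,
                         code = standard_genetic_code(),
                         calibration = "mixture") {
  pi <- as_pi(pi)
  pi <- pmax(pi, 1e-12); pi <- pi / sum(pi)
  tv <- traversal(tp)
  cs <- mixture_scale_factor(classes, kappa, pi, code, calibration)
  if (cs <= 0) cs <- 1
  omegas <- unique(c(classes$omega_back, classes$omega_fore))
  eigs <- lapply(omegas, function(w) {
    build_rate_matrix(kappa, w, pi, code, scale = cs)$eig
  })
  n_class <- nrow(classes)
  P <- vector("list", n_class)
  for (k in seq_len(n_class)) {
    Pk <- vector("list", nrow(tv$edge))
    for (e in seq_len(nrow(tv$edge))) {
      w <- if (tv$fore[e]) classes$omega_fore[k] else classes$omega_back[k]
      Pk[[e]] <- tm_eig(eigs[[match(w, omegas)]], tv$length[e])
    }
    P[[k]] <- Pk
  }
  list(P = P, tv = tv, classes = classes, pi = pi, scale = cs)
}

# internal: pruning for one class over a taxa x sites state matrix whose
# rows are ordered as tv$tip_label.  Returns log-likelihood per site.
prune_class <- function(states, tv, P_edges, pi) {
  S <- ncol(states)
  n_node_total <- tv$n_tip + tv$n_node
  partial <- vector("list", n_node_total)
  logscale <- numeric(S)
  for (e in seq_len(nrow(tv$edge))) {
    parent <- tv$edge[e, 1]
    child <- tv$edge[e, 2]
    P <- P_edges[[e]]
    if (child <= tv$n_tip) {
      idx <- states[child, ]
      contrib <- matrix(1, nrow(P), S)
      obs <- !is.na(idx)
      if (any(obs)) contrib[, obs] <- P[, idx[obs], drop = FALSE]
    } else {
      contrib <- P %*% partial[[child]]
    }
    cs <- colSums(contrib)
    contrib <- contrib / rep(cs, each = nrow(P))
    logscale <- logscale + log(cs)
    partial[[parent]] <- if (is.null(partial[[parent]])) contrib else
      partial[[parent]] * contrib
  }
  root <- partial[[tv$root]]
  log(colSums(pi * root)) + logscale
}

# internal: collapse duplicate site columns; returns states over patterns,
# integer weights, and the site -> pattern map
site_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  u <- !duplicated(key)
  map <- match(key, key[u])
  list(states = states[, u, drop = FALSE],
       weights = as.numeric(tabulate(map, nbins = sum(u))),
       map = map)
}

# internal: reorder alignment rows to the tree's tip labels, with the
# spec'd taxon-mismatch error
states_for_tree <- function(aln, tv) {
  miss <- setdiff(tv$tip_label, aln$taxa)
  if (length(miss)) {
    stop("tree leaves missing from alignment: ",
         paste(miss, collapse = ", "))
  }
  aln$states[tv$tip_label, , drop = FALSE]
}

#' Per-site, per-class pruning log-likelihoods
#'
#' Computes, for every codon site and every omega class, the Felsenstein
#' pruning likelihood of the site pattern conditional on that class, in
#' log space with per-node scaling (no underflow for large trees).
#' Missing states are marginalized (partial vector of ones).
#'
#' @param aln a `codon_alignment`; taxa must cover the tree's leaves.
#' @param tree a `tagged_phylo` or ape `phylo`.
#' @param classes class specification: data frame with columns `weight`,
#'   `omega_back`, `omega_fore` (see [model_class_spec()]), or an
#'   `omega_model`.
#' @param kappa transition/transversion ratio.
#' @param pi codon frequencies.
#' @param calibration `"mixture"` for mixture-level rate scaling, or a
#'   positive number freezing the scale factor.
#' @return A `class_site_lik` object: list with `logL` (sites x classes
#'   matrix of per-site conditional log-likelihoods), `class_omegas`
#'   (background omega per class), `class_weights`, `scale`.
#' @export
class_site_likelihoods <- function(aln, tree, classes, kappa, pi,
                                   calibration = "mixture") {
  if (inherits(classes, "omega_model")) classes <- model_class_spec(classes)
  stopifnot(is.data.frame(classes),
            all(c("weight", "omega_back", "omega_fore") %in%
                names(classes)))
  w <- classes$weight
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12) {
    stop("class weights must be non-negative and sum to 1")
  }
  eng <- build_engine(tree, classes, kappa, pi, aln$code, calibration)
  states <- states_for_tree(aln, eng$tv)
  pat <- site_patterns(states)
  logL_pat <- sapply(seq_len(nrow(classes)), function(k) {
    prune_class(pat$states, eng$tv, eng$P[[k]], eng$pi)
  })
  logL_pat <- matrix(logL_pat, ncol = nrow(classes))
  structure(
    list(logL = logL_pat[pat$map, , drop = FALSE],
         class_omegas = classes$omega_back,
         class_weights = w,
         scale = eng$scale),
    class = "class_site_lik")
}

#' Mixture log-likelihood over site classes
#'
#' Sums, over sites, the log of the weight-mixed per-class likelihoods,
#' using log-sum-exp for numerical stability.
#'
#' @param csl a `class_site_lik` from [class_site_likelihoods()].
#' @param weights optional replacement class weights (defaults to the
#'   weights stored in `csl`).
#' @return total log-likelihood (scalar).
#' @export
mixture_log_likelihood <- function(csl, weights = NULL) {
  w <- if (is.null(weights)) csl$class_weights else weights
  if (abs(sum(w) - 1) > 1e-9) stop("class weights must sum to 1")
  if (nrow(csl$logL) == 0L) {
    warning("empty alignment: log-likelihood is 0")
    return(0)
  }
  sum(logsumexp_rows(csl$logL, log(pmax(w, 0))))
}

# internal: row-wise log(sum_k exp(x_k + shift_k)); -Inf shifts allowed
logsumexp_rows <- function(X, shift, row_weights = NULL) {
  X <- sweep(X, 2, shift, "+")
  m <- do.call(pmax, c(as.data.frame(X), na.rm = TRUE))
  m[!is.finite(m)] <- 0
  v <- m + log(rowSums(exp(X - m)))
  if (is.null(row_weights)) v else v * row_weights
}

#' Per-site log-likelihood curve over an omega grid
#'
#' Precomputes single-class pruning log-likelihoods for every site on a
#' log-spaced omega grid and fits a natural cubic spline through each
#' site's curve.  Site-mixture models can then be optimized by cheap
#' interpolation instead of re-running pruning at every candidate
#' parameter vector (see the methods vignette for the accuracy of this
#' scheme).  `kappa`, branch lengths and the rate calibration are fixed
#' for the whole curve.
#'
#' @param aln,tree,kappa,pi as in [class_site_likelihoods()].
#' @param calibration numeric scale factor freezing the rate calibration
#'   (typically the M0 fit's value), or `"mixture"` treating each grid
#'   point as a single-class model of unit rate.
#' @param omega_grid grid of omega values (default 120 log-spaced points
#'   between 1e-9 and 15).
#' @return A `site_lik_curve` object usable with [eval_site_curve()].
#' @export
site_likelihood_curve <- function(aln, tree, kappa, pi,
                                  calibration,
                                  omega_grid = default_omega_grid()) {
  omega_grid <- sort(omega_grid)
  tv <- traversal(tree)
  states <- states_for_tree(aln, tv)
  pat <- site_patterns(states)
  pi_ <- as_pi(pi)
  pi_ <- pmax(pi_, 1e-12); pi_ <- pi_ / sum(pi_)
  code <- aln$code
  cs <- if (is.numeric(calibration)) calibration else NA_real_
  Y <- matrix(NA_real_, ncol(pat$states), length(omega_grid))
  for (g in seq_along(omega_grid)) {
    sc <- if (is.na(cs)) TRUE else cs
    eig <- build_rate_matrix(kappa, omega_grid[g], pi_, code,
                             scale = sc)$eig
    P_edges <- lapply(seq_len(nrow(tv$edge)), function(e) {
      tm_eig(eig, tv$length[e])
    })
    Y[, g] <- prune_class(pat$states, tv, P_edges, pi_)
  }
  u <- log(omega_grid)
  structure(
    list(u = u, Y = Y, M2 = spline_second_derivs(u, Y),
         pattern_weights = pat$weights, map = pat$map,
         n_sites = aln$n_sites, kappa = kappa, calibration = cs),
    class = "site_lik_curve")
}

default_omega_grid <- function(n = 120L, lo = 1e-9, hi = 15) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# internal: natural cubic spline second derivatives for many curves that
# share one knot vector; Y is curves x knots, returns same shape.
spline_second_derivs <- function(u, Y) {
  G <- length(u)
  h <- diff(u)
  n_in <- G - 2L
  A <- matrix(0, n_in, n_in)
  for (i in seq_len(n_in)) {
    A[i, i] <- 2 * (h[i] + h[i + 1])
    if (i > 1) A[i, i - 1] <- h[i]
    if (i < n_in) A[i, i + 1] <- h[i + 1]
  }
  slopes <- sweep(Y[, -1, drop = FALSE] - Y[, -G, drop = FALSE],
                  2, h, "/")                   # curves x (G-1)
  D <- 6 * (slopes[, -1, drop = FALSE] - slopes[, -(G - 1), drop = FALSE])
  M_in <- t(solve(A, t(D)))                     # curves x (G-2)
  cbind(0, M_in, 0)
}

#' Evaluate a site log-likelihood curve at omega values
#'
#' @param curve a [site_likelihood_curve()] object.
#' @param omegas numeric vector of omega values (clamped to the grid
#'   range).
#' @param per_site if `TRUE` (default) expand to all alignment sites;
#'   otherwise return values on the distinct site patterns.
#' @return matrix of interpolated per-site log-likelihoods, sites (or
#'   patterns) x length(omegas).
#' @export
eval_site_curve <- function(curve, omegas, per_site = TRUE) {
  u <- curve$u
  x <- log(pmax(omegas, exp(u[1])))
  x <- pmin(pmax(x, u[1]), u[length(u)])
  i <- findInterval(x, u, all.inside = TRUE)
  h <- u[i + 1] - u[i]
  a <- (u[i + 1] - x) / h
  b <- 1 - a
  out <- sapply(seq_along(x), function(j) {
    ii <- i[j]
    a[j] * curve$Y[, ii] + b[j] * curve$Y[, ii + 1] +
      ((a[j]^3 - a[j]) * curve$M2[, ii] +
       (b[j]^3 - b[j]) * curve$M2[, ii + 1]) * h[j]^2 / 6
  })
  out <- matrix(out, nrow = nrow(curve$Y))
  if (per_site) out[curve$map, , drop = FALSE] else out
}

# internal: mixture log-likelihood straight from a curve (pattern space)
curve_mixture_loglik <- function(curve, omegas, weights) {
  L <- eval_site_curve(curve, omegas, per_site = FALSE)
  sum(logsumexp_rows(L, log(pmax(weights, 0)),
                     row_weights = curve$pattern_weights))
}
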