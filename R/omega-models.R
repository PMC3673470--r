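# The omega-distribution model zoo.
#
# M0           one ratio, all sites and branches.
# M7           omega ~ Beta(p, q), discretized into K equal-weight classes.
# M8           M7 plus one extra class: proportion ps = 1 - p0, omega_s >= 1.
# M8a          M8 with omega_s fixed at 1 (the boundary null of M8 vs M8a).
# BranchSiteA  revised branch-site model A: classes 0 (omega0 < 1
#              everywhere), 1 (neutral everywhere), 2a/2b (background
#              omega0 or 1, foreground omega2 >= 1); null fixes omega2 = 1.
# TwoRatio     one site class, separate foreground/background omega.

MODEL_VARIANTS <- c("M0", "M7", "M8", "M8a",
                    "BranchSiteA", "BranchSiteA_null", "TwoRatio")

#' Specify an omega model
#'
#' Creates a model specification holding the variant and its parameters
#' (free parameters are given starting/field values; constraints of the
#' variant are validated).
#'
#' @param variant one of `"M0"`, `"M7"`, `"M8"`, `"M8a"`,
#'   `"BranchSiteA"`, `"BranchSiteA_null"`, `"TwoRatio"`.
#' @param kappa transition/transversion ratio (default 2).
#' @param omega M0 omega (default 0.2).
#' @param beta_p,beta_q beta shape parameters of the purifying component.
#' @param p0 proportion of beta-distributed sites (M8/M8a), or of the
#'   fully-purifying class (branch-site A).
#' @param p1 proportion of the neutral class (branch-site A).
#' @param omega_s omega of the extra M8 class (>= 1; fixed at 1 for M8a).
#' @param omega0 purifying-class omega of branch-site A (in (0, 1)).
#' @param omega2 foreground omega of branch-site A (>= 1; fixed at 1 in
#'   the null).
#' @param omega_fore,omega_back two-ratio branch omegas.
#' @param K number of beta discretization categories (default 10).
#' @return An `omega_model` list.
#' @examples
#' m <- omega_model("M8", beta_p = 0.2, beta_q = 2, p0 = 0.95,
#'                  omega_s = 2)
#' @export
omega_model <- function(variant, kappa = 2, omega = 0.2,
                        beta_p = 1, beta_q = 2, p0 = 0.9, p1 = 0.05,
                        omega_s = 1.5, omega0 = 0.1, omega2 = 2,
                        omega_fore = 0.2, omega_back = 0.2, K = 10L) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (K < 2L) stop("K must be at least 2")
  if (kappa <= 0) stop("kappa must be positive")
  m <- list(variant = variant, kappa = kappa, K = as.integer(K))
  if (variant == "M0") {
    if (omega < 0) stop("omega must be non-negative")
    m$omega <- omega
  } else if (variant %in% c("M7", "M8", "M8a")) {
    if (beta_p <= 0 || beta_q <= 0) stop("beta shapes must be positive")
    m$beta_p <- beta_p
    m$beta_q <- beta_q
    if (variant != "M7") {
      if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
      m$p0 <- p0
      m$p_s <- 1 - p0
      m$omega_s <- if (variant == "M8a") 1 else omega_s
      if (variant == "M8" && omega_s < 1) {
        stop("M8 requires omega_s >= 1 (use M8a for the boundary null)")
      }
    }
  } else if (variant %in% c("BranchSiteA", "BranchSiteA_null")) {
    if (p0 < 0 || p1 < 0 || p0 + p1 > 1 || p0 + p1 <= 0) {
      stop("branch-site proportions need p0, p1 >= 0, 0 < p0 + p1 <= 1")
    }
    if (omega0 < 0 || omega0 >= 1) stop("omega0 must lie in [0, 1)")
    m$p0 <- p0
    m$p1 <- p1
    m$omega0 <- omega0
    m$omega2 <- if (variant == "BranchSiteA_null") 1 else omega2
    if (variant == "BranchSiteA" && omega2 < 1) {
      stop("branch-site model A requires omega2 >= 1")
    }
  } else {  # TwoRatio
    if (omega_fore < 0 || omega_back < 0) stop("omegas must be >= 0")
    m$omega_fore <- omega_fore
    m$omega_back <- omega_back
  }
  structure(m, class = "omega_model")
}

#' @export
print.omega_model <- function(x, ...) {
  pars <- setdiff(names(x), c("variant", "K"))
  cat("<omega_model> ", x$variant, ": ",
      paste(pars, vapply(x[pars], function(v) format(v, digits = 4), ""),
            sep = " = ", collapse = ", "),
      " (K = ", x$K, ")\n", sep = "")
  invisible(x)
}

#' Discretize a beta distribution into equal-weight omega categories
#'
#' Splits Beta(p, q) into `K` equal-probability bins and represents each
#' bin by its conditional mean, the standard computational realization of
#' the continuous beta site-class distribution.
#'
#' @param p,q beta shape parameters (> 0).
#' @param K number of categories (>= 2).
#' @return list with `omegas` (strictly increasing bin means in (0, 1))
#'   and `weights` (all `1/K`).
#' @examples
#' discretize_beta(1, 1, 2)$omegas  # 0.25 0.75
#' @export
discretize_beta <- function(p, q, K = 10L) {
  if (p <= 0 || q <= 0) stop("beta shape parameters must be positive")
  if (K < 2L) stop("K must be at least 2")
  # qbeta warns about reduced accuracy for very extreme shapes; the bin
  # means below come from pbeta differences and are insensitive to it
  edges <- suppressWarnings(
    stats::qbeta(seq(0, 1, length.out = K + 1), p, q))
  # conditional mean over [a,b]: mean * (I_b(p+1,q) - I_a(p+1,q)) / (1/K)
  cdf1 <- stats::pbeta(edges, p + 1, q)
  means <- (p / (p + q)) * K * diff(cdf1)
  # guard against round-off collapsing extreme bins; keep strict order
  means <- pmin(pmax(means, 1e-12), 1 - 1e-12)
  for (i in seq_len(K - 1)) {
    if (means[i + 1] <= means[i]) {
      means[i + 1] <- means[i] * (1 + 1e-9) + 1e-15
    }
  }
  list(omegas = means, weights = rep(1 / K, K))
}

#' Class specification of an omega model
#'
#' Expands an `omega_model` into its per-class mixture representation:
#' one row per site class with the class weight and the omega applying on
#' background and foreground branches.  Classes are ordered by increasing
#' background omega within each structural block (beta classes ascending,
#' extra/foreground classes last).
#'
#' @param model an [omega_model()].
#' @return data frame with columns `weight`, `omega_back`, `omega_fore`.
#' @export
model_class_spec <- function(model) {
  stopifnot(inherits(model, "omega_model"))
  v <- model$variant
  if (v == "M0") {
    return(data.frame(weight = 1, omega_back = model$omega,
                      omega_fore = model$omega))
  }
  if (v == "TwoRatio") {
    return(data.frame(weight = 1, omega_back = model$omega_back,
                      omega_fore = model$omega_fore))
  }
  if (v %in% c("M7", "M8", "M8a")) {
    d <- discretize_beta(model$beta_p, model$beta_q, model$K)
    if (v == "M7") {
      return(data.frame(weight = d$weights, omega_back = d$omegas,
                        omega_fore = d$omegas))
    }
    w <- c(d$weights * model$p0, 1 - model$p0)
    om <- c(d$omegas, model$omega_s)
    return(data.frame(weight = w, omega_back = om, omega_fore = om))
  }
  # branch-site model A: classes 0, 1, 2a, 2b
  p0 <- model$p0; p1 <- model$p1
  p2 <- 1 - p0 - p1
  w <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
  data.frame(weight = w,
             omega_back = c(model$omega0, 1, model$omega0, 1),
             omega_fore = c(model$omega0, 1, model$omega2, model$omega2))
}

# internal: number of free model parameters by variant (branch-length
# parameters are counted separately by fit())
n_free_model_params <- function(variant, kappa_free = TRUE) {
  base <- switch(variant,
    M0 = 1L, M7 = 2L, M8 = 4L, M8a = 3L,
    BranchSiteA = 4L, BranchSiteA_null = 3L, TwoRatio = 2L)
  base + as.integer(kappa_free)
}

# internal: does the variant use foreground branch tags
uses_foreground <- function(variant) {
  variant %in% c("BranchSiteA", "BranchSiteA_null", "TwoRatio")
}
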