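# Per-site posterior probabilities over omega classes.
#
# NEB (naive empirical Bayes) plugs the MLE mixture weights into Bayes'
# rule site by site.  BEB averages the same posterior over a uniform
# 11 x 11 grid on (p0, omega_s) for the M8 family, weighting each grid
# point by the likelihood of the whole alignment with the beta shape
# parameters held at their MLEs -- a documented simplification of the
# reference Bayes empirical Bayes scheme (see vignette).

#' Per-site posterior class probabilities
#'
#' @param fit a `fit_result` for the model whose classes `csl` was
#'   computed under.
#' @param csl a [class_site_likelihoods()] result at the fitted MLE.
#' @param method `"NEB"` or `"BEB"` (BEB requires an M8-family fit and
#'   `extra_lik`).
#' @param extra_lik for BEB: function taking a vector of omega values
#'   and returning the per-site conditional log-likelihood matrix
#'   (sites x omegas) for a single class at that omega, e.g. a closure
#'   over [eval_site_curve()] or exact pruning.
#' @param grid_n BEB grid resolution per axis (default 11).
#' @param omega_s_max upper end of the BEB omega_s grid (default 11).
#' @return A `site_posteriors` object: list with `PP` (sites x classes,
#'   rows summing to one), `class_omegas`, `method`.
#' @export
site_class_posteriors <- function(fit, csl, method = c("NEB", "BEB"),
                                  extra_lik = NULL, grid_n = 11L,
                                  omega_s_max = 11) {
  method <- match.arg(method)
  stopifnot(inherits(csl, "class_site_lik"))
  w <- csl$class_weights
  if (length(w) != ncol(csl$logL)) stop("class count mismatch")
  if (method == "NEB") {
    PP <- neb_pp(csl$logL, w)
  } else {
    if (!fit$model$variant %in% c("M8", "M8a")) {
      stop("BEB posteriors are defined for the M8 model family")
    }
    if (is.null(extra_lik)) {
      stop("BEB requires 'extra_lik' to evaluate the positive-selection ",
           "class on the omega_s grid")
    }
    K <- fit$model$K
    beta_logL <- csl$logL[, seq_len(K), drop = FALSE]
    p0_grid <- (2 * seq_len(grid_n) - 1) / (2 * grid_n)
    ws_grid <- 1 + (omega_s_max - 1) *
      (2 * seq_len(grid_n) - 1) / (2 * grid_n)
    extra_logL <- extra_lik(ws_grid)          # sites x grid_n
    accum <- matrix(0, nrow(csl$logL), K + 1L)
    log_marg <- matrix(NA_real_, grid_n, grid_n)
    PP_list <- vector("list", grid_n * grid_n)
    idx <- 0L
    for (i in seq_along(p0_grid)) {
      for (j in seq_along(ws_grid)) {
        idx <- idx + 1L
        wg <- c(rep(p0_grid[i] / K, K), 1 - p0_grid[i])
        lg <- cbind(beta_logL, extra_logL[, j])
        log_marg[i, j] <- sum(logsumexp_rows(lg, log(wg)))
        PP_list[[idx]] <- neb_pp(lg, wg)
      }
    }
    gm <- as.vector(t(log_marg))
    gw <- exp(gm - max(gm))
    gw <- gw / sum(gw)
    PP <- accum
    for (g in seq_along(PP_list)) PP <- PP + gw[g] * PP_list[[g]]
  }
  structure(
    list(PP = PP, class_omegas = csl$class_omegas, method = method),
    class = "site_posteriors")
}

# internal: Bayes rule per site, log space
neb_pp <- function(logL, w) {
  X <- sweep(logL, 2, log(pmax(w, 0)), "+")
  m <- do.call(pmax, c(as.data.frame(X), na.rm = TRUE))
  m[!is.finite(m)] <- 0
  E <- exp(X - m)
  E / rowSums(E)
}

#' @export
print.site_posteriors <- function(x, ...) {
  cat("<site_posteriors> ", nrow(x$PP), " sites x ", ncol(x$PP),
      " classes (", x$method, ")\n", sep = "")
  invisible(x)
}
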