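# Maximum-likelihood fitting.
#
# fit() maximizes the exact pruning likelihood of any model variant with
# nlminb over box-constrained parameters (log scale for rate-like
# parameters, natural scale with closed bounds for proportions and the
# boundary-constrained omegas, so that nested null models are exactly
# reachable).  Branch lengths are optimized jointly, as a single rate
# scale on the input tree's relative lengths, or held fixed.
#
# fit_site_models() is the production path for the M0 -> M7/M8a/M8
# ladder: after the M0 fit it freezes kappa, branch lengths and the rate
# calibration and optimizes the mixture models over precomputed per-site
# likelihood curves (see site_likelihood_curve), which makes replicated
# simulation studies tractable.  The two paths agree to within optimizer
# tolerance (tested).

#' Optimizer settings for model fitting
#'
#' @param branch_mode `"joint"` (every branch length free), `"scale"`
#'   (one rate multiplier on the input tree's relative lengths), or
#'   `"fixed"` (input lengths used as-is).
#' @param n_starts number of optimization starts (1 deterministic
#'   default + `n_starts - 1` seeded random restarts).
#' @param seed integer seed controlling the random restarts.
#' @param kappa if non-`NULL`, fix kappa at this value.
#' @param calibration `"mixture"` for mixture-level rate scaling or a
#'   positive number freezing the scale factor (see vignette).
#' @param init optional list of named numeric vectors of model
#'   parameters used as additional starts (e.g. a nested model's MLE).
#' @param control passed to [stats::nlminb()].
#' @return list of settings for [fit()].
#' @export
fit_opts <- function(branch_mode = c("joint", "scale", "fixed"),
                     n_starts = 3L, seed = 1L, kappa = NULL,
                     calibration = "mixture", init = NULL,
                     control = list(iter.max = 500L, eval.max = 4000L,
                                    rel.tol = 1e-9)) {
  list(branch_mode = match.arg(branch_mode),
       n_starts = max(1L, as.integer(n_starts)),
       seed = as.integer(seed), kappa = kappa,
       calibration = calibration, init = init, control = control)
}

# ---- parameter packing --------------------------------------------------

# A spec is a data frame: name, trans ("log"/"id"), lower, upper, start
# (all on the transformed scale).
par_row <- function(name, value, trans, lo, hi) {
  v <- if (trans == "log") log(value) else value
  data.frame(name = name, trans = trans,
             lower = if (trans == "log") log(lo) else lo,
             upper = if (trans == "log") log(hi) else hi,
             start = min(max(v, if (trans == "log") log(lo) else lo),
                         if (trans == "log") log(hi) else hi),
             stringsAsFactors = FALSE)
}

model_param_spec <- function(model, kappa_fixed = FALSE) {
  v <- model$variant
  rows <- list()
  if (!kappa_fixed) {
    rows <- c(rows, list(par_row("kappa", model$kappa, "log", 0.05, 50)))
  }
  if (v == "M0") {
    rows <- c(rows, list(par_row("omega", max(model$omega, 1e-4), "log",
                                 1e-4, 20)))
  } else if (v %in% c("M7", "M8", "M8a")) {
    rows <- c(rows,
              list(par_row("beta_p", model$beta_p, "log", 0.005, 99),
                   par_row("beta_q", model$beta_q, "log", 0.005, 99)))
    if (v %in% c("M8", "M8a")) {
      rows <- c(rows, list(par_row("p0", model$p0, "id", 0, 1)))
    }
    if (v == "M8") {
      rows <- c(rows, list(par_row("omega_s", model$omega_s, "id", 1, 15)))
    }
  } else if (v %in% c("BranchSiteA", "BranchSiteA_null")) {
    s <- model$p0 + model$p1
    f <- model$p0 / s
    rows <- c(rows,
              list(par_row("prop_total", s, "id", 1e-6, 1),
                   par_row("prop_split", f, "id", 0, 1),
                   par_row("omega0", max(model$omega0, 1e-6), "log",
                           1e-6, 1)))
    if (v == "BranchSiteA") {
      rows <- c(rows, list(par_row("omega2", model$omega2, "id", 1, 15)))
    }
  } else {  # TwoRatio
    rows <- c(rows,
              list(par_row("omega_back", max(model$omega_back, 1e-4),
                           "log", 1e-4, 20),
                   par_row("omega_fore", max(model$omega_fore, 1e-4),
                           "log", 1e-4, 20)))
  }
  do.call(rbind, rows)
}

# apply a transformed parameter vector back onto the model
apply_params <- function(model, spec, theta) {
  val <- ifelse(spec$trans == "log", exp(theta), theta)
  names(val) <- spec$name
  for (nm in spec$name) {
    if (nm == "prop_total" || nm == "prop_split") next
    model[[nm]] <- unname(val[nm])
  }
  if ("prop_total" %in% spec$name) {
    s <- unname(val["prop_total"]); f <- unname(val["prop_split"])
    model$p0 <- s * f
    model$p1 <- s * (1 - f)
    # keep the 2a/2b split defined when both proportions vanish
    if (model$p0 + model$p1 <= 0) model$p0 <- 1e-12
  }
  if (model$variant == "M8a") model$omega_s <- 1
  if (model$variant == "BranchSiteA_null") model$omega2 <- 1
  if (!is.null(model$p0) && model$variant %in% c("M8", "M8a")) {
    model$p_s <- 1 - model$p0
  }
  model
}

# ---- exact-likelihood fitting ------------------------------------------

#' Fit an omega model by maximum likelihood
#'
#' Maximizes the exact mixture pruning likelihood of the given model
#' variant over its free parameters, with bounded multi-start
#' quasi-Newton optimization.  Deterministic for a given seed.
#'
#' @param aln a `codon_alignment`.
#' @param tree a `tagged_phylo` or ape `phylo` (branch models require
#'   foreground tags).
#' @param model an [omega_model()] giving the variant and start values.
#' @param opts an [fit_opts()] list.
#' @param pi codon frequencies (default F3x4 from the alignment).
#' @return A `fit_result`: list with `model` (MLE parameter values),
#'   `lnL`, `tree` (fitted branch lengths), `branch_mode`,
#'   `n_free_params`, `converged`, `n_starts`, `seed`, `method`
#'   (`"exact"`), `calibration` (rate scale factor at the MLE).
#' @export
fit <- function(aln, tree, model, opts = fit_opts(),
                pi = codon_frequencies(aln, "F3x4")) {
  stopifnot(inherits(model, "omega_model"))
  if (aln$n_sites == 0L) stop("cannot fit a model to a 0-site alignment")
  tp <- as_tagged_phylo(tree)
  if (uses_foreground(model$variant) && !any(tp$fore)) {
    warning("branch model fitted to a tree with no foreground branches")
  }
  tv <- traversal(tp)
  states <- states_for_tree(aln, tv)
  pat <- site_patterns(states)
  pi_ <- as_pi(pi); pi_ <- pmax(pi_, 1e-12); pi_ <- pi_ / sum(pi_)
  code <- aln$code
  kappa_fixed <- !is.null(opts$kappa)
  if (kappa_fixed) model$kappa <- opts$kappa
  spec <- model_param_spec(model, kappa_fixed)
  base_len <- tv$length
  if (opts$branch_mode == "joint") {
    bl <- pmax(base_len, 1e-4)
    bspec <- do.call(rbind, lapply(seq_along(bl), function(e) {
      par_row(paste0(".bl", e), bl[e], "log", 1e-8, 30)
    }))
    spec <- rbind(spec, bspec)
  } else if (opts$branch_mode == "scale") {
    spec <- rbind(spec, par_row(".scale", 1, "log", 1e-4, 100))
  }
  n_model_par <- sum(!startsWith(spec$name, "."))

  eval_theta <- function(theta) {
    m <- apply_params(model, spec[!startsWith(spec$name, "."), ,
                                  drop = FALSE],
                      theta[!startsWith(spec$name, ".")])
    classes <- model_class_spec(m)
    tvl <- tv
    if (opts$branch_mode == "joint") {
      tvl$length <- exp(theta[startsWith(spec$name, ".")])
    } else if (opts$branch_mode == "scale") {
      tvl$length <- base_len * exp(theta[spec$name == ".scale"])
    }
    cs <- mixture_scale_factor(classes, m$kappa, pi_, code,
                               opts$calibration)
    if (!is.finite(cs) || cs <= 0) return(NULL)
    omegas <- unique(c(classes$omega_back, classes$omega_fore))
    eigs <- lapply(omegas, function(w) {
      build_rate_matrix(m$kappa, w, pi_, code, scale = cs)$eig
    })
    logL <- matrix(NA_real_, ncol(pat$states), nrow(classes))
    Pcache <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(classes))) {
      P_edges <- vector("list", nrow(tvl$edge))
      for (e in seq_len(nrow(tvl$edge))) {
        w <- if (tvl$fore[e]) classes$omega_fore[k] else
          classes$omega_back[k]
        ck <- paste0(match(w, omegas), "_", e)
        Pe <- Pcache[[ck]]
        if (is.null(Pe)) {
          Pe <- tm_eig(eigs[[match(w, omegas)]], tvl$length[e])
          assign(ck, Pe, envir = Pcache)
        }
        P_edges[[e]] <- Pe
      }
      logL[, k] <- prune_class(pat$states, tvl, P_edges, pi_)
    }
    list(model = m, logL = logL, weights = classes$weight, scale = cs,
         lengths = tvl$length)
  }
  objective <- function(theta) {
    ev <- eval_theta(theta)
    if (is.null(ev)) return(1e10)
    ll <- sum(logsumexp_rows(ev$logL, log(pmax(ev$weights, 0)),
                             row_weights = pat$weights))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  starts <- list(spec$start)
  if (!is.null(opts$init)) {
    for (ini in opts$init) {
      th <- spec$start
      for (nm in names(ini)) {
        i <- match(nm, spec$name)
        if (is.na(i)) next
        v <- if (spec$trans[i] == "log") log(ini[[nm]]) else ini[[nm]]
        th[i] <- min(max(v, spec$lower[i]), spec$upper[i])
      }
      starts <- c(starts, list(th))
    }
  }
  n_rand <- opts$n_starts - 1L
  if (n_rand > 0L) {
    starts <- c(starts, withr::with_seed(opts$seed, {
      lapply(seq_len(n_rand), function(i) {
        jit <- stats::runif(nrow(spec), -1.5, 1.5)
        pmin(pmax(spec$start + jit, spec$lower), spec$upper)
      })
    }))
  }
  best <- NULL
  for (th in starts) {
    res <- tryCatch(
      stats::nlminb(th, objective, lower = spec$lower,
                    upper = spec$upper, control = opts$control),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed")
  ev <- eval_theta(best$par)
  tp_fit <- tp
  edge_order <- match(paste(tv$edge[, 1], tv$edge[, 2]),
                      paste(tp$tree$edge[, 1], tp$tree$edge[, 2]))
  tp_fit$tree$edge.length[edge_order] <- ev$lengths
  structure(
    list(model = ev$model, lnL = -best$objective, tree = tp_fit,
         branch_mode = opts$branch_mode,
         n_free_params = n_model_par +
           sum(startsWith(spec$name, ".")),
         converged = identical(best$convergence, 0L),
         n_starts = length(starts), seed = opts$seed,
         method = "exact", calibration = ev$scale, pi = pi_,
         message = best$message),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$model$variant, ": lnL = ",
      format(x$lnL, digits = 10), " (", x$n_free_params,
      " free params, ", if (x$converged) "converged" else
        "NOT converged", ", method = ", x$method, ")\n", sep = "")
  invisible(x)
}

# ---- curve-accelerated site-model ladder -------------------------------

# internal: fit one site-mixture variant over a precomputed curve
curve_fit_mixture <- function(curve, variant, K, kappa, opts,
                              tree, pi) {
  model <- omega_model(variant, kappa = kappa, K = K)
  spec <- model_param_spec(model, kappa_fixed = TRUE)
  objective <- function(theta) {
    m <- apply_params(model, spec, theta)
    cl <- model_class_spec(m)
    ll <- curve_mixture_loglik(curve, cl$omega_back, cl$weight)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- list(spec$start)
  if (!is.null(opts$init)) {
    for (ini in opts$init) {
      th <- spec$start
      for (nm in names(ini)) {
        i <- match(nm, spec$name)
        if (is.na(i)) next
        v <- if (spec$trans[i] == "log") log(ini[[nm]]) else ini[[nm]]
        th[i] <- min(max(v, spec$lower[i]), spec$upper[i])
      }
      starts <- c(starts, list(th))
    }
  }
  n_rand <- opts$n_starts - 1L
  if (n_rand > 0L) {
    starts <- c(starts, withr::with_seed(opts$seed + 17L, {
      lapply(seq_len(n_rand), function(i) {
        jit <- stats::runif(nrow(spec), -1.5, 1.5)
        pmin(pmax(spec$start + jit, spec$lower), spec$upper)
      })
    }))
  }
  best <- NULL
  for (th in starts) {
    res <- tryCatch(
      stats::nlminb(th, objective, lower = spec$lower,
                    upper = spec$upper, control = opts$control),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("all optimization starts failed (", variant, ")")
  m <- apply_params(model, spec, best$par)
  structure(
    list(model = m, lnL = -best$objective, tree = tree,
         branch_mode = "fixed", n_free_params = nrow(spec),
         converged = identical(best$convergence, 0L),
         n_starts = length(starts), seed = opts$seed,
         method = "curve", calibration = curve$calibration, pi = pi,
         message = best$message),
    class = "fit_result")
}

#' Fit the M0 / M7 / M8a / M8 site-model ladder
#'
#' The production fitting path: fits M0 (kappa, omega, and a rate scale
#' on the input tree's relative branch lengths), then freezes kappa,
#' branch lengths and the rate calibration at the M0 estimates and fits
#' the requested beta site-mixture models over a precomputed per-site
#' omega likelihood curve.  M8 is warm-started from the M7 and M8a
#' solutions (both lie on its parameter boundary), which guarantees the
#' nesting inequalities numerically.
#'
#' @param aln a `codon_alignment`.
#' @param tree a `tagged_phylo` or ape `phylo`.
#' @param models character vector among `"M7"`, `"M8a"`, `"M8"`.
#' @param K beta discretization categories (default 10).
#' @param opts an [fit_opts()]; `branch_mode` applies to the M0 stage.
#' @param pi codon frequencies (default F3x4).
#' @param omega_grid grid for [site_likelihood_curve()].
#' @return A `site_model_fits` list: one `fit_result` per fitted model
#'   (`$M0`, `$M7`, ...) plus `$curve`, `$kappa`, `$calibration`,
#'   `$tree` (the M0-scaled tree) and `$pi`.
#' @export
fit_site_models <- function(aln, tree, models = c("M7", "M8a", "M8"),
                            K = 10L,
                            opts = fit_opts(branch_mode = "scale",
                                            n_starts = 1L),
                            pi = codon_frequencies(aln, "F3x4"),
                            omega_grid = default_omega_grid()) {
  models <- match.arg(models, c("M7", "M8a", "M8"), several.ok = TRUE)
  m0 <- fit(aln, tree, omega_model("M0", K = K), opts, pi)
  kappa <- m0$model$kappa
  pi_ <- m0$pi
  r <- unscaled_rates(kappa, pi_, aln$code)
  c0 <- unname(r["syn"] + m0$model$omega * r["ns"])
  curve <- site_likelihood_curve(aln, m0$tree, kappa, pi_,
                                 calibration = c0,
                                 omega_grid = omega_grid)
  out <- list(M0 = m0)
  copts <- opts
  copts$n_starts <- max(opts$n_starts, 4L)
  if ("M7" %in% models) {
    out$M7 <- curve_fit_mixture(curve, "M7", K, kappa, copts,
                                m0$tree, pi_)
  }
  if ("M8a" %in% models) {
    o <- copts
    if (!is.null(out$M7)) {
      o$init <- c(o$init, list(c(beta_p = out$M7$model$beta_p,
                                 beta_q = out$M7$model$beta_q,
                                 p0 = 1)))
    }
    out$M8a <- curve_fit_mixture(curve, "M8a", K, kappa, o,
                                 m0$tree, pi_)
  }
  if ("M8" %in% models) {
    o <- copts
    warm <- list()
    if (!is.null(out$M8a)) {
      warm <- c(warm, list(c(beta_p = out$M8a$model$beta_p,
                             beta_q = out$M8a$model$beta_q,
                             p0 = out$M8a$model$p0, omega_s = 1)))
    }
    if (!is.null(out$M7)) {
      warm <- c(warm, list(c(beta_p = out$M7$model$beta_p,
                             beta_q = out$M7$model$beta_q,
                             p0 = 1, omega_s = 2)))
    }
    o$init <- c(o$init, warm)
    out$M8 <- curve_fit_mixture(curve, "M8", K, kappa, o, m0$tree, pi_)
    # the nested solutions sit on M8's boundary; never report worse
    for (nested in c("M8a", "M7")) {
      if (!is.null(out[[nested]]) &&
          out$M8$lnL < out[[nested]]$lnL) {
        refit <- out[[nested]]$model
        m8m <- omega_model("M8", kappa = kappa,
                           beta_p = refit$beta_p, beta_q = refit$beta_q,
                           p0 = if (is.null(refit$p0)) 1 else refit$p0,
                           omega_s = 1, K = K)
        cl <- model_class_spec(m8m)
        ll <- curve_mixture_loglik(curve, cl$omega_back, cl$weight)
        if (ll > out$M8$lnL) {
          out$M8$model <- m8m
          out$M8$lnL <- ll
        }
      }
    }
  }
  structure(c(out, list(curve = curve, kappa = kappa, calibration = c0,
                        tree = m0$tree, pi = pi_)),
            class = "site_model_fits")
}

#' Fit the branch-model battery (M0, two-ratio, branch-site A)
#'
#' Fits M0 with a rate scale, then the two-ratio model and the revised
#' branch-site model A with its null (omega2 = 1) on the M0-fitted
#' branch lengths, with kappa frozen at the M0 estimate and each
#' alternative warm-started from its null.
#'
#' @param aln a `codon_alignment`.
#' @param tree a `tagged_phylo` with at least one foreground branch.
#' @param opts an [fit_opts()].
#' @param pi codon frequencies.
#' @param models subset of `c("TwoRatio", "BranchSiteA")`.
#' @return list of `fit_result`s: `$M0`, `$TwoRatio`,
#'   `$BranchSiteA_null`, `$BranchSiteA` (as requested).
#' @export
fit_branch_models <- function(aln, tree,
                              models = c("TwoRatio", "BranchSiteA"),
                              opts = fit_opts(branch_mode = "scale",
                                              n_starts = 2L),
                              pi = codon_frequencies(aln, "F3x4")) {
  models <- match.arg(models, c("TwoRatio", "BranchSiteA"),
                      several.ok = TRUE)
  tp <- as_tagged_phylo(tree)
  if (!any(tp$fore)) stop("branch models need a foreground branch")
  m0 <- fit(aln, tp, omega_model("M0"), opts, pi)
  kappa <- m0$model$kappa
  r <- unscaled_rates(kappa, m0$pi, aln$code)
  c0 <- unname(r["syn"] + m0$model$omega * r["ns"])
  fixed <- opts
  fixed$branch_mode <- "fixed"
  fixed$kappa <- kappa
  fixed$calibration <- c0
  out <- list(M0 = m0)
  if ("TwoRatio" %in% models) {
    fx <- fixed
    fx$init <- list(c(omega_back = m0$model$omega,
                      omega_fore = m0$model$omega))
    out$TwoRatio <- fit(aln, m0$tree,
                        omega_model("TwoRatio",
                                    omega_fore = m0$model$omega,
                                    omega_back = m0$model$omega),
                        fx, pi)
    if (out$TwoRatio$lnL < m0$lnL) {  # boundary guard (M0 is nested)
      out$TwoRatio$model$omega_back <- m0$model$omega
      out$TwoRatio$model$omega_fore <- m0$model$omega
      out$TwoRatio$lnL <- m0$lnL
    }
  }
  if ("BranchSiteA" %in% models) {
    w0 <- min(max(m0$model$omega, 1e-4), 0.9)
    null_model <- omega_model("BranchSiteA_null", p0 = 0.8, p1 = 0.1,
                              omega0 = w0)
    out$BranchSiteA_null <- fit(aln, m0$tree, null_model, fixed, pi)
    fa <- fixed
    nm <- out$BranchSiteA_null$model
    fa$init <- list(c(prop_total = nm$p0 + nm$p1,
                      prop_split = nm$p0 / (nm$p0 + nm$p1),
                      omega0 = nm$omega0, omega2 = 1))
    out$BranchSiteA <- fit(aln, m0$tree,
                           omega_model("BranchSiteA", p0 = nm$p0,
                                       p1 = nm$p1, omega0 = nm$omega0,
                                       omega2 = 2),
                           fa, pi)
    if (out$BranchSiteA$lnL < out$BranchSiteA_null$lnL) {
      out$BranchSiteA$model <- nm
      out$BranchSiteA$model$variant <- "BranchSiteA"
      out$BranchSiteA$model$omega2 <- 1
      out$BranchSiteA$lnL <- out$BranchSiteA_null$lnL
    }
  }
  out
}
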