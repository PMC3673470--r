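# The conservation machinery: posterior-weighted mean omega per site,
# the conservation index (1 - omega for purifying sites, zero for
# neutral/positive sites), and the minimum-omega significance category
# obtained by accumulating posterior probability from the lowest omega
# class upward until it exceeds a threshold.

#' Posterior-weighted mean omega per site
#'
#' @param post a [site_class_posteriors()] result.
#' @return numeric vector, one weighted mean omega per site
#'   (`sum_k PP_k * omega_k`).
#' @export
weighted_mean_omega <- function(post) {
  stopifnot(inherits(post, "site_posteriors"))
  as.numeric(post$PP %*% post$class_omegas)
}

#' Conservation index from mean omega
#'
#' `1 - omega_bar` for sites under purifying selection
#' (`omega_bar < 1`), and zero for neutral or positively selected sites
#' (`omega_bar >= 1`), yielding a continuous 0-1 spectrum of
#' weak-to-strong purifying selection.
#'
#' @param omega_bar per-site weighted mean omega (non-negative).
#' @return numeric vector of conservation indices in `[0, 1]`.
#' @examples
#' conservation_index(c(0.1, 1.476, 1, 0))  # 0.9 0 0 1
#' @export
conservation_index <- function(omega_bar) {
  if (any(omega_bar < 0, na.rm = TRUE)) {
    stop("negative mean omega: upstream invariant breached")
  }
  ifelse(omega_bar < 1, 1 - omega_bar, 0)
}

#' Minimum-omega significance category per site
#'
#' Accumulates posterior probability from the lowest omega class upward;
#' the first class at which the cumulative probability exceeds
#' `pp_threshold` is the site's minimum-omega category.  If the
#' threshold is never exceeded earlier, the final class is used.  A site
#' is flagged as significantly purifying when its category omega is
#' below `low_omega`.
#'
#' @param post a [site_class_posteriors()] result with classes ordered
#'   by increasing omega.
#' @param pp_threshold posterior-probability threshold (default 0.95).
#' @param low_omega omega cutoff defining "low omega" categories
#'   (default 0.25).
#' @return data frame with `min_omega_class` (1-based class index),
#'   `min_omega_value`, `significant_purifying` per site.
#' @export
min_omega_category <- function(post, pp_threshold = 0.95,
                               low_omega = 0.25) {
  stopifnot(inherits(post, "site_posteriors"))
  om <- post$class_omegas
  if (is.unsorted(om, strictly = FALSE)) {
    stop("classes must be ordered by increasing omega")
  }
  cum <- t(apply(post$PP, 1, cumsum))
  if (ncol(post$PP) == 1L) cum <- matrix(cum, ncol = 1L)
  K <- length(om)
  cls <- apply(cum > pp_threshold, 1, function(z) {
    i <- which(z)
    if (length(i)) i[1] else K
  })
  data.frame(min_omega_class = cls,
             min_omega_value = om[cls],
             significant_purifying = om[cls] < low_omega)
}

#' Per-site conservation profile
#'
#' Combines the posterior summaries into the per-site profile used for
#' disease-mutation mapping: weighted mean omega, conservation index,
#' minimum-omega category, and the mapping between alignment columns and
#' the reference sequence's 1-based protein coordinates (columns where
#' the reference carries a gap get no reference position).
#'
#' @param post a [site_class_posteriors()] result.
#' @param aln the `codon_alignment` the posteriors were computed from;
#'   its `reference` taxon (if set) drives the coordinate mapping.
#' @param pp_threshold,low_omega see [min_omega_category()].
#' @return A `conservation_profile` data frame: `alignment_column`,
#'   `reference_position`, `omega_bar`, `ci`, `min_omega_class`,
#'   `min_omega_value`, `significant_purifying`.
#' @export
conservation_profile <- function(post, aln, pp_threshold = 0.95,
                                 low_omega = 0.25) {
  ob <- weighted_mean_omega(post)
  ci <- conservation_index(ob)
  mc <- min_omega_category(post, pp_threshold, low_omega)
  ref_pos <- rep(NA_integer_, length(ob))
  if (!is.null(aln$reference)) {
    res <- reference_residue_columns(aln)
    ref_pos[res] <- seq_along(res)
  }
  out <- data.frame(alignment_column = seq_along(ob),
                    reference_position = ref_pos,
                    omega_bar = ob, ci = ci,
                    min_omega_class = mc$min_omega_class,
                    min_omega_value = mc$min_omega_value,
                    significant_purifying = mc$significant_purifying)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

# internal: alignment columns holding a residue (no gap character) of
# the reference sequence, in order; their ranks are the 1-based protein
# coordinates of the ungapped reference.
reference_residue_columns <- function(aln) {
  if (is.null(aln$reference)) stop("alignment has no reference taxon")
  trip <- aln$codons[aln$reference, ]
  which(!grepl("-", trip, fixed = TRUE))
}
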