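# Likelihood-ratio tests between nested model variants.  Degrees of
# freedom are fixed by the variant pair: M7 vs M8 compares chi-square
# with 2 df (M8 adds p_s and omega_s); M8a vs M8, the branch-site A null
# vs alternative, and M0 vs the two-ratio model each use 1 df.

NESTED_PAIRS <- data.frame(
  null = c("M7", "M8a", "BranchSiteA_null", "M0"),
  alt = c("M8", "M8", "BranchSiteA", "TwoRatio"),
  df = c(2L, 1L, 1L, 1L))

#' Likelihood-ratio test of nested codon models
#'
#' @param null_fit,alt_fit `fit_result`s of a nested variant pair
#'   (M7 vs M8; M8a vs M8; branch-site A null vs alternative; M0 vs
#'   two-ratio), fitted to the same data.
#' @param boundary_mix if `TRUE`, use the 50:50 mixture of chi-square
#'   with 0 and 1 df appropriate for a boundary null, instead of the
#'   default plain chi-square reference (only meaningful for 1-df
#'   boundary tests; off by default).
#' @return An `lrt_result`: list with `test_name`, `stat`
#'   (`max(0, 2 * (lnL_alt - lnL_null))`), `df`, `p_raw`.
#' @examples
#' # stat at the 5% chi-square(1) critical value
#' # lrt of fits with 2*(lnL_alt-lnL_null) = 3.841459 gives p ~ 0.05
#' @export
lrt <- function(null_fit, alt_fit, boundary_mix = FALSE) {
  stopifnot(inherits(null_fit, "fit_result"),
            inherits(alt_fit, "fit_result"))
  vn <- null_fit$model$variant
  va <- alt_fit$model$variant
  hit <- which(NESTED_PAIRS$null == vn & NESTED_PAIRS$alt == va)
  if (length(hit) != 1L) {
    stop("'", vn, "' is not a supported nested null of '", va, "'")
  }
  df <- NESTED_PAIRS$df[hit]
  stat <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  p <- if (boundary_mix && df == 1L) {
    if (stat <= 0) 1 else
      0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  structure(
    list(test_name = paste0(vn, "_vs_", va), stat = stat, df = df,
         p_raw = p, boundary_mix = boundary_mix),
    class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("<lrt_result> ", x$test_name, ": 2*dlnL = ",
      format(x$stat, digits = 6), ", df = ", x$df, ", p = ",
      format(x$p_raw, digits = 4), "\n", sep = "")
  invisible(x)
}
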