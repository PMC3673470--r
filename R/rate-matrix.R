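# Goldman-Yang-style codon rate matrices.  Instantaneous rates are zero for
# codon pairs differing at more than one nucleotide; single-step rates are
# proportional to the target codon's equilibrium frequency, multiplied by
# kappa for transitions and omega for nonsynonymous changes.

# Cache of the codon-pair classification (single-step / transition /
# synonymous masks) for the standard code; built once per session.
.codonsel_cache <- new.env(parent = emptyenv())

codon_pair_structure <- function(code = standard_genetic_code()) {
  key <- paste(code$sense_codons, collapse = "")
  hit <- .codonsel_cache[[key]]
  if (!is.null(hit)) return(hit)
  sense <- code$sense_codons
  n <- length(sense)
  b <- lapply(1:3, function(p) substring(sense, p, p))
  diff_p <- lapply(1:3, function(p) outer(b[[p]], b[[p]], "!="))
  ndiff <- diff_p[[1]] + diff_p[[2]] + diff_p[[3]]
  single <- ndiff == 1L
  is_ts_pair <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    m <- outer(b[[p]], b[[p]], is_ts_pair)
    ts <- ts | (m & diff_p[[p]] &
                (ndiff == 1L))
  }
  aa <- code$sense_aa
  nonsyn <- outer(aa, aa, "!=")
  out <- list(single = single, ts = ts & single, nonsyn = nonsyn & single)
  assign(key, out, envir = .codonsel_cache)
  out
}

# internal: unscaled off-diagonal factor matrices, so that
# Q_offdiag = (syn_part + omega * nonsyn_part) with pi columns included.
# Returns list(base_syn, base_ns): 61x61 matrices.
q_parts <- function(kappa, pi, code = standard_genetic_code()) {
  st <- codon_pair_structure(code)
  fac <- matrix(0, length(pi), length(pi))
  fac[st$single] <- 1
  fac[st$ts] <- kappa
  fac <- sweep(fac, 2, pi, "*")
  list(syn = fac * !st$nonsyn, ns = fac * st$nonsyn)
}

# internal: expected rates (substitutions per codon per unit time) of the
# unscaled matrix, split into synonymous and nonsynonymous parts, so the
# rate at any omega is rate_syn + omega * rate_ns.
unscaled_rates <- function(kappa, pi, code = standard_genetic_code()) {
  parts <- q_parts(kappa, pi, code)
  c(syn = sum(pi * rowSums(parts$syn)),
    ns = sum(pi * rowSums(parts$ns)))
}

#' Build a codon substitution rate matrix
#'
#' Constructs the 61x61 instantaneous rate matrix of a Goldman-Yang-style
#' codon model for one omega class: off-diagonal entries are zero for
#' multi-nucleotide changes and otherwise proportional to the target
#' codon's frequency, times `kappa` for transitions and `omega` for
#' nonsynonymous changes.  The matrix is time-reversible with respect to
#' `pi` and, when `scale = TRUE`, normalized so the expected rate
#' \eqn{-\sum_i \pi_i q_{ii}} is one substitution per codon per unit
#' branch length.  Mixture models rescale all their class matrices by a
#' single shared factor instead (see the methods vignette).
#'
#' @param kappa transition/transversion rate ratio, > 0.
#' @param omega nonsynonymous/synonymous rate ratio, >= 0.
#' @param pi `codon_frequencies` or length-61 numeric vector.  Zero
#'   entries are floored at 1e-12 and renormalized so the reversible
#'   symmetrization is defined.
#' @param code genetic code.
#' @param scale if `TRUE` (default) normalize to unit expected rate; if a
#'   positive number, divide rates by it (used for shared mixture-level
#'   scaling); if `FALSE`, leave unscaled.
#' @return A `rate_matrix` object: list with `Q`, `kappa`, `omega`, `pi`,
#'   and the symmetric eigendecomposition used by [transition_matrix()].
#' @examples
#' Q <- build_rate_matrix(2, 0.5, codon_frequencies(mode = "uniform"))
#' max(abs(rowSums(Q$Q)))  # ~0
#' @export
build_rate_matrix <- function(kappa, omega, pi,
                              code = standard_genetic_code(),
                              scale = TRUE) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("kappa must be a single positive number")
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0) {
    stop("omega must be a single non-negative number")
  }
  pi <- as_pi(pi)
  pi <- pmax(pi, 1e-12)
  pi <- pi / sum(pi)
  parts <- q_parts(kappa, pi, code)
  Q <- parts$syn + omega * parts$ns
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (isTRUE(scale)) {
    if (rate > 0) Q <- Q / rate
  } else if (is.numeric(scale)) {
    if (scale <= 0) stop("numeric scale must be positive")
    Q <- Q / scale
  }
  eig <- rev_eigen(Q, pi)
  structure(
    list(Q = Q, kappa = kappa, omega = omega, pi = pi,
         unscaled_rate = rate, eig = eig),
    class = "rate_matrix")
}

# internal: eigendecomposition of a pi-reversible Q via the similarity
# transform B = D^{1/2} Q D^{-1/2} (symmetric); P(t) recovers as
# D^{-1/2} U exp(L t) U' D^{1/2}.
rev_eigen <- function(Q, pi) {
  s <- sqrt(pi)
  B <- Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors / s,      # D^{-1/2} U  (rows scaled)
       right = t(e$vectors * s))  # U' D^{1/2}
}

# internal fast path: P(t) from a cached decomposition, no validation
tm_eig <- function(eig, t) {
  P <- (eig$left * rep(exp(eig$values * t), each = nrow(eig$left))) %*%
    eig$right
  P[P < 0] <- 0
  P
}

#' Codon transition probability matrix
#'
#' Computes `P(t) = exp(Qt)` for a [build_rate_matrix()] object via the
#' symmetric eigendecomposition of the reversible generator.  Tiny
#' negative entries from round-off are clipped to zero.
#'
#' @param Q a `rate_matrix`.
#' @param t branch length, >= 0 (expected substitutions per codon under
#'   the matrix's scaling).
#' @return 61x61 row-stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (!inherits(Q, "rate_matrix")) stop("Q must be a rate_matrix")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("branch length t must be a single non-negative number")
  }
  P <- tm_eig(Q$eig, t)
  if (anyNA(P)) {  # numerical failure: scaling-and-squaring fallback
    P <- expm_ss(Q$Q, t)
    P[P < 0] <- 0
  }
  dimnames(P) <- dimnames(Q$Q)
  P
}

# internal: scaling-and-squaring matrix exponential (Taylor + squaring),
# fallback when the eigendecomposition misbehaves.
expm_ss <- function(Q, t) {
  A <- Q * t
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1, max(abs(A))))) + 4L)
  A <- A / 2^s
  P <- diag(n)
  term <- diag(n)
  for (k in 1:16) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("<rate_matrix> kappa = ", format(x$kappa, digits = 4),
      ", omega = ", format(x$omega, digits = 4),
      ", expected rate = ", format(-sum(x$pi * diag(x$Q)), digits = 4),
      "\n", sep = "")
  invisible(x)
}
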