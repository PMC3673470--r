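# Codon state space.  All matrices in the package index sense codons in the
# fixed lexicographic order over the base alphabet T, C, A, G (TTT, TTC,
# TTA, TTG, TCT, ... GGG minus stops), the dominant convention of codon-model
# software.  The standard code has 61 sense codons and 3 stops.

#' Genetic code table
#'
#' Builds a genetic code object: the 64-triplet translation table and the
#' ordered list of sense (non-stop) codons that defines the codon state
#' indexing used by every matrix in the package.
#'
#' @param aa a 64-character string of amino-acid symbols (`*` for stop) in
#'   T,C,A,G lexicographic codon order.  The default is the standard code.
#' @return An object of class `genetic_code`: a list with `table` (named
#'   character vector over all 64 codons), `sense_codons` (ordered character
#'   vector, length 61 for the standard code), `stop_codons`, and
#'   `sense_aa` (amino acid per sense codon).
#' @examples
#' gc <- standard_genetic_code()
#' length(gc$sense_codons)  # 61
#' gc$table[["ATG"]]        # "M"
#' @export
standard_genetic_code <- function(aa = NULL) {
  bases <- c("T", "C", "A", "G")
  # order is b1 slowest, b3 fastest: TTT TTC TTA TTG TCT ...
  codons <- paste0(rep(bases, each = 16), rep(rep(bases, each = 4), 4),
                   rep(bases, 16))
  if (is.null(aa)) {
    aa <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  }
  aa <- strsplit(aa, "")[[1]]
  if (length(aa) != 64L) stop("genetic code must define all 64 triplets")
  table <- stats::setNames(aa, codons)
  sense <- codons[aa != "*"]
  structure(
    list(table = table,
         sense_codons = sense,
         stop_codons = codons[aa == "*"],
         sense_aa = stats::setNames(aa[aa != "*"], sense)),
    class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> ", length(x$sense_codons), " sense codons, ",
      length(x$stop_codons), " stops (",
      paste(x$stop_codons, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Translate codon triplets to amino-acid symbols
#'
#' @param codons character vector of triplets (ACGT alphabet, T for U).
#' @param code a [standard_genetic_code()] object.
#' @return character vector of one-letter amino-acid symbols (`*` = stop,
#'   `NA` for triplets containing non-ACGT characters).
#' @export
translate_codons <- function(codons, code = standard_genetic_code()) {
  out <- unname(code$table[toupper(codons)])
  out
}

# internal: map triplets to sense-codon state indices (NA = missing/ambiguous)
codon_states <- function(codons, code) {
  match(toupper(codons), code$sense_codons)
}
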