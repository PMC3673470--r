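# Codon alignments: taxa x codon-site matrices over the 61 sense-codon
# states, with NA marking missing/ambiguous/gap triplets.  The original
# triplet characters are kept alongside the state matrix so that writing
# FASTA round-trips exactly and reference-coordinate mapping can see gaps.

new_codon_alignment <- function(taxa, states, codons, code,
                                reference = NULL) {
  rownames(states) <- taxa
  rownames(codons) <- taxa
  structure(
    list(taxa = taxa, states = states, codons = codons,
         n_sites = ncol(states), reference = reference, code = code),
    class = "codon_alignment")
}

#' Read an in-frame codon alignment from FASTA
#'
#' Sequences are validated to be in reading frame (length a multiple of
#' three) and free of stop codons; any triplet containing a gap or non-ACGT
#' character becomes a missing state, which the likelihood machinery
#' marginalizes over.  Taxon names are the FASTA descriptions up to the
#' first whitespace.
#'
#' @param input path to a FASTA file, or a character vector holding FASTA
#'   text (detected by the presence of a `>` header).
#' @param code genetic code, see [standard_genetic_code()].
#' @param reference optional taxon name used later for protein-coordinate
#'   mapping; must be present in the alignment.
#' @return A `codon_alignment`: list with `taxa`, `states` (taxa x sites
#'   integer matrix of sense-codon indices, NA = missing), `codons`
#'   (character matrix of the original triplets), `n_sites`, `reference`,
#'   `code`.
#' @examples
#' aln <- read_codon_alignment(c(">a", "ATGAAA", ">b", "ATGAAG"))
#' aln$n_sites  # 2
#' @export
read_codon_alignment <- function(input, code = standard_genetic_code(),
                                 reference = NULL) {
  if (length(input) > 1L || grepl(">", input[1], fixed = TRUE)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(input, path)
  } else {
    path <- input
    if (!file.exists(path)) stop("alignment file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  taxa <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon name(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  lens <- nchar(seqs)
  bad <- lens %% 3L != 0L
  if (any(bad)) {
    stop("sequence length not a multiple of 3 (out of frame) for: ",
         paste(taxa[bad], collapse = ", "))
  }
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have equal length")
  }
  n_sites <- lens[1] %/% 3L
  codons <- matrix("", nrow = length(taxa), ncol = n_sites)
  for (i in seq_along(taxa)) {
    codons[i, ] <- substring(seqs[i], 3L * seq_len(n_sites) - 2L,
                             3L * seq_len(n_sites))
  }
  states <- matrix(codon_states(codons, code),
                   nrow = length(taxa), ncol = n_sites)
  # stop codons: clean ACGT triplets translating to '*' are rejected
  is_stop <- matrix(codons %in% code$stop_codons,
                    nrow = length(taxa), ncol = n_sites)
  if (any(is_stop)) {
    w <- which(is_stop, arr.ind = TRUE)[1, ]
    stop("stop codon (", codons[w[1], w[2]], ") in taxon '", taxa[w[1]],
         "' at codon site ", w[2],
         ": nonsense codons are not permitted in a coding alignment")
  }
  if (!is.null(reference) && !reference %in% taxa) {
    stop("reference taxon '", reference, "' not found in alignment")
  }
  new_codon_alignment(taxa, states, codons, code, reference)
}

#' Write a codon alignment to FASTA
#'
#' Writes the original triplets (including gap/ambiguity characters), so
#' that read/write round-trips are exact.
#'
#' @param aln a `codon_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- apply(aln$codons, 1, paste0, collapse = "")
  set <- Biostrings::BStringSet(stats::setNames(seqs, aln$taxa))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$taxa), " taxa x ", x$n_sites,
      " codon sites; ", sum(is.na(x$states)), " missing triplet(s)",
      if (!is.null(x$reference)) paste0("; reference: ", x$reference),
      "\n", sep = "")
  invisible(x)
}

#' Codon equilibrium frequencies
#'
#' Estimates the stationary sense-codon distribution pi used by the
#' substitution model: `uniform` (1/61 each), `F3x4` (product of
#' position-specific nucleotide frequencies renormalized over sense
#' codons, the common default of codon-model software), or `F61`
#' (observed sense-codon proportions with a pseudocount).
#'
#' @param aln a `codon_alignment` (only required for the empirical modes).
#' @param mode `"F3x4"`, `"uniform"`, or `"F61"`.
#' @param pseudocount added to each sense-codon count in F61 mode
#'   (default 0.5) so unseen codons keep positive mass.
#' @return A `codon_frequencies` object: list with `pi` (length-61 named
#'   numeric summing to one) and `mode`.
#' @export
codon_frequencies <- function(aln = NULL,
                              mode = c("F3x4", "uniform", "F61"),
                              pseudocount = 0.5) {
  mode <- match.arg(mode)
  code <- if (is.null(aln)) standard_genetic_code() else aln$code
  sense <- code$sense_codons
  if (mode == "uniform") {
    pi <- stats::setNames(rep(1 / length(sense), length(sense)), sense)
    return(structure(list(pi = pi, mode = mode),
                     class = "codon_frequencies"))
  }
  if (is.null(aln) || length(aln$taxa) == 0L || aln$n_sites == 0L) {
    stop("empirical frequency mode '", mode,
         "' requires a non-empty alignment")
  }
  obs <- aln$codons[!is.na(aln$states)]  # clean sense triplets only
  if (mode == "F61") {
    counts <- table(factor(obs, levels = sense)) + pseudocount
    pi <- as.numeric(counts) / sum(counts)
  } else {  # F3x4
    nt <- c("T", "C", "A", "G")
    fpos <- sapply(1:3, function(p) {
      tab <- table(factor(substring(obs, p, p), levels = nt))
      as.numeric(tab) / sum(tab)
    })  # 4 x 3
    rownames(fpos) <- nt
    w <- fpos[substring(sense, 1, 1), 1] *
         fpos[substring(sense, 2, 2), 2] *
         fpos[substring(sense, 3, 3), 3]
    pi <- w / sum(w)
  }
  structure(list(pi = stats::setNames(pi, sense), mode = mode),
            class = "codon_frequencies")
}

#' @export
print.codon_frequencies <- function(x, ...) {
  cat("<codon_frequencies> mode = ", x$mode, ", ",
      sum(x$pi > 0), "/", length(x$pi), " codons with positive mass\n",
      sep = "")
  invisible(x)
}

# internal: coerce a codon_frequencies or bare numeric vector to pi
as_pi <- function(pi, n = 61L) {
  if (inherits(pi, "codon_frequencies")) pi <- pi$pi
  if (length(pi) != n) stop("pi must have ", n, " entries")
  if (any(pi < 0)) stop("pi entries must be non-negative")
  pi / sum(pi)
}
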