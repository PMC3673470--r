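# Disease-associated mutation (DAM) handling: reading variant tables
# keyed to a reference protein's 1-based coordinates, mapping them
# through reference gaps onto alignment columns, attaching conservation
# values, and summarizing the overlap between disease sites and highly
# conserved sites.

#' Read a disease-associated mutation table
#'
#' Tab-separated input with columns `gene`, `protein_position`,
#' `ref_aa`, `alt_aa`, `source_id`, and optionally `external_score` (a
#' pass-through classifier score in `[0, 1]`, e.g. an ingested
#' PolyPhen-2 value).  Lines beginning with `#` are ignored.
#'
#' @param path TSV file path.
#' @return data frame of DAM records.
#' @examples
#' example <- system.file("extdata", "example_dams_synthetic.tsv",
#'                        package = "codonsel")
#' read_dam_table(example)
#' @export
read_dam_table <- function(path) {
  if (!file.exists(path)) stop("DAM table not found: ", path)
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("gene", "protein_position", "ref_aa", "alt_aa", "source_id")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("DAM table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!"external_score" %in% names(d)) d$external_score <- NA_real_
  if (any(d$protein_position < 1)) {
    stop("protein_position must be >= 1")
  }
  if (any(d$ref_aa == d$alt_aa)) {
    stop("ref_aa and alt_aa must differ (missense records only)")
  }
  d
}

#' Map disease mutations onto alignment columns and conservation values
#'
#' Maps each record's 1-based protein coordinate in the ungapped
#' reference sequence through the reference's alignment gaps to its
#' alignment column, then copies the conservation values from the
#' profile.  Records whose position exceeds the reference length are
#' skipped with a warning.  The stated reference amino acid is compared
#' with the translated reference codon; mismatches are flagged
#' (`ref_aa_match = FALSE`) but kept, since variant tables are commonly
#' keyed to a different isoform or assembly than the alignment.
#'
#' @param dams DAM data frame (see [read_dam_table()]).
#' @param aln `codon_alignment` with a `reference` taxon.
#' @param profile a [conservation_profile()] for the same alignment.
#' @return the DAM table with `mapped_column`, `mapped_ci`,
#'   `mapped_omega_bar`, `min_omega_class`, `significant_purifying`,
#'   `ref_aa_match` columns added (skipped records dropped).
#' @export
map_dams <- function(dams, aln, profile) {
  if (is.null(aln$reference)) {
    stop("alignment has no designated reference taxon")
  }
  res_cols <- reference_residue_columns(aln)
  n_res <- length(res_cols)
  keep <- dams$protein_position <= n_res
  if (any(!keep)) {
    warning(sum(!keep), " DAM record(s) beyond the reference length (",
            n_res, " residues) skipped: ",
            paste(dams$source_id[!keep], collapse = ", "))
  }
  d <- dams[keep, , drop = FALSE]
  d$mapped_column <- res_cols[d$protein_position]
  d$mapped_ci <- profile$ci[d$mapped_column]
  d$mapped_omega_bar <- profile$omega_bar[d$mapped_column]
  d$min_omega_class <- profile$min_omega_class[d$mapped_column]
  d$significant_purifying <-
    profile$significant_purifying[d$mapped_column]
  ref_codons <- aln$codons[aln$reference, d$mapped_column]
  ref_trans <- translate_codons(ref_codons, aln$code)
  d$ref_aa_match <- !is.na(ref_trans) & ref_trans == d$ref_aa
  rownames(d) <- NULL
  d
}

#' Summarize disease-mutation overlap with conserved sites
#'
#' Counts mapped disease mutations at or above a conservation-index
#' threshold, overall and per gene.
#'
#' @param mapped output of [map_dams()] (possibly several genes bound
#'   together).
#' @param ci_threshold conservation-index cutoff (default 0.9).
#' @return list with `overall` (one-row data frame: `n`,
#'   `n_ci_at_or_above`, `n_below`, `prop_at_or_above`) and `per_gene`
#'   (same columns by gene).
#' @export
dam_overlap_summary <- function(mapped, ci_threshold = 0.9) {
  summarize <- function(d) {
    n <- nrow(d)
    hi <- sum(d$mapped_ci >= ci_threshold)
    data.frame(n = n, n_ci_at_or_above = hi, n_below = n - hi,
               prop_at_or_above = if (n > 0) hi / n else NA_real_)
  }
  if (nrow(mapped) == 0L) {
    return(list(overall = summarize(mapped),
                per_gene = cbind(data.frame(gene = character()),
                                 summarize(mapped)[0, ]),
                ci_threshold = ci_threshold))
  }
  per_gene <- do.call(rbind, lapply(split(mapped, mapped$gene),
                                    summarize))
  per_gene <- cbind(data.frame(gene = rownames(per_gene)), per_gene)
  rownames(per_gene) <- NULL
  list(overall = summarize(mapped), per_gene = per_gene,
       ci_threshold = ci_threshold)
}
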