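# Multiple-testing correction over hypothesis families.  Related tests
# on the same data set are grouped into named families and the
# Benjamini-Hochberg step-up false-discovery-rate adjustment (default;
# Holm step-down available) is applied independently within each family.
# Families may share member tests.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, multiply the i-th smallest
#' p-value by m/i, enforce monotonicity from the largest rank downward,
#' cap at one, and return in the original order.
#'
#' @param p_raw numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted p-values, same order as the input.
#' @examples
#' bh_fdr(c(0.034, 0.009))  # 0.034 0.018
#' @export
bh_fdr <- function(p_raw) {
  if (!is.numeric(p_raw)) stop("p-values must be numeric")
  if (length(p_raw) && (anyNA(p_raw) || any(p_raw < 0 | p_raw > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' Adjust p-values within a hypothesis family
#'
#' @param p_raw numeric vector of p-values.
#' @param method `"BH"` (Benjamini-Hochberg step-up, default) or
#'   `"Holm"` (step-down).
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p_raw, method = c("BH", "Holm")) {
  method <- match.arg(method)
  if (length(p_raw) && (anyNA(p_raw) || any(p_raw < 0 | p_raw > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  switch(method,
         BH = stats::p.adjust(p_raw, method = "BH"),
         Holm = stats::p.adjust(p_raw, method = "holm"))
}

#' Enumerate hypothesis families from a study manifest
#'
#' Expands the manifest's family definitions into `hypothesis_family`
#' objects, checking that every family member refers to a test declared
#' for its data set.  The global test list enumerates every
#' (data set, test) pair exactly once; families may overlap.
#'
#' @param manifest a study manifest (see [read_study_manifest()] /
#'   [nshl_study_design()]): a list with `datasets` (each with `id` and
#'   `tests`) and `families` (named list of member lists, each member a
#'   `c(dataset, test)` pair).
#' @return list with `families` (list of `hypothesis_family`: family_id,
#'   `members` data frame with dataset/test columns, `p_raw`, `p_adj`
#'   slots), `tests` (data frame of all distinct (dataset, test) pairs),
#'   `family_sizes` (named integer vector).
#' @export
build_test_families <- function(manifest) {
  ds <- manifest$datasets
  if (is.null(ds) || length(ds) == 0L) {
    return(list(families = list(),
                tests = data.frame(dataset = character(),
                                   test = character()),
                family_sizes = integer()))
  }
  declared <- do.call(rbind, lapply(ds, function(d) {
    if (is.null(d$id) || is.null(d$tests)) {
      stop("each dataset needs 'id' and 'tests' entries")
    }
    data.frame(dataset = d$id, test = unlist(d$tests),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(declared)) {
    stop("duplicate (dataset, test) declaration in manifest")
  }
  fams <- manifest$families
  out <- lapply(names(fams), function(fid) {
    mem <- do.call(rbind, lapply(fams[[fid]], function(m) {
      m <- unlist(m)
      if (length(m) != 2L) {
        stop("family '", fid, "' member must be a (dataset, test) pair")
      }
      data.frame(dataset = m[1], test = m[2], stringsAsFactors = FALSE)
    }))
    ok <- paste(mem$dataset, mem$test) %in%
      paste(declared$dataset, declared$test)
    if (!all(ok)) {
      stop("family '", fid, "' references undeclared test(s): ",
           paste(paste(mem$dataset[!ok], mem$test[!ok]), collapse = "; "))
    }
    structure(list(family_id = fid, members = mem,
                   p_raw = rep(NA_real_, nrow(mem)),
                   p_adj = rep(NA_real_, nrow(mem))),
              class = "hypothesis_family")
  })
  names(out) <- names(fams)
  list(families = out, tests = declared,
       family_sizes = vapply(out, function(f) nrow(f$members), 1L))
}

#' @export
print.hypothesis_family <- function(x, ...) {
  cat("<hypothesis_family> ", x$family_id, ": ", nrow(x$members),
      " member test(s)\n", sep = "")
  invisible(x)
}
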