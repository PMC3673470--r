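# Study manifests: a single structured YAML document describing data
# sets (alignment/tree paths, reference taxon, foreground clade, tests),
# hypothesis families, thresholds and correction method.  The manifest
# is echoed verbatim into every output bundle for provenance.

#' Read and validate a study manifest
#'
#' @param path YAML file path.
#' @return validated manifest list.
#' @export
read_study_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  validate_manifest(m)
}

#' Validate a study manifest
#'
#' Checks required keys, threshold ranges, and that family members
#' resolve to declared tests (via [build_test_families()]).
#'
#' @param m manifest list.
#' @return the manifest, invisibly on success.
#' @export
validate_manifest <- function(m) {
  miss <- setdiff(c("datasets", "families"), names(m))
  if (length(miss)) {
    stop("manifest lacks key(s): ", paste(miss, collapse = ", "))
  }
  for (d in m$datasets) {
    dmiss <- setdiff(c("id", "tests"), names(d))
    if (length(dmiss)) {
      stop("dataset entry lacks key(s): ",
           paste(dmiss, collapse = ", "))
    }
  }
  th <- m$thresholds
  if (!is.null(th)) {
    for (k in intersect(names(th),
                        c("pp_threshold", "low_omega", "ci_threshold"))) {
      if (th[[k]] <= 0 || th[[k]] >= 1) {
        stop("threshold '", k, "' must lie in (0, 1)")
      }
    }
  }
  if (!is.null(m$correction) &&
      !m$correction %in% c("BH", "Holm")) {
    stop("correction must be 'BH' or 'Holm'")
  }
  build_test_families(m)  # validates family membership
  invisible(m)
}

#' Deafness-gene study design (13 families, 50 tests)
#'
#' The multi-gene hypothesis-test design used for nonsyndromic
#' hearing-loss gene panels: 19 site-model data sets each with the
#' M7-vs-M8 and M8-vs-M8a tests (38 site tests), plus three tetrapod
#' and three bat Tecta regions each carrying a branch-site and a
#' two-ratio test (6 + 6 branch tests), grouped into 13 hypothesis
#' families: one per single-gene data set (A-I), one for the longest
#' Myo15 region (J), one for the Tecta mammal analyses (K, 14 tests),
#' one for the Tecta bat analyses (L, 12 tests), and one comparing the
#' three Myo15 regions with one another (M, 6 tests, overlapping J).
#' This is a design skeleton (ids, tests, families) for enumeration and
#' FDR bookkeeping; attach alignment/tree paths to fit real data.
#'
#' @return manifest list (no file paths).
#' @export
nshl_study_design <- function() {
  site_tests <- list("M7_vs_M8", "M8a_vs_M8")
  branch_tests <- list("BranchSiteA", "TwoRatio")
  single_genes <- c("Tectb", "Otog", "Col11a2", "Strc", "Ush1g",
                    "Pou3f4", "Kcnq4", "Gjb2", "Cldn14")
  myo_regions <- c("Myo15_I", "Myo15_II", "Myo15_III")
  tecta_mammal <- c("Tecta", "Tecta_ex7", "Tecta_ex9", "Tecta_ex18_19")
  tecta_tetrapod <- c("Tecta_ex7_tetrapod", "Tecta_ex9_tetrapod",
                      "Tecta_ex18_19_tetrapod")
  tecta_bat <- c("Tecta_ex7_bat", "Tecta_ex9_bat", "Tecta_ex18_19_bat")
  datasets <- c(
    lapply(c(single_genes, myo_regions, tecta_mammal),
           function(id) list(id = id, tests = site_tests)),
    lapply(tecta_bat,
           function(id) list(id = id,
                             tests = c(site_tests, branch_tests),
                             foreground = "bats")),
    lapply(tecta_tetrapod,
           function(id) list(id = id, tests = branch_tests,
                             foreground = "mammals")))
  pair <- function(id, tests) lapply(tests, function(t) list(id, t))
  families <- c(
    stats::setNames(lapply(single_genes, pair, tests = site_tests),
                    LETTERS[1:9]),
    list(J = pair("Myo15_III", site_tests),
         K = c(unlist(lapply(tecta_mammal, pair, tests = site_tests),
                      recursive = FALSE),
               unlist(lapply(tecta_tetrapod, pair,
                             tests = branch_tests),
                      recursive = FALSE)),
         L = c(unlist(lapply(tecta_bat, pair, tests = site_tests),
                      recursive = FALSE),
               unlist(lapply(tecta_bat, pair, tests = branch_tests),
                      recursive = FALSE)),
         M = unlist(lapply(myo_regions, pair, tests = site_tests),
                    recursive = FALSE)))
  list(datasets = datasets, families = families,
       thresholds = list(pp_threshold = 0.95, low_omega = 0.25,
                         ci_threshold = 0.9),
       correction = "BH")
}
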