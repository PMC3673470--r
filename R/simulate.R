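# Synthetic data with ground truth.  Alignments are evolved site by site
# down the tree under the generative counterpart of the inference models:
# a site class is drawn from the mixture weights, the root codon from pi,
# and each branch transition from the class- and branch-tag-appropriate
# probability matrix (mixture-level rate scaling, so branch lengths mean
# expected substitutions per codon under the weighted model).  Classes
# are i.i.d. across sites, matching the site-model assumption.

#' Simulate a codon alignment under an omega model
#'
#' @param tree `tagged_phylo` or ape `phylo` with branch lengths.
#' @param model an [omega_model()] (generative parameter values).
#' @param n_codons number of codon sites (>= 0).
#' @param kappa transition/transversion ratio used for simulation
#'   (overrides `model$kappa` if given).
#' @param pi `codon_frequencies` (default uniform).
#' @param seed integer seed; identical seed and inputs give identical
#'   output.
#' @param missing_fraction fraction of (taxon, site) triplets replaced
#'   by missing states (default 0).
#' @return list with `aln` (a `codon_alignment`) and `truth` (a
#'   `simulation_truth`: per-site true class and omegas, per-branch
#'   tags, the model, and the seed).
#' @export
simulate_alignment <- function(tree, model, n_codons, kappa = NULL,
                               pi = codon_frequencies(mode = "uniform"),
                               seed = 1L, missing_fraction = 0) {
  stopifnot(inherits(model, "omega_model"), n_codons >= 0)
  if (!is.null(kappa)) model$kappa <- kappa
  tp <- as_tagged_phylo(tree)
  code <- standard_genetic_code()
  classes <- model_class_spec(model)
  tv <- traversal(tp)
  n_tip <- tv$n_tip
  truth_classes <- integer(0)
  states <- matrix(NA_integer_, n_tip, n_codons)
  if (n_codons > 0) {
    eng <- build_engine(tp, classes, model$kappa, pi, code,
                        calibration = "mixture")
    withr::with_seed(seed, {
      truth_classes <- sample.int(nrow(classes), n_codons,
                                  replace = TRUE,
                                  prob = classes$weight)
      pi_ <- eng$pi
      node_states <- matrix(NA_integer_, n_tip + tv$n_node, n_codons)
      node_states[tv$root, ] <- sample.int(length(pi_), n_codons,
                                           replace = TRUE, prob = pi_)
      # preorder = reversed postorder edge list
      for (e in rev(seq_len(nrow(tv$edge)))) {
        parent <- tv$edge[e, 1]
        child <- tv$edge[e, 2]
        ps <- node_states[parent, ]
        cs <- integer(n_codons)
        for (k in unique(truth_classes)) {
          P <- eng$P[[k]][[e]]
          sel <- which(truth_classes == k)
          for (s in unique(ps[sel])) {
            at <- sel[ps[sel] == s]
            cs[at] <- sample.int(ncol(P), length(at), replace = TRUE,
                                 prob = P[s, ])
          }
        }
        node_states[child, ] <- cs
      }
      states <- node_states[seq_len(n_tip), , drop = FALSE]
      if (missing_fraction > 0) {
        n_miss <- round(missing_fraction * length(states))
        drop <- sample.int(length(states), n_miss)
        states[drop] <- NA_integer_
      }
    })
  }
  codons <- matrix(code$sense_codons[states], n_tip, n_codons)
  codons[is.na(states)] <- "---"
  aln <- new_codon_alignment(tv$tip_label, states, codons, code)
  truth <- structure(
    list(site = data.frame(
           site = seq_len(n_codons),
           class = truth_classes,
           omega_back = classes$omega_back[truth_classes],
           omega_fore = classes$omega_fore[truth_classes]),
         branch_fore = tv$fore, model = model, seed = seed,
         class_spec = classes),
    class = "simulation_truth")
  list(aln = aln, truth = truth)
}

#' Simulate a random phylogeny
#'
#' Random topology via [ape::rtree()] with branch lengths rescaled to a
#' target mean, for use as a simulation input tree.
#'
#' @param n_taxa number of leaves.
#' @param seed integer seed.
#' @param mean_branch_length mean branch length after rescaling
#'   (expected substitutions per codon; default 0.15, a divergence in
#'   the range typical of mammal-wide coding alignments).
#' @return a `tagged_phylo` (all branches background).
#' @export
simulate_tree <- function(n_taxa, seed = 1L, mean_branch_length = 0.15) {
  tr <- withr::with_seed(seed, ape::rtree(n_taxa))
  tr$edge.length <- tr$edge.length *
    (mean_branch_length / mean(tr$edge.length))
  as_tagged_phylo(tr)
}

#' Default synthetic study manifest
#'
#' A small multi-gene study design with the statistical structure the
#' analysis assumes: each gene evolves under an M8 mixture dominated by
#' strong purifying selection (beta component concentrated near zero)
#' with a small positively selected fraction, and carries a table of
#' synthetic disease mutations enriched at sites drawn from the lowest
#' omega class.
#'
#' @param n_genes number of genes (default 3).
#' @param n_taxa leaves per gene tree (default 16).
#' @param n_codons codon sites per gene (default 400).
#' @param beta_p,beta_q generative beta shapes (default 0.2, 2: mean
#'   omega 0.09, heavy mass near zero).
#' @param p0 proportion of beta-distributed sites (default 0.95).
#' @param omega_s generative positive-class omega (default 1.8).
#' @param kappa transition/transversion ratio (default 2.5).
#' @param n_dams_per_gene synthetic disease mutations per gene
#'   (default 6).
#' @param dam_enrichment probability that a synthetic DAM is placed at a
#'   site whose true class is the lowest omega class (default 0.9;
#'   remaining DAMs are placed uniformly).
#' @param mean_branch_length see [simulate_tree()].
#' @return manifest list consumable by [simulate_study()] and
#'   [build_test_families()].
#' @export
synthetic_study_manifest <- function(n_genes = 3L, n_taxa = 16L,
                                     n_codons = 400L, beta_p = 0.2,
                                     beta_q = 2, p0 = 0.95,
                                     omega_s = 1.8, kappa = 2.5,
                                     n_dams_per_gene = 6L,
                                     dam_enrichment = 0.9,
                                     mean_branch_length = 0.15) {
  genes <- lapply(seq_len(n_genes), function(i) {
    list(id = sprintf("gene%02d", i), n_taxa = n_taxa,
         n_codons = n_codons,
         model = list(variant = "M8", beta_p = beta_p, beta_q = beta_q,
                      p0 = p0, omega_s = omega_s, kappa = kappa),
         tests = list("M7_vs_M8", "M8a_vs_M8"),
         n_dams = n_dams_per_gene, dam_enrichment = dam_enrichment,
         mean_branch_length = mean_branch_length)
  })
  families <- stats::setNames(lapply(genes, function(g) {
    list(list(g$id, "M7_vs_M8"), list(g$id, "M8a_vs_M8"))
  }), paste0("F", seq_len(n_genes)))
  list(datasets = genes, families = families,
       thresholds = list(pp_threshold = 0.95, low_omega = 0.25,
                         ci_threshold = 0.9),
       correction = "BH")
}

#' Simulate a study fixture bundle
#'
#' Writes, for every gene in the manifest, a FASTA alignment, a Newick
#' tree, a per-site truth TSV and a synthetic DAM TSV (positions
#' enriched at sites whose true class is the lowest omega class), plus
#' an echo of the manifest.  The first taxon of each gene is designated
#' the reference (synthetic alignments are ungapped, so protein and
#' alignment coordinates coincide).
#'
#' @param manifest see [synthetic_study_manifest()]; per-gene entries
#'   need `id`, `n_taxa`, `n_codons`, `model`, and optionally `n_dams`,
#'   `dam_enrichment`, `mean_branch_length`.
#' @param seed integer master seed; per-gene seeds are derived from it.
#' @param dir output directory (created if needed).
#' @return the manifest augmented with file paths (`alignment`, `tree`,
#'   `truth`, `dams`, `reference` per dataset), invisibly written to
#'   `dir/manifest.echo.yaml`.
#' @export
simulate_study <- function(manifest, seed = 1L, dir = tempfile("study")) {
  need <- c("datasets")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    stop("manifest lacks key(s): ", paste(miss, collapse = ", "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(manifest$datasets)) {
    g <- manifest$datasets[[i]]
    gmiss <- setdiff(c("id", "n_taxa", "n_codons", "model"), names(g))
    if (length(gmiss)) {
      stop("dataset ", i, " lacks key(s): ",
           paste(gmiss, collapse = ", "))
    }
    gseed <- (seed * 1009L + i * 7919L) %% .Machine$integer.max
    gdir <- file.path(dir, g$id)
    dir.create(gdir, showWarnings = FALSE)
    tp <- simulate_tree(g$n_taxa, seed = gseed,
                        mean_branch_length =
                          g$mean_branch_length %||% 0.15)
    model <- do.call(omega_model, g$model)
    sim <- simulate_alignment(tp, model, g$n_codons, seed = gseed + 1L)
    sim$aln$reference <- sim$aln$taxa[1]
    fa <- file.path(gdir, "alignment.fasta")
    write_codon_alignment(sim$aln, fa)
    nwk <- file.path(gdir, "tree.nwk")
    ape::write.tree(tp$tree, nwk)
    truth_path <- file.path(gdir, "truth.tsv")
    tdf <- sim$truth$site
    hdr <- c(paste0("# seed: ", gseed + 1L),
             paste0("# model: ", model$variant))
    writeLines(hdr, truth_path)
    suppressWarnings(utils::write.table(
      tdf, truth_path, sep = "\t", quote = FALSE, row.names = FALSE,
      append = TRUE))
    dams <- withr::with_seed(gseed + 2L, {
      synth_dams(g$id, sim, g$n_dams %||% 6L,
                 g$dam_enrichment %||% 0.9)
    })
    dam_path <- file.path(gdir, "dams.tsv")
    writeLines(paste0("# seed: ", gseed + 2L), dam_path)
    suppressWarnings(utils::write.table(
      dams, dam_path, sep = "\t", quote = FALSE, row.names = FALSE,
      append = TRUE))
    manifest$datasets[[i]]$alignment <- fa
    manifest$datasets[[i]]$tree <- nwk
    manifest$datasets[[i]]$truth <- truth_path
    manifest$datasets[[i]]$dams <- dam_path
    manifest$datasets[[i]]$reference <- sim$aln$taxa[1]
  }
  manifest$seed <- seed
  yaml::write_yaml(manifest, file.path(dir, "manifest.echo.yaml"))
  manifest$dir <- dir
  manifest
}

# internal: synthetic DAM table; draws positions at lowest-class sites
# with probability `enrichment`, uniformly otherwise
synth_dams <- function(gene, sim, n_dams, enrichment) {
  truth <- sim$truth$site
  lowest <- truth$site[truth$class == 1L]
  aa <- translate_codons(sim$aln$codons[1, ], sim$aln$code)
  aa_all <- setdiff(unique(unname(sim$aln$code$sense_aa)), NA)
  pos <- integer(n_dams)
  for (j in seq_len(n_dams)) {
    pos[j] <- if (length(lowest) && stats::runif(1) < enrichment) {
      lowest[sample.int(length(lowest), 1L)]
    } else {
      sample.int(nrow(truth), 1L)
    }
  }
  ref <- aa[pos]
  alt <- vapply(ref, function(a) {
    sample(setdiff(aa_all, a), 1L)
  }, "")
  data.frame(gene = gene, protein_position = pos, ref_aa = ref,
             alt_aa = unname(alt),
             source_id = sprintf("%s_synthvar%02d", gene,
                                 seq_len(n_dams)),
             external_score = round(stats::runif(n_dams), 3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
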