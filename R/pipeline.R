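# End-to-end study orchestration: fit -> LRTs -> family-wise FDR ->
# site posteriors -> conservation profiles -> DAM mapping -> TSV report
# bundle.  Posteriors and conservation indices are always computed from
# the M8 fit, whether or not the LRTs are significant; significance is
# carried as a separate flag.

SITE_TEST_NAMES <- c("M7_vs_M8", "M8a_vs_M8")
BRANCH_TEST_NAMES <- c("BranchSiteA", "TwoRatio")

#' Run a complete selection/conservation study
#'
#' Executes every declared test on every data set of the manifest,
#' applies the family-wise FDR correction, computes BEB site posteriors
#' and conservation profiles from each data set's M8 fit, maps any
#' disease-mutation tables, and writes the TSV report bundle.
#'
#' @param manifest a validated manifest whose datasets carry `alignment`
#'   and `tree` paths (see [simulate_study()] for the synthetic case);
#'   optional per-dataset keys: `reference` (taxon), `foreground_clade`
#'   (leaf labels whose stem branch is foreground), `dams` (TSV path).
#' @param out_dir output directory for the report bundle (created).
#' @param seed integer seed passed to the optimizers.
#' @param opts base [fit_opts()] for the fitting stages.
#' @param posterior_method `"BEB"` (default) or `"NEB"`.
#' @return A `study_result` list: `tests` (one row per family
#'   membership), `profiles` (per-gene conservation profiles), `dams`
#'   (mapped records), `dam_summary`, `fits`, `out_dir`.
#' @export
run_study <- function(manifest, out_dir = tempfile("study_out"),
                      seed = 1L,
                      opts = fit_opts(branch_mode = "scale",
                                      n_starts = 2L, seed = seed),
                      posterior_method = c("BEB", "NEB")) {
  posterior_method <- match.arg(posterior_method)
  validate_manifest(manifest)
  fam <- build_test_families(manifest)
  th <- manifest$thresholds %||% list()
  pp_thr <- th$pp_threshold %||% 0.95
  low_om <- th$low_omega %||% 0.25
  ci_thr <- th$ci_threshold %||% 0.9
  correction <- manifest$correction %||% "BH"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("# codonsel %s | R %s.%s",
            as.character(utils::packageVersion("codonsel")),
            R.version$major, R.version$minor),
    sprintf("# seed: %d | correction: %s", seed, correction))

  for (d in manifest$datasets) {
    for (key in c("alignment", "tree")) {
      if (is.null(d[[key]])) {
        stop("dataset '", d$id, "' lacks a '", key, "' path; ",
             "run_study needs data files (see simulate_study)")
      }
      if (!file.exists(d[[key]])) {
        stop("dataset '", d$id, "': ", key, " file not found: ",
             d[[key]])
      }
    }
  }

  fits <- list()
  profiles <- list()
  mapped_dams <- list()
  lrt_results <- list()
  for (d in manifest$datasets) {
    aln <- read_codon_alignment(d$alignment,
                                reference = d$reference %||% NULL)
    tp <- read_newick(d$tree)
    if (!is.null(d$foreground_clade)) {
      tp <- tag_foreground(tp, unlist(d$foreground_clade))
    }
    tests <- unlist(d$tests)
    unknown <- setdiff(tests, c(SITE_TEST_NAMES, BRANCH_TEST_NAMES))
    if (length(unknown)) {
      stop("dataset '", d$id, "' declares unknown test(s): ",
           paste(unknown, collapse = ", "))
    }
    dfit <- list()
    if (any(tests %in% SITE_TEST_NAMES) ||
        !is.null(d$dams) || isTRUE(d$profile)) {
      sm <- fit_site_models(aln, tp, opts = opts)
      dfit$site <- sm
      for (t in intersect(tests, SITE_TEST_NAMES)) {
        lr <- if (t == "M7_vs_M8") lrt(sm$M7, sm$M8) else
          lrt(sm$M8a, sm$M8)
        lrt_results[[paste(d$id, t)]] <-
          list(dataset = d$id, test = t, lnL_null = if (t == "M7_vs_M8")
            sm$M7$lnL else sm$M8a$lnL, lnL_alt = sm$M8$lnL, lr = lr)
      }
      for (nm in c("M0", "M7", "M8a", "M8")) {
        if (!is.null(sm[[nm]]) && !sm[[nm]]$converged) {
          log_lines <- c(log_lines,
                         sprintf("# WARNING: %s %s fit not converged",
                                 d$id, nm))
        }
      }
      # posteriors and conservation from the M8 fit, in all cases
      m8 <- sm$M8
      csl <- class_site_likelihoods(aln, sm$tree,
                                    model_class_spec(m8$model),
                                    sm$kappa, sm$pi,
                                    calibration = sm$calibration)
      post <- site_class_posteriors(
        m8, csl, method = posterior_method,
        extra_lik = function(ws) eval_site_curve(sm$curve, ws))
      prof <- conservation_profile(post, aln, pp_thr, low_om)
      sig <- lrt_results[[paste(d$id, "M7_vs_M8")]]
      prof$site_test_significant <-
        if (is.null(sig)) NA else sig$lr$p_raw < 0.05
      pos_class <- which(post$class_omegas > 1)
      prof$positive_site <- if (length(pos_class)) {
        apply(post$PP[, pos_class, drop = FALSE], 1, max) > pp_thr
      } else FALSE
      profiles[[d$id]] <- prof
      if (!is.null(d$dams)) {
        dams <- read_dam_table(d$dams)
        mapped_dams[[d$id]] <- map_dams(dams, aln, prof)
      }
    }
    if (any(tests %in% BRANCH_TEST_NAMES)) {
      if (!any(as_tagged_phylo(tp)$fore)) {
        stop("dataset '", d$id, "' declares branch tests but no ",
             "foreground branch (tag the tree or set foreground_clade)")
      }
      bm <- fit_branch_models(aln, tp,
                              models = intersect(tests,
                                                 BRANCH_TEST_NAMES),
                              opts = opts)
      dfit$branch <- bm
      if ("BranchSiteA" %in% tests) {
        lr <- lrt(bm$BranchSiteA_null, bm$BranchSiteA)
        lrt_results[[paste(d$id, "BranchSiteA")]] <-
          list(dataset = d$id, test = "BranchSiteA",
               lnL_null = bm$BranchSiteA_null$lnL,
               lnL_alt = bm$BranchSiteA$lnL, lr = lr)
      }
      if ("TwoRatio" %in% tests) {
        lr <- lrt(bm$M0, bm$TwoRatio)
        lrt_results[[paste(d$id, "TwoRatio")]] <-
          list(dataset = d$id, test = "TwoRatio",
               lnL_null = bm$M0$lnL, lnL_alt = bm$TwoRatio$lnL,
               lr = lr)
      }
    }
    fits[[d$id]] <- dfit
  }

  # family-wise correction; one output row per family membership
  rows <- list()
  for (f in fam$families) {
    key <- paste(f$members$dataset, f$members$test)
    p_raw <- vapply(key, function(k) lrt_results[[k]]$lr$p_raw, 0)
    p_adj <- adjust_pvalues(p_raw, correction)
    for (i in seq_len(nrow(f$members))) {
      r <- lrt_results[[key[i]]]
      rows[[length(rows) + 1L]] <- data.frame(
        family = f$family_id, dataset = r$dataset, test = r$test,
        lnL_null = r$lnL_null, lnL_alt = r$lnL_alt,
        stat = r$lr$stat, df = r$lr$df,
        p_raw = p_raw[i], p_adj = p_adj[i])
    }
  }
  tests_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(), dataset = character(),
               test = character(), lnL_null = numeric(),
               lnL_alt = numeric(), stat = numeric(), df = integer(),
               p_raw = numeric(), p_adj = numeric())

  dam_df <- if (length(mapped_dams)) {
    do.call(rbind, c(mapped_dams, list(make.row.names = FALSE)))
  } else NULL
  dam_summary <- if (!is.null(dam_df)) {
    dam_overlap_summary(dam_df, ci_thr)
  } else NULL

  meta <- c(sprintf("# correction: %s", correction),
            sprintf("# seed: %d", seed))
  write_tsv_meta(tests_df, file.path(out_dir, "tests.tsv"), meta)
  if (length(profiles)) {
    prof_df <- do.call(rbind, lapply(names(profiles), function(g) {
      cbind(data.frame(gene = g), profiles[[g]])
    }))
    write_tsv_meta(prof_df, file.path(out_dir, "sites.tsv"), meta)
  }
  if (!is.null(dam_df)) {
    write_tsv_meta(dam_df, file.path(out_dir, "dams.tsv"), meta)
    write_tsv_meta(dam_summary$per_gene,
                   file.path(out_dir, "dam_summary.tsv"),
                   c(meta, sprintf("# overall: %d/%d at ci >= %s",
                                   dam_summary$overall$n_ci_at_or_above,
                                   dam_summary$overall$n,
                                   format(ci_thr))))
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.echo.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  structure(
    list(tests = tests_df, profiles = profiles, dams = dam_df,
         dam_summary = dam_summary, fits = fits, out_dir = out_dir),
    class = "study_result")
}

# internal: TSV with '#' metadata lines, single header, NA as "NA"
write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> ", length(unique(x$tests$dataset)),
      " data set(s), ", nrow(x$tests), " family-membership row(s); ",
      "outputs in ", x$out_dir, "\n", sep = "")
  invisible(x)
}
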