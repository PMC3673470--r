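# Site posteriors, FDR correction, hypothesis-family bookkeeping.

test_that("NEB posteriors follow Bayes' rule", {
  csl <- structure(
    list(logL = log(matrix(c(0.001, 0.009), 1, 2)),
         class_omegas = c(0.1, 1.5), class_weights = c(0.9, 0.1)),
    class = "class_site_lik")
  fit <- structure(list(model = omega_model("M7")),
                   class = "fit_result")
  pp <- site_class_posteriors(fit, csl, "NEB")
  expect_equal(unname(pp$PP[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  # single class is degenerate
  one <- structure(
    list(logL = matrix(rnorm(5), 5, 1), class_omegas = 0.2,
         class_weights = 1), class = "class_site_lik")
  pp1 <- site_class_posteriors(fit, one, "NEB")
  expect_equal(unname(pp1$PP[, 1]), rep(1, 5))

  # rows always sum to one
  set.seed(3)
  many <- structure(
    list(logL = matrix(rnorm(60, sd = 4), 10, 6),
         class_omegas = sort(runif(6)),
         class_weights = rep(1 / 6, 6)), class = "class_site_lik")
  ppm <- site_class_posteriors(fit, many, "NEB")
  expect_lt(max(abs(rowSums(ppm$PP) - 1)), 1e-9)

  # raising a site's class-k likelihood strictly raises PP_k
  bumped <- many
  bumped$logL[4, 2] <- bumped$logL[4, 2] + 0.5
  ppb <- site_class_posteriors(fit, bumped, "NEB")
  expect_gt(ppb$PP[4, 2], ppm$PP[4, 2])
})

test_that("BEB grid posteriors are proper and close to NEB here", {
  tp <- simulate_tree(8, seed = 41)
  sim <- simulate_alignment(tp, omega_model("M8", kappa = 2,
                                            beta_p = 0.3, beta_q = 2,
                                            p0 = 0.9, omega_s = 2),
                            120, seed = 43)
  sm <- fit_site_models(sim$aln, tp, models = c("M8a", "M8"),
                        opts = fit_opts(branch_mode = "scale",
                                        n_starts = 1), pi = uniform_pi())
  csl <- class_site_likelihoods(sim$aln, sm$tree,
                                model_class_spec(sm$M8$model),
                                sm$kappa, sm$pi,
                                calibration = sm$calibration)
  beb <- site_class_posteriors(
    sm$M8, csl, "BEB",
    extra_lik = function(ws) eval_site_curve(sm$curve, ws))
  expect_lt(max(abs(rowSums(beb$PP) - 1)), 1e-9)
  expect_true(all(beb$PP >= 0 & beb$PP <= 1))
  expect_error(site_class_posteriors(sm$M8, csl, "BEB"), "extra_lik")
  expect_error(site_class_posteriors(sm$M0, csl, "BEB"), "M8")
})

test_that("BH adjustment reproduces worked examples and the oracle", {
  expect_equal(bh_fdr(c(0.009, 0.034)), c(0.018, 0.034))
  expect_equal(bh_fdr(c(0.455, 0.584)), c(0.584, 0.584))
  expect_equal(bh_fdr(0.03), 0.03)
  famK <- c(0.094, 0.561, 0.409, 0.389, 0.010, 0.002, 0.999, 0.974,
            0.087, 0.943, 0.144, 0.160, 1.000, 0.780)
  adjK <- bh_fdr(famK)
  expect_equal(adjK[famK == 0.002], 0.028, tolerance = 1e-12)
  expect_equal(round(adjK[famK == 0.094], 3), 0.329)

  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.5, NA)), "0, 1")

  # equals the step-up rejection-set definition on random vectors
  set.seed(9)
  alphas <- seq(0.01, 0.99, by = 0.01)
  for (i in 1:20) {
    p <- runif(sample(1:20, 1))
    adj <- bh_fdr(p)
    expect_true(all(adj >= p - 1e-15))
    for (a in alphas[c(5, 25, 50, 75, 95)]) {
      expect_identical(adj <= a, bh_reject_oracle(p, a))
    }
    # order invariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm], tolerance = 1e-15)
  }
  # equal values are a fixed point
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
})

test_that("Holm option matches stats::p.adjust step-down", {
  p <- c(0.038, 0.011, 0.828, 0.630, 0.071, 0.021)
  expect_equal(adjust_pvalues(p, "Holm"), p.adjust(p, "holm"))
})

test_that("family enumeration validates and counts the study design", {
  des <- nshl_study_design()
  fam <- build_test_families(des)
  expect_equal(nrow(fam$tests), 50)
  expect_length(fam$families, 13)
  expect_identical(sort(as.integer(fam$family_sizes)),
                   c(rep(2L, 10), 6L, 12L, 14L))
  # overlap: the longest-region tests appear in two families
  j <- fam$families$J$members
  m <- fam$families$M$members
  expect_true(all(paste(j$dataset, j$test) %in%
                  paste(m$dataset, m$test)))

  expect_identical(build_test_families(list(datasets = list()))$tests,
                   data.frame(dataset = character(),
                              test = character()))

  mini <- list(datasets = list(list(id = "g1",
                                    tests = list("M7_vs_M8",
                                                 "M8a_vs_M8"))),
               families = list(A = list(list("g1", "M7_vs_M8"),
                                        list("g1", "M8a_vs_M8"))))
  fm <- build_test_families(mini)
  expect_equal(unname(fm$family_sizes["A"]), 2L)

  bad <- mini
  bad$families$A[[2]] <- list("g1", "NoSuchTest")
  expect_error(build_test_families(bad), "undeclared")
})
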