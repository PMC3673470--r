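# Model specifications, beta discretization, fitting and LRTs.

test_that("model constraints are validated", {
  expect_error(omega_model("M8", omega_s = 0.5), "omega_s >= 1")
  expect_error(omega_model("M7", beta_p = 0), "positive")
  expect_error(omega_model("BranchSiteA", omega2 = 0.5), "omega2 >= 1")
  expect_error(omega_model("BranchSiteA", p0 = 0.8, p1 = 0.4),
               "proportions")
  expect_error(omega_model("M0", K = 1), "K")
  expect_equal(omega_model("M8a", p0 = 0.8)$omega_s, 1)
  expect_equal(omega_model("BranchSiteA_null")$omega2, 1)
})

test_that("beta discretization matches the quadrature oracle", {
  d <- discretize_beta(1, 1, 2)
  expect_equal(d$omegas, c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(d$weights, c(0.5, 0.5))

  d2 <- discretize_beta(0.2, 1.5, 10)
  expect_equal(mean(d2$omegas), 0.2 / 1.7, tolerance = 1e-6)

  for (shapes in list(c(0.2, 1.5), c(1, 1), c(2, 5), c(0.5, 0.5))) {
    K <- 10
    got <- discretize_beta(shapes[1], shapes[2], K)$omegas
    oracle <- beta_bin_means_oracle(shapes[1], shapes[2], K)
    expect_equal(got, oracle, tolerance = 1e-6)
    expect_true(all(diff(got) > 0))
    expect_true(all(got > 0 & got < 1))
  }
  expect_error(discretize_beta(-1, 2), "positive")
})

test_that("class specifications form proper mixtures", {
  for (m in list(omega_model("M0"), omega_model("M7"),
                 omega_model("M8", p0 = 0.85, omega_s = 2.5),
                 omega_model("M8a", p0 = 0.7),
                 omega_model("BranchSiteA", p0 = 0.6, p1 = 0.2),
                 omega_model("TwoRatio"))) {
    cl <- model_class_spec(m)
    expect_equal(sum(cl$weight), 1, tolerance = 1e-12)
    expect_true(all(cl$weight >= 0))
    expect_true(all(cl$omega_back >= 0 & cl$omega_fore >= 0))
  }
  bsa <- model_class_spec(omega_model("BranchSiteA", p0 = 0.6,
                                      p1 = 0.2, omega0 = 0.1,
                                      omega2 = 3))
  expect_equal(bsa$omega_fore, c(0.1, 1, 3, 3))
  expect_equal(bsa$omega_back, c(0.1, 1, 0.1, 1))
  expect_equal(bsa$weight[3] / bsa$weight[4], 0.6 / 0.2,
               tolerance = 1e-12)
})

test_that("M0 on identical sequences collapses branch lengths", {
  aln <- read_codon_alignment(c(">A", "ATGAAATTTCCC", ">B",
                                "ATGAAATTTCCC", ">C", "ATGAAATTTCCC"))
  tp <- read_newick("((A:0.1,B:0.1):0.05,C:0.1);")
  f <- fit(aln, tp, omega_model("M0"),
           fit_opts(branch_mode = "joint", n_starts = 1),
           pi = uniform_pi())
  expect_equal(f$lnL, 4 * log(1 / 61), tolerance = 1e-4)
  expect_lt(max(f$tree$tree$edge.length), 1e-5)
})

test_that("M0 omega recovery agrees with a grid-search oracle", {
  tp <- simulate_tree(8, seed = 3)
  sim <- simulate_alignment(tp, omega_model("M0", kappa = 2,
                                            omega = 0.2), 300,
                            seed = 5)
  f <- fit(sim$aln, tp, omega_model("M0"),
           fit_opts(branch_mode = "scale", n_starts = 1),
           pi = uniform_pi())
  expect_gt(f$model$omega, 0.15)
  expect_lt(f$model$omega, 0.25)
  # independent profile grid search on omega at the generating tree
  grid <- seq(0.1, 0.35, by = 0.025)
  prof <- vapply(grid, function(w) {
    exact_model_loglik(sim$aln, tp, omega_model("M0", kappa = 2,
                                                omega = w),
                       kappa = 2, uniform_pi(), calibration = "mixture")
  }, 0)
  expect_lt(abs(grid[which.max(prof)] - f$model$omega), 0.06)
})

test_that("site-model ladder respects nesting and matches exact lnL", {
  tp <- simulate_tree(8, seed = 19)
  sim <- simulate_alignment(tp, omega_model("M8", kappa = 2,
                                            beta_p = 0.3, beta_q = 2,
                                            p0 = 0.9, omega_s = 2),
                            150, seed = 23)
  sm <- fit_site_models(sim$aln, tp, opts = fit_opts(
    branch_mode = "scale", n_starts = 1, seed = 2), pi = uniform_pi())
  expect_gte(sm$M8$lnL, sm$M7$lnL - 1e-6)
  expect_gte(sm$M8$lnL, sm$M8a$lnL - 1e-6)
  # curve-reported lnL agrees with exact pruning at the same parameters
  exact <- exact_model_loglik(sim$aln, sm$tree, sm$M8$model, sm$kappa,
                              sm$pi, sm$calibration)
  expect_lt(abs(sm$M8$lnL - exact), 0.02)
})

test_that("fits are bit-identical for identical seeds", {
  tp <- simulate_tree(6, seed = 29)
  sim <- simulate_alignment(tp, omega_model("M0", omega = 0.3), 80,
                            seed = 31)
  f1 <- fit(sim$aln, tp, omega_model("M0"),
            fit_opts(branch_mode = "scale", n_starts = 3, seed = 7),
            pi = uniform_pi())
  f2 <- fit(sim$aln, tp, omega_model("M0"),
            fit_opts(branch_mode = "scale", n_starts = 3, seed = 7),
            pi = uniform_pi())
  expect_identical(f1$model$omega, f2$model$omega)
  expect_identical(f1$model$kappa, f2$model$kappa)
  expect_identical(f1$lnL, f2$lnL)
})

test_that("LRT arithmetic and df mapping follow the nested pairs", {
  mk <- function(variant, lnL) {
    structure(list(model = omega_model(variant), lnL = lnL),
              class = "fit_result")
  }
  same <- lrt(mk("M8a", -100), mk("M8", -100))
  expect_equal(same$stat, 0)
  expect_equal(same$p_raw, 1)
  expect_equal(same$df, 1)

  crit <- lrt(mk("M8a", -100), mk("M8", -100 + 3.841459 / 2))
  expect_equal(crit$p_raw, 0.05, tolerance = 1e-4)

  expect_equal(lrt(mk("M7", -10), mk("M8", -9))$df, 2)
  expect_equal(lrt(mk("BranchSiteA_null", -10),
                   mk("BranchSiteA", -9))$df, 1)
  expect_equal(lrt(mk("M0", -10), mk("TwoRatio", -9))$df, 1)
  expect_error(lrt(mk("M7", -10), mk("TwoRatio", -9)), "nested")
  # negative improvements clip to zero
  expect_equal(lrt(mk("M8a", -99), mk("M8", -100))$stat, 0)
  # boundary mixture option halves the tail probability
  bm <- lrt(mk("M8a", -100), mk("M8", -99), boundary_mix = TRUE)
  plain <- lrt(mk("M8a", -100), mk("M8", -99))
  expect_equal(bm$p_raw, plain$p_raw / 2, tolerance = 1e-12)
})
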