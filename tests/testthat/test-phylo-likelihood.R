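# Newick handling and pruning likelihoods.

test_that("newick parsing handles lengths, tags and malformed input", {
  tr <- read_newick("(A:0.1,B:0.2);")
  expect_length(tr$tree$tip.label, 2)
  expect_setequal(tr$tree$edge.length, c(0.1, 0.2))
  expect_false(any(tr$fore))

  tagged <- read_newick("((A:0.1,B:0.1)#1:0.05,C:0.2);")
  expect_equal(sum(tagged$fore), 1)
  # the tagged edge is the stem of {A, B}
  mrca <- ape::getMRCA(tagged$tree, c("A", "B"))
  expect_equal(tagged$tree$edge[tagged$fore, 2], mrca)

  tip_tag <- read_newick("(A#1:0.1,B:0.2);")
  expect_equal(sum(tip_tag$fore), 1)
  expect_identical(tip_tag$tree$tip.label, c("A", "B"))

  expect_error(read_newick("(A:0.1,"), "parse error")
  expect_error(read_newick("(A:0.1,B:0.2));"), "position")
  expect_error(read_newick("((A:0.1,B:0.2):0.1,A:0.2);"), "duplicate")
  expect_warning(read_newick("(A,B);"), "branch length")
})

test_that("clade files tag the stem branch", {
  tr <- read_newick("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);",
                    clades = list(c("C", "D")))
  expect_equal(sum(tr$fore), 1)
  expect_equal(tr$tree$edge[tr$fore, 2], ape::getMRCA(tr$tree,
                                                      c("C", "D")))
  expect_error(tag_foreground(tr, c("A", "Z")), "not in tree")
  expect_error(tag_foreground(tr, c("A", "C")), "root")
})

test_that("pruning equals exhaustive enumeration on small trees", {
  set.seed(7)
  for (case in 1:25) {
    n_tip <- sample(2:4, 1)
    tp <- random_rooted_tree(n_tip)
    tv <- codonsel:::traversal(tp)
    piv <- runif(61); piv <- piv / sum(piv)
    eig <- build_rate_matrix(runif(1, 0.5, 5), runif(1, 0.05, 2),
                             piv)$eig
    P_edges <- lapply(tv$length, function(t) codonsel:::tm_eig(eig, t))
    states <- matrix(sample(c(1:61, NA), n_tip * 2, replace = TRUE),
                     n_tip, 2)
    ll <- codonsel:::prune_class(states, tv, P_edges, piv)
    for (s in 1:2) {
      bf <- brute_force_site_lik(tv, P_edges, piv, states[, s])
      expect_equal(exp(ll[s]), bf, tolerance = 1e-12)
    }
  }
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  set.seed(11)
  tp <- random_rooted_tree(6)
  aln <- simulate_alignment(tp, omega_model("M0", omega = 0.4), 40,
                            seed = 3)$aln
  cl <- data.frame(weight = 1, omega_back = 0.4, omega_fore = 0.4)
  ll <- function(tree) {
    sum(class_site_likelihoods(aln, tree, cl, kappa = 2,
                               pi = uniform_pi())$logL)
  }
  base <- ll(tp)
  unrooted <- codonsel::as_tagged_phylo(ape::unroot(tp$tree))
  expect_equal(ll(unrooted), base, tolerance = 1e-10)
  rerooted <- codonsel::as_tagged_phylo(
    ape::root(ape::unroot(tp$tree), outgroup = tp$tree$tip.label[4],
              resolve.root = TRUE))
  expect_equal(ll(rerooted), base, tolerance = 1e-10)
})

test_that("an all-missing taxon does not change the likelihood", {
  aln2 <- read_codon_alignment(c(">A", "ATGAAATTT", ">B", "ATGAAGTTC"))
  aln3 <- read_codon_alignment(c(">A", "ATGAAATTT", ">B", "ATGAAGTTC",
                                 ">X", "---------"))
  cl <- data.frame(weight = 1, omega_back = 0.3, omega_fore = 0.3)
  base <- sum(class_site_likelihoods(
    aln2, read_newick("(A:0.1,B:0.3);"), cl, 2, uniform_pi())$logL)
  with_x <- sum(class_site_likelihoods(
    aln3, read_newick("((B:0.2,X:0.5):0.1,A:0.1);"), cl, 2,
    uniform_pi())$logL)
  expect_equal(with_x, base, tolerance = 1e-10)
})

test_that("degenerate cases: zero branches, missing columns, mismatch", {
  star <- read_newick("(A:0,B:0,C:0);")
  aln <- read_codon_alignment(c(">A", "ATG", ">B", "ATG", ">C", "ATG"))
  cl <- data.frame(weight = 1, omega_back = 0.5, omega_fore = 0.5)
  csl <- class_site_likelihoods(aln, star, cl, 2, uniform_pi())
  expect_equal(csl$logL[1, 1], log(1 / 61), tolerance = 1e-10)

  alnm <- read_codon_alignment(c(">A", "---", ">B", "---", ">C", "---"))
  cslm <- class_site_likelihoods(alnm, star, cl, 2, uniform_pi())
  expect_equal(cslm$logL[1, 1], 0, tolerance = 1e-12)

  bad <- read_codon_alignment(c(">A", "ATG", ">B", "ATG"))
  expect_error(class_site_likelihoods(bad, star, cl, 2, uniform_pi()),
               "C")
})

test_that("mixture log-likelihood: degenerate mixtures and permutation", {
  tp <- read_newick("((A:0.2,B:0.1):0.1,C:0.3);")
  aln <- simulate_alignment(tp, omega_model("M0", omega = 0.5), 30,
                            seed = 5)$aln
  one <- class_site_likelihoods(
    aln, tp, data.frame(weight = 1, omega_back = 0.5,
                        omega_fore = 0.5), 2, uniform_pi())
  two <- class_site_likelihoods(
    aln, tp, data.frame(weight = c(0.5, 0.5),
                        omega_back = c(0.5, 0.5),
                        omega_fore = c(0.5, 0.5)), 2, uniform_pi())
  expect_equal(mixture_log_likelihood(two), mixture_log_likelihood(one),
               tolerance = 1e-10)
  # permuting site order leaves the total unchanged
  perm <- one
  perm$logL <- one$logL[sample(nrow(one$logL)), , drop = FALSE]
  expect_equal(mixture_log_likelihood(perm),
               mixture_log_likelihood(one), tolerance = 1e-12)
  # empty alignment
  empty <- one
  empty$logL <- one$logL[0, , drop = FALSE]
  expect_warning(val <- mixture_log_likelihood(empty), "empty")
  expect_equal(val, 0)
})

test_that("site curve interpolation matches direct pruning", {
  set.seed(13)
  tp <- random_rooted_tree(6)
  aln <- simulate_alignment(tp, omega_model("M8", beta_p = 0.3,
                                            beta_q = 2, p0 = 0.9,
                                            omega_s = 2), 60,
                            seed = 17)$aln
  curve <- site_likelihood_curve(aln, tp, kappa = 2, pi = uniform_pi(),
                                 calibration = 1)
  for (w in c(0.004, 0.07, 0.6, 1.9)) {
    direct <- class_site_likelihoods(
      aln, tp, data.frame(weight = 1, omega_back = w, omega_fore = w),
      2, uniform_pi(), calibration = 1)$logL[, 1]
    interp <- eval_site_curve(curve, w)[, 1]
    expect_lt(max(abs(direct - interp)), 2e-3)
  }
})
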