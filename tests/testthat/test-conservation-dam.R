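# Conservation index, minimum-omega categories, DAM mapping.

fake_post <- function(PP, omegas) {
  structure(list(PP = PP, class_omegas = omegas, method = "NEB"),
            class = "site_posteriors")
}

test_that("weighted mean omega is the posterior convex combination", {
  p <- fake_post(matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE),
                 c(0.1, 1.5))
  ob <- weighted_mean_omega(p)
  expect_equal(ob, c(0.1, 0.8), tolerance = 1e-12)

  set.seed(5)
  PP <- matrix(runif(40), 10, 4)
  PP <- PP / rowSums(PP)
  om <- sort(runif(4, 0, 3))
  ob2 <- weighted_mean_omega(fake_post(PP, om))
  expect_true(all(ob2 >= min(om) - 1e-12 & ob2 <= max(om) + 1e-12))
})

test_that("conservation index is 1 - omega for purifying sites else 0", {
  expect_equal(conservation_index(0.1), 0.9)
  expect_equal(conservation_index(1.476), 0)  # positively selected site
  expect_equal(conservation_index(1), 0)
  expect_equal(conservation_index(0), 1)
  expect_error(conservation_index(-0.1), "negative")
  # ci == max(0, 1 - omega_bar) sitewise
  ob <- runif(100, 0, 2)
  expect_equal(conservation_index(ob), pmax(0, 1 - ob))
})

test_that("minimum-omega categories accumulate PP from the lowest class", {
  p1 <- fake_post(matrix(c(1, 0, 0), 1), c(0.05, 0.2, 1.3))
  c1 <- min_omega_category(p1)
  expect_equal(c1$min_omega_class, 1)
  expect_true(c1$significant_purifying)

  p2 <- fake_post(matrix(c(0.60, 0.36, 0.04), 1), c(0.0, 0.2, 1.3))
  c2 <- min_omega_category(p2)
  expect_equal(c2$min_omega_class, 2)
  expect_equal(c2$min_omega_value, 0.2)
  expect_true(c2$significant_purifying)

  p3 <- fake_post(matrix(c(0.10, 0.10, 0.80), 1), c(0.0, 0.2, 1.5))
  c3 <- min_omega_category(p3)
  expect_equal(c3$min_omega_class, 3)
  expect_false(c3$significant_purifying)

  # never exceeding the threshold falls back to the final class
  p4 <- fake_post(matrix(c(0.5, 0.3, 0.2), 1), c(0.0, 0.2, 1.5))
  expect_equal(min_omega_category(p4)$min_omega_class, 3)

  expect_error(min_omega_category(fake_post(matrix(c(0.5, 0.5), 1),
                                            c(1, 0.5))),
               "increasing")
})

test_that("shifting mass to lower classes never raises the category", {
  set.seed(11)
  om <- c(0.01, 0.1, 0.4, 1.2)
  for (i in 1:25) {
    PP <- runif(4); PP <- PP / sum(PP)
    base <- min_omega_category(fake_post(matrix(PP, 1), om))
    from <- sample(2:4, 1)
    d <- PP[from] * runif(1)
    PP2 <- PP
    PP2[from] <- PP2[from] - d
    PP2[from - 1] <- PP2[from - 1] + d
    shifted <- min_omega_category(fake_post(matrix(PP2, 1), om))
    expect_lte(shifted$min_omega_class, base$min_omega_class)
  }
})

test_that("DAM mapping handles gaps, bounds and mismatched residues", {
  # reference has a gap at column 3: protein position p maps past it
  aln <- read_codon_alignment(
    c(">ref", "ATGAAA---TTTCCCGGG", ">oth", "ATGAAGCATTTCCCAGGA"),
    reference = "ref")
  post <- fake_post(matrix(rep(c(0.98, 0.02), each = 6), 6, 2),
                    c(0.05, 1.2))
  prof <- conservation_profile(post, aln)
  expect_equal(prof$reference_position,
               c(1L, 2L, NA, 3L, 4L, 5L))

  dams <- data.frame(gene = "g", protein_position = c(1, 4, 5),
                     ref_aa = c("M", "F", "P"),
                     alt_aa = c("T", "S", "L"),
                     source_id = paste0("v", 1:3),
                     external_score = c(0.9, 0.8, NA))
  mapped <- map_dams(dams, aln, prof)
  expect_equal(mapped$mapped_column, c(1L, 5L, 6L))
  expect_equal(mapped$mapped_ci, prof$ci[c(1, 5, 6)])
  # ref_aa check: column 5 is CCC = P, not F -> mismatch flagged
  expect_identical(mapped$ref_aa_match, c(TRUE, FALSE, FALSE))

  over <- rbind(dams, data.frame(gene = "g", protein_position = 10,
                                 ref_aa = "A", alt_aa = "V",
                                 source_id = "v4",
                                 external_score = NA))
  expect_warning(m2 <- map_dams(over, aln, prof), "skipped")
  expect_equal(nrow(m2), 3)
})

test_that("overlap summaries count conserved disease sites", {
  mk <- function(ci) data.frame(gene = "g", mapped_ci = ci)
  s <- dam_overlap_summary(mk(c(0.95, 0.99, 0.20, 0.91, 0.85)))
  expect_equal(s$overall$n_ci_at_or_above, 3)
  expect_equal(s$overall$n, 5)
  s2 <- dam_overlap_summary(mk(rep(1, 4)))
  expect_equal(s2$overall$prop_at_or_above, 1)
  s3 <- dam_overlap_summary(data.frame(gene = character(),
                                       mapped_ci = numeric()))
  expect_equal(s3$overall$n, 0)
})
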