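# Codon state space, alignment I/O, frequencies, rate and transition
# matrices.

test_that("standard genetic code has 61 sense codons in TCAG order", {
  gc <- standard_genetic_code()
  expect_length(gc$sense_codons, 61)
  expect_identical(gc$stop_codons, c("TAA", "TAG", "TGA"))
  expect_identical(gc$sense_codons[1:4], c("TTT", "TTC", "TTA", "TTG"))
  expect_identical(unname(gc$table[c("ATG", "TGG", "AAA")]),
                   c("M", "W", "K"))
  expect_error(standard_genetic_code("FF"), "64")
})

test_that("FASTA reading validates frame, stops, duplicates, gaps", {
  aln <- read_codon_alignment(c(">a", "ATGAAA", ">b", "ATGAAG"))
  expect_equal(aln$n_sites, 2)
  expect_equal(length(aln$taxa), 2)
  expect_false(anyNA(aln$states))

  expect_error(read_codon_alignment(c(">a", "ATGAAAT")), "frame")
  expect_error(read_codon_alignment(c(">a", "ATGTAAATG")),
               "taxon 'a' at codon site 2")
  expect_error(read_codon_alignment(c(">a", "ATGAAA", ">a", "ATGAAA")),
               "duplicate")

  gap <- read_codon_alignment(c(">a", "ATG--AAAA"))
  expect_true(is.na(gap$states[1, 2]))
  expect_false(is.na(gap$states[1, 1]))
  amb <- read_codon_alignment(c(">a", "ATGANG"))
  expect_true(is.na(amb$states[1, 2]))
})

test_that("write/read round-trip is an identity on states", {
  txt <- c(">a some description", "ATG--AAAATTT", ">b", "ATGCCAAAATGG")
  aln <- read_codon_alignment(txt)
  path <- tempfile(fileext = ".fa")
  write_codon_alignment(aln, path)
  aln2 <- read_codon_alignment(path)
  expect_identical(aln2$states, aln$states)
  expect_identical(aln2$codons, aln$codons)
  expect_identical(aln2$taxa, aln$taxa)
})

test_that("codon frequencies: uniform, F3x4, F61 behave as defined", {
  u <- codon_frequencies(mode = "uniform")
  expect_equal(unname(u$pi), rep(1 / 61, 61))

  atg <- read_codon_alignment(c(">a", "ATGATG", ">b", "ATGATG"))
  f34 <- codon_frequencies(atg, "F3x4")
  expect_equal(unname(f34$pi[["ATG"]]), 1)
  expect_equal(sum(f34$pi), 1, tolerance = 1e-12)

  mixed <- read_codon_alignment(c(">a", "ATGAAATTTCCC", ">b",
                                  "ATGAAGTTCCCA"))
  for (mode in c("F3x4", "F61")) {
    f <- codon_frequencies(mixed, mode)
    expect_equal(sum(f$pi), 1, tolerance = 1e-12)
    expect_true(all(f$pi >= 0))
  }
  f61 <- codon_frequencies(mixed, "F61")
  expect_true(all(f61$pi > 0))  # pseudocount keeps unseen codons positive

  expect_error(codon_frequencies(mode = "F61"), "non-empty")
})

test_that("rate matrix obeys the single-step GY structure", {
  gc <- standard_genetic_code()
  u <- uniform_pi()
  Q <- build_rate_matrix(2, 0.5, u)
  i <- match("AAA", gc$sense_codons)
  # synonymous transition AAA->AAG vs nonsynonymous transversion AAA->AAC
  expect_equal(Q$Q[i, match("AAG", gc$sense_codons)] /
               Q$Q[i, match("AAC", gc$sense_codons)], 4,
               tolerance = 1e-12)
  # multi-nucleotide change has rate zero
  expect_identical(Q$Q[i, match("ACC", gc$sense_codons)], 0)
  expect_lt(max(abs(rowSums(Q$Q))), 1e-10)
  # unit expected rate under default scaling
  expect_equal(-sum(Q$pi * diag(Q$Q)), 1, tolerance = 1e-10)

  # kappa = omega = 1, uniform pi: all single-step rates equal
  Q1 <- build_rate_matrix(1, 1, u)
  off <- Q1$Q[row(Q1$Q) != col(Q1$Q)]
  pos <- off[off > 0]
  expect_lt(diff(range(pos)), 1e-14)

  expect_error(build_rate_matrix(0, 1, u), "kappa")
  expect_error(build_rate_matrix(2, -1, u), "omega")
})

test_that("detailed balance holds for random parameters", {
  set.seed(1)
  for (i in 1:5) {
    piv <- runif(61); piv <- piv / sum(piv)
    Q <- build_rate_matrix(runif(1, 0.3, 8), runif(1, 0, 3), piv)
    F <- Q$pi * Q$Q
    expect_lt(max(abs(F - t(F))), 1e-10)
  }
})

test_that("transition matrices are stochastic and consistent", {
  Q <- build_rate_matrix(2.5, 0.3, uniform_pi())
  expect_equal(transition_matrix(Q, 0), diag(61), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- transition_matrix(Q, 1e-6)
  expect_lt(max(abs(P - (diag(61) + Q$Q * 1e-6))), 1e-9)
  # Chapman-Kolmogorov via independent exponentiations
  expect_lt(max(abs(transition_matrix(Q, 0.3) %*%
                    transition_matrix(Q, 0.2) -
                    transition_matrix(Q, 0.5))), 1e-8)
  for (t in c(0.01, 0.5, 3, 20)) {
    Pt <- transition_matrix(Q, t)
    expect_lt(max(abs(rowSums(Pt) - 1)), 1e-10)
    expect_gte(min(Pt), 0)
  }
  expect_error(transition_matrix(Q, -0.1), "non-negative")
})
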