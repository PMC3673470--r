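---
title: "Site-model selection inference and conservation indices: methods"
author: "codonsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-model selection inference and conservation indices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science and of the
numerical choices behind it.  It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The substitution model

All models are Goldman–Yang-style Markov codon models on the 61 sense
codons of the standard genetic code, indexed in lexicographic order
over the base alphabet T, C, A, G (the dominant convention of
codon-model software; `standard_genetic_code()` documents the order).
The instantaneous rate from codon *i* to *j* is zero when the codons
differ at more than one nucleotide position and otherwise

  q_ij ∝ π_j · κ^[transition] · ω^[nonsynonymous],

with κ the transition/transversion rate ratio and ω = dN/dS the
nonsynonymous/synonymous ratio.  Equilibrium codon frequencies π come
from the alignment: `F3x4` (position-specific nucleotide frequencies,
the default), `F61` (observed codon proportions, 0.5 pseudocount so
unseen codons keep mass), or `uniform`.  Zero entries of π are floored
at 1e-12 inside `build_rate_matrix()` so the reversible symmetrization
stays defined; `codon_frequencies()` itself reports exact values.
Which frequency model best matches any given published analysis is
generally unknowable from reported tables; F3x4 is a default, not a
reproduction guarantee.

Transition probabilities P(t) = exp(Qt) are computed through the
symmetric eigendecomposition of D^{1/2} Q D^{-1/2} (D = diag π), with
a scaling-and-squaring fallback on numerical failure.  Tiny negative
entries from round-off are clipped to zero.

**Rate scaling.**  A single-class matrix is scaled to one expected
substitution per codon per unit branch length.  Mixture models divide
*all* class matrices by one shared factor — the weight-averaged
expected rate over classes (background ω on branch models) — so that a
branch length means "expected substitutions per codon under the
weighted model" and low-ω classes correctly evolve more slowly than
high-ω classes.  This mixture-level calibration is used exactly by the
simulator and by exact-likelihood fits; the accelerated fitting path
freezes the factor at the M0 fit's value (below).

## The model zoo and its tests

* **M0** — one ω for all sites and branches.
* **M7** — ω ~ Beta(p, q) across sites, discretized into K
  equal-probability categories represented by their conditional means
  (`discretize_beta()`; the means average exactly to p/(p+q)).
  K = 10 by default, the de-facto standard; configurable.
* **M8** — M7 plus an extra class: proportion p_s = 1 − p0 of sites
  with ω_s ≥ 1.  (Some reference implementations also allow an
  unconstrained-ω_s variant that can fit ω_s < 1; this package keeps
  the ω_s ≥ 1 constraint of the positive-selection test and documents
  the difference.)
* **M8a** — M8 with ω_s = 1 fixed: the boundary null of the
  M8-vs-M8a test.
* **Branch-site model A (revised)** — four site classes; class 0 has
  ω0 < 1 everywhere, class 1 is neutral everywhere, classes 2a/2b keep
  their background behaviour (ω0 or 1) on background branches but take
  ω2 ≥ 1 on designated foreground branches.  Proportions are
  parameterized by (p0, p1) with the 2a/2b remainder split
  proportionally.  The null fixes ω2 = 1.
* **Two-ratio** — one site class, separate foreground and background ω.

Likelihoods use Felsenstein pruning over site patterns, in log space
with per-node scaling (no underflow for trees of ≥ 1000 taxa); missing
triplets (gaps/ambiguity) are marginalized.  Any triplet containing a
non-ACGT character becomes missing — the package does not reproduce
manual alignment curation, so ambiguity is handled by marginalization
rather than by removal.  Unrooted trees are used as parsed (basal
multifurcation); reversibility makes the likelihood root-invariant,
which the tests verify against the pulley principle.

Likelihood-ratio tests use fixed df by variant pair: M7 vs M8 → χ²₂
(M8 adds p_s and ω_s); M8 vs M8a, branch-site A, and two-ratio → χ²₁.
The χ²₁ reference for the boundary nulls (ω_s = 1, ω2 = 1) is the
conventional, conservative choice and is the default; a 50:50
χ²₀:χ²₁ mixture option (`boundary_mix`) is provided and is *not* the
default.

## Fitting: exact path and curve path

`fit()` maximizes the exact mixture likelihood with bounded
multi-start `nlminb`: log scale for κ, ω and beta shapes; natural
scale with *closed* box bounds for proportions (p0 ∈ [0, 1]) and the
boundary-constrained ω_s, ω2 ∈ [1, 15] — so every nested null is an
exactly reachable point of its alternative's parameter space.
Convergence uses |Δℓ| relative tolerance 1e-9; results are
bit-reproducible given the seed.  Branch lengths are handled by
`branch_mode`: `"joint"` (every length free), `"scale"` (a single rate
multiplier on the input tree's relative lengths), or `"fixed"`.

The production ladder `fit_site_models()` is designed for replicated
studies:

1. Fit M0 with κ, ω and a tree scale free (`"scale"`; input trees
   carry estimated branch lengths, so re-estimating only an overall
   rate is the pragmatic default — full joint optimization remains
   available through `fit()`).
2. Freeze κ, the branch lengths and the rate calibration
   c0 = r_syn + ω̂_M0 · r_ns at the M0 estimates.
3. Precompute, for every site, the single-class log-likelihood on a
   120-point ω grid, log-spaced on [1e-9, 15], and interpolate with a
   natural cubic spline in log ω (per-site curves share one knot
   vector, so the spline solve is a single matrix operation).  Because
   each class's likelihood depends only on its ω once the calibration
   is frozen, any M7/M8/M8a parameter vector is then evaluated by
   interpolation plus a log-sum-exp mix — thousands of optimizer
   evaluations cost what two pruning passes would.
4. Fit M7, M8a, M8 over the curve with multi-starts; M8 is
   additionally warm-started from the M7 (p0 = 1) and M8a (ω_s = 1)
   solutions, which lie on its boundary, and is never reported below
   them.  This makes the nesting inequalities ℓ(M8) ≥ ℓ(M7), ℓ(M8) ≥
   ℓ(M8a) hold numerically, not just asymptotically.

The curve is an approximation: against exact pruning at matched
parameters the interpolated total log-likelihood agrees to ~1e-3 units
on a 500-codon alignment (tested at 2e-3 per site-class value), far
inside the tolerances of any statistical statement made here.  Exact
and curve fits are cross-checked in the test suite.  Freezing the
mixture-scale factor at c0 instead of re-solving it per candidate
mixture changes only an overall branch-time calibration, which the M0
scale estimate has already absorbed; the simulator, by contrast,
always applies the exact mixture-level scaling of its generative
model.

`fit_branch_models()` runs M0, then the two-ratio and branch-site A
models with κ and branch lengths frozen at M0 (exact likelihoods, no
curve — foreground/background structure breaks the one-dimensional ω
dependence), each alternative warm-started from its null and
boundary-guarded the same way.

## Posteriors, conservation, disease mutations

NEB posteriors plug the MLE weights into Bayes' rule per site.  BEB
averages the same posterior over an 11 × 11 uniform grid on
(p0, ω_s) — midpoints of [0, 1] for p0 and of [1, 11] for ω_s — with
beta shapes held at their MLEs and grid points weighted by the
alignment's marginal likelihood.  This is a documented simplification
of the reference Bayes-empirical-Bayes scheme (which also integrates
the beta shapes); posterior *standard errors* are out of scope.
Posteriors and everything downstream are computed from the M8 fit for
every data set, significant or not; LRT significance is carried as a
separate flag.

Per site, ω̄ = Σ_k PP_k ω_k; the conservation index is
CI = 1 − ω̄ if ω̄ < 1, else 0 (equivalently max(0, 1 − ω̄)).  The
minimum-ω category accumulates posterior mass from the lowest ω class
upward and takes the first class where it exceeds `pp_threshold`
(default 0.95; the final class if never exceeded); category ω <
`low_omega` (default 0.25) flags significant purifying selection.

Coordinates are 1-based throughout; amino-acid and codon sites map
one-to-one.  A disease-mutation position is a coordinate in the
*ungapped* reference sequence and is mapped to its alignment column by
skipping reference gap columns — the simplest defensible convention
when the variant table and the alignment use the same isoform.
Records beyond the reference length are skipped with a warning; a
mismatch between the stated reference amino acid and the translated
reference codon flags the record (`ref_aa_match = FALSE`) without
dropping it, since variant tables are often keyed to a different
assembly or isoform.  External classifier scores are a pass-through
column only.

## Multiple testing

Tests are grouped into named hypothesis families (families may share
members; the overlapping membership is reported once per family).  The
default correction is Benjamini–Hochberg step-up, implemented via
`stats::p.adjust` and verified in the tests against an independent
step-up rejection-set oracle and against worked-example family
corrections; those worked examples (families of 2, 12 and 14 related
tests) are reproduced exactly by BH.  A Holm step-down option is
provided for designs whose reported corrections follow step-down
arithmetic; the package defaults to BH rather than guessing intent
per family.

## The synthetic-data generator

`simulate_alignment()` draws a class per site i.i.d. from the mixture
weights (the site-model assumption — deliberately matching the
inference model, with no ω autocorrelation along the sequence), the
root codon from π, and child states down the tree from the class- and
branch-appropriate transition matrices; branch-site classes 2a/2b use
ω2 on foreground branches.  Missing-state injection is exact and
optional; no stop codon can ever be generated.  All randomness in a
call flows from one seed; fixtures carry their seeds in header lines.

`synthetic_study_manifest()` fixes the default study conditions:
3 genes, 16 taxa, 400 codons, branch lengths averaging 0.15
substitutions/codon (mammal-wide divergence scale), κ = 2.5, and an
M8 generative mixture Beta(0.2, 2) (mean ω ≈ 0.09, heavily
concentrated near zero) with p0 = 0.95 and ω_s = 1.8 — i.e., genes
dominated by strong purifying selection with a small positively
selected fraction, the regime the conservation index is built for.
Six synthetic disease mutations per gene are placed at
lowest-ω-class sites with probability 0.9 (uniformly otherwise),
emulating the enrichment of disease alleles at conserved sites.

What the generator does **not** emulate: indels and alignment error,
manual removal of ambiguous regions, ω autocorrelation, lineage-
specific convergence, isoform/assembly coordinate mismatches.  Passing
tests therefore demonstrate correctness of the inference machinery
under its own assumptions, not robustness to real-data pathologies.

## Test design and problem sizes

The statistical suites run at sizes chosen to make replicated
maximum-likelihood fitting routine on a single core: the null-
calibration suite uses 50 replicates of 8 taxa × 200 codons simulated
under M8a (the M8-vs-M8a test, nominally conservative at the ω_s = 1
boundary under χ²₁, must reject at α = 0.05 in at most 8% of
replicates); the recovery suite uses 50 seeds of 16 taxa × 500 codons
under M8 with p_s = 0.10, ω_s = 2.0 (median ω̂_s must fall in
[1.5, 2.5] and the LRT must reject in the majority); the end-to-end
conservation suite runs the default synthetic study and requires ≥90%
of truly-lowest-class sites that reach the PP > 0.95 categorization to
have CI ≥ 0.9, and enriched synthetic disease mutations to be more
conserved than uniform controls.  `scripts/acceptance.R` recomputes
the same quantities at moderate replicate counts, seeded from its
`--seed` argument.

## Known limitations

* No tree topology inference and no empirical codon matrices,
  dN/dS counting methods, or episodic-selection models.
* The BEB grid fixes the beta shapes at their MLEs; uncertainty in
  (p, q) is not propagated.
* κ and branch lengths are frozen after M0 in the production ladder; a
  full joint re-optimization per model is available through `fit()`
  but is substantially slower.
* The conservation index inherits the limitations of ω̄: it measures
  long-term average constraint, not episodic or compensatory dynamics.
* `--threads` in the CLI is accepted for interface compatibility;
  computation is single-threaded, so results are trivially independent
  of it.
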