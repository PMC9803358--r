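---
title: "Detecting convergent evolutionary rate shifts for a binary phenotype"
author: "rershift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent evolutionary rate shifts for a binary phenotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A trait such as mammalian hairlessness that arose independently in several
lineages leaves a molecular footprint: genomic elements whose function is
tied to the trait tend to change their evolutionary rate on exactly the
branches where the trait changed. `rershift` implements the full analysis
chain for detecting that footprint from per-element phylogenetic trees: the
branch lengths of an element's tree measure how much that element changed
along each lineage, and the question is whether, after removing each
element's overall rate and each branch's expected rate, the residual rate is
systematically higher (or lower) on the foreground branches carrying the
phenotype.

The package ships the 62-species mammal tree with average branch lengths as
its coordinate system, a species table with the hairless/marine
classification, and a synthetic-data generator that plants known rate shifts
so every stage of the pipeline can be validated end to end without any
external download.

## Branch coordinates and foreground assignment

All branch-indexed vectors live on the master tree. The printed topology has
a trifurcating root, so branches are "all non-root nodes": `2n - 3 = 121`
branches for `n = 62` tips, enumerated in the cladewise order of the parsed
Newick (deterministic given the string). Terminal branches are named by
their tip; an internal branch is named
`"<alphabetically first descendant tip>.<descendant count>"`, which is
unique because clades are either nested or disjoint.

A binary phenotype is a set of foreground branches: the extant carriers plus
ancestral branches added by backpropagation (an internal branch is
foreground when *all* its descendant tips are). Two deliberate exceptions to
the plain rule, both taken from the biology rather than the algorithm:

* the elephant–manatee ancestor is forced to background even though both
  daughters are hairless — extinct woolly mammoths show the elephant lineage
  was haired after that split, so two independent losses are the
  parsimonious reading (`assign_foreground(exclude = ...)`);
* the marine foreground adds only the cetacean (dolphin–orca) ancestor, not
  the ancestor of the walrus–seal cherry, which was plausibly amphibious.

This yields the 11-branch hairless foreground (10 extant + 1 ancestral) and
a 6-branch marine foreground used throughout.

## Relative evolutionary rates

For an element with branch lengths \(b\) on the master topology pruned to
its species (suppressed nodes' lengths summed), with pruned master lengths
\(m\):

1. both length vectors are square-root transformed. Branch lengths are
   substitution counts, whose variance grows with their mean
   (Poisson-like); the square root approximately stabilizes that variance,
   which is the "mean–variance correction" this kind of analysis requires;
2. a through-origin scale \(\lambda_e = \sum\sqrt{m b}/\sum m\) captures the
   element's overall rate (no intercept: a zero-length master branch
   predicts a zero-length element branch);
3. the raw relative rate of branch \(i\) is the residual
   \(r_i = \sqrt{b_i} - \lambda_e \sqrt{m_i}\);
4. each branch's residuals are divided by their standard deviation across
   elements, making rates comparable between branches. Branches present in
   fewer than 10 elements are set missing rather than normalized against
   noise. Elements with fewer than `min_species = 10` species are skipped.

Division without centering follows the construction above — the residual
means are already near zero (at 10,000 null elements the largest per-branch
mean magnitude is ~0.03) and centering would hide genuine per-branch
composition effects.

One consequence of cross-element standardization worth knowing: when a
substantial fraction of elements carries a planted (or real) foreground
shift, those elements inflate the foreground branches' SD, which compresses
the *null* elements' foreground rates and makes their association p-values
conservative. Calibration is exact under a fully null generator (the test
suite checks KS uniformity at 2,000 elements) and errs toward fewer false
positives under contamination.

### Body size as a confounder

Several hairless mammals are huge (elephant, rhino, whales), so rate effects
correlated with body size could masquerade as hairlessness effects. Log
adult weight (weights span five orders of magnitude, hence the log) is
reconstructed over the whole tree by maximum likelihood under Brownian
motion — generalized least squares with the tree covariance, equivalent to
the joint likelihood maximizer, with the value at each branch's child node
used as that branch's covariate — and regressed out of each element's rates
by ordinary least squares; the residuals are the body-size-corrected rates.

This linear correction neutralizes moderate confounding: with the
generator's default multiplicative body-size effect (`confounder_slope =
0.02`, about a 1.3-fold rate spread across the observed weight range,
which matches the magnitude of body-size-linked rate variation in mammals),
type-I error on confounded null elements returns to the nominal level. A
much stronger multiplicative effect leaves a nonlinear residue a linear
regression cannot remove entirely — a known limitation shared by the
original design.

## Association and permulation p-values

Per element, Kendall's tau-b between rates and the 0/1 foreground indicator
over non-missing branches, with a two-sided p from the tie-corrected normal
approximation (ties are unavoidable: the indicator is binary). Tau-b rather
than tau-a so the heavy indicator ties enter the denominator. The
implementation is an O(n log n) rank-sum form verified in the tests to be
numerically identical to `cor.test` and to brute-force pair enumeration.
Benjamini–Hochberg correction is applied across elements (genes and
noncoding elements are intended to be corrected as separate result sets).

Parametric p-values are calibrated only if the element-level null really is
exchangeable, which phylogenetic correlation violates; hence *permulations*:
null phenotypes that preserve the species relationships. A null phenotype is
drawn by simulating a Brownian motion trait on the master tree (rate 1 —
only tip ranks matter), marking the 10 largest tips foreground, and
backpropagating; the draw is accepted only when exactly one ancestral branch
turns foreground, matching the observed 11/1 structure. Rejection sampling
is the simplest mechanism that guarantees the structure exactly; the
acceptance rate (~0.2 on this tree) is recorded. With 1,000 nulls the
smallest observable empirical p is 1/1000, and zero counts are reported at
that floor.

The empirical p is the proportion of null statistics *as extreme or more
extreme* than the observed one, compared by magnitude (`|null| >= |obs|`),
with the statistic's sign carrying direction. A sign-directional variant is
available (`alternative = "directional"`), but its null support is
(0, 0.5], so the magnitude comparison is the default — it is the definition
under which null permulation p-values are uniform, which is what the Q-Q
diagnostic (`qq_uniformity`) assumes.

## Bayes factors for confounded phenotypes

Nearly all marine mammals in the alignment are hairless, so the two
phenotypes are heavily confounded. Per element, the package computes the
Jeffreys–Zellner–Siow Bayes factor of
\(\text{indicator} \sim \text{intercept} + \text{RER}\) against the
intercept-only model, for each phenotype, and their ratio; a ratio of 5 or
more counts as strong hairless-specific support. The binary indicator as the
*response* of a linear model is statistically odd but is exactly the model
contrasted here, kept for faithfulness to the analysis it reproduces.

The BF is computed by one-dimensional adaptive quadrature of the
mixture-of-g representation (Cauchy prior scale \(\sqrt{2}/2\) on the
standardized slope, inverse-gamma(1/2, \(n r^2/2\)) mixing density),
evaluated on the log-g scale with the integrand shifted by its mode for
numerical stability; the tests pin it to an independent dense-grid
trapezoid integration at 1e-6 relative error. The BF depends on the data
only through \(R^2\) and \(n\), and is invariant to affine rescaling of the
rates.

## Geneset enrichment

Elements are ranked by `sign(statistic) * (-log p)` (natural log; parametric
p of exactly zero falls back to the floored permulation p). Read literally,
"sign times log p" would rank strong accelerations *lowest*; the package
uses the orientation under which larger scores mean stronger acceleration
and keeps the literal form behind `literal = TRUE`.

Each annotation set with at least `min_set = 10` scored members is compared
to the background by Wilcoxon rank-sum; the reported statistic is
\(U/(n_1 n_2) - 0.5\), i.e. AUC − 0.5: +0.5 when every member outranks every
background element, −0.5 for the reverse, 0 for no enrichment. The test is
two-sided, direction read off the statistic's sign. Set-level permulation
p-values recompute the AUC statistic under every null phenotype from the
cached element-level null statistics — the same nulls as the element tests,
so set-level correlation among member elements is respected.

Noncoding elements are attached to genes and microRNAs by proximity: an
element maps to every target within 10,000 bases (boundary inclusive,
distance zero when overlapping, strand ignored), via `GenomicRanges`.

## Species-specific shifts

For each hairless species individually, each element is tested by a
two-sided one-sample Wilcoxon signed-rank of background-minus-focal rate
differences. Because all differences share the focal draw, this test flags
any element whose focal rate sits away from the background median — it is
deliberately generous per species (under the null roughly 40% of elements
are flagged per species at \(\alpha = 0.05\)), and the information is in the
*convergence*: the Fisher-exact enrichment of the hair geneset as a function
of the minimum number of species sharing a shift strengthens with the
cutoff, while the \(k = 1\) odds ratio is undefined because nearly every
element has at least one flagged species. A calibrated alternative
(`method = "outlier_rank"`, the rank of the focal value within the
background, uniform under exchangeability) is provided for per-species
inference. The significance threshold defaults to \(\alpha = 0.05\).

## Conserved noncoding element construction

From scored conservation intervals (BED, 0-based half-open): remove any
interval overlapping a coding region (whole-element removal, not trimming),
keep score strictly greater than 350 (applied before merging), merge
intervals less than 10 bp apart (gap 0–9; adjacency merges), and drop
merged elements shorter than 40 bp. The result is idempotent and
order-independent; merged elements carry the maximum constituent score.

## The synthetic generator

`simulate_elements` draws, per element, an overall rate \(r_e\) (log-normal,
sdlog 0.5 — about the cross-gene rate spread seen in mammalian gene sets),
then sets branch lengths
\(b = r_e\, m_b\, (1+\delta)^{\mathbb 1[\text{fg} \wedge \text{responsive}]}
e^{\varepsilon}\), \(\varepsilon \sim N(0, \sigma^2)\), with independent
species dropout. Multiplicative log-normal noise keeps lengths positive and
heteroskedastic, matching the premise of the square-root correction. The
planted study conditions used throughout the tests and the analysis scripts
are \(\delta = 1\) (doubled foreground rate), \(\sigma = 0.1\), 5% dropout,
25% responsive elements, on the 11-branch hairless foreground;
`simulate_confounded` adds the body-size multiplier described above.

What the generator does *not* emulate: alignment and tree-estimation error,
gene-tree/species-tree discordance, correlated rate variation among
neighboring elements, and lineage-specific (non-convergent) shifts. Passing
tests therefore demonstrate the statistical machinery under the model's own
assumptions, not robustness to everything real data do.

## Numerical and design notes

* Seeds are explicit arguments everywhere randomness occurs; fixed seed
  implies byte-identical outputs.
* Degenerate inputs: constant rate vectors give `NA` association statistics
  and BF 1 (with a warning); all-zero difference vectors give `NA` species
  shifts; branches with zero cross-element variance are set missing with a
  warning.
* Score ties in enrichment use midranks; where a total order is needed the
  tie-break is statistic magnitude, then element id.
* Problem sizes in the test suite — 2,000 elements for calibration, 10,000
  for the standardization property, 400–1,000 for recovery, 500–1,000
  permulations — were chosen as the smallest sizes at which the binomial and
  KS bounds being asserted are informative.
* `run_pipeline()` orchestrates rer → covariate regression → association →
  permulation → Bayes factors → enrichment → species tests and writes every
  table with its seed and parameters in header comments; the numbered
  scripts under `analysis/` are thin narrative drivers over the same
  functions.
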