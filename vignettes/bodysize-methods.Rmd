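---
title: "Reconstructing body-size evolution on time-scaled fossil phylogenies"
author: "paleosize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing body-size evolution on time-scaled fossil phylogenies}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(paleosize)
```

This vignette is the package's account of the methods it implements, the
choices made where the underlying procedures leave genuine freedom, and
what the test suite does and does not establish.

## The analysis in one paragraph

Rhabdodontidae is a small clade of ornithopod dinosaurs endemic to the
Late Cretaceous European archipelago: *Rhabdodon* in the west, *Mochlodon*
and *Zalmoxes* in the east.  Because these islands' faunas are a classic
hunting ground for insular dwarfism, the question is whether *Zalmoxes*
(maximum femora 320–333 mm) is small relative to the clade's ancestral
condition.  The package answers it by (i) building a reference phylogeny
of 25 basal ornithopods from morphological parsimony results plus
published insertions for dryosaurids and basal ankylopollexians, (ii)
calibrating it against time from stratigraphic-range midpoints, and (iii)
reconstructing ancestral log10 maximum femur lengths by weighted
squared-change parsimony.  Run end to end (`run_bodysize_evolution()` on
the packaged fixtures, or `scripts/acceptance.R`), the pipeline
reconstructs ≈340 mm at the Rhabdodontidae node and ≈242 mm at the
*Mochlodon* node; replacing the single *Rhabdodon* terminal by small
(210 mm) and large (820 mm) sister species lowers the rhabdodontid
ancestor to ≈305 mm.

## Parsimony engine

Characters are state *sets*: a fixed cell is a singleton, a polymorphic
cell (`{01}` or `(01)`) its members, and missing (`?`) or inapplicable
(`-`) cells the full alphabet of their character — the standard scoring
convention, under which missing data can never add steps.  Unordered
characters cost 1 per change; ordered characters cost |i−j|.  Scoring uses
a bitmask Fitch pass for unordered characters on binary trees and Sankoff
dynamic programming (exact on polytomies and for ordered costs)
everywhere else; both kernels are compiled.  The test suite pins both
against complete enumeration of internal-node assignments on trees of up
to 8 tips.

Heuristic search is classical: random addition sequences, then
first-improvement branch swapping in a seeded, shuffled rearrangement
order — so results are exactly reproducible given a seed — with TBR moves
implemented as subtree pruning plus rerooting of the pruned part, and an
optional parsimony ratchet (double the weight of a random quarter of the
characters, swap, restore, swap).  All distinct optimal topologies
reachable through equal-length rearrangements are collected up to a cap
(default 20,000).  `branch_and_bound()` provides a provably exact
reference for up to 12 taxa and anchors a 50-seed equality property in the
acceptance suite.

Ensemble indices follow their definitions: CI = Σmᵢ/L, HI = 1 − CI,
RI = (Σgᵢ − L)/(Σgᵢ − Σmᵢ), RC = CI·RI, with mᵢ the minimum conceivable
steps of character *i* on any tree (a minimum hitting-set computation over
state sets; an interval computation for ordered characters) and gᵢ its
steps on the star tree.  Characters with gᵢ = mᵢ cannot retain synapomorphy
and are excluded from the RI sums — algebraically identical to the usual
convention of including them, since they always realise exactly mᵢ steps.
Inactive or zero-weight characters are excluded throughout.

Unambiguous synapomorphies are defined strictly: a change is reported on a
branch only if *every* most-parsimonious reconstruction, on every supplied
tree, places the same single derived state at the child end and a
different state at the parent end.  This is computed from Sankoff
subtree-cost tables plus an outside-cost pass (so it implies agreement of
accelerated and delayed transformation), not from any one arbitrary
optimisation.

## Time-scaling

`date_basic()` assigns each node the age of its oldest descendant tip —
the minimal stratigraphically consistent calibration, which necessarily
leaves zero-length branches wherever a node's age is inherited from a
child.  `date_equal()` then adds a root length (default 10 My, the
conventional arbitrary choice) to the root age and lets each maximal chain
of zero-length branches share the duration of its nearest positive
ancestral branch equally: a chain of *k* zero branches plus its donor is
re-divided into *k*+1 equal durations, applied root-to-tips so that
earlier reallocations can feed later chains.  Tip ages never move; all
durations come out strictly positive; every root-to-tip path sums to root
age minus tip age (both properties are enforced over hundreds of random
trees in the tests).

One genuine degree of freedom survives in this procedure: the *order* in
which zero branches are resolved.  Resolving each maximal chain in one
step (`order = "chain"`, the default) spreads the donor evenly along the
chain; resolving one branch at a time rootward-first (`order = "branch"`)
halves the donor repeatedly, concentrating time near the root of the
chain.  Historical implementations of this method are sensitive in
exactly this way because they process zero branches in input-file edge
order.  Both orderings are exposed and both are exercised by the
acceptance suite: for the split-*Rhabdodon* analysis they give ≈305 mm and
≈297 mm at the Rhabdodontidae node, bracketing the value a user of the
original tooling would obtain.  Where two chains hang from one donor, the
preorder-first chain is resolved first; the sibling branch then becomes
positive as a consequence, which also settles how a split terminal's two
equal-aged tips are handled (the "individual vs joint sharing" question
has one coherent answer in the chain formulation).

## Weighted squared-change parsimony

Given strictly positive durations, the reconstruction minimises
Σ_branches (x_child − x_parent)²/duration.  The optimum is characterised
by stationarity — each internal value is the 1/duration-weighted mean of
its neighbours — and is found exactly by solving the corresponding linear
system; no iteration, no tolerance beyond machine arithmetic.  The tests
verify stationarity to 1e-10, agreement with a general-purpose numeric
minimiser to 1e-8, agreement of the root state with the
generalised-least-squares Brownian estimate computed by explicit
covariance algebra, affine equivariance, and unbiased root recovery over
500 Brownian simulations (within three Monte-Carlo standard errors).

The analysis scale is log10 femur length, the transform the comparative
table itself stores; states are back-transformed (10^x) only for
reporting, rounded to the nearest mm.  `simulate.scp_fit()` turns a fit
into a parametric bootstrap generator using the fitted root and the mean
squared change per My as the Brownian rate.

## The reference topology and data fixtures

The 25-taxon backbone is data, not code
(`inst/extdata/ornithopod_backbone.nwk`), assembled from the stated
sources: rhabdodontids as (*Rhabdodon*, (*Mochlodon*, *Zalmoxes*)), sister
to *Tenontosaurus* + (Dryosauridae + Ankylopollexia); a jeholosaurid
clade, *Hypsilophodon*, the *Thescelosaurus*–*Parksosaurus* pair,
*Gasparinisaura* and *Talenkauen* arranged pectinately below; the
dryosaurid ladder (*Callovosaurus* basal) and the ankylopollexian ladder
(*Camptosaurus* basal).  The resolution of the non-rhabdodontid backbone
is not fully recoverable from prose, so the shipped tree is the
text-compatible resolution that best reproduces the published ancestral
states; users can substitute any topology with the same labels, e.g.:

```{r alternatives, eval = FALSE}
alt <- read_newick("...your resolution...")
run_bodysize_evolution(load_femur_table(), alt)$mrca
```

The femur table keeps all 27 comparative rows; the primary analysis uses
the 25 that appear in the backbone — one *Rhabdodon* terminal at the genus
maximum (820 mm), leaving the *R. priscus* (600 mm) and small-form
(210 mm) rows unused until the split variant.  The element table keeps the
one specimen excluded from the femur analysis (a specifically
indeterminate *Zalmoxes* humerus), since it still calibrates element
proportions.  Both tables retain their decimal-comma typography to
exercise the parser flag that normalises it.

## Body-length chain

Proportion ratios are calibrated from the measurement table's own
(element, femur, body) triples — one reference row per (species, element),
preferring directly measured over estimated lengths, else the largest
element.  Body length is femur length times the per-species body:femur
ratio, rounded half-up to 0.1 m to match the table's presentation; before
rounding the chain is exactly linear in element length.  The per-row
implied body:femur ratios all fall in 7.0–7.7, but no single ratio
reproduces every printed value across species — `ratio_audit()` reports
the residual one-decimal mismatches (7 of 28 rows) rather than forcing
them; all six *Mochlodon vorosi* rows are reproduced exactly, which is the
within-species consistency the calibration is designed around.

## Synthetic data: what the tests do and do not show

`random_dated_tree()` draws uniform (or Yule) topologies with tip ages
uniform on 66–163 Ma — the stratigraphic span of the packaged ornithopod
table — and dates them with the same basic + equal-sharing procedure used
for real data, so generated trees satisfy the dating invariants by
construction.  `simulate_characters()` uses a per-branch Bernoulli change
to a uniformly chosen different state; it makes no claim to be a
realistic model of morphological evolution (no Mk likelihood, no
rate heterogeneity, no correlated characters).  Its zero-homoplasy mode
places each character's single change on its own branch, which guarantees
the generating tree attains the conceivable minimum length with CI = 1 —
ideal for search verification because the optimum is known, but easier
than real matrices, whose homoplasy and missing data create many optima
and rugged search landscapes.  The noisy-model searches are therefore
checked against exact branch-and-bound instead.  Passing these tests
shows the algorithms are correct; it does not show that a heuristic search
with any particular settings will conquer a given hard empirical matrix.

Test and acceptance problem sizes are deliberate package choices: search
verification at 19 × 79 (unordered) and 58 × 233 (with a leading
all-zero dummy column stripped on input and six ordered characters),
exact-vs-heuristic equality over 50 random matrices of 8–10 taxa,
squared-change properties on 10-tip trees, dating properties on 200
random trees, and 500 Brownian replicates for root recovery.

## Known limitations

* Search rearrangements are generated in R around compiled scoring; large
  matrices (hundreds of taxa) would want compiled neighbourhoods and
  incremental scoring as well.
* Bootstrap support uses light per-replicate searches by default;
  supports on hard matrices are conservative.
* No implied weighting, no likelihood or Bayesian inference, no
  stochastic (cal3 / fossilized birth–death) time-scaling, and no
  confidence intervals on ancestral states — the reconstruction is a
  point estimate, and squared-change parsimony shares Brownian motion's
  tendency to pull extremes toward the mean (visible in how strongly the
  820 mm *Rhabdodon* terminal is discounted across its long terminal
  branch).
* The dating order question above is irreducible without the original
  input files; both orderings are reported rather than adjudicated.
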