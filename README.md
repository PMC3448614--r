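# paleosize

Quantitative reconstruction of body-size evolution in fossil vertebrates,
built around the rhabdodontid ornithopod dinosaurs of the Late Cretaceous
European archipelago.  The scientific question the package serves: were the
small-bodied eastern rhabdodontids (*Zalmoxes*, *Mochlodon*) island dwarfs,
or does the ancestral body size reconstructed for Rhabdodontidae show that
only *Rhabdodon* departed from the plesiomorphic condition, as an
autapomorphic giant?  Answering it takes a chain of standard but rarely
co-packaged paleo-phylogenetic steps, all provided here for reuse on other
clades:

1. **Maximum-parsimony phylogenetics** for morphological matrices: Fitch and
   ordered (|i−j| cost) Sankoff optimisation, random-addition TBR heuristic
   search with a parsimony ratchet, exact branch-and-bound for small
   matrices, ensemble indices (CI, HI, RI, RC), strict and reduced
   consensus, nonparametric bootstrap, and unambiguous synapomorphy
   mapping.
2. **Paleontological time-scaling** ("equal" method): tips dated at
   stratigraphic range midpoints, node ages from the oldest-descendant
   rule, then an arbitrary root length (default 10 My) shared equally along
   chains of zero-length branches so that every branch has positive
   duration.
3. **Weighted squared-change parsimony** ancestral states for continuous
   traits: internal values minimising Σ (Δx)²/Δt over branches, solved
   exactly as a sparse linear system; equivalent to maximum-likelihood
   ancestral states under Brownian motion.  Applied to log10 maximum femur
   length (mm) and back-transformed for reporting.
4. **Ratio-based body-size estimation**: incomplete skeletal element →
   complete element length → femur-equivalent length → total body length,
   calibrated per species from reference specimens.
5. **Synthetic data generators** (trees with fossil-like tip ages, Brownian
   traits, discrete character matrices with optional zero-homoplasy
   construction) so every stage is testable against known ground truth.

The package ships its study data as plain-text fixtures: the comparative
ornithopod femur/age table, the rhabdodontid skeletal-element measurement
table, and the 25-taxon reference topology (rhabdodontids nested among
basal ornithopods with dryosaurid and basal ankylopollexian insertions).

## Worked example

```r
library(paleosize)

tab  <- load_femur_table()     # 27 taxa: max femur (mm), log10, age (Ma)
tree <- load_backbone_tree()   # 25-taxon reference topology

res <- run_bodysize_evolution(tab, tree, root_length = 10,
         split = list(taxon = "Rhabdodon_sp",
                      labels = c("Rhabdodon_small_sp", "Rhabdodon_large_sp"),
                      femur_mm = c(210, 820), age = c(71, 71)))
print(res$fit)
#> Weighted squared-change parsimony fit
#>   trait: log10 max femur length (mm); 25 tips, 24 internal nodes
#>   minimised cost: 0.0259531 (trait^2/My); mean rate 0.000540689 per My
#>   root state: 2.43103 (back-transformed: 269.791)
round(res$mrca)
#> Rhabdodontidae      Mochlodon
#>            340            242
round(res$mrca_split)
#> Rhabdodontidae      Mochlodon
#>            305            238
```

The primary analysis reconstructs an ancestral femur of ~340 mm for
Rhabdodontidae — squarely in the 320–333 mm range of *Zalmoxes* itself, so
no support for *Zalmoxes* dwarfing — and ~242 mm for *Mochlodon*, a mild
decrease.  Splitting the *Rhabdodon* terminal into its small (210 mm) and
large (820 mm) adult forms lowers the rhabdodontid ancestor to ~305 mm,
still far above a dwarfing scenario, while *Rhabdodon* itself stands out as
an autapomorphic giant.

A parsimony search on simulated data with known truth:

```r
sim <- random_dated_tree(12, seed = 7)
cm  <- simulate_characters(sim$tree, 22, zero_homoplasy = TRUE, seed = 8)
hs  <- heuristic_search(cm, n_addition_sequences = 5, seed = 9, ratchet = 1)
print(hs)
#> Maximum-parsimony search result
#>   matrix: 12 taxa x 22 characters
#>   best length: 22 steps; 1 most-parsimonious topology
#>   CI = 1.000  HI = 0.000  RI = 1.000  RC = 1.000
```

And the body-length chain audit on the measurement table:

```r
print(ratio_audit(load_element_table()))
#> Body:femur ratio audit (28 rows; band 7.0-7.7)
#>   implied ratios 7.10-7.62; 0 outside band; 21/28 printed body lengths
#>   reproduced at 0.1 m
#>   ...
```

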