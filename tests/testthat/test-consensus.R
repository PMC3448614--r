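test_that("strict consensus of identical trees is that tree", {
  tr <- rand_topo(8)
  cons <- strict_consensus(list(tr, tr, tr))
  expect_equal(paleosize:::topology_key(cons), paleosize:::topology_key(tr))
})

test_that("conflicting clades collapse to a polytomy", {
  t1 <- read_newick("(((A,B),C),D);")
  t2 <- read_newick("(((A,C),B),D);")
  cons <- strict_consensus(list(t1, t2))
  # only the ABC clade survives; AB vs AC conflict collapses
  keys <- paleosize:::clade_keys(cons, nontrivial = TRUE)
  expect_equal(keys, paste(c("A", "B", "C"), collapse = "\r"))
})

test_that("consensus clades are contained in every input tree", {
  set.seed(401)
  for (i in 1:20) {
    trees <- replicate(4, rand_topo(9), simplify = FALSE)
    # share a common backbone half the time
    if (i %% 2 == 0) trees <- c(trees, trees[1])
    cons <- strict_consensus(trees)
    ck <- paleosize:::clade_keys(cons, nontrivial = TRUE)
    for (tr in trees)
      expect_true(all(ck %in% paleosize:::clade_keys(tr, nontrivial = TRUE)) ||
                  length(ck) == 0)
  }
})

test_that("strict consensus is idempotent", {
  set.seed(402)
  trees <- replicate(5, rand_topo(8), simplify = FALSE)
  c1 <- strict_consensus(trees)
  c2 <- strict_consensus(list(c1, c1))
  expect_equal(paleosize:::topology_key(c2), paleosize:::topology_key(c1))
})

test_that("differing tip sets are rejected", {
  expect_error(strict_consensus(list(rand_topo(6),
                                     rand_topo(6, labels = letters[1:6]))),
               "tip sets")
})

test_that("pruning a rogue taxon restores resolution", {
  # two trees differing only in where the rogue R sits
  cons <- strict_consensus(list(
    read_newick("(((((A,B),C),D),R),E);"),
    read_newick("((((A,B),C),(D,R)),E);")))
  red <- reduced_consensus(list(
    read_newick("(((((A,B),C),D),R),E);"),
    read_newick("((((A,B),C),(D,R)),E);")), prune = "R")
  n_clades <- function(tr) length(paleosize:::clade_keys(tr, nontrivial = TRUE))
  expect_gte(n_clades(red), n_clades(cons))
  expect_true(ape::is.binary(red))
})

test_that("pruning an absent taxon changes nothing; overpruning errors", {
  trees <- replicate(3, rand_topo(7), simplify = FALSE)
  a <- strict_consensus(trees)
  b <- reduced_consensus(trees, prune = "not_here")
  expect_equal(paleosize:::topology_key(a), paleosize:::topology_key(b))
  expect_error(reduced_consensus(trees, prune = paste0("t", 1:5)),
               "fewer than 3")
})

test_that("clade count never drops after pruning rogues (random sets)", {
  set.seed(403)
  for (i in 1:10) {
    base <- rand_topo(8)
    base7 <- write_newick(ape::drop.tip(base, "t8"))
    trees <- lapply(1:4, function(k) {
      # graft the wildcard as sister to a random tip by newick surgery
      host <- sample(paste0("t", 1:7), 1)
      read_newick(sub(paste0("\\b", host, "\\b"),
                      paste0("(", host, ",t8)"), base7))
    })
    n_clades <- function(tr) length(paleosize:::clade_keys(tr, nontrivial = TRUE))
    cons_all <- strict_consensus(trees)
    red <- reduced_consensus(trees, prune = "t8")
    cons_restricted <- ape::drop.tip(cons_all, "t8")
    expect_gte(n_clades(red), n_clades(cons_restricted))
  }
})

test_that("bootstrap support separates clean signal from noise", {
  sim <- random_dated_tree(7, seed = 411)
  base <- simulate_characters(sim$tree, 12, zero_homoplasy = TRUE, seed = 412)
  set.seed(410)
  clean <- character_matrix(base$cells[, sample(12, 60, replace = TRUE)],
                            taxa = base$taxa)
  hs <- heuristic_search(clean, n_addition_sequences = 2, seed = 413,
                         keep_all_mpts = FALSE)
  ref <- strict_consensus(hs$trees)
  bs_clean <- bootstrap_support(clean, ref, replicates = 30, seed = 414)
  expect_true(all(bs_clean$support >= 0 & bs_clean$support <= 100))
  expect_gte(mean(bs_clean$support), 95)

  set.seed(415)
  noise_cells <- matrix(as.character(sample(0:1, 7 * 60, replace = TRUE)),
                        7, 60, dimnames = list(sim$tree$tip.label, NULL))
  noise <- character_matrix(noise_cells)
  bs_noise <- bootstrap_support(noise, ref, replicates = 30, seed = 416)
  expect_lt(mean(bs_noise$support), mean(bs_clean$support) - 30)

  # determinism under a fixed seed
  bs2 <- bootstrap_support(clean, ref, replicates = 30, seed = 414)
  expect_equal(bs_clean, bs2)
  expect_error(bootstrap_support(clean, ref, replicates = 0), "replicates")
})
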