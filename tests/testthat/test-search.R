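test_that("heuristic search recovers the generating tree on clean data", {
  sim <- random_dated_tree(10, seed = 301)
  cm <- simulate_characters(sim$tree, 18, zero_homoplasy = TRUE, seed = 302)
  hs <- heuristic_search(cm, n_addition_sequences = 4, seed = 303)
  expect_equal(hs$length, sum(paleosize:::min_steps_per_char(cm)))
  expect_equal(hs$indices$CI, 1)
  # the true unrooted topology is among the MPTs
  true_key <- paleosize:::st_key(
    paleosize:::st_from_phylo(sim$tree, cm$taxa), length(cm$taxa))
  found_keys <- vapply(hs$trees, function(t)
    paleosize:::st_key(paleosize:::st_from_phylo(t, cm$taxa),
                       length(cm$taxa)), "")
  expect_true(true_key %in% found_keys)
})

test_that("search is deterministic under a fixed seed", {
  sim <- random_dated_tree(8, seed = 311)
  cm <- simulate_characters(sim$tree, 12, change_prob = 0.3, seed = 312)
  a <- heuristic_search(cm, n_addition_sequences = 3, seed = 99, ratchet = 1)
  b <- heuristic_search(cm, n_addition_sequences = 3, seed = 99, ratchet = 1)
  expect_equal(a$length, b$length)
  expect_equal(lapply(a$trees, paleosize:::topology_key),
               lapply(b$trees, paleosize:::topology_key))
  expect_equal(a$log, b$log)
})

test_that("branch and bound enumerates exactly on tiny cases", {
  # 4 taxa, constant matrix: all 3 unrooted topologies tie at length 0
  cm <- character_matrix(matrix("0", 4, 3), taxa = LETTERS[1:4])
  bb <- branch_and_bound(cm)
  expect_equal(bb$length, 0)
  expect_equal(bb$mpt_count, 3)
  expect_error(branch_and_bound(
    character_matrix(matrix("0", 13, 2), taxa = letters[1:13])), "12 taxa")
})

test_that("heuristic search equals branch and bound on random instances", {
  set.seed(321)
  for (s in 1:10) {
    n <- if (s > 8) 10 else 8
    sim <- random_dated_tree(n, seed = 321 + s)
    cm <- simulate_characters(sim$tree, 15, change_prob = 0.3,
                              missing_fraction = 0.1, seed = 351 + s)
    hs <- heuristic_search(cm, n_addition_sequences = 6, seed = s,
                           ratchet = 2, keep_all_mpts = FALSE)
    bb <- branch_and_bound(cm, upper_bound = hs$length)
    expect_equal(hs$length, bb$length, info = paste("seed", s))
  }
})

test_that("MPT collection respects the cap and flags truncation", {
  # a maximally uninformative matrix has very many equal-length trees
  cm <- character_matrix(matrix("0", 7, 2), taxa = letters[1:7])
  hs <- heuristic_search(cm, n_addition_sequences = 1, seed = 5, cap = 10)
  expect_lte(hs$mpt_count, 10)
  expect_true(hs$truncated)
})

test_that("ratchet escapes a poor starting tree", {
  sim <- random_dated_tree(12, seed = 331)
  cm <- simulate_characters(sim$tree, 40, change_prob = 0.25, seed = 332)
  hs0 <- heuristic_search(cm, n_addition_sequences = 1, seed = 7,
                          swap = "spr", ratchet = 0, keep_all_mpts = FALSE)
  hs1 <- heuristic_search(cm, n_addition_sequences = 1, seed = 7,
                          swap = "spr", ratchet = 3, keep_all_mpts = FALSE)
  expect_lte(hs1$length, hs0$length)
})

test_that("searches refuse degenerate inputs", {
  expect_error(heuristic_search(
    character_matrix(matrix("0", 3, 2), taxa = letters[1:3])), "4 taxa")
})
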