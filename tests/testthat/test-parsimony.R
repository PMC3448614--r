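test_that("character_length matches hand-derived toy scores", {
  tr <- read_newick("((A,B),(C,D));")
  expect_equal(character_length(tr, c(A = 0, B = 0, C = 1, D = 1)), 1L)
  expect_equal(character_length(tr, c(A = 0, B = 1, C = 1, D = 0)), 2L)
  expect_equal(character_length(read_newick("(A,B);"), c(A = 0, B = 2),
                                ordered = TRUE), 2L)
  expect_equal(character_length(tr, c(A = 1, B = 1, C = 1, D = 1)), 0L)
  # polymorphic tip can avoid the change
  expect_equal(character_length(tr, c(A = 0, B = 0, C = "{01}", D = 0)), 0L)
  # missing data never adds steps
  expect_equal(character_length(tr, c(A = 0, B = "?", C = 1, D = "?")), 1L)
})

test_that("scores equal exhaustive enumeration on random instances", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    tr <- rand_topo(n)
    ns <- sample(2:3, 1)
    toks <- setNames(random_tokens(n, ns = ns), tr$tip.label)
    for (ordd in c(FALSE, TRUE)) {
      got <- character_length(tr, toks, ordered = ordd)
      want <- brute_force_steps(tr, toks, ordered = ordd)
      expect_equal(got, want,
                   info = sprintf("i=%d ordered=%s toks=%s", i, ordd,
                                  paste(toks, collapse = " ")))
    }
  }
})

test_that("scores are exact on polytomous trees too", {
  set.seed(203)
  tr <- read_newick("((A,B,C),(D,E),F);")
  for (i in 1:15) {
    toks <- setNames(random_tokens(6, ns = 3), tr$tip.label)
    for (ordd in c(FALSE, TRUE))
      expect_equal(character_length(tr, toks, ordered = ordd),
                   brute_force_steps(tr, toks, ordered = ordd))
  }
})

test_that("tree_length sums characters, respects weights/activity, and is column-order invariant", {
  tr <- read_newick("((A,B),(C,D));")
  cells <- rbind(A = c("0", "0"), B = c("0", "1"), C = c("1", "1"),
                 D = c("1", "0"))
  cm <- character_matrix(cells)
  expect_equal(tree_length(tr, cm), 3)
  cm_rev <- character_matrix(cells[, 2:1])
  expect_equal(tree_length(tr, cm_rev), 3)
  cm_w <- character_matrix(cells, weights = c(2, 1))
  expect_equal(tree_length(tr, cm_w), 4)
  cm_off <- character_matrix(cells, active = c(FALSE, TRUE))
  expect_equal(tree_length(tr, cm_off), 2)
  expect_error(tree_length(read_newick("((A,B),(C,E));"), cm), "mismatch.*E")
})

test_that("adding a character adds at least its minimum steps to any tree", {
  set.seed(204)
  for (i in 1:10) {
    n <- 7
    tr <- rand_topo(n)
    cells <- matrix(random_tokens(n * 5, ns = 2, p_poly = 0, p_missing = 0.2),
                    n, 5)
    cm <- character_matrix(cells, taxa = tr$tip.label)
    extra <- random_tokens(n, ns = 3, p_poly = 0.1)
    cm2 <- character_matrix(cbind(cells, extra), taxa = tr$tip.label)
    m_extra <- paleosize:::min_steps_per_char(
      character_matrix(matrix(extra, ncol = 1), taxa = tr$tip.label))
    expect_gte(tree_length(tr, cm2), tree_length(tr, cm) + m_extra)
  }
})

test_that("ensemble indices follow their definitions", {
  # homoplasy-free matrix: CI = 1, HI = 0
  tr <- read_newick("((A,B),(C,D));")
  cm <- character_matrix(rbind(A = c("0", "0"), B = c("0", "0"),
                               C = c("1", "0"), D = c("1", "1")))
  L <- tree_length(tr, cm)
  ix <- ensemble_indices(cm, L)
  expect_equal(ix$CI, 1)
  expect_equal(ix$HI, 0)

  # hand case: one character A0 B0 C1 D1 E1, m = 1, g = 2; on a tree
  # realising 1 step RI = (2-1)/(2-1) = 1
  tr5 <- read_newick("((A,B),(C,(D,E)));")
  cm5 <- character_matrix(matrix(c("0", "0", "1", "1", "1"), ncol = 1,
                                 dimnames = list(c("A", "B", "C", "D", "E"))))
  expect_equal(paleosize:::min_steps_per_char(cm5), 1L)
  expect_equal(paleosize:::star_steps_per_char(cm5), 2L)
  L5 <- tree_length(tr5, cm5)
  expect_equal(L5, 1)
  expect_equal(ensemble_indices(cm5, L5)$RI, 1)

  # the same character on a tree where it needs 2 steps: RI = 0
  tr5b <- read_newick("((A,C),(B,(D,E)));")
  expect_equal(ensemble_indices(cm5, tree_length(tr5b, cm5))$RI, 0)

  expect_error(ensemble_indices(cm5, 0), "impossible")
})

test_that("indices agree with phangorn on a random binary matrix", {
  skip_if_not_installed("phangorn")
  set.seed(205)
  n <- 8
  tr <- rand_topo(n)
  cells <- matrix(as.character(sample(0:1, n * 20, replace = TRUE)), n, 20)
  cm <- character_matrix(cells, taxa = tr$tip.label)
  rownames(cells) <- tr$tip.label
  pd <- phangorn::phyDat(cells, type = "USER", levels = c("0", "1"))
  expect_equal(tree_length(tr, cm), phangorn::parsimony(tr, pd))
  L <- tree_length(tr, cm)
  ix <- ensemble_indices(cm, L)
  expect_equal(ix$CI, phangorn::CI(tr, pd), tolerance = 1e-9)
  expect_equal(ix$RI, phangorn::RI(tr, pd), tolerance = 1e-9)
})

test_that("ordered characters accumulate |i-j| costs", {
  tr <- read_newick("((A,B),(C,D));")
  # each cherry mixes 0 and 2, so each costs 2 regardless of topology
  expect_equal(character_length(tr, c(A = 0, B = 2, C = 2, D = 0),
                                ordered = TRUE), 4L)
  # grouping the extremes lets one 0->2 transition serve the whole clade
  expect_equal(character_length(tr, c(A = 2, B = 2, C = 0, D = 0),
                                ordered = TRUE), 2L)
  # unordered treats 0->2 as a single step
  expect_equal(character_length(tr, c(A = 0, B = 2, C = 2, D = 0)), 2L)
})
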