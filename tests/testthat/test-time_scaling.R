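test_that("midpoint ages are the arithmetic midpoint and validate ranges", {
  expect_equal(unname(midpoint_ages(data.frame(taxon = "s", oldest = 86.3,
                                               youngest = 83.6))), 84.95)
  expect_equal(unname(midpoint_ages(list(x = c(70, 70)))), 70)
  expect_error(midpoint_ages(data.frame(taxon = "bad", oldest = 60,
                                        youngest = 70)), "inverted")
  set.seed(501)
  for (i in 1:20) {
    y <- runif(1, 60, 100); o <- y + runif(1, 0, 40)
    m <- unname(midpoint_ages(list(t = c(o, y))))
    expect_true(m >= y && m <= o)
  }
})

test_that("basic dating assigns oldest-descendant ages", {
  tr <- read_newick("((X,Y),Z);")
  dt <- date_basic(tr, c(X = 100, Y = 90, Z = 100))
  ages <- node_ages(dt, labels = FALSE)
  rt <- paleosize:::root_node(dt)
  expect_equal(ages[rt], 100)
  anc_xy <- ape::getMRCA(dt, c("X", "Y"))
  expect_equal(ages[anc_xy], 100)
  expect_true(any(dt$edge.length == 0))
  expect_error(date_basic(tr, c(X = 100, Y = 90)), "Z")

  # caterpillar over the packaged ages: root age equals the oldest tip
  tab <- load_femur_table()
  cat_tree <- read_newick(paste0(
    paste(rep("(", 26), collapse = ""), tab$taxon[1],
    paste(sprintf(",%s)", tab$taxon[-1]), collapse = ""), ";"))
  dt2 <- date_basic(cat_tree, setNames(tab$age_Ma, tab$taxon))
  expect_equal(max(node_ages(dt2)), 163)
  # no node younger than any descendant tip
  expect_true(all(dt2$edge.length >= 0))
})

test_that("equal sharing reproduces the worked three-tip example", {
  dt <- xyz_equal_tree(10)
  ages <- node_ages(dt, labels = FALSE)
  rt <- paleosize:::root_node(dt)
  expect_equal(ages[rt], 110)
  expect_equal(ages[ape::getMRCA(dt, c("X", "Y"))], 105)
  expect_true(all(dt$edge.length > 0))
  expect_equal(min(dt$edge.length), 5)
})

test_that("a tree without zero branches only has its root raised", {
  # oldest-descendant dating always leaves zero branches, so build a
  # strictly positive calibration by hand
  tr <- read_newick("((A,B),C);")
  tr$node.ages <- c(80, 70, 100, 120, 95)   # A B C root AB
  tr$edge.length <- tr$node.ages[tr$edge[, 1]] - tr$node.ages[tr$edge[, 2]]
  class(tr) <- c("dated_phylo", "phylo")
  eq <- date_equal(tr, root_length = 10)
  a2 <- node_ages(eq, labels = FALSE)
  rt <- paleosize:::root_node(tr)
  expect_equal(a2[rt], 130)
  keep <- setdiff(seq_along(a2), rt)
  expect_equal(a2[keep], tr$node.ages[keep])
})

test_that("equal dating yields strictly positive durations and conserves path lengths", {
  set.seed(502)
  for (i in 1:60) {
    n <- sample(4:25, 1)
    tr <- rand_topo(n)
    # clustered ages force long zero chains
    ages <- setNames(sample(seq(66, 163, by = 0.5), n, replace = TRUE),
                     tr$tip.label)
    dt <- date_equal(date_basic(tr, ages), root_length = 10)
    expect_true(all(dt$edge.length > 0))
    av <- node_ages(dt, labels = FALSE)
    rt <- paleosize:::root_node(dt)
    # tip ages unchanged, and every root-to-tip path sums to root - tip age
    expect_equal(av[seq_len(n)], unname(ages[dt$tip.label]))
    depth <- ape::node.depth.edgelength(dt)
    expect_equal(depth[seq_len(n)], av[rt] - av[seq_len(n)],
                 tolerance = 1e-9)
  }
})

test_that("iterative and recursive chain resolution agree", {
  # independent recursive re-implementation of the preorder chain rule
  recursive_equal <- function(basic, root_length) {
    tree <- paleosize:::reorder_cladewise(basic)
    age <- tree$node.ages
    rt <- paleosize:::root_node(tree)
    age[rt] <- age[rt] + root_length
    ch <- paleosize:::children_list(tree)
    pre <- c(rt, tree$edge[, 2])
    rank <- integer(length(age)); rank[pre] <- seq_along(pre)
    walk <- function(u) {
      for (v in (ch[[u]])[order(rank[ch[[u]]])]) {
        if (age[u] - age[v] <= 1e-9) {
          chain <- v
          repeat {
            kz <- ch[[chain[length(chain)]]]
            kz <- kz[age[chain[length(chain)]] - age[kz] <= 1e-9]
            if (!length(kz)) break
            chain <- c(chain, kz[which.min(rank[kz])])
          }
          p <- tree$edge[tree$edge[, 2] == u, 1]
          step <- (age[p] - age[chain[length(chain)]]) / (length(chain) + 1)
          age[u] <<- age[p] - step
          if (length(chain) > 1)
            for (k in seq_len(length(chain) - 1))
              age[chain[k]] <<- age[p] - (k + 1) * step
        }
        walk(v)
      }
    }
    walk(rt)
    age
  }
  set.seed(503)
  for (i in 1:15) {
    n <- sample(5:15, 1)
    tr <- rand_topo(n)
    ages <- setNames(sample(c(66, 71, 80, 84.5, 100), n, replace = TRUE),
                     tr$tip.label)
    basic <- date_basic(tr, ages)
    a1 <- node_ages(date_equal(basic, 10), labels = FALSE)
    a2 <- recursive_equal(basic, 10)
    expect_equal(a1, a2, tolerance = 1e-9, info = paste("tree", i))
  }
})

test_that("small root lengths approach basic ages in the limit", {
  # as root_length -> 0+ the time available to spread along zero chains
  # vanishes, so every node age approaches its basic (oldest-descendant)
  # value
  # nodes whose zero chain is fed only by the root stem collapse back to
  # their basic ages; chains fed by an interior donor keep sharing that
  # donor and are excluded from the property
  tr <- read_newick("((A,B),(C,D));")
  ages <- c(A = 80, B = 70, C = 100, D = 90)
  basic <- date_basic(tr, ages)
  eq <- date_equal(basic, root_length = 1e-7)
  a_eq <- node_ages(eq, labels = FALSE)
  a_b <- node_ages(basic, labels = FALSE)
  rt <- paleosize:::root_node(tr)
  cd <- ape::getMRCA(tr, c("C", "D"))
  expect_equal(a_eq[c(1:4, rt, cd)], a_b[c(1:4, rt, cd)], tolerance = 1e-6)
  expect_true(all(eq$edge.length > 0))
})

test_that("invalid root lengths and ages are rejected", {
  tr <- read_newick("((A,B),C);")
  expect_error(date_equal(tr, root_length = 0,
                          tip_ages = c(A = 1, B = 1, C = 1)), "root_length")
  expect_error(date_basic(tr, c(A = -5, B = 1, C = 1)), "positive")
})
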