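test_that("constant tips reconstruct constant, zero-cost states", {
  dt <- xyz_equal_tree()
  fit <- weighted_scp(dt, c(X = 2.5, Y = 2.5, Z = 2.5), backtransform = identity)
  expect_equal(unname(fit$node_states), rep(2.5, 5))
  expect_equal(fit$cost, 0)
})

test_that("closed-form small cases are exact", {
  # star tree, equal durations: root is the mean
  star <- read_newick("(A,B,C);")
  star$edge.length <- c(1, 1, 1)
  star$node.ages <- c(0, 0, 0, 1)
  class(star) <- c("dated_phylo", "phylo")
  fit <- weighted_scp(star, c(A = 0, B = 3, C = 6), backtransform = identity)
  expect_equal(unname(coef(fit)), 3)

  # two tips, durations 1 and 2: inverse-duration weighted mean
  two <- read_newick("(A,B);")
  two$edge.length <- c(1, 2)
  two$node.ages <- c(1, 0, 2)
  class(two) <- c("dated_phylo", "phylo")
  fit2 <- weighted_scp(two, c(A = 0, B = 6), backtransform = identity)
  expect_equal(unname(coef(fit2)), (0 / 1 + 6 / 2) / (1 / 1 + 1 / 2))
})

test_that("the reconstruction satisfies weighted-mean stationarity", {
  set.seed(601)
  for (i in 1:20) {
    sim <- random_dated_tree(sample(5:20, 1))
    x <- simulate_bm(sim$tree, root_value = 2.5, sigma2 = 0.01)$tips
    fit <- weighted_scp(sim$tree, x, backtransform = identity)
    tr <- fit$tree
    st <- fit$node_states
    nt <- ape::Ntip(tr)
    for (v in (nt + 1):(nt + tr$Nnode)) {
      nb <- c(tr$edge[tr$edge[, 1] == v, 2], tr$edge[tr$edge[, 2] == v, 1])
      bl <- c(tr$edge.length[tr$edge[, 1] == v],
              tr$edge.length[tr$edge[, 2] == v])
      expect_equal(st[v], sum(st[nb] / bl) / sum(1 / bl), tolerance = 1e-10)
    }
  }
})

test_that("scp_cost evaluates the objective and the optimum beats perturbations", {
  set.seed(602)
  sim <- random_dated_tree(8)
  x <- simulate_bm(sim$tree, 0, 1)$tips
  fit <- weighted_scp(sim$tree, x, backtransform = identity)
  nt <- ape::Ntip(sim$tree)
  opt_internal <- fit$node_states[(nt + 1):length(fit$node_states)]
  base <- scp_cost(sim$tree, x, opt_internal)
  expect_equal(base, fit$cost, tolerance = 1e-12)
  for (k in seq_along(opt_internal)) {
    for (eps in c(-1e-3, 1e-3)) {
      pert <- opt_internal
      pert[k] <- pert[k] + eps
      expect_gt(scp_cost(sim$tree, x, pert), base)
    }
  }
  expect_error(scp_cost(sim$tree, x, opt_internal[-1]), "internal values")
  expect_equal(scp_cost(xyz_equal_tree(),
                        c(X = 1, Y = 1, Z = 1), c(1, 1)), 0)
})

test_that("the exact solution matches a general-purpose optimizer", {
  set.seed(603)
  for (i in 1:50) {
    sim <- random_dated_tree(10)
    x <- simulate_bm(sim$tree, 2, 0.05)$tips
    fit <- weighted_scp(sim$tree, x, backtransform = identity)
    nt <- ape::Ntip(sim$tree)
    internal0 <- rep(mean(x), sim$tree$Nnode)
    opt <- optim(internal0, function(par) scp_cost(sim$tree, x, par),
                 method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 5000))
    expect_lte(fit$cost, opt$value + 1e-8)
    expect_equal(fit$cost, opt$value, tolerance = 1e-6)
  }
})

test_that("the root state equals the GLS/Brownian estimate", {
  set.seed(604)
  for (i in 1:12) {
    sim <- random_dated_tree(sample(4:8, 1))
    x <- simulate_bm(sim$tree, 1, 0.2)$tips
    fit <- weighted_scp(sim$tree, x, backtransform = identity)
    V <- ape::vcv(sim$tree)
    y <- x[rownames(V)]
    one <- rep(1, nrow(V))
    Vi <- solve(V)
    gls_root <- drop(solve(t(one) %*% Vi %*% one) %*% t(one) %*% Vi %*% y)
    rt <- paleosize:::root_node(sim$tree)
    expect_equal(fit$node_states[rt], gls_root, tolerance = 1e-8)
  }
})

test_that("reconstructions agree with an independent ML implementation", {
  skip_if_not_installed("phytools")
  set.seed(605)
  sim <- random_dated_tree(12)
  x <- simulate_bm(sim$tree, 2.5, 0.01)$tips
  fit <- weighted_scp(sim$tree, x, backtransform = identity)
  anc <- phytools::fastAnc(sim$tree, x)
  expect_equal(unname(coef(fit)), unname(anc[as.character(
    (ape::Ntip(sim$tree) + 1):(ape::Ntip(sim$tree) + sim$tree$Nnode))]),
    tolerance = 1e-6)
})

test_that("reconstruction is affine-equivariant", {
  set.seed(606)
  sim <- random_dated_tree(9)
  x <- simulate_bm(sim$tree, 0, 1)$tips
  f1 <- weighted_scp(sim$tree, x, backtransform = identity)
  f2 <- weighted_scp(sim$tree, 3.2 * x - 1.7, backtransform = identity)
  expect_equal(f2$node_states, 3.2 * f1$node_states - 1.7, tolerance = 1e-9)
})

test_that("zero-duration trees are refused with advice", {
  tr <- read_newick("((X,Y),Z);")
  basic <- date_basic(tr, c(X = 100, Y = 90, Z = 100))
  expect_error(weighted_scp(basic, c(X = 1, Y = 2, Z = 3)), "date_equal")
})

test_that("split_terminal replaces a tip by a cherry and updates traits", {
  tr <- load_backbone_tree()
  traits <- setNames(load_femur_table()$log10_femur, load_femur_table()$taxon)
  sp <- split_terminal(tr, "Rhabdodon_sp",
                       data.frame(label = c("small", "large"),
                                  age = c(71, 71),
                                  value = log10(c(210, 820))),
                       traits = traits)
  expect_equal(ape::Ntip(sp$tree), ape::Ntip(tr) + 1)
  expect_false("Rhabdodon_sp" %in% sp$tree$tip.label)
  expect_true(all(c("small", "large") %in% sp$tree$tip.label))
  expect_equal(unname(sp$traits[c("small", "large")]), log10(c(210, 820)))
  expect_error(split_terminal(tr, "nope", data.frame(
    label = c("a", "b"), age = c(1, 1), value = c(0, 0))), "not in tree")
  expect_error(split_terminal(tr, "Rhabdodon_sp", data.frame(
    label = c("Mochlodon_vorosi", "b"), age = c(1, 1), value = c(0, 0))),
    "duplicate")
})

test_that("splitting into two copies of the original value barely moves other nodes", {
  tab <- load_femur_table()
  tr <- load_backbone_tree()
  traits <- setNames(tab$log10_femur, tab$taxon)[tr$tip.label]
  ages <- setNames(tab$age_Ma, tab$taxon)[tr$tip.label]
  fit0 <- weighted_scp(date_equal(date_basic(tr, ages), 10), traits)
  v <- traits[["Rhabdodon_sp"]]
  sp <- split_terminal(tr, "Rhabdodon_sp",
                       data.frame(label = c("ra", "rb"),
                                  age = rep(ages[["Rhabdodon_sp"]], 2),
                                  value = c(v, v)), traits = traits)
  fit1 <- weighted_scp(date_equal(date_basic(
    sp$tree, c(ages[setdiff(names(ages), "Rhabdodon_sp")], sp$tip_ages)), 10),
    sp$traits)
  moch <- c("Mochlodon_suessi", "Mochlodon_vorosi")
  expect_equal(mrca_state(fit1, moch, backtransform = FALSE),
               mrca_state(fit0, moch, backtransform = FALSE),
               tolerance = 0.02)
})
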