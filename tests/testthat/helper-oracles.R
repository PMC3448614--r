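# Independent oracles used across the test files.  These deliberately share
# no code with the package's scoring path: state sets are re-parsed here and
# scores come from complete enumeration of internal-node assignments.

# state set (0-based integer vector) for a cell token, given alphabet size
oracle_state_set <- function(tok, ns) {
  if (tok %in% c("?", "-")) return(0:(ns - 1))
  as.integer(strsplit(gsub("[{}()]", "", tok), "")[[1]])
}

# exhaustive minimum steps of one character on a rooted tree: enumerate all
# internal-node state assignments and take the cheapest
brute_force_steps <- function(tree, tokens, ordered = FALSE) {
  tokens <- tokens[tree$tip.label]
  ns <- max(unlist(lapply(tokens[!tokens %in% c("?", "-")], function(t)
    oracle_state_set(t, 99))), 0) + 1L
  if (ns < 2) return(0L)
  nt <- ape::Ntip(tree)
  ntot <- nt + tree$Nnode
  tipsets <- lapply(tokens, oracle_state_set, ns = ns)
  cost <- function(a, b) if (ordered) abs(a - b) else as.integer(a != b)
  internal <- (nt + 1L):ntot
  grid <- rep(list(0:(ns - 1)), length(internal))
  best <- Inf
  # also enumerate tip choices for polymorphic/missing tips? equivalently,
  # per edge take the min cost over the tip's allowed states
  combos <- as.matrix(do.call(expand.grid, grid))
  for (r in seq_len(nrow(combos))) {
    assign <- combos[r, ]
    state_of <- function(v) assign[[v - nt]]
    tot <- 0
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]; c_ <- tree$edge[i, 2]
      sp <- state_of(p)
      tot <- tot + if (c_ <= nt) min(vapply(tipsets[[c_]], cost, 0L, a = sp))
                   else cost(sp, state_of(c_))
    }
    if (tot < best) best <- tot
  }
  as.integer(best)
}

# random cell tokens with controlled polymorphism/missingness
random_tokens <- function(ntaxa, ns = 3, p_poly = 0.15, p_missing = 0.15) {
  vapply(seq_len(ntaxa), function(i) {
    u <- runif(1)
    if (u < p_missing) sample(c("?", "-"), 1)
    else if (u < p_missing + p_poly && ns >= 2) {
      k <- sample(2:ns, 1)
      paste0("{", paste(sort(sample(0:(ns - 1), k)), collapse = ""), "}")
    } else as.character(sample(0:(ns - 1), 1))
  }, "")
}

rand_topo <- function(n, labels = paste0("t", seq_len(n))) {
  tr <- ape::rtopology(n, rooted = TRUE, tip.label = labels)
  tr$edge.length <- NULL
  tr
}

# the worked three-tip dating example used in several tests
xyz_equal_tree <- function(root_length = 10) {
  date_equal(read_newick("((X,Y),Z);"), root_length = root_length,
             tip_ages = c(X = 100, Y = 90, Z = 100))
}

# split specification of the Rhabdodon terminal used by the body-size tests
rhabdodon_split <- function() {
  list(taxon = "Rhabdodon_sp",
       labels = c("Rhabdodon_small_sp", "Rhabdodon_large_sp"),
       femur_mm = c(210, 820), age = c(71, 71))
}
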