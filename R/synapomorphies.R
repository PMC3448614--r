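# Unambiguous synapomorphy mapping: state changes present on a branch under
# *every* most-parsimonious character-state reconstruction, on every
# supplied most-parsimonious tree (hence under both accelerated and delayed
# transformation).

# Per-edge optimal (parent,child) state pairs for one character on one tree,
# via Sankoff subtree costs (up pass) plus an outside-cost down pass.
mpr_edge_pairs <- function(tree, tipmask, ns, ordered) {
  edge <- tree$edge
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  S <- .c_sankoff_table(edge, ntip, tipmask, ns, ordered)
  INF <- 2^28
  cost_ts <- function(t, s) if (ordered) abs(t - s) else (t != s) * 1L
  cmat <- outer(0:(ns - 1), 0:(ns - 1), function(a, b)
    if (ordered) abs(a - b) else (a != b) * 1L)

  ch <- children_list(tree)
  rt <- root_node(tree)
  # minc[[v]][t+1]: min over states s of (cost(t,s) + S[v,s])
  minc <- function(v) {
    vapply(1:ns, function(t1)
      min(cmat[t1, ] + pmin(S[v, ], INF)), 0)
  }
  O <- matrix(INF, ntot, ns)           # outside cost per node/state
  O[rt, ] <- 0
  pre <- c(rt, reorder_cladewise(tree)$edge[, 2])
  mc <- vector("list", ntot)
  get_mc <- function(v) {
    if (is.null(mc[[v]])) mc[[v]] <<- minc(v)
    mc[[v]]
  }
  for (u in pre) {
    kids <- ch[[u]]
    if (is.null(kids)) next
    sib_sum <- rowSums(do.call(cbind, c(list(rep(0, ns)),
                                        lapply(kids, get_mc))))
    for (v in kids) {
      # outside of v given v's parent state t: O[u,t] + sum of siblings' minc
      base_t <- O[u, ] + sib_sum - get_mc(v)
      O[v, ] <- vapply(1:ns, function(s1)
        min(base_t + cmat[, s1]), 0)
    }
  }
  Ltot <- min(O[rt, ] + vapply(1:ns, function(s) {
    kids <- ch[[rt]]
    sum(vapply(kids, function(v) get_mc(v)[s], 0))
  }, 0))

  pairs <- vector("list", nrow(edge))
  for (i in seq_len(nrow(edge))) {
    u <- edge[i, 1]; v <- edge[i, 2]
    kids <- ch[[u]]
    sib_sum <- rowSums(do.call(cbind, c(list(rep(0, ns)),
                                        lapply(kids, get_mc)))) - get_mc(v)
    tot <- outer(1:ns, 1:ns, function(t1, s1)
      O[u, t1] + sib_sum[t1] + cmat[cbind(t1, s1)] + pmin(S[v, s1], INF))
    opt <- which(tot <= min(tot) + 1e-9, arr.ind = TRUE)
    pairs[[i]] <- cbind(parent_state = opt[, 1] - 1L,
                        child_state = opt[, 2] - 1L)
  }
  list(pairs = pairs, length = Ltot)
}

#' Unambiguous synapomorphies across most-parsimonious trees
#'
#' For every branch (identified by the tip set of the clade it subtends)
#' reports the character-state changes that occur on that branch under
#' every most-parsimonious reconstruction of every supplied tree: the
#' child's state is the same single derived state in all optimal
#' reconstructions and differs from every optimal parent state.  Changes
#' whose optimisation is ambiguous (as is common with much missing data)
#' are excluded.
#'
#' @param trees one or more most-parsimonious trees (or a
#'   \code{parsimony_search}).
#' @param cm the \code{char_matrix} they were inferred from.
#' @return data frame of class \code{synapomorphy_map}: columns
#'   \code{clade} (comma-separated tips), \code{character} (1-based index),
#'   \code{derived_state} (symbol).
#' @export
unambiguous_synapomorphies <- function(trees, cm) {
  trees <- as_tree_list(trees)
  per_tree <- lapply(trees, synapomorphies_one_tree, cm = cm)
  tab <- per_tree[[1]]
  if (length(per_tree) > 1) {
    key <- function(d) paste(d$clade, d$character, d$derived_state)
    keep <- key(tab) %in% Reduce(intersect, lapply(per_tree, key))
    tab <- tab[keep, , drop = FALSE]
  }
  tab <- tab[order(tab$clade, tab$character), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("synapomorphy_map", class(tab))
  tab
}

synapomorphies_one_tree <- function(tree, cm) {
  masks <- align_matrix_tree(tree, cm)
  nt <- ape::Ntip(tree)
  splits <- clade_splits(tree)
  clade_of_node <- c(tree$tip.label,
                     vapply(splits, paste, "", collapse = ","))
  out <- list()
  for (j in seq_len(ncol(masks))) {
    if (!cm$active[j] || cm$weights[j] == 0) next
    ns <- cm$nstates[j]
    if (ns <= 1) next
    full <- bitwShiftL(1L, ns) - 1L
    if (all(masks[, j] == full)) next       # all-missing character
    mp <- mpr_edge_pairs(tree, masks[, j], ns, cm$ordered[j])
    for (i in seq_along(mp$pairs)) {
      p <- mp$pairs[[i]]
      derived <- unique(p[, "child_state"])
      if (length(derived) == 1 && all(p[, "parent_state"] != derived)) {
        v <- tree$edge[i, 2]
        out[[length(out) + 1]] <- data.frame(
          clade = clade_of_node[v], character = j,
          derived_state = cm$symbols[derived + 1L])
      }
    }
  }
  if (!length(out))
    return(data.frame(clade = character(0), character = integer(0),
                      derived_state = character(0)))
  do.call(rbind, out)
}

#' @export
print.synapomorphy_map <- function(x, max_tips = 4, ...) {
  cat("Unambiguous synapomorphies (", nrow(x), " changes)\n", sep = "")
  if (nrow(x)) {
    short <- vapply(strsplit(x$clade, ",", fixed = TRUE), function(tt)
      if (length(tt) > max_tips)
        paste0(paste(head(tt, max_tips), collapse = ","), ",... [",
               length(tt), " tips]")
      else paste(tt, collapse = ","), "")
    print(data.frame(clade = short, character = x$character,
                     state = x$derived_state), row.names = FALSE)
  }
  invisible(x)
}
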