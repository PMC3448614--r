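# Heuristic and exact maximum-parsimony tree search.
#
# Internal representation during search: a bare 1-based edge matrix.  Tips
# keep the row numbers they have in the character matrix; internal nodes are
# numbered upward from ntip+1 in order of creation (no ape renumbering until
# a tree leaves the search).  Scoring kernels accept any edge order.

st_root <- function(edge) setdiff(edge[, 1], edge[, 2])[1]

st_length <- function(edge, cm) {
  .c_tree_length(edge, length(cm$taxa), cm$masks, as.integer(cm$ordered),
                 as.integer(cm$nstates), cm$weights * cm$active)
}

# Unrooted-topology key: sorted bipartitions, each written as the side not
# containing the anchor (lowest-numbered tip present).
st_key <- function(edge, ntip) {
  ntot <- max(edge)
  below <- vector("list", ntot)
  tips_in <- sort(unique(edge[edge[, 2] <= ntip, 2]))
  anchor <- tips_in[1]
  for (t in tips_in) below[[t]] <- t
  ord <- postorder_rows(edge)
  for (i in ord) below[[edge[i, 1]]] <- c(below[[edge[i, 1]]], below[[edge[i, 2]]])
  parts <- character(0)
  for (i in seq_len(nrow(edge))) {
    v <- edge[i, 2]
    if (v <= ntip) next
    side <- sort(below[[v]])
    if (anchor %in% side) side <- setdiff(tips_in, side)
    if (length(side) > 1 && length(side) < length(tips_in) - 1)
      parts <- c(parts, paste(side, collapse = ","))
  }
  paste(sort(unique(parts)), collapse = "|")
}

# rows of `edge` in postorder (children before parents)
postorder_rows <- function(edge) {
  child_rows <- split(seq_len(nrow(edge)), edge[, 1])
  out <- integer(nrow(edge))
  k <- 0L
  # repeated sweep (trees are small): emit a row once its child subtree is done
  emitted <- rep(FALSE, nrow(edge))
  while (k < nrow(edge)) {
    prog <- FALSE
    for (i in seq_len(nrow(edge))) {
      if (emitted[i]) next
      v <- edge[i, 2]
      rows_v <- child_rows[[as.character(v)]]
      if (is.null(rows_v) || all(emitted[rows_v])) {
        k <- k + 1L; out[k] <- i; emitted[i] <- TRUE; prog <- TRUE
      }
    }
    if (!prog) stop("edge matrix is not a tree")
  }
  out
}

# Convert a search edge matrix to an ape phylo (tips renumbered 1..k in
# label order of the taxa present), rooted as stored.
st_to_phylo <- function(edge, taxa) {
  ntip <- length(taxa)
  lab <- character(max(edge))
  lab[seq_len(ntip)] <- taxa
  build <- function(v) {
    kids <- edge[edge[, 1] == v, 2]
    if (!length(kids)) return(lab[v])
    paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")")
  }
  nwk <- paste0(build(st_root(edge)), ";")
  ape::read.tree(text = nwk)
}

st_from_phylo <- function(tree, taxa) {
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) stop("tree contains taxa absent from matrix")
  edge <- tree$edge
  ntip_tree <- ape::Ntip(tree)
  map <- integer(ntip_tree + tree$Nnode)
  map[seq_len(ntip_tree)] <- idx
  map[(ntip_tree + 1):length(map)] <- length(taxa) + seq_len(tree$Nnode)
  cbind(map[edge[, 1]], map[edge[, 2]])
}

# Insert tip `t` on edge row `i` using fresh internal node id `newnode`.
st_insert <- function(edge, i, t, newnode) {
  a <- edge[i, 1]; b <- edge[i, 2]
  edge[i, ] <- c(a, newnode)
  rbind(edge, c(newnode, b), c(newnode, t))
}

# Detach the subtree under edge row `i`; returns list(rest, sub).
# The pruned node's parent is smoothed away (its other child is re-attached
# to the grandparent, or becomes the new root).
st_detach <- function(edge, i) {
  v <- edge[i, 2]; u <- edge[i, 1]
  ntot <- max(edge)
  in_sub <- rep(FALSE, ntot)
  in_sub[v] <- TRUE
  repeat {
    grow <- edge[in_sub[edge[, 1]] & !in_sub[edge[, 2]], 2]
    if (!length(grow)) break
    in_sub[grow] <- TRUE
  }
  sub_rows <- in_sub[edge[, 1]]
  sub <- edge[sub_rows, , drop = FALSE]
  rest <- edge[!sub_rows, , drop = FALSE]
  rest <- rest[-which(rest[, 1] == u & rest[, 2] == v), , drop = FALSE]
  sib_row <- which(rest[, 1] == u)
  par_row <- which(rest[, 2] == u)
  if (length(par_row)) {
    rest[par_row, 2] <- rest[sib_row, 2]
    rest <- rest[-sib_row, , drop = FALSE]
  } else {
    rest <- rest[-sib_row, , drop = FALSE]  # sibling becomes the new root
  }
  list(rest = rest, sub = sub, subroot = v)
}

# All rootings of a detached subtree: re-hang `sub` from a new basal node on
# each of its edges.  Returns list of list(sub, subroot).
st_rerootings <- function(sub, subroot, newnode) {
  out <- list(list(sub = sub, subroot = subroot))
  if (!nrow(sub)) return(out)
  for (i in seq_len(nrow(sub))) {
    s2 <- sub
    # reverse edges on the path from new basal edge to old root
    a <- s2[i, 1]; b <- s2[i, 2]
    s2 <- s2[-i, , drop = FALSE]
    # reorient: walk from a up to old subroot, flipping
    path <- integer(0)
    node <- a
    while (node != subroot) {
      r <- which(s2[, 2] == node)
      path <- c(path, r)
      node <- s2[r, 1]
    }
    if (length(path)) s2[path, ] <- s2[path, c(2, 1)]
    s2 <- rbind(s2, c(newnode, a), c(newnode, b))
    out[[length(out) + 1]] <- list(sub = st_suppress_unary(s2),
                                   subroot = newnode)
  }
  out
}

# Splice out internal nodes left with a single child (created by rerooting
# a subtree at one of its edges).
st_suppress_unary <- function(edge) {
  repeat {
    kids <- tabulate(edge[, 1], max(edge))
    unary <- which(kids == 1L)
    unary <- unary[unary %in% edge[, 2]]   # keep the root even if unary
    if (!length(unary)) return(edge)
    v <- unary[1]
    up <- which(edge[, 2] == v)
    down <- which(edge[, 1] == v)
    edge[up, 2] <- edge[down, 2]
    edge <- edge[-down, , drop = FALSE]
  }
}

# Reattach sub on edge row i of rest (or above the root when i == 0L),
# using fresh node id `newnode`.
st_attach <- function(rest, sub, subroot, i, newnode) {
  if (i == 0L) {
    rbind(rest, sub, c(newnode, st_root(rest)), c(newnode, subroot))
  } else {
    a <- rest[i, 1]; b <- rest[i, 2]
    rest[i, ] <- c(a, newnode)
    rbind(rest, sub, c(newnode, b), c(newnode, subroot))
  }
}

# Random-addition starting tree.
st_random_addition <- function(cm, order = NULL) {
  ntip <- length(cm$taxa)
  ord <- if (is.null(order)) sample.int(ntip) else order
  nextnode <- ntip + 1L
  edge <- rbind(c(nextnode, ord[1]), c(nextnode, ord[2]))
  for (k in 3:ntip) {
    t <- ord[k]
    nextnode <- nextnode + 1L
    best <- Inf; best_edge <- NULL
    rows <- sample.int(nrow(edge))
    for (i in rows) {
      cand <- st_insert(edge, i, t, nextnode)
      L <- st_length(cand, cm)
      if (L < best) { best <- L; best_edge <- cand }
    }
    edge <- best_edge
  }
  edge
}

# One TBR (or SPR) first-improvement pass.  Returns improved edge or NULL.
st_swap_once <- function(edge, cm, L0, tbr = TRUE) {
  ntip <- length(cm$taxa)
  prune_rows <- sample.int(nrow(edge))
  for (i in prune_rows) {
    det <- st_detach(edge, i)
    if (nrow(det$rest) < 2) next
    newnode <- max(edge) + 2L
    roots <- if (tbr && nrow(det$sub) > 2)
      st_rerootings(det$sub, det$subroot, newnode + 1L)
    else list(list(sub = det$sub, subroot = det$subroot))
    targets <- sample.int(nrow(det$rest))
    for (rr in roots) {
      for (ti in targets) {
        cand <- st_attach(det$rest, rr$sub, rr$subroot, ti, newnode)
        if (st_length(cand, cm) < L0) return(cand)
      }
    }
  }
  NULL
}

st_local_search <- function(edge, cm, tbr = TRUE) {
  L <- st_length(edge, cm)
  repeat {
    better <- st_swap_once(edge, cm, L, tbr = tbr)
    if (is.null(better)) break
    edge <- better
    L <- st_length(edge, cm)
  }
  list(edge = edge, length = L)
}

# Collect equal-length neighbours of a set of optimal trees (bounded BFS).
st_collect_mpts <- function(edges, cm, L, cap, tbr = TRUE, max_expand = 200L) {
  ntip <- length(cm$taxa)
  pool <- list(); keys <- character(0)
  queue <- list()
  for (e in edges) {
    k <- st_key(e, ntip)
    if (!k %in% keys) { keys <- c(keys, k); pool[[length(pool) + 1]] <- e
                        queue[[length(queue) + 1]] <- e }
  }
  truncated <- FALSE
  expanded <- 0L
  while (length(queue) && length(pool) < cap && expanded < max_expand) {
    edge <- queue[[1]]; queue[[1]] <- NULL
    expanded <- expanded + 1L
    for (i in seq_len(nrow(edge))) {
      det <- st_detach(edge, i)
      if (nrow(det$rest) < 2) next
      newnode <- max(edge) + 2L
      roots <- if (tbr && nrow(det$sub) > 2)
        st_rerootings(det$sub, det$subroot, newnode + 1L)
      else list(list(sub = det$sub, subroot = det$subroot))
      for (rr in roots) for (ti in seq_len(nrow(det$rest))) {
        cand <- st_attach(det$rest, rr$sub, rr$subroot, ti, newnode)
        if (st_length(cand, cm) == L) {
          k <- st_key(cand, ntip)
          if (!k %in% keys) {
            if (length(pool) >= cap) { truncated <- TRUE; break }
            keys <- c(keys, k)
            pool[[length(pool) + 1]] <- cand
            queue[[length(queue) + 1]] <- cand
          }
        }
      }
    }
  }
  if (length(queue) || expanded >= max_expand && length(pool) >= cap)
    truncated <- truncated || length(pool) >= cap
  list(pool = pool, truncated = truncated)
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition-sequence starting trees improved by first-improvement
#' branch swapping (TBR: tree bisection and reconnection, i.e. pruning with
#' rerooting of the pruned part; optionally plain SPR), optionally followed
#' by a parsimony ratchet (iterated reweight-swap-restore-swap) from the
#' best tree of each addition sequence.  Distinct optimal topologies are
#' collected up to a cap.  Fully reproducible under a fixed seed.
#'
#' @param cm a \code{char_matrix} (>= 4 taxa).
#' @param n_addition_sequences number of random addition replicates.
#' @param seed integer seed for the whole search.
#' @param swap \code{"tbr"} or \code{"spr"}.
#' @param ratchet number of ratchet iterations per addition sequence (0 to
#'   disable).
#' @param perturb_fraction fraction of active characters upweighted (x2)
#'   during a ratchet perturbation phase.
#' @param keep_all_mpts collect all distinct optimal topologies reachable
#'   through equal-length swaps (up to \code{cap}); otherwise only the
#'   distinct optima found directly.
#' @param cap maximum number of stored topologies.
#' @param outgroup taxon used to root reported trees (default the matrix's
#'   first taxon, the usual outgroup-first convention).
#' @param verbose print per-replicate progress.
#' @return an object of class \code{parsimony_search}: fields \code{trees}
#'   (a \code{multiPhylo}), \code{length}, \code{per_char_steps},
#'   \code{indices} (CI/HI/RI/RC), \code{mpt_count}, \code{truncated},
#'   \code{log} (per-replicate best lengths), \code{seed}.
#' @export
heuristic_search <- function(cm, n_addition_sequences = 10, seed = 1,
                             swap = c("tbr", "spr"), ratchet = 0,
                             perturb_fraction = 0.25, keep_all_mpts = TRUE,
                             cap = 20000, outgroup = cm$taxa[1],
                             verbose = FALSE) {
  swap <- match.arg(swap)
  ntip <- length(cm$taxa)
  if (ntip < 4) stop("need at least 4 taxa to search")
  set.seed(seed)
  tbr <- swap == "tbr"
  best_L <- Inf
  best_edges <- list()
  log <- data.frame(replicate = integer(0), phase = character(0),
                    length = numeric(0))
  for (rep_i in seq_len(n_addition_sequences)) {
    edge <- st_random_addition(cm)
    res <- st_local_search(edge, cm, tbr = tbr)
    log <- rbind(log, data.frame(replicate = rep_i, phase = "addseq+swap",
                                 length = res$length))
    if (ratchet > 0) {
      for (it in seq_len(ratchet)) {
        pick <- which(cm$active)
        up <- sample(pick, max(1, round(perturb_fraction * length(pick))))
        cm2 <- cm
        cm2$weights[up] <- cm2$weights[up] * 2
        pert <- st_local_search(res$edge, cm2, tbr = tbr)
        res2 <- st_local_search(pert$edge, cm, tbr = tbr)
        if (res2$length <= res$length) res <- res2
        log <- rbind(log, data.frame(replicate = rep_i,
                                     phase = sprintf("ratchet%02d", it),
                                     length = res$length))
      }
    }
    if (res$length < best_L - 1e-9) {
      best_L <- res$length
      best_edges <- list(res$edge)
    } else if (abs(res$length - best_L) <= 1e-9) {
      best_edges[[length(best_edges) + 1]] <- res$edge
    }
    if (verbose)
      message(sprintf("addseq %d: length %g (best %g)", rep_i, res$length, best_L))
  }
  truncated <- FALSE
  if (keep_all_mpts) {
    col <- st_collect_mpts(best_edges, cm, best_L, cap, tbr = tbr)
    pool <- col$pool
    truncated <- col$truncated
  } else {
    keys <- vapply(best_edges, st_key, "", ntip = ntip)
    pool <- best_edges[!duplicated(keys)]
  }
  finalize_search(pool, cm, best_L, truncated, log, seed, outgroup)
}

finalize_search <- function(pool, cm, L, truncated, log, seed, outgroup) {
  trees <- lapply(pool, st_to_phylo, taxa = cm$taxa)
  trees <- lapply(trees, function(tr)
    ape::root(tr, outgroup = outgroup, resolve.root = TRUE))
  class(trees) <- "multiPhylo"
  steps <- tree_length(trees[[1]], cm, per_character = TRUE)
  structure(list(
    trees = trees, length = L, per_char_steps = steps,
    indices = ensemble_indices(cm, L), mpt_count = length(trees),
    truncated = truncated, log = log, seed = seed,
    ntax = length(cm$taxa), nchar = ncol(cm$masks)
  ), class = "parsimony_search")
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("Maximum-parsimony search result\n")
  cat(sprintf("  matrix: %d taxa x %d characters\n", x$ntax, x$nchar))
  cat(sprintf("  best length: %g steps; %d most-parsimonious topolog%s%s\n",
              x$length, x$mpt_count, if (x$mpt_count == 1) "y" else "ies",
              if (x$truncated) " (capped)" else ""))
  ix <- x$indices
  cat(sprintf("  CI = %.3f  HI = %.3f  RI = %.3f  RC = %.3f\n",
              ix$CI, ix$HI, ix$RI, ix$RC))
  invisible(x)
}

#' @export
summary.parsimony_search <- function(object, ...) {
  print(object)
  cat("\nPer-character steps (first MPT):\n")
  print(table(object$per_char_steps))
  cat("\nSearch log:\n")
  print(utils::tail(object$log, 10))
  invisible(object)
}

#' Exact branch-and-bound maximum-parsimony search
#'
#' Enumerates addition positions depth-first, pruning partial trees whose
#' length already exceeds the best complete tree.  Guaranteed to find all
#' most-parsimonious topologies; feasible for small matrices only (<= 12
#' taxa).  Serves as the exact oracle for \code{\link{heuristic_search}}.
#'
#' @param cm a \code{char_matrix} with 4..12 taxa.
#' @param outgroup taxon used to root reported trees.
#' @param upper_bound optional known upper bound on the optimal length
#'   (e.g. from a heuristic run); partial trees longer than the current
#'   bound are pruned, so a valid bound only speeds the search up and
#'   cannot change the result.
#' @return a \code{parsimony_search} (with \code{log} recording the number
#'   of partial trees examined).
#' @export
branch_and_bound <- function(cm, outgroup = cm$taxa[1], upper_bound = Inf) {
  ntip <- length(cm$taxa)
  if (ntip < 4) stop("need at least 4 taxa")
  if (ntip > 12)
    stop("branch_and_bound is limited to 12 taxa (got ", ntip,
         "); use heuristic_search()")
  # order taxa by decreasing missingness-adjusted variability is overkill
  # here; fixed input order keeps the oracle simple and deterministic
  nextnode <- ntip + 1L
  base <- rbind(c(nextnode, 1L), c(nextnode, 2L))
  best <- new.env()
  best$L <- upper_bound
  best$pool <- list()
  best$keys <- character(0)
  best$visited <- 0L
  recurse <- function(edge, k, nextnode) {
    best$visited <- best$visited + 1L
    L <- st_length(edge, cm)
    if (L > best$L) return(invisible())
    if (k > ntip) {
      if (L < best$L) {
        best$L <- L; best$pool <- list(); best$keys <- character(0)
      }
      key <- st_key(edge, ntip)
      if (!key %in% best$keys) {
        best$keys <- c(best$keys, key)
        best$pool[[length(best$pool) + 1]] <- edge
      }
      return(invisible())
    }
    for (i in seq_len(nrow(edge)))
      recurse(st_insert(edge, i, k, nextnode), k + 1L, nextnode + 1L)
    invisible()
  }
  recurse(base, 3L, nextnode + 1L)
  log <- data.frame(replicate = 1L, phase = "branch_and_bound",
                    length = best$L)
  log$visited <- best$visited
  finalize_search(best$pool, cm, best$L, FALSE, log, NA_integer_, outgroup)
}
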