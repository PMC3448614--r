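# Consensus trees and bootstrap clade support.

#' Strict consensus of a set of trees
#'
#' The rooted tree containing exactly the clades present in every input
#' tree.
#'
#' @param trees a \code{multiPhylo} or list of rooted \code{phylo} objects
#'   on an identical tip set.
#' @return a rooted \code{phylo}, possibly polytomous.
#' @export
strict_consensus <- function(trees) {
  trees <- as_tree_list(trees)
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(tipsets, paste, "", collapse = "\r"))) != 1)
    stop("trees have differing tip sets")
  if (length(trees) == 1) return(trees[[1]])
  ape::consensus(trees, p = 1, rooted = TRUE)
}

#' Reduced strict consensus after pruning unstable taxa
#'
#' Prunes the listed taxa from every input tree (suppressing the resulting
#' degree-2 nodes), then takes the strict consensus.  Removing "wildcard"
#' taxa whose position varies across most-parsimonious trees typically
#' yields a much better resolved consensus for the remaining taxa.
#'
#' @param trees trees on an identical tip set.
#' @param prune character vector of taxa to drop (taxa absent from the
#'   trees are ignored).
#' @return a rooted \code{phylo}.
#' @export
reduced_consensus <- function(trees, prune) {
  trees <- as_tree_list(trees)
  keep <- setdiff(trees[[1]]$tip.label, prune)
  if (length(keep) < 3)
    stop("pruning would leave fewer than 3 taxa")
  pruned <- lapply(trees, function(t) {
    drop <- intersect(prune, t$tip.label)
    if (length(drop)) ape::drop.tip(t, drop) else t
  })
  strict_consensus(pruned)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "parsimony_search")) trees <- trees$trees
  trees <- unclass(trees)
  if (!length(trees)) stop("no trees supplied")
  lapply(trees, validate_phylo)
  trees
}

# Bipartition keys of a tree: each internal edge as the tip side not
# containing the anchor label, canonically sorted.  Root placement thus
# does not affect the key set.
bipart_keys <- function(tree, anchor = NULL) {
  labs <- sort(tree$tip.label)
  if (is.null(anchor)) anchor <- labs[1]
  nt <- ape::Ntip(tree)
  splits <- clade_splits(tree)
  keys <- character(0)
  for (s in splits) {
    side <- if (anchor %in% s) setdiff(labs, s) else s
    if (length(side) > 1 && length(side) < nt - 1)
      keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Nonparametric bootstrap clade support
#'
#' Resamples characters with replacement, reruns a (light) parsimony search
#' per replicate, takes the strict consensus of the trees found, and
#' reports, for every internal branch of a reference tree, the percentage
#' of replicate consensus trees containing that bipartition.
#'
#' @param cm a \code{char_matrix}.
#' @param reference the tree whose branches are annotated (e.g. the strict
#'   consensus of the full search).
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed (reproducible).
#' @param n_addition_sequences,swap,ratchet per-replicate search settings
#'   (kept deliberately light by default).
#' @return data frame of class \code{bootstrap_support}: one row per
#'   internal branch of \code{reference} with the clade's tips and support
#'   in percent.
#' @export
bootstrap_support <- function(cm, reference, replicates = 100, seed = 1,
                              n_addition_sequences = 2, swap = c("spr", "tbr"),
                              ratchet = 0) {
  swap <- match.arg(swap)
  if (replicates < 1) stop("replicates must be >= 1")
  set.seed(seed)
  anchor <- sort(reference$tip.label)[1]
  ref_keys <- bipart_keys(reference, anchor)
  counts <- setNames(numeric(length(ref_keys)), ref_keys)
  active_idx <- which(cm$active)
  rep_seeds <- sample.int(.Machine$integer.max - 1, replicates)
  for (r in seq_len(replicates)) {
    take <- sample(active_idx, length(active_idx), replace = TRUE)
    cmr <- resample_columns(cm, take)
    sr <- heuristic_search(cmr, n_addition_sequences = n_addition_sequences,
                           seed = rep_seeds[r], swap = swap, ratchet = ratchet,
                           keep_all_mpts = FALSE, verbose = FALSE)
    cons <- strict_consensus(sr$trees)
    hit <- bipart_keys(cons, anchor)
    present <- ref_keys %in% hit
    counts[present] <- counts[present] + 1
  }
  out <- data.frame(
    clade = vapply(strsplit(ref_keys, "\r", fixed = TRUE), paste, "",
                   collapse = ","),
    support = 100 * counts / replicates,
    row.names = NULL)
  class(out) <- c("bootstrap_support", class(out))
  out
}

resample_columns <- function(cm, idx) {
  character_matrix(cm$cells[, idx, drop = FALSE], taxa = cm$taxa,
                   ordered = cm$ordered[idx], active = cm$active[idx],
                   weights = cm$weights[idx], symbols = cm$symbols)
}
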