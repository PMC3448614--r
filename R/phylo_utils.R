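#' Read a rooted tree from a Newick string or file
#'
#' Thin wrapper around \code{\link[ape]{read.tree}} that validates the result
#' as a rooted phylogeny with unique tip labels, the tree container used
#' throughout this package.
#'
#' @param text a Newick string (terminated by \code{;}).
#' @param file alternatively, path to a Newick file. Exactly one of
#'   \code{text}/\code{file} must be given.
#' @return an object of class \code{phylo}, rooted, possibly with
#'   \code{edge.length} (branch durations in My) if present in the input.
#' @examples
#' tr <- read_newick("((A:1,B:2):3,C:4);")
#' write_newick(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  tr <- if (is.null(file)) {
    if (!grepl(";", text, fixed = TRUE))
      stop("malformed Newick: no terminating ';' in input")
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  } else {
    ape::read.tree(file = file)
  }
  if (is.null(tr)) {
    # locate the first unbalanced parenthesis to aid diagnosis
    if (!is.null(text)) {
      bal <- cumsum((strsplit(text, "")[[1]] == "(") -
                    (strsplit(text, "")[[1]] == ")"))
      pos <- which(bal < 0)[1]
      if (is.na(pos)) pos <- nchar(text)
      stop("Newick parse error near character ", pos)
    }
    stop("Newick parse error in file ", file)
  }
  validate_phylo(tr)
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree a \code{phylo} object.
#' @param file optional path; if \code{NULL} the Newick string is returned.
#' @param digits significant digits for branch durations.
#' @return the Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

# Validate the structural invariants of the package's tree container:
# exactly one root, connected acyclic, unique tip labels.
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  ntot <- ape::Ntip(tree) + tree$Nnode
  parent_count <- tabulate(tree$edge[, 2], ntot)
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(unique(roots)) != 1L) stop("tree must have exactly one root")
  if (any(parent_count > 1L)) stop("node with more than one parent: not a tree")
  invisible(tree)
}

# Root node number (ape convention: Ntip + 1, but derive it defensively).
root_node <- function(tree) {
  unique(setdiff(tree$edge[, 1], tree$edge[, 2]))
}

# Edge indices in preorder (parents before children).
preorder_edges <- function(tree) {
  tree <- reorder_cladewise(tree)
  seq_len(nrow(tree$edge))
}

reorder_cladewise <- function(tree) {
  attr_keep <- tree$node.ages
  tree2 <- ape::reorder.phylo(tree, "cladewise")
  tree2$node.ages <- attr_keep
  tree2
}

# children list indexed by node number
children_list <- function(tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", ntot)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# parent vector indexed by node (0 for root)
parent_vec <- function(tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  p <- integer(ntot)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# Bitmask-free clade representation: for each internal node, the sorted
# vector of tip labels below it.  Used by consensus and bootstrap counting.
clade_splits <- function(tree) {
  nt <- ape::Ntip(tree)
  ntot <- nt + tree$Nnode
  below <- vector("list", ntot)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  tree <- reorder_cladewise(tree)
  for (i in rev(seq_len(nrow(tree$edge)))) {
    e <- tree$edge[i, ]
    below[[e[1]]] <- c(below[[e[1]]], below[[e[2]]])
  }
  lapply((nt + 1L):ntot, function(n) sort(below[[n]]))
}

# Canonical string keys for clades (non-trivial ones only if requested)
clade_keys <- function(tree, nontrivial = FALSE) {
  keys <- vapply(clade_splits(tree), paste, "", collapse = "\r")
  if (nontrivial) {
    nt <- ape::Ntip(tree)
    sizes <- lengths(strsplit(keys, "\r", fixed = TRUE))
    keys <- keys[sizes > 1 & sizes < nt]
  }
  keys
}

# Uniform random rooted binary topology on given labels (seeded by caller).
random_topology <- function(labels) {
  n <- length(labels)
  if (n < 3) stop("need at least 3 tips")
  tr <- ape::rtopology(n, rooted = TRUE, tip.label = sample(labels))
  tr$edge.length <- NULL
  tr
}

# Hash-friendly canonical form of a topology (label-sorted Newick, no lengths)
topology_key <- function(tree) {
  t2 <- tree
  t2$edge.length <- NULL
  t2$node.label <- NULL
  paste(sort(clade_keys(t2)), collapse = "|")
}
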