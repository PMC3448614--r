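#' Range-midpoint tip ages
#'
#' Converts stratigraphic ranges (oldest, youngest, in Ma before present) to
#' point ages at the range midpoint, the convention used to calibrate fossil
#' tips against time.
#'
#' @param ranges a data frame or matrix with columns \code{oldest} and
#'   \code{youngest} (Ma), rownames (or a \code{taxon} column) identifying
#'   taxa; or a named list of length-2 numeric vectors.
#' @return named numeric vector of midpoint ages (Ma).
#' @examples
#' midpoint_ages(data.frame(taxon = "X", oldest = 86.3, youngest = 83.6))
#' @export
midpoint_ages <- function(ranges) {
  if (is.list(ranges) && !is.data.frame(ranges) && is.null(dim(ranges))) {
    ranges <- data.frame(taxon = names(ranges),
                         oldest = vapply(ranges, `[`, 0, 1),
                         youngest = vapply(ranges, `[`, 0, 2))
  }
  ranges <- as.data.frame(ranges)
  taxa <- if ("taxon" %in% names(ranges)) as.character(ranges$taxon) else rownames(ranges)
  old <- as.numeric(ranges$oldest); young <- as.numeric(ranges$youngest)
  bad <- which(old < young)
  if (length(bad))
    stop("inverted stratigraphic range for: ", paste(taxa[bad], collapse = ", "))
  setNames((old + young) / 2, taxa)
}

#' Basic (oldest-descendant) dating of a topology
#'
#' Assigns every internal node the age of its oldest descendant tip.  This
#' is the minimal stratigraphically consistent calibration; wherever a node
#' inherits its age from a child the connecting branch has zero duration.
#' Use \code{\link{date_equal}} to obtain strictly positive durations.
#'
#' @param tree a rooted \code{phylo}.
#' @param tip_ages named numeric vector of tip ages (Ma before present);
#'   every tip label of \code{tree} must be present.
#' @return a \code{dated_phylo}: a \code{phylo} with \code{node.ages}
#'   (length \code{Ntip + Nnode}, in node-number order) and
#'   \code{edge.length} equal to parent age minus child age (My; zero
#'   durations possible here).
#' @export
date_basic <- function(tree, tip_ages) {
  validate_phylo(tree)
  miss <- setdiff(tree$tip.label, names(tip_ages))
  if (length(miss))
    stop("missing tip age for: ", paste(miss, collapse = ", "))
  if (any(tip_ages[tree$tip.label] <= 0))
    stop("tip ages must be strictly positive (Ma before present)")
  nt <- ape::Ntip(tree)
  ntot <- nt + tree$Nnode
  age <- numeric(ntot)
  age[seq_len(nt)] <- as.numeric(tip_ages[tree$tip.label])
  tree <- reorder_cladewise(tree)
  for (i in rev(seq_len(nrow(tree$edge)))) {
    e <- tree$edge[i, ]
    age[e[1]] <- max(age[e[1]], age[e[2]])
  }
  tree$node.ages <- age
  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  class(tree) <- unique(c("dated_phylo", class(tree)))
  tree
}

#' "Equal" time-scaling: share a root length along zero-duration chains
#'
#' Implements the equal dating method for paleontological trees: the root
#' age of a basic (oldest-descendant) calibration is increased by an
#' arbitrary \code{root_length}; each maximal chain of zero-duration
#' branches then shares the duration of the nearest positive ancestral
#' branch equally among that branch and the chain, processed root-to-tip.
#' All resulting branch durations are strictly positive; tip ages are
#' unchanged.
#'
#' Where several zero chains hang below the same donor branch the chain
#' encountered first in preorder is resolved first; subsequent chains then
#' see the updated (shorter, still positive) donor.  This makes the
#' procedure deterministic.
#'
#' @param basic a \code{dated_phylo} from \code{\link{date_basic}} (zero
#'   durations allowed), or a plain \code{phylo} plus \code{tip_ages}.
#' @param root_length extra time (My) added below the root; default 10.
#' @param tip_ages optional, used when \code{basic} is an undated topology.
#' @param order \code{"chain"} (default): each maximal zero chain and its
#'   donor are re-divided in one step, so a chain of k zero branches yields
#'   k+1 equal durations.  \code{"branch"}: zero branches are resolved one
#'   at a time rootward-first, each splitting only with its immediate donor,
#'   which yields successively halved durations down a chain.  The two
#'   orderings coincide except along chains of length > 1; both are
#'   legitimate readings of "sharing the time equally between unconstrained
#'   branches" and historical implementations are order-sensitive in
#'   exactly this way.
#' @return a \code{dated_phylo} with all branch durations strictly > 0.
#' @examples
#' tr <- read_newick("((X,Y),Z);")
#' dt <- date_equal(tr, root_length = 10,
#'                  tip_ages = c(X = 100, Y = 90, Z = 100))
#' node_ages(dt)
#' @export
date_equal <- function(basic, root_length = 10, tip_ages = NULL,
                       order = c("chain", "branch")) {
  order <- match.arg(order)
  if (root_length <= 0) stop("root_length must be > 0")
  if (!inherits(basic, "dated_phylo")) {
    if (is.null(tip_ages))
      stop("supply a dated_phylo from date_basic(), or tip_ages")
    basic <- date_basic(basic, tip_ages)
  }
  tree <- reorder_cladewise(basic)
  age <- tree$node.ages
  rt <- root_node(tree)
  age[rt] <- age[rt] + root_length

  par <- parent_vec(tree)
  ch <- children_list(tree)
  ntot <- length(age)
  # preorder node sequence (edge children in cladewise order)
  pre_nodes <- c(rt, tree$edge[, 2])
  pre_rank <- integer(ntot); pre_rank[pre_nodes] <- seq_along(pre_nodes)

  dur <- function(v) age[par[v]] - age[v]
  repeat {
    zero_child <- tree$edge[, 2][age[tree$edge[, 1]] - age[tree$edge[, 2]] <= .ps_tol$age]
    if (!length(zero_child)) break
    # first zero branch in preorder: its ancestral branch is positive
    v0 <- zero_child[which.min(pre_rank[zero_child])]
    u <- par[v0]                       # top of chain; donor is (par[u] -> u)
    if (u == rt) stop("internal error: zero branch at root after root_length")
    chain <- v0
    if (order == "chain") repeat {
      kids <- ch[[chain[length(chain)]]]
      zk <- kids[age[chain[length(chain)]] - age[kids] <= .ps_tol$age]
      if (!length(zk)) break
      chain <- c(chain, zk[which.min(pre_rank[zk])])
    }
    k <- length(chain)
    top <- age[par[u]]
    bottom <- age[chain[k]]
    step <- (top - bottom) / (k + 1)
    # re-space donor + chain equally; bottom node keeps its age
    age[u] <- top - step
    if (k > 1)
      for (i in seq_len(k - 1)) age[chain[i]] <- top - (i + 1) * step
  }

  tree$node.ages <- age
  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(tree$edge.length <= 0))
    stop("internal error: non-positive duration after equal sharing")
  class(tree) <- unique(c("dated_phylo", class(tree)))
  tree
}

#' Node ages of a dated tree
#'
#' @param tree a \code{dated_phylo}.
#' @param labels if \code{TRUE}, name entries by tip label / node number.
#' @return numeric vector of ages (Ma), tips first then internal nodes in
#'   ape node-number order.
#' @export
node_ages <- function(tree, labels = TRUE) {
  if (is.null(tree$node.ages)) stop("tree carries no node ages; run date_basic/date_equal")
  a <- tree$node.ages
  if (labels) {
    nt <- ape::Ntip(tree)
    names(a) <- c(tree$tip.label, paste0("node", (nt + 1L):(nt + tree$Nnode)))
  }
  a
}

#' @export
print.dated_phylo <- function(x, ...) {
  nt <- ape::Ntip(x)
  rt <- root_node(x)
  cat("Time-calibrated phylogeny:", nt, "tips,", x$Nnode, "internal nodes\n")
  cat(sprintf("  root age %.3f Ma; tip ages %.3f-%.3f Ma\n",
              x$node.ages[rt], min(x$node.ages[1:nt]), max(x$node.ages[1:nt])))
  cat(sprintf("  branch durations %.4g-%.4g My%s\n",
              min(x$edge.length), max(x$edge.length),
              if (any(x$edge.length <= 0)) " (contains zero-length branches)" else ""))
  invisible(x)
}
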