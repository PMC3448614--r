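# Seeded generators for trees, Brownian traits, and discrete character
# matrices with known ground truth.  Every pipeline stage can be exercised
# against data whose generating parameters are known exactly.

#' Random time-calibrated tree with fossil-like tip ages
#'
#' Draws a rooted binary topology (uniform over topologies, or
#' Yule/equal-splits), assigns tip ages uniformly in a stratigraphic
#' window, and calibrates node ages by the oldest-descendant rule followed
#' by equal sharing of a root length, so every branch duration is strictly
#' positive.
#'
#' @param n_tips number of tips (>= 3).
#' @param tip_age_range window (Ma) tips are drawn from; default 66-163 Ma,
#'   the Callovian-Maastrichtian span of the ornithopod data the package is
#'   built around.
#' @param root_length root length (My) for \code{\link{date_equal}}.
#' @param model \code{"uniform"} topology or \code{"yule"} (equal-rates
#'   splitting).
#' @param seed optional integer seed; \code{NULL} uses the current RNG
#'   state.
#' @return list: \code{tree} (a \code{dated_phylo}), \code{tip_ages}.
#' @export
random_dated_tree <- function(n_tips, tip_age_range = c(66, 163),
                              root_length = 10,
                              model = c("uniform", "yule"), seed = NULL) {
  model <- match.arg(model)
  if (n_tips < 3) stop("n_tips must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  labels <- paste0("t", seq_len(n_tips))
  topo <- if (model == "uniform")
    ape::rtopology(n_tips, rooted = TRUE, tip.label = labels)
  else ape::rtree(n_tips, tip.label = labels)
  topo$edge.length <- NULL
  ages <- setNames(runif(n_tips, tip_age_range[1], tip_age_range[2]), labels)
  tree <- date_equal(date_basic(topo, ages), root_length = root_length)
  list(tree = tree, tip_ages = ages)
}

#' Simulate Brownian motion on a dated tree
#'
#' Evolves a continuous trait from the root by adding, along each branch,
#' an independent normal increment with mean zero and variance
#' \code{sigma2} times the branch duration.
#'
#' @param tree a \code{dated_phylo} (positive durations).
#' @param root_value trait value at the root.
#' @param sigma2 Brownian rate (trait^2 per My), >= 0.
#' @param seed optional integer seed.
#' @return list: \code{tips} (named trait vector, a valid input to
#'   \code{\link{weighted_scp}}), \code{nodes} (true values at all nodes,
#'   node-number order), \code{sigma2}, \code{root_value}.
#' @export
simulate_bm <- function(tree, root_value = 0, sigma2 = 1, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (is.null(tree$edge.length)) stop("tree must have branch durations")
  if (!is.null(seed)) set.seed(seed)
  nt <- ape::Ntip(tree)
  ntot <- nt + tree$Nnode
  x <- numeric(ntot)
  x[root_node(tree)] <- root_value
  tr <- reorder_cladewise(tree)
  inc <- rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
  for (i in seq_len(nrow(tr$edge)))
    x[tr$edge[i, 2]] <- x[tr$edge[i, 1]] + inc[i]
  list(tips = setNames(x[seq_len(nt)], tree$tip.label), nodes = x,
       sigma2 = sigma2, root_value = root_value)
}

#' Simulate discrete characters on a tree
#'
#' Evolves unordered characters by a per-branch Bernoulli change model
#' (with probability \code{change_prob} the state jumps to a uniformly
#' chosen different state), or, in zero-homoplasy mode, marks each
#' character with a single 0->1 change on its own branch so that the true
#' tree attains the minimum conceivable length and CI = 1.
#'
#' @param tree a rooted binary \code{phylo} (branch lengths not used).
#' @param n_char number of characters.
#' @param alphabet number of states (>= 2).
#' @param change_prob per-branch change probability.
#' @param missing_fraction fraction of cells replaced by \code{"?"}.
#' @param zero_homoplasy if \code{TRUE}, one change per character on a
#'   distinct branch (requires \code{n_char} <= number of branches).
#' @param seed optional integer seed.
#' @return a \code{char_matrix}; in zero-homoplasy mode the marked branches
#'   are stored in \code{attr(, "true_changes")}.
#' @export
simulate_characters <- function(tree, n_char, alphabet = 2,
                                change_prob = 0.1, missing_fraction = 0,
                                zero_homoplasy = FALSE, seed = NULL) {
  if (alphabet < 2) stop("alphabet must have at least 2 states")
  if (!is.null(seed)) set.seed(seed)
  nt <- ape::Ntip(tree)
  ntot <- nt + tree$Nnode
  tr <- reorder_cladewise(tree)
  nedge <- nrow(tr$edge)
  cells <- matrix("0", nt, n_char)
  true_changes <- NULL
  if (zero_homoplasy) {
    if (n_char > nedge)
      stop("zero-homoplasy mode needs n_char <= number of branches (",
           nedge, ")")
    true_changes <- sample.int(nedge, n_char)
    for (j in seq_len(n_char)) {
      x <- integer(ntot)
      for (i in seq_len(nedge)) {
        x[tr$edge[i, 2]] <- x[tr$edge[i, 1]] +
          (i == true_changes[j])
      }
      cells[, j] <- as.character(x[seq_len(nt)])
    }
  } else {
    for (j in seq_len(n_char)) {
      x <- integer(ntot)
      chg <- runif(nedge) < change_prob
      jump <- sample.int(alphabet - 1, nedge, replace = TRUE)
      for (i in seq_len(nedge)) {
        p <- x[tr$edge[i, 1]]
        x[tr$edge[i, 2]] <- if (chg[i]) (p + jump[i]) %% alphabet else p
      }
      cells[, j] <- as.character(x[seq_len(nt)])
    }
  }
  if (missing_fraction > 0)
    cells[matrix(runif(length(cells)) < missing_fraction,
                 nrow(cells))] <- "?"
  cm <- character_matrix(cells, taxa = tree$tip.label)
  attr(cm, "true_changes") <- true_changes
  cm
}
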