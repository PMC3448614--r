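#' Weighted squared-change parsimony ancestral states
#'
#' Reconstructs ancestral values of a continuous trait on a time-calibrated
#' tree by minimising the sum over branches of (squared change) / (branch
#' duration).  The minimiser satisfies, at every internal node, the
#' stationarity condition that the node's value is the 1/duration-weighted
#' mean of its neighbours' values; it is found exactly by solving the
#' corresponding linear system, and coincides with the maximum-likelihood
#' ancestral states under Brownian motion on the same tree.
#'
#' @param tree a \code{dated_phylo} with strictly positive branch durations
#'   (see \code{\link{date_equal}}).
#' @param traits named numeric vector: one finite value per tip label
#'   (e.g. log10 maximum femur length in mm).
#' @param backtransform function applied to states for reporting (default
#'   \code{function(x) 10^x}, matching a log10-scale trait); use
#'   \code{identity} for untransformed traits.
#' @param trait_name label stored with the fit.
#' @return an object of class \code{scp_fit} with components
#'   \code{node_states} (values at all nodes, tips first), \code{cost}
#'   (the minimised objective, trait^2/My), \code{rate} (mean squared
#'   change per My across branches), \code{tree}, \code{backtransform}.
#' @examples
#' tr <- date_equal(read_newick("((A,B),C);"), 10,
#'                  tip_ages = c(A = 80, B = 70, C = 90))
#' fit <- weighted_scp(tr, c(A = 2.1, B = 2.3, C = 2.6),
#'                     backtransform = identity)
#' coef(fit)
#' @export
weighted_scp <- function(tree, traits, backtransform = function(x) 10^x,
                         trait_name = "trait") {
  if (is.null(tree$edge.length) || is.null(tree$node.ages))
    stop("tree must be time-calibrated; run date_basic() then date_equal()")
  if (any(tree$edge.length <= 0))
    stop("zero or negative branch durations present; run date_equal() first")
  nt <- ape::Ntip(tree)
  miss <- setdiff(tree$tip.label, names(traits))
  if (length(miss)) stop("no trait value for: ", paste(miss, collapse = ", "))
  x_tip <- as.numeric(traits[tree$tip.label])
  if (any(!is.finite(x_tip))) stop("non-finite trait values supplied")

  ntot <- nt + tree$Nnode
  internal <- (nt + 1L):ntot
  idx <- integer(ntot); idx[internal] <- seq_along(internal)
  A <- matrix(0, tree$Nnode, tree$Nnode)
  b <- numeric(tree$Nnode)
  w <- 1 / tree$edge.length
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c_ <- tree$edge[i, 2]; wi <- w[i]
    ip <- idx[p]
    A[ip, ip] <- A[ip, ip] + wi
    if (c_ > nt) {
      ic <- idx[c_]
      A[ic, ic] <- A[ic, ic] + wi
      A[ip, ic] <- A[ip, ic] - wi
      A[ic, ip] <- A[ic, ip] - wi
    } else {
      b[ip] <- b[ip] + wi * x_tip[c_]
    }
  }
  x_int <- solve(A, b)
  states <- c(x_tip, x_int)

  cost <- sum((states[tree$edge[, 1]] - states[tree$edge[, 2]])^2 * w)
  fit <- structure(list(
    node_states = states,
    cost = cost,
    rate = cost / nrow(tree$edge),
    tree = tree,
    traits = setNames(x_tip, tree$tip.label),
    trait_name = trait_name,
    backtransform = backtransform
  ), class = "scp_fit")
  fit
}

#' Objective value of a squared-change parsimony assignment
#'
#' Evaluates the weighted squared-change criterion for an arbitrary
#' assignment of internal-node values, e.g. to compare a candidate
#' reconstruction against the exact optimum.
#'
#' @param tree a \code{dated_phylo} with positive durations.
#' @param traits named tip values (as in \code{\link{weighted_scp}}).
#' @param internal_values numeric vector of internal-node values in node
#'   number order (root first), length \code{tree$Nnode}.
#' @return the objective: sum over branches of squared change divided by
#'   duration.
#' @export
scp_cost <- function(tree, traits, internal_values) {
  nt <- ape::Ntip(tree)
  if (length(internal_values) != tree$Nnode)
    stop("need exactly ", tree$Nnode, " internal values (got ",
         length(internal_values), ")")
  if (any(!is.finite(internal_values))) stop("missing internal value")
  if (any(tree$edge.length <= 0)) stop("branch durations must be positive")
  x <- c(as.numeric(traits[tree$tip.label]), as.numeric(internal_values))
  if (any(!is.finite(x))) stop("missing or non-finite tip value")
  sum((x[tree$edge[, 1]] - x[tree$edge[, 2]])^2 / tree$edge.length)
}

#' Split a terminal into a cherry of new tips
#'
#' Replaces one tip by a clade (usually a pair) of new tips — e.g. dividing
#' a genus-level terminal into small and large species — and returns the
#' updated topology together with an updated trait vector.  The tree is
#' returned undated: rerun \code{\link{date_basic}} / \code{\link{date_equal}}
#' with the new tip ages.
#'
#' @param tree a \code{phylo} (dated or not; dating is dropped).
#' @param taxon tip label to replace.
#' @param new_tips data frame with columns \code{label}, \code{age},
#'   \code{value} (one row per new tip, >= 2 rows).
#' @param traits optional named trait vector to update alongside.
#' @return list with \code{tree} (undated \code{phylo}), \code{tip_ages}
#'   entries for the new tips, and \code{traits} (updated vector, if given).
#' @export
split_terminal <- function(tree, taxon, new_tips, traits = NULL) {
  if (!taxon %in% tree$tip.label) stop("taxon not in tree: ", taxon)
  new_tips <- as.data.frame(new_tips)
  if (nrow(new_tips) < 2) stop("need at least 2 new tips")
  if (anyDuplicated(c(setdiff(tree$tip.label, taxon), new_tips$label)))
    stop("duplicate labels after split")
  cherry <- paste0("(", paste(new_tips$label, collapse = ","), ");")
  sub <- ape::read.tree(text = cherry)
  base <- tree
  base$edge.length <- NULL
  base$node.ages <- NULL
  class(base) <- "phylo"
  tr2 <- ape::bind.tree(base, sub, where = match(taxon, base$tip.label))
  validate_phylo(tr2)
  ages <- setNames(as.numeric(new_tips$age), new_tips$label)
  out <- list(tree = tr2, tip_ages = ages)
  if (!is.null(traits)) {
    tv <- traits[setdiff(names(traits), taxon)]
    out$traits <- c(tv, setNames(as.numeric(new_tips$value), new_tips$label))
  }
  out
}

# ---- scp_fit methods ------------------------------------------------------

#' @export
print.scp_fit <- function(x, ...) {
  cat("Weighted squared-change parsimony fit\n")
  cat(sprintf("  trait: %s; %d tips, %d internal nodes\n",
              x$trait_name, ape::Ntip(x$tree), x$tree$Nnode))
  cat(sprintf("  minimised cost: %.6g (trait^2/My); mean rate %.6g per My\n",
              x$cost, x$rate))
  rt <- root_node(x$tree)
  cat(sprintf("  root state: %.6g (back-transformed: %.6g)\n",
              x$node_states[rt], x$backtransform(x$node_states[rt])))
  invisible(x)
}

#' @export
coef.scp_fit <- function(object, ...) {
  nt <- ape::Ntip(object$tree)
  setNames(object$node_states[(nt + 1L):length(object$node_states)],
           paste0("node", (nt + 1L):length(object$node_states)))
}

#' @export
fitted.scp_fit <- function(object, ...) {
  nt <- ape::Ntip(object$tree)
  setNames(object$node_states,
           c(object$tree$tip.label,
             paste0("node", (nt + 1L):length(object$node_states))))
}

#' Per-branch standardized changes of a squared-change parsimony fit
#'
#' @param object an \code{scp_fit}.
#' @param ... unused.
#' @return numeric vector, one per branch: change / sqrt(duration).  Under
#'   Brownian motion these are approximately iid normal.
#' @export
residuals.scp_fit <- function(object, ...) {
  tr <- object$tree
  (object$node_states[tr$edge[, 2]] - object$node_states[tr$edge[, 1]]) /
    sqrt(tr$edge.length)
}

#' Ancestral-state table of a squared-change parsimony fit
#'
#' @param object an \code{scp_fit}.
#' @param mrca_of optional named list: each element a vector of tip labels;
#'   the summary then also reports the state at each set's most recent
#'   common ancestor (e.g. a clade of interest).
#' @param ... unused.
#' @return data frame with node, age (Ma), state, and back-transformed state.
#' @export
summary.scp_fit <- function(object, mrca_of = NULL, ...) {
  tr <- object$tree
  nt <- ape::Ntip(tr)
  ids <- seq_along(object$node_states)
  out <- data.frame(
    node = c(tr$tip.label, paste0("node", (nt + 1L):length(ids))),
    type = rep(c("tip", "internal"), c(nt, tr$Nnode)),
    age_Ma = tr$node.ages,
    state = object$node_states,
    backtransformed = object$backtransform(object$node_states))
  if (!is.null(mrca_of)) {
    rows <- lapply(names(mrca_of), function(nm) {
      n <- mrca_node(tr, mrca_of[[nm]])
      data.frame(node = nm, type = "mrca", age_Ma = tr$node.ages[n],
                 state = object$node_states[n],
                 backtransformed = object$backtransform(object$node_states[n]))
    })
    out <- rbind(out, do.call(rbind, rows))
  }
  class(out) <- c("summary.scp_fit", class(out))
  out
}

#' State at the most recent common ancestor of a set of tips
#'
#' @param fit an \code{scp_fit}.
#' @param tips character vector of tip labels (>= 2).
#' @param backtransform report on the back-transformed scale?
#' @return the reconstructed state at the MRCA.
#' @export
mrca_state <- function(fit, tips, backtransform = TRUE) {
  n <- mrca_node(fit$tree, tips)
  s <- fit$node_states[n]
  if (backtransform) fit$backtransform(s) else s
}

mrca_node <- function(tree, tips) {
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss)) stop("tips not in tree: ", paste(miss, collapse = ", "))
  if (length(tips) == 1) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Plot a squared-change parsimony fit as a traitgram
#'
#' Draws node age (x, reversed: past to the left) against reconstructed
#' state (y), connecting nodes along branches.
#'
#' @param x an \code{scp_fit}.
#' @param backtransform plot back-transformed states?
#' @param show_labels label the tips?
#' @param ... further arguments to \code{plot}.
#' @export
plot.scp_fit <- function(x, backtransform = FALSE, show_labels = TRUE, ...) {
  tr <- x$tree
  st <- if (backtransform) x$backtransform(x$node_states) else x$node_states
  age <- tr$node.ages
  graphics::plot(NA, xlim = rev(range(age)), ylim = range(st),
                 xlab = "age (Ma)",
                 ylab = if (backtransform) paste0(x$trait_name, " (back-transformed)")
                        else x$trait_name, ...)
  for (i in seq_len(nrow(tr$edge)))
    graphics::segments(age[tr$edge[i, 1]], st[tr$edge[i, 1]],
                       age[tr$edge[i, 2]], st[tr$edge[i, 2]], col = "grey40")
  nt <- ape::Ntip(tr)
  graphics::points(age[1:nt], st[1:nt], pch = 16)
  graphics::points(age[(nt + 1):length(age)], st[(nt + 1):length(st)],
                   pch = 21, bg = "grey80")
  if (show_labels)
    graphics::text(age[1:nt], st[1:nt], tr$tip.label, pos = 4, cex = 0.6)
  invisible(x)
}

#' Simulate Brownian trait evolution from a fitted reconstruction
#'
#' Uses the fitted root state and mean squared-change rate as Brownian
#' parameters on the fit's own tree, giving parametric-bootstrap style
#' replicates of the tip data.
#'
#' @param object an \code{scp_fit}.
#' @param nsim number of replicate tip-data sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data frame, one column per replicate, rownames = tip labels.
#' @export
simulate.scp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rt <- root_node(object$tree)
  reps <- replicate(nsim,
    simulate_bm(object$tree, root_value = object$node_states[rt],
                sigma2 = object$rate)$tips)
  out <- as.data.frame(reps)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$tree$tip.label
  out
}
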