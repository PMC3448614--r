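# Scoring a character matrix on trees, and the ensemble fit indices.

# Align a char_matrix's rows with a tree's tips; errors list offenders.
align_matrix_tree <- function(tree, cm) {
  extra_tree <- setdiff(tree$tip.label, cm$taxa)
  extra_mat <- setdiff(cm$taxa, tree$tip.label)
  if (length(extra_tree) || length(extra_mat))
    stop("taxon mismatch between tree and matrix",
         if (length(extra_tree)) paste0("; in tree only: ",
                                        paste(extra_tree, collapse = ", ")),
         if (length(extra_mat)) paste0("; in matrix only: ",
                                       paste(extra_mat, collapse = ", ")))
  cm$masks[match(tree$tip.label, cm$taxa), , drop = FALSE]
}

# Per-character (unweighted) step counts of a matrix on a tree.
score_chars_on_tree <- function(tree, cm) {
  masks <- align_matrix_tree(tree, cm)
  .c_score_chars(tree$edge, ape::Ntip(tree), masks,
                 as.integer(cm$ordered), as.integer(cm$nstates))
}

#' Minimum steps of one character on a tree
#'
#' The minimum weighted number of state changes a single character requires
#' on a given tree: unordered changes cost 1, ordered changes cost
#' |i - j|.  Polymorphic tips may take any member of their state set;
#' missing (\code{"?"}) and inapplicable (\code{"-"}) tips any state.
#'
#' @param tree rooted \code{phylo} (polytomies allowed).
#' @param column named vector of cell tokens (or integers), one per tip;
#'   taxa missing from \code{column} are scored as missing data.
#' @param ordered is the character ordered?
#' @return integer: the minimum number of (weighted) changes.
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' character_length(tr, c(A = 0, B = 0, C = 1, D = 1))  # 1
#' @export
character_length <- function(tree, column, ordered = FALSE) {
  validate_phylo(tree)
  toks <- setNames(rep("?", ape::Ntip(tree)), tree$tip.label)
  known <- intersect(names(column), tree$tip.label)
  toks[known] <- as.character(column[known])
  cm <- character_matrix(matrix(toks, ncol = 1), taxa = names(toks),
                         ordered = ordered)
  as.integer(score_chars_on_tree(tree, cm))
}

#' Parsimony length of a tree
#'
#' Total weighted tree length: the sum over active characters of minimum
#' step counts times character weights.
#'
#' @param tree rooted \code{phylo}.
#' @param cm a \code{char_matrix}.
#' @param per_character return the per-character unweighted step counts
#'   instead of the total.
#' @return numeric length (integer-valued for unit weights), or an integer
#'   vector of per-character steps.
#' @export
tree_length <- function(tree, cm, per_character = FALSE) {
  steps <- score_chars_on_tree(tree, cm)
  if (per_character) return(steps)
  sum(steps[cm$active] * cm$weights[cm$active])
}

# Minimum conceivable steps of each character on *any* tree (m_i).
# Unordered: smallest state subset intersecting every non-missing tip set,
# minus one (exact search over subsets; morphological alphabets are tiny).
# Ordered: span of the tightest interval meeting every tip set.
min_steps_per_char <- function(cm) {
  nchr <- ncol(cm$masks)
  out <- integer(nchr)
  for (j in seq_len(nchr)) {
    ns <- cm$nstates[j]
    full <- bitwShiftL(1L, ns) - 1L
    sets <- cm$masks[, j]
    sets <- sets[sets != full & sets != 0L]    # ignore missing tips
    if (!length(sets)) { out[j] <- 0L; next }
    if (cm$ordered[j]) {
      lo <- vapply(sets, function(m) min(which(bitwAnd(m, bitwShiftL(1L, 0:(ns - 1))) != 0L)) - 1L, 1L)
      hi <- vapply(sets, function(m) max(which(bitwAnd(m, bitwShiftL(1L, 0:(ns - 1))) != 0L)) - 1L, 1L)
      out[j] <- max(0L, max(lo) - min(hi))
    } else {
      found <- NA_integer_
      for (k in 1:ns) {
        combs <- combn(ns, k)
        for (ci in seq_len(ncol(combs))) {
          sub <- sum(bitwShiftL(1L, combs[, ci] - 1L))
          if (all(bitwAnd(sets, sub) != 0L)) { found <- k; break }
        }
        if (!is.na(found)) break
      }
      out[j] <- found - 1L
    }
  }
  out
}

# Steps of each character on the star tree (g_i): the maximum a character
# can conceivably require.  Root state chosen to minimise total cost.
star_steps_per_char <- function(cm) {
  nchr <- ncol(cm$masks)
  out <- integer(nchr)
  for (j in seq_len(nchr)) {
    ns <- cm$nstates[j]
    full <- bitwShiftL(1L, ns) - 1L
    sets <- cm$masks[, j]
    sets <- sets[sets != full & sets != 0L]
    if (!length(sets)) { out[j] <- 0L; next }
    costs <- vapply(0:(ns - 1), function(r) {
      if (cm$ordered[j]) {
        sum(vapply(sets, function(m) {
          st <- which(bitwAnd(m, bitwShiftL(1L, 0:(ns - 1))) != 0L) - 1L
          min(abs(st - r))
        }, 1))
      } else {
        sum(bitwAnd(sets, bitwShiftL(1L, r)) == 0L)
      }
    }, 0)
    out[j] <- as.integer(min(costs))
  }
  out
}

#' Ensemble fit indices (CI, HI, RI, RC)
#'
#' Summarise how well a character matrix fits a tree of a given length:
#' consistency index CI = sum(m_i)/L, homoplasy index HI = 1 - CI,
#' retention index RI = (sum(g_i) - L)/(sum(g_i) - sum(m_i)), and rescaled
#' consistency RC = CI * RI, where m_i is the minimum conceivable steps of
#' character i on any tree and g_i its steps on the star tree.  Characters
#' with g_i = m_i cannot show retained synapomorphy; they contribute to CI
#' (via m_i and their steps in L) but are excluded from the RI sums.
#' Inactive and zero-weight characters are excluded throughout.
#'
#' @param cm a \code{char_matrix}.
#' @param length tree length L (as from \code{\link{tree_length}}).
#' @return named list with CI, HI, RI, RC and the sums M = sum(m_i),
#'   G = sum(g_i).
#' @export
ensemble_indices <- function(cm, length) {
  use <- cm$active & cm$weights > 0
  w <- cm$weights[use]
  m <- min_steps_per_char(cm)[use]
  g <- star_steps_per_char(cm)[use]
  M <- sum(w * m)
  G <- sum(w * g)
  if (length < M)
    stop("impossible length: ", length, " < minimum conceivable ", M)
  CI <- if (length > 0) M / length else 1
  info <- g > m
  # L restricted to retention-informative characters: uninformative ones
  # always realise exactly m_i steps
  L_ri <- length - sum(w[!info] * m[!info])
  G_i <- sum(w[info] * g[info])
  M_i <- sum(w[info] * m[info])
  RI <- if (G_i > M_i) (G_i - L_ri) / (G_i - M_i) else NA_real_
  list(CI = CI, HI = 1 - CI, RI = RI,
       RC = if (is.na(RI)) NA_real_ else CI * RI, M = M, G = G)
}
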