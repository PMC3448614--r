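# End-to-end workflows wiring the stages together, with JSON/Newick output.

#' Phylogenetic analysis workflow
#'
#' Reads (or takes) a character matrix, runs the heuristic parsimony
#' search, computes ensemble indices, strict (and optionally reduced)
#' consensus, and unambiguous synapomorphies, and optionally writes a JSON
#' report plus Newick trees and a reproducibility manifest.
#'
#' @param cm a \code{char_matrix}, or a file path readable by
#'   \code{\link{read_matrix}}.
#' @param format,strip_leading_dummy,ordered_indices passed to
#'   \code{\link{read_matrix}} when \code{cm} is a path.
#' @param seed search seed.
#' @param search_args list of extra arguments to
#'   \code{\link{heuristic_search}}.
#' @param prune taxa to drop for a reduced consensus (\code{NULL} to skip).
#' @param out_dir if non-NULL, directory to write \code{report.json},
#'   \code{mpts.nwk}, \code{consensus.nwk} and \code{manifest.json} into.
#' @return (invisibly) a list: \code{search} (the
#'   \code{parsimony_search}), \code{consensus}, \code{reduced} (or NULL),
#'   \code{synapomorphies}, \code{report} (plain-list summary).
#' @export
run_phylo <- function(cm, format = "auto", strip_leading_dummy = FALSE,
                      ordered_indices = NULL, seed = 1,
                      search_args = list(), prune = NULL, out_dir = NULL) {
  input <- if (is.character(cm)) cm else NULL
  if (is.character(cm))
    cm <- read_matrix(file = cm, format = format,
                      strip_leading_dummy = strip_leading_dummy,
                      ordered_indices = ordered_indices)
  stage <- "search"
  res <- tryCatch({
    sr <- do.call(heuristic_search, c(list(cm = cm, seed = seed), search_args))
    stage <- "consensus"
    cons <- strict_consensus(sr$trees)
    red <- if (!is.null(prune)) reduced_consensus(sr$trees, prune) else NULL
    stage <- "synapomorphies"
    syn <- unambiguous_synapomorphies(sr$trees, cm)
    list(search = sr, consensus = cons, reduced = red, synapomorphies = syn)
  }, error = function(e)
    stop("phylo workflow failed at stage '", stage, "': ",
         conditionMessage(e)))
  report <- list(
    ntax = length(cm$taxa), nchar = ncol(cm$masks),
    length = res$search$length,
    CI = res$search$indices$CI, HI = res$search$indices$HI,
    RI = res$search$indices$RI, RC = res$search$indices$RC,
    mpt_count = res$search$mpt_count, truncated = res$search$truncated,
    seed = seed,
    n_synapomorphies = nrow(res$synapomorphies))
  res$report <- report
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ape::write.tree(res$search$trees, file.path(out_dir, "mpts.nwk"))
    ape::write.tree(res$consensus, file.path(out_dir, "consensus.nwk"))
    if (!is.null(res$reduced))
      ape::write.tree(res$reduced, file.path(out_dir, "reduced_consensus.nwk"))
    write_manifest(out_dir, input = input, seed = seed,
                   params = c(list(strip_leading_dummy = strip_leading_dummy,
                                   ordered_indices = ordered_indices,
                                   prune = prune), search_args))
  }
  invisible(res)
}

#' Body-size evolution workflow
#'
#' The full continuous-trait pipeline: tip femur lengths and ages, a
#' reference topology, oldest-descendant dating plus equal sharing of a
#' root length, weighted squared-change parsimony on log10 femur length,
#' and back-transformation to mm.  Optionally repeats the analysis with one
#' terminal split into small and large sister species.
#'
#' @param tip_table a \code{tip_data} data frame (or file path); needs
#'   columns \code{taxon}, \code{log10_femur} (or \code{femur_mm}),
#'   \code{age_Ma}.
#' @param tree reference topology (\code{phylo} or Newick file path); tips
#'   must appear in \code{tip_table}; table rows not in the tree are
#'   ignored.
#' @param root_length root length in My (default 10).
#' @param split optional list describing a terminal split, e.g.
#'   \code{list(taxon = "Rhabdodon_sp", labels = c("small","large"),
#'   femur_mm = c(210, 820), age = c(71, 71))}.
#' @param mrca_of named list of tip sets at whose MRCAs states are
#'   reported (defaults to the rhabdodontid clades of the packaged
#'   analysis when present in the tree).
#' @param order zero-branch sharing order, see \code{\link{date_equal}}.
#' @param out_dir if non-NULL, write \code{asr.json}, \code{dated.nwk}
#'   (and split-variant files) plus a manifest.
#' @return (invisibly) list: \code{fit}, \code{dated}, \code{states}
#'   (summary data frame), and when split: \code{fit_split},
#'   \code{dated_split}, \code{states_split}; \code{mrca} /
#'   \code{mrca_split}: back-transformed states (mm) at the requested
#'   MRCAs.
#' @export
run_bodysize_evolution <- function(tip_table, tree, root_length = 10,
                                   split = NULL, mrca_of = NULL,
                                   order = "chain", out_dir = NULL) {
  input_tab <- if (is.character(tip_table)) tip_table else NULL
  if (is.character(tip_table)) tip_table <- read_tip_table(file = tip_table)
  if (is.character(tree)) tree <- read_newick(file = tree)
  stage <- "traits"
  res <- tryCatch({
    tab <- tip_table[tip_table$taxon %in% tree$tip.label, , drop = FALSE]
    missing <- setdiff(tree$tip.label, tab$taxon)
    if (length(missing))
      stop("no tip data for: ", paste(missing, collapse = ", "))
    lf <- if ("log10_femur" %in% names(tab) && !anyNA(tab$log10_femur))
      setNames(tab$log10_femur, tab$taxon)
    else setNames(log10(tab$femur_mm), tab$taxon)
    ages <- setNames(tab$age_Ma, tab$taxon)
    stage <- "dating"
    dated <- date_equal(date_basic(tree, ages), root_length = root_length,
                        order = order)
    stage <- "ancestral states"
    fit <- weighted_scp(dated, lf, trait_name = "log10 max femur length (mm)")
    if (is.null(mrca_of)) {
      mrca_of <- list()
      rh <- grep("^(Rhabdodon|Mochlodon|Zalmoxes)", tree$tip.label, value = TRUE)
      mo <- grep("^Mochlodon", tree$tip.label, value = TRUE)
      if (length(rh) > 1) mrca_of$Rhabdodontidae <- rh
      if (length(mo) > 1) mrca_of$Mochlodon <- mo
    }
    out <- list(fit = fit, dated = dated,
                states = summary(fit, mrca_of = mrca_of),
                mrca = vapply(mrca_of, function(tt) mrca_state(fit, tt), 0))
    if (!is.null(split)) {
      stage <- "split variant"
      vals <- if (!is.null(split$femur_mm)) log10(split$femur_mm) else split$value
      sp <- split_terminal(tree, split$taxon,
                           data.frame(label = split$labels, age = split$age,
                                      value = vals))
      ages2 <- c(ages[setdiff(sp$tree$tip.label, split$labels)], sp$tip_ages)
      lf2 <- c(lf[setdiff(sp$tree$tip.label, split$labels)],
               setNames(vals, split$labels))
      dated2 <- date_equal(date_basic(sp$tree, ages2),
                           root_length = root_length, order = order)
      fit2 <- weighted_scp(dated2, lf2,
                           trait_name = "log10 max femur length (mm)")
      # clades that contained the split taxon gain the new tips instead
      mrca_of2 <- lapply(names(mrca_of), function(nm) {
        tt <- mrca_of[[nm]]
        if (split$taxon %in% tt) c(setdiff(tt, split$taxon), split$labels)
        else tt
      })
      names(mrca_of2) <- names(mrca_of)
      out$fit_split <- fit2
      out$dated_split <- dated2
      out$states_split <- summary(fit2, mrca_of = mrca_of2)
      out$mrca_split <- vapply(mrca_of2, function(tt) mrca_state(fit2, tt), 0)
    }
    out
  }, error = function(e)
    stop("body-size workflow failed at stage '", stage, "': ",
         conditionMessage(e)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    report <- list(
      n_taxa = ape::Ntip(res$dated),
      root_length_My = root_length,
      scp_cost = res$fit$cost,
      mrca_mm = as.list(round(res$mrca)),
      states = lapply(split(res$states, seq_len(nrow(res$states))), function(r)
        list(node = r$node, age_Ma = r$age_Ma, log10 = r$state,
             mm = r$backtransformed)))
    if (!is.null(res$fit_split))
      report$mrca_mm_split <- as.list(round(res$mrca_split))
    jsonlite::write_json(report, file.path(out_dir, "asr.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ape::write.tree(res$dated, file.path(out_dir, "dated.nwk"))
    if (!is.null(res$fit_split))
      ape::write.tree(res$dated_split, file.path(out_dir, "dated_split.nwk"))
    write_manifest(out_dir, input = input_tab, seed = NULL,
                   params = list(root_length = root_length, order = order,
                                 split = split))
  }
  invisible(res)
}

write_manifest <- function(out_dir, input = NULL, seed = NULL, params = list()) {
  manifest <- list(
    package = "paleosize",
    version = as.character(utils::packageVersion("paleosize")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = input,
    input_md5 = if (!is.null(input)) unname(tools::md5sum(input)) else NULL,
    seed = seed,
    params = params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
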