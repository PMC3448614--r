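#' Read a tip data table (femur lengths and ages)
#'
#' Reads a delimited table of taxa with maximum femur length (mm), its
#' log10, and tip age (Ma, a stratigraphic-range midpoint).  Numeric
#' columns may use decimal commas (the typographic convention of many
#' European data tables) when \code{decimal_comma = TRUE}.  When both a
#' femur column and a log10 column are present each row is checked for
#' consistency to 1e-6.
#'
#' @param text table text; or use \code{file}.
#' @param file path to a delimited file.
#' @param sep field separator (default \code{";"}).
#' @param decimal_comma accept \code{","} as the decimal mark in numeric
#'   columns.
#' @return a data frame of class \code{tip_data} with columns \code{taxon},
#'   \code{femur_mm}, \code{log10_femur}, \code{age_Ma} plus any extra
#'   columns present.
#' @export
read_tip_table <- function(text = NULL, file = NULL, sep = ";",
                           decimal_comma = TRUE) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  empty_input <- if (is.null(text)) !file.size(file) else !nzchar(trimws(text))
  df <- if (empty_input) data.frame() else {
    con <- if (is.null(text)) file else textConnection(text)
    read.table(con, sep = sep, header = TRUE, stringsAsFactors = FALSE,
               quote = "\"", comment.char = "", strip.white = TRUE)
  }
  if (nrow(df) == 0) {
    out <- data.frame(taxon = character(0), femur_mm = numeric(0),
                      log10_femur = numeric(0), age_Ma = numeric(0))
    class(out) <- c("tip_data", class(out))
    return(out)
  }
  names(df)[1] <- "taxon"
  aliases <- c(max_femur_mm = "femur_mm", femur = "femur_mm",
               log10femur = "log10_femur", age = "age_Ma")
  for (a in names(aliases)) {
    hit <- which(tolower(names(df)) == a)
    if (length(hit)) names(df)[hit[1]] <- aliases[a]
  }
  num_cols <- intersect(c("femur_mm", "log10_femur", "age_Ma",
                          "body_length_m", "element_length_mm"), names(df))
  for (cc in num_cols) {
    raw <- as.character(df[[cc]])
    if (decimal_comma) raw <- gsub(",", ".", raw, fixed = TRUE)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & nzchar(trimws(raw)) & !is.na(df[[cc]]))
    if (length(bad))
      stop("unparseable numeric cell in row ", bad[1], ", column '", cc,
           "': '", df[[cc]][bad[1]], "'")
    df[[cc]] <- val
  }
  if (all(c("femur_mm", "log10_femur") %in% names(df))) {
    both <- which(!is.na(df$femur_mm) & !is.na(df$log10_femur))
    off <- both[abs(log10(df$femur_mm[both]) - df$log10_femur[both]) > 1e-6]
    if (length(off))
      stop("log10 column inconsistent with femur length in row(s): ",
           paste(off, collapse = ", "))
  }
  if ("age_Ma" %in% names(df) && any(df$age_Ma <= 0, na.rm = TRUE))
    stop("tip ages must be strictly positive")
  class(df) <- c("tip_data", class(df))
  df
}

#' Path to a packaged data file
#'
#' @param name file name under the package's \code{extdata} directory;
#'   with no argument, lists the available files.
#' @return a file path (or a vector of file names).
#' @export
paleosize_extdata <- function(name = NULL) {
  dir <- system.file("extdata", package = "paleosize")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop("no packaged file '", name, "'; available: ",
         paste(list.files(dir), collapse = ", "))
  path
}

#' Packaged ornithopod femur-length and age table
#'
#' The curated comparative table of maximum femoral lengths (mm, with
#' log10) and stratigraphic-range midpoint ages (Ma) for basal ornithopods
#' from Orodromeus to Planicoxa, including all rhabdodontids.  The three
#' Rhabdodon entries (820 mm genus maximum used in the primary analysis,
#' 600 mm R. priscus, and the 210 mm small adult form) are distinct rows;
#' the primary 25-taxon analysis uses \code{Rhabdodon_sp} only.
#'
#' @return a \code{tip_data} data frame (27 rows).
#' @export
load_femur_table <- function() {
  read_tip_table(file = paleosize_extdata("ornithopod_femora.csv"))
}

#' Packaged rhabdodontid skeletal-element measurement table
#'
#' Histologically sampled limb elements of Mochlodon, Zalmoxes and
#' Rhabdodon: measured or estimated element length (mm), the inferred
#' femur-equivalent length (mm), the estimated total body length (m), and
#' the ontogenetic stage from bone histology.
#'
#' @return a data frame (28 rows).
#' @export
load_element_table <- function() {
  df <- read.table(paleosize_extdata("rhabdodontid_elements.csv"), sep = ";",
                   header = TRUE, stringsAsFactors = FALSE)
  for (cc in c("element_length_mm", "femur_length_mm", "body_length_m"))
    df[[cc]] <- as.numeric(gsub(",", ".", df[[cc]], fixed = TRUE))
  df$element_estimated <- df$element_estimated == "yes"
  df$femur_estimated <- df$femur_estimated == "yes"
  df
}

#' Packaged 25-taxon ornithopod backbone topology
#'
#' The composite reference topology used for the body-size analyses: the
#' rhabdodontid clade (Rhabdodon, (Mochlodon, Zalmoxes)) nested among basal
#' ornithopods, with the dryosaurid and basal ankylopollexian insertions.
#' The backbone outside Rhabdodontidae is a curated assembly and can be
#' substituted by any user tree with the same tip labels.
#'
#' @return a rooted \code{phylo} (25 tips, no branch lengths).
#' @export
load_backbone_tree <- function() {
  read_newick(file = paleosize_extdata("ornithopod_backbone.nwk"))
}
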