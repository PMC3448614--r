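#' Construct a morphological character matrix
#'
#' The container used by the parsimony engine: taxa by characters, each cell
#' a state set.  Cells are given as strings: a single state symbol, a
#' polymorphism \code{"{01}"} (or \code{"(01)"}), \code{"?"} for missing, or
#' \code{"-"} for inapplicable.  Missing and inapplicable cells are scored
#' as the full state set of their character, the standard parsimony
#' convention.
#'
#' @param cells character matrix (taxa x characters) of cell tokens.
#' @param taxa taxon labels (rownames of \code{cells} by default).
#' @param ordered logical vector: characters whose states lie on a linear
#'   scale, with change cost |i - j| (default all unordered, cost 1).
#' @param active logical vector; inactive characters are excluded from tree
#'   lengths and ensemble indices.
#' @param weights numeric character weights (default 1).
#' @param symbols state alphabet, by symbol position (default digits 0-9).
#' @return an object of class \code{char_matrix}.
#' @export
character_matrix <- function(cells, taxa = rownames(cells), ordered = FALSE,
                             active = TRUE, weights = 1,
                             symbols = as.character(0:9)) {
  cells <- as.matrix(cells)
  if (is.null(taxa)) stop("taxon labels required")
  nchr <- ncol(cells)
  ntax <- nrow(cells)
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  ordered <- rep_len(ordered, nchr)
  active <- rep_len(active, nchr)
  weights <- rep_len(as.numeric(weights), nchr)
  dimnames(cells) <- NULL

  state_idx <- function(tok) {
    # indices (0-based) of the states named in a cell token, NULL for ?/-
    if (tok %in% c("?", "-")) return(NULL)
    chars <- strsplit(gsub("[{}()]", "", tok), "")[[1]]
    idx <- match(chars, symbols) - 1L
    if (anyNA(idx)) stop("unknown state symbol in cell '", tok, "'")
    idx
  }
  obs <- vector("list", nchr)
  for (j in seq_len(nchr)) {
    ids <- unlist(lapply(cells[, j], state_idx))
    obs[[j]] <- if (is.null(ids)) integer(0) else sort(unique(ids))
  }
  nstates <- vapply(obs, function(o) if (length(o)) max(o) + 1L else 1L, 1L)
  masks <- matrix(0L, ntax, nchr)
  for (j in seq_len(nchr)) {
    full <- bitwShiftL(1L, nstates[j]) - 1L
    for (i in seq_len(ntax)) {
      idx <- state_idx(cells[i, j])
      masks[i, j] <- if (is.null(idx)) full else
        sum(bitwShiftL(1L, idx))
    }
  }
  structure(list(taxa = as.character(taxa), cells = cells, masks = masks,
                 nstates = nstates, ordered = ordered, active = active,
                 weights = weights, symbols = symbols),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d taxa x %d characters\n",
              length(x$taxa), ncol(x$cells)))
  cat(sprintf("  %d ordered, %d inactive, %d with missing data\n",
              sum(x$ordered), sum(!x$active),
              sum(apply(x$cells, 2, function(cc) any(cc %in% c("?", "-"))))))
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) c(length(x$taxa), ncol(x$cells))

#' Read a character matrix (NEXUS subset, TNT xread, or plain rows)
#'
#' A dialect-tolerant reader for the text formats morphological matrices
#' circulate in.  The NEXUS subset covers DATA/CHARACTERS blocks with
#' DIMENSIONS, FORMAT (SYMBOLS, MISSING, GAP) and MATRIX (interleaved rows
#' are accumulated per taxon); the TNT dialect covers a plain
#' \code{xread 'title' nchar ntax} block.  Polymorphic cells may be written
#' \code{\{01\}} or \code{(01)}.
#'
#' @param text matrix text; or use \code{file}.
#' @param file path to a matrix file.
#' @param format \code{"auto"} (detect), \code{"nexus"}, \code{"tnt"}, or
#'   \code{"plain"} (whitespace-separated \code{taxon states} rows).
#' @param strip_leading_dummy drop an all-zero first character (as added to
#'   matrices so that programs numbering characters from 0 line up with a
#'   1-based character list); character numbering then shifts down by one.
#'   It is an error if the first character is not all-zero.
#' @param ordered_indices 1-based character numbers (after any dummy
#'   stripping) to flag as ordered.
#' @return a \code{char_matrix}.
#' @export
read_matrix <- function(text = NULL, file = NULL,
                        format = c("auto", "nexus", "tnt", "plain"),
                        strip_leading_dummy = FALSE, ordered_indices = NULL) {
  format <- match.arg(format)
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("^\\s*#nexus", text, ignore.case = TRUE)) "nexus"
              else if (grepl("\\bxread\\b", text, ignore.case = TRUE)) "tnt"
              else "plain"
  }
  parsed <- switch(format,
                   nexus = parse_nexus_matrix(text),
                   tnt = parse_tnt_matrix(text),
                   plain = parse_plain_matrix(text))
  cells <- parsed$cells
  nchr <- ncol(cells)
  if (!is.null(parsed$ntax) && parsed$ntax != nrow(cells))
    stop("header declares ", parsed$ntax, " taxa but matrix has ", nrow(cells))
  if (!is.null(parsed$nchar) && parsed$nchar != nchr)
    stop("header declares ", parsed$nchar, " characters but matrix has ", nchr)
  if (strip_leading_dummy) {
    if (!all(cells[, 1] == "0"))
      stop("strip_leading_dummy requested but first character is not all-zero")
    cells <- cells[, -1, drop = FALSE]
    nchr <- nchr - 1L
  }
  ordered <- rep(FALSE, nchr)
  if (!is.null(ordered_indices)) {
    if (any(ordered_indices < 1 | ordered_indices > nchr))
      stop("ordered_indices out of range 1..", nchr)
    ordered[ordered_indices] <- TRUE
  }
  character_matrix(cells, taxa = parsed$taxa, ordered = ordered,
                   symbols = parsed$symbols %||% as.character(0:9))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a state string like "01{23}?(01)-" into cell tokens.
tokenize_states <- function(s, rowname = "") {
  chars <- strsplit(s, "")[[1]]
  toks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars))
        stop("unclosed polymorphism in row '", rowname, "'")
      toks <- c(toks, paste0("{", paste(chars[(i + 1):(j - 1)], collapse = ""), "}"))
      i <- j + 1L
    } else if (grepl("\\s", ch)) {
      i <- i + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

# Rows arrive as "taxon  statestring"; accumulate per taxon (handles
# interleaved blocks), then check for raggedness.
rows_to_cells <- function(lines) {
  taxa <- character(0)
  cells <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^('[^']+'|\"[^\"]+\"|\\S+)\\s+(.*)$", ln))[[1]]
    if (length(m) < 3) stop("cannot parse matrix row: '", ln, "'")
    tax <- gsub("^['\"]|['\"]$", "", m[2])
    toks <- tokenize_states(m[3], tax)
    k <- match(tax, taxa)
    if (is.na(k)) { taxa <- c(taxa, tax); cells[[length(taxa)]] <- toks }
    else cells[[k]] <- c(cells[[k]], toks)
  }
  if (!length(taxa)) return(list(taxa = character(0),
                                 cells = matrix(character(0), 0, 0)))
  lens <- lengths(cells)
  if (length(unique(lens)) != 1)
    stop("ragged matrix: rows have ", paste(unique(lens), collapse = "/"),
         " characters (taxa ", paste(taxa[lens != max(lens)], collapse = ", "), ")")
  list(taxa = taxa, cells = do.call(rbind, cells))
}

strip_nexus_comments <- function(text) gsub("\\[[^]]*\\]", "", text)

parse_nexus_matrix <- function(text) {
  text <- strip_nexus_comments(text)
  ntax <- nchar_ <- NULL
  symbols <- NULL
  m <- regmatches(text, regexec("NTAX\\s*=\\s*([0-9]+)", text, ignore.case = TRUE))[[1]]
  if (length(m)) ntax <- as.integer(m[2])
  m <- regmatches(text, regexec("NCHAR\\s*=\\s*([0-9]+)", text, ignore.case = TRUE))[[1]]
  if (length(m)) nchar_ <- as.integer(m[2])
  m <- regmatches(text, regexec("SYMBOLS\\s*=\\s*\"([^\"]*)\"", text, ignore.case = TRUE))[[1]]
  if (length(m)) symbols <- strsplit(gsub("\\s", "", m[2]), "")[[1]]
  m <- regexpr("MATRIX", text, ignore.case = TRUE)
  if (m < 0) stop("no MATRIX keyword found in NEXUS input")
  body <- substr(text, m + attr(m, "match.length"), nchar(text))
  end <- regexpr(";", body, fixed = TRUE)
  if (end < 0) stop("MATRIX block not terminated by ';'")
  body <- substr(body, 1, end - 1)
  out <- rows_to_cells(strsplit(body, "\n")[[1]])
  c(out, list(ntax = ntax, nchar = nchar_, symbols = symbols))
}

parse_tnt_matrix <- function(text) {
  # xread ['title'] nchar ntax <rows> ;
  text <- sub("^.*?\\bxread\\b", "", text, ignore.case = TRUE)
  text <- sub("'[^']*'", "", text)   # optional quoted title
  m <- regexec("^\\s*([0-9]+)\\s+([0-9]+)\\s*\n(.*)$", text)
  g <- regmatches(text, m)[[1]]
  if (length(g) < 4) stop("cannot parse TNT xread header (expected 'nchar ntax')")
  nchar_ <- as.integer(g[2]); ntax <- as.integer(g[3])
  body <- strsplit(g[4], "\n")[[1]]
  body <- body[!grepl("^\\s*&", body)]           # interleave markers
  stop_at <- grep(";", body, fixed = TRUE)
  if (length(stop_at)) {
    body[stop_at[1]] <- sub(";.*$", "", body[stop_at[1]])
    body <- body[seq_len(stop_at[1])]
  }
  out <- rows_to_cells(body)
  c(out, list(ntax = ntax, nchar = nchar_, symbols = NULL))
}

parse_plain_matrix <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  lines <- lines[!grepl("^\\s*#", lines)]
  rows_to_cells(lines)
}

#' Serialize a character matrix
#'
#' Writes a \code{char_matrix} back to text; parsing the result reproduces
#' the cell contents exactly.
#'
#' @param x a \code{char_matrix}.
#' @param format \code{"nexus"}, \code{"tnt"} or \code{"plain"}.
#' @param file optional output path.
#' @return the text (invisibly when written to file).
#' @export
write_matrix <- function(x, format = c("nexus", "tnt", "plain"), file = NULL) {
  format <- match.arg(format)
  ntax <- length(x$taxa); nchr <- ncol(x$cells)
  lab <- ifelse(grepl("\\s", x$taxa), paste0("'", x$taxa, "'"), x$taxa)
  pad <- formatC(lab, width = max(nchar(lab)) + 2, flag = "-")
  rows <- paste0(pad, apply(x$cells, 1, paste, collapse = ""))
  out <- switch(format,
    nexus = paste0("#NEXUS\nBEGIN DATA;\nDIMENSIONS NTAX=", ntax,
                   " NCHAR=", nchr, ";\nFORMAT SYMBOLS=\"",
                   paste(x$symbols, collapse = ""),
                   "\" MISSING=? GAP=-;\nMATRIX\n",
                   paste(rows, collapse = "\n"), "\n;\nEND;\n"),
    tnt = paste0("xread 'exported matrix'\n", nchr, " ", ntax, "\n",
                 paste(rows, collapse = "\n"), "\n;\n"),
    plain = paste0(paste(rows, collapse = "\n"), "\n"))
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}
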