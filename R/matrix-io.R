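#' Read a character matrix from NEXUS or a delimited table
#'
#' The NEXUS reader handles `CHARACTERS`/`DATA` blocks with standard
#' symbols `0-9`, polymorphism written as `{01}` or `(01)`, missing as
#' `?` (or the `MISSING` symbol declared in `FORMAT`) and gap `-`
#' (treated as missing). An optional `ASSUMPTIONS` block `TYPESET`
#' declaring `ord:`/`unord:` character lists sets the per-character
#' `ordered` flags. The table reader expects taxa in the first column
#' and one column per character, cells like `"0"`, `"0/1"`, `"?"`.
#'
#' @param path input file.
#' @param format `"nexus"` or `"table"`.
#' @param sep field separator for `format = "table"` (default tab).
#' @return a [characterMatrix()] object.
#' @export
readCharacterMatrix <- function(path, format = c("nexus", "table"), sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (format == "table") {
    df <- utils::read.delim(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE, colClasses = "character")
    m <- as.matrix(df)
    cm <- characterMatrix(m, taxa = rownames(m))
    cm$meta$id <- colnames(m)
    cm$meta$label <- colnames(m)
    dimnames(cm$cells) <- list(cm$taxa, cm$meta$id)
    return(validateCharacterMatrix(cm))
  }
  readNexusCharacters(path)
}

readNexusCharacters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)          # strip NEXUS comments
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header): ", path)
  upper <- toupper(txt)
  blockStart <- regexpr("BEGIN\\s+(CHARACTERS|DATA)\\s*;", upper)
  if (blockStart < 0) stop("no CHARACTERS/DATA block in ", path)
  rest <- substr(txt, blockStart, nchar(txt))
  blockEnd <- regexpr("END\\s*;", toupper(rest))
  block <- substr(rest, 1, blockEnd - 1)

  getNum <- function(key) {
    m <- regmatches(block, regexpr(paste0("(?i)", key, "\\s*=\\s*[0-9]+"),
                                   block, perl = TRUE))
    if (!length(m)) return(NA_integer_)
    as.integer(sub(".*=\\s*", "", m))
  }
  ntax <- getNum("NTAX"); nchar_ <- getNum("NCHAR")
  missTok <- regmatches(block, regexpr("(?i)MISSING\\s*=\\s*\\S", block, perl = TRUE))
  missChar <- if (length(missTok)) substr(missTok, nchar(missTok), nchar(missTok)) else "?"

  matStart <- regexpr("(?i)MATRIX", block, perl = TRUE)
  if (matStart < 0) stop("no MATRIX command in ", path)
  matTxt <- substr(block, matStart + 6, nchar(block))
  matTxt <- sub(";.*$", "", matTxt)
  rows <- trimws(strsplit(matTxt, "\n")[[1]])
  rows <- rows[nzchar(rows)]

  taxa <- character(0); cellList <- list()
  for (row in rows) {
    name <- sub("\\s.*$", "", row)
    if (grepl("^'", row)) {                    # quoted taxon label
      name <- sub("^'([^']*)'.*$", "\\1", row)
      states <- sub("^'[^']*'\\s*", "", row)
    } else states <- sub("^\\S+\\s*", "", row)
    states <- gsub("\\s", "", states)
    cells <- tokenizeStateRow(states, missChar)
    if (name %in% taxa) {                      # interleaved continuation
      k <- match(name, taxa)
      cellList[[k]] <- c(cellList[[k]], cells)
    } else {
      taxa <- c(taxa, name)
      cellList[[length(taxa)]] <- cells
    }
  }
  lens <- lengths(cellList)
  if (length(unique(lens)) != 1L)
    stop("unequal row lengths in MATRIX of ", path)
  if (!is.na(nchar_) && lens[1] != nchar_)
    stop("MATRIX rows have ", lens[1], " characters but NCHAR=", nchar_)
  if (!is.na(ntax) && length(taxa) != ntax)
    stop("MATRIX has ", length(taxa), " taxa but NTAX=", ntax)
  cells <- matrix(do.call(c, cellList), nrow = length(taxa), byrow = TRUE)
  cm <- characterMatrix(cells, taxa = taxa)

  # optional ASSUMPTIONS / TYPESET ordering declarations
  ordIdx <- parseTypeset(txt, nrow(cm$meta))
  if (length(ordIdx)) cm$meta$ordered[ordIdx] <- TRUE
  validateCharacterMatrix(cm)
}

# split a compact NEXUS state row into a list of state sets
tokenizeStateRow <- function(s, missChar = "?") {
  out <- list(); i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i
      while (j <= n && substr(s, j, j) != close) j <- j + 1L
      if (j > n) stop("unbalanced ", ch, " in matrix row")
      out[[length(out) + 1L]] <-
        sort(unique(as.integer(strsplit(substr(s, i + 1L, j - 1L), "")[[1]])))
      i <- j + 1L
    } else {
      out[[length(out) + 1L]] <-
        if (ch %in% c(missChar, "-", "?")) integer(0) else as.integer(ch)
      i <- i + 1L
    }
  }
  out
}

parseTypeset <- function(txt, nChar) {
  m <- regmatches(txt, regexpr("(?is)TYPESET[^;]*;", txt, perl = TRUE))
  if (!length(m)) return(integer(0))
  ord <- regmatches(m, regexpr("(?i)ord\\s*:\\s*[0-9 \\-]+", m, perl = TRUE))
  if (!length(ord)) return(integer(0))
  spec <- trimws(sub("(?i)ord\\s*:\\s*", "", ord, perl = TRUE))
  idx <- integer(0)
  for (tok in strsplit(spec, "\\s+")[[1]]) {
    if (grepl("-", tok)) {
      ab <- as.integer(strsplit(tok, "-")[[1]])
      idx <- c(idx, seq(ab[1], ab[2]))
    } else idx <- c(idx, as.integer(tok))
  }
  idx[idx >= 1 & idx <= nChar]
}

#' Write a character matrix to NEXUS or a delimited table
#'
#' NEXUS output uses `{}` for polymorphic cells and `?` for missing, and
#' records ordered characters in an `ASSUMPTIONS` block `TYPESET` so the
#' flags survive a round trip.
#'
#' @param cm a `charMatrix`.
#' @param path output file.
#' @param format `"nexus"` or `"table"`.
#' @return `path`, invisibly.
#' @export
writeCharacterMatrix <- function(cm, path, format = c("nexus", "table")) {
  format <- match.arg(format)
  if (format == "table") {
    m <- apply(cm$cells, c(1, 2), function(cell) {
      s <- cell[[1]]
      if (!length(s)) "?" else paste(s, collapse = "/")
    })
    df <- data.frame(taxon = cm$taxa, m, check.names = FALSE)
    colnames(df) <- c("taxon", cm$meta$id)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  fmtCell <- function(s) {
    if (!length(s)) "?"
    else if (length(s) == 1L) as.character(s)
    else paste0("{", paste(s, collapse = ""), "}")
  }
  rows <- vapply(seq_along(cm$taxa), function(i) {
    paste0(format(cm$taxa[i], width = max(nchar(cm$taxa)) + 2L),
           paste(vapply(cm$cells[i, ], fmtCell, character(1)), collapse = ""))
  }, character(1))
  maxSym <- max(cm$meta$n_states) - 1L
  out <- c("#NEXUS", "",
           "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(cm$taxa), nrow(cm$meta)),
           sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;",
                   paste(0:maxSym, collapse = "")),
           "  MATRIX", paste0("    ", rows), "  ;", "END;")
  if (any(cm$meta$ordered)) {
    out <- c(out, "",
             "BEGIN ASSUMPTIONS;",
             sprintf("  TYPESET * mygatypes = ord: %s, unord: %s;",
                     paste(which(cm$meta$ordered), collapse = " "),
                     paste(which(!cm$meta$ordered), collapse = " ")),
             "END;")
  }
  writeLines(out, path)
  invisible(path)
}
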