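#' Discrete character matrix with state-set cells
#'
#' The central data container for scored characters: a taxa-by-characters
#' grid whose cells are *sets* of integer states. A cell with two or more
#' states records a polymorphic taxon; an empty set records a missing
#' score. Per-character metadata carries an identifier (e.g. `"C11"`),
#' a label, the number of states, and whether the character is ordered
#' (states form a linear series) or unordered.
#'
#' @param cells a `nTaxa x nChar` matrix of mode `list`, each element an
#'   integer vector of states (possibly empty = missing), *or* a
#'   character matrix of cell strings such as `"0"`, `"0/1"`, `"{01}"`,
#'   `"(01)"`, `"?"`, `"-"` which is parsed with [parseCellToken()].
#' @param taxa character vector of taxon labels (defaults to rownames).
#' @param meta data frame with columns `id`, `label`, `n_states`,
#'   `ordered`; defaults are generated from the data (ids `C1..Cn`,
#'   `n_states` = 1 + max observed state, unordered).
#' @return an object of class `charMatrix`.
#' @examples
#' m <- matrix(c("0", "1", "0/1", "?"), 2, 2,
#'             dimnames = list(c("Aname", "Atrax"), NULL))
#' cm <- characterMatrix(m)
#' cellStates(cm, "Aname", "C2")
#' @export
characterMatrix <- function(cells, taxa = NULL, meta = NULL) {
  if (is.character(cells)) {
    raw <- cells
    cells <- matrix(lapply(raw, parseCellToken), nrow(raw), ncol(raw),
                    dimnames = dimnames(raw))
  }
  stopifnot(is.matrix(cells), is.list(cells))
  if (is.null(taxa)) taxa <- rownames(cells)
  if (is.null(taxa)) stop("taxa labels required (argument or rownames)")
  nChar <- ncol(cells)
  if (is.null(meta)) {
    maxState <- vapply(seq_len(nChar), function(j) {
      s <- unlist(cells[, j])
      if (length(s)) max(s) else 0L
    }, integer(1))
    meta <- data.frame(id = paste0("C", seq_len(nChar)),
                       label = paste0("C", seq_len(nChar)),
                       n_states = pmax(maxState + 1L, 2L),
                       ordered = FALSE,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "n_states", "ordered") %in% names(meta)),
            nrow(meta) == nChar)
  if (is.null(meta$label)) meta$label <- meta$id
  dimnames(cells) <- list(taxa, meta$id)
  obj <- structure(list(taxa = as.character(taxa), meta = meta, cells = cells),
                   class = "charMatrix")
  validateCharacterMatrix(obj)
}

#' Parse one matrix cell token into a state set
#'
#' Accepts single digits (`"3"`), polymorphism as `"{01}"`, `"(01)"`, or
#' slash/comma-delimited (`"0/1"`, `"0,2"`), and the missing markers
#' `"?"`, `"-"` and `""` (empty integer vector).
#' @param token a single cell string.
#' @return sorted integer vector of states (possibly empty).
#' @export
parseCellToken <- function(token) {
  token <- trimws(token)
  if (is.na(token) || token %in% c("?", "-", "")) return(integer(0))
  inner <- gsub("^[{(]|[})]$", "", token)
  parts <- strsplit(inner, "[/,]")[[1]]
  if (length(parts) == 1L && nchar(parts) > 1L)
    parts <- strsplit(parts, "")[[1]]            # "{01}" compact form
  states <- suppressWarnings(as.integer(parts))
  if (anyNA(states)) stop("cannot parse cell token: '", token, "'")
  sort(unique(states))
}

#' Validate the character-matrix contract
#'
#' Every cell's states must be non-negative integers below the
#' character's `n_states`; taxa labels unique.
#' @param cm a `charMatrix`.
#' @return `cm`, invisibly; stops otherwise.
#' @export
validateCharacterMatrix <- function(cm) {
  stopifnot(inherits(cm, "charMatrix"))
  if (anyDuplicated(cm$taxa)) stop("duplicate taxon labels")
  if (anyDuplicated(cm$meta$id)) stop("duplicate character ids")
  for (j in seq_len(ncol(cm$cells))) {
    k <- cm$meta$n_states[j]
    s <- unlist(cm$cells[, j])
    if (length(s) && (any(s < 0L) || any(s >= k)))
      stop("character ", cm$meta$id[j], ": state outside 0..", k - 1L)
  }
  invisible(cm)
}

#' @export
print.charMatrix <- function(x, ...) {
  cat("charMatrix:", length(x$taxa), "taxa x", nrow(x$meta), "characters\n")
  nMiss <- sum(vapply(x$cells, length, integer(1)) == 0L)
  nPoly <- sum(vapply(x$cells, length, integer(1)) >= 2L)
  cat("  missing cells:", nMiss, " polymorphic cells:", nPoly, "\n")
  cat("  characters:", paste(utils::head(x$meta$id, 8), collapse = ", "),
      if (nrow(x$meta) > 8) "...", "\n")
  invisible(x)
}

#' Accessors for `charMatrix` objects
#'
#' @param cm a `charMatrix`.
#' @param taxon,char taxon label and character id.
#' @return `taxaNames`/`charIds`: character vectors; `cellStates`: the
#'   integer state set of one cell; `charStates`: a named list of state
#'   sets for one character across all taxa.
#' @name charMatrix-accessors
#' @export
taxaNames <- function(cm) cm$taxa

#' @rdname charMatrix-accessors
#' @export
charIds <- function(cm) cm$meta$id

#' @rdname charMatrix-accessors
#' @export
cellStates <- function(cm, taxon, char) cm$cells[[taxon, char]]

#' @rdname charMatrix-accessors
#' @export
charStates <- function(cm, char) {
  stats::setNames(cm$cells[, char], cm$taxa)
}

#' Subset a character matrix
#'
#' @param x a `charMatrix`.
#' @param i taxa (labels or indices); @param j characters (ids or indices).
#' @param ... ignored.
#' @return a `charMatrix` on the selected taxa/characters.
#' @export
`[.charMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$taxa)
  if (missing(j)) j <- seq_len(nrow(x$meta))
  if (is.character(j)) j <- match(j, x$meta$id)
  cells <- x$cells[i, j, drop = FALSE]
  characterMatrix(cells, taxa = rownames(cells),
                  meta = x$meta[j, , drop = FALSE])
}

#' Restrict a tree and matrix to their common taxa
#'
#' Analyses operate on the intersection of tree tips and matrix taxa;
#' names dropped from either side are reported via a message and
#' attached as attributes for the run log.
#'
#' @param phy an [ape::phylo] object.
#' @param cm a `charMatrix`.
#' @return list with elements `tree`, `matrix`, `dropped_from_tree`,
#'   `dropped_from_matrix`.
#' @export
intersectTaxa <- function(phy, cm) {
  common <- intersect(phy$tip.label, cm$taxa)
  if (length(common) < 3L) stop("fewer than 3 taxa shared by tree and matrix")
  dropT <- setdiff(phy$tip.label, common)
  dropM <- setdiff(cm$taxa, common)
  if (length(dropT) || length(dropM))
    message("intersectTaxa: dropped ", length(dropT), " tree tips, ",
            length(dropM), " matrix taxa")
  phy2 <- if (length(dropT)) ape::keep.tip(phy, common) else phy
  list(tree = phy2, matrix = cm[common, ],
       dropped_from_tree = dropT, dropped_from_matrix = dropM)
}
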