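#' Baum-Ragan matrix representation of a set of input trees
#'
#' Encodes every informative clade (non-root internal node with at
#' least 2 members and at least 1 non-member among its source tree's
#' tips) of every rooted input tree as a binary pseudo-character:
#' clade members score 1, the source tree's other taxa 0, and taxa
#' absent from that tree are missing. An all-zero pseudo-outgroup row
#' is appended for rooting the parsimony search.
#'
#' @param trees list (or `multiPhylo`) of rooted input trees with
#'   overlapping tip sets.
#' @param taxa optional taxon universe (defaults to the union of tip
#'   sets); useful when some taxa occur in no encoded clade.
#' @param outgroupLabel label of the all-zero pseudo-outgroup row.
#' @return object of class `mrpMatrix`: `mat` (taxa + outgroup rows by
#'   clade columns, entries 0/1/NA), `taxa`, `outgroup`, `provenance`
#'   (data frame: source tree, clade id, clade size).
#' @export
encodeMRP <- function(trees, taxa = NULL, outgroupLabel = "MRP_outgroup") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    flagged <- isFALSE(attr(tr, "rooted"))
    # ape's unrooted shape: basal multifurcation above internal structure
    # (a pure star is accepted: it is rooted as written, just uninformative)
    if (flagged || (!ape::is.rooted(tr) && tr$Nnode > 1L))
      stop("input tree ", i, " is unrooted: root it first (e.g. on the ",
           "study outgroup) before MRP encoding")
  }
  universe <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  if (!is.null(taxa)) universe <- sort(unique(c(universe, taxa)))
  if (outgroupLabel %in% universe)
    stop("outgroup label collides with a taxon name")
  cols <- list(); prov <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    tips <- tr$tip.label
    clades <- ape::prop.part(tr)
    for (ci in seq_along(clades)) {
      members <- tips[clades[[ci]]]
      if (length(members) < 2L || length(members) >= length(tips)) next
      col <- rep(NA_integer_, length(universe))
      names(col) <- universe
      col[tips] <- 0L
      col[members] <- 1L
      cols[[length(cols) + 1L]] <- col
      prov[[length(prov) + 1L]] <-
        data.frame(source = i, clade = ci, size = length(members))
    }
  }
  mat <- if (length(cols)) rbind(do.call(cbind, cols), 0L) else
    matrix(integer(0), nrow = length(universe) + 1L)
  rownames(mat) <- c(universe, outgroupLabel)
  if (length(cols)) colnames(mat) <- paste0("mrp", seq_along(cols))
  structure(list(mat = mat, taxa = universe, outgroup = outgroupLabel,
                 provenance = if (length(prov)) do.call(rbind, prov)
                              else data.frame()),
            class = "mrpMatrix")
}

#' @export
print.mrpMatrix <- function(x, ...) {
  cat("mrpMatrix:", length(x$taxa), "taxa (+ pseudo-outgroup),",
      ncol(x$mat), "clade columns from",
      length(unique(x$provenance$source)), "input trees\n")
  invisible(x)
}

#' Convert an MRP matrix to a character matrix
#'
#' Allows NEXUS export of the pseudo-character matrix via
#' [writeCharacterMatrix()] for external verification.
#' @param mrp an `mrpMatrix`.
#' @return a `charMatrix` of binary characters with NA cells as missing.
#' @export
mrpAsCharacterMatrix <- function(mrp) {
  m <- mrp$mat
  cells <- matrix(lapply(seq_along(m), function(i)
    if (is.na(m[i])) integer(0) else as.integer(m[i])),
    nrow(m), ncol(m), dimnames = dimnames(m))
  characterMatrix(cells, taxa = rownames(m))
}

mrpToPhyDat <- function(mrp) {
  m <- matrix(as.character(mrp$mat), nrow(mrp$mat),
              dimnames = dimnames(mrp$mat))
  m[is.na(m)] <- "?"
  phangorn::phyDat(m, type = "USER", levels = c("0", "1"), ambiguity = "?")
}

#' Heuristic parsimony search on an MRP matrix
#'
#' Random-addition starting trees followed by NNI then SPR
#' hill-climbing (Fitch parsimony; missing entries free to take any
#' state). All equally most-parsimonious topologies found across starts
#' are returned, rooted on the all-zero pseudo-outgroup (which is then
#' removed). Returned supertrees are topology-only (no branch lengths).
#'
#' @param mrp an `mrpMatrix` from [encodeMRP()].
#' @param nStarts number of random-addition starts (>= 1).
#' @param seed integer seed.
#' @return object of class `mrpSearch`: `trees` (`multiPhylo` of
#'   distinct optimal rooted supertrees), `score` (best parsimony
#'   length), `start_scores` (score of each random-addition start,
#'   before rearrangement).
#' @export
parsimonySearch <- function(mrp, nStarts = 10L, seed = 1L) {
  stopifnot(inherits(mrp, "mrpMatrix"))
  if (nStarts < 1L) stop("nStarts must be >= 1")
  if (!ncol(mrp$mat)) stop("empty MRP matrix: nothing to optimize")
  pd <- mrpToPhyDat(mrp)
  found <- list(); scores <- numeric(0); startScores <- numeric(0)
  withSeed(seed, {
    for (s in seq_len(nStarts)) {
      tr0 <- phangorn::random.addition(pd)
      startScores[s] <- phangorn::parsimony(tr0, pd)
      tr1 <- phangorn::optim.parsimony(tr0, pd, method = "fitch",
                                       rearrangements = "NNI", trace = 0)
      tr2 <- phangorn::optim.parsimony(tr1, pd, method = "fitch",
                                       rearrangements = "SPR", trace = 0)
      found[[s]] <- tr2
      scores[s] <- phangorn::parsimony(tr2, pd)
    }
  })
  best <- min(scores)
  keep <- found[scores == best]
  # deduplicate topologies
  uniq <- list()
  for (tr in keep) {
    dup <- any(vapply(uniq, function(u)
      phangorn::RF.dist(u, tr, check.labels = TRUE) == 0, logical(1)))
    if (!dup) uniq[[length(uniq) + 1L]] <- tr
  }
  rooted <- lapply(uniq, function(tr) {
    tr <- ape::root(tr, outgroup = mrp$outgroup, resolve.root = TRUE)
    tr <- ape::drop.tip(tr, mrp$outgroup)
    tr$edge.length <- NULL
    tr
  })
  class(rooted) <- "multiPhylo"
  structure(list(trees = rooted, score = best, start_scores = startScores,
                 n_starts = nStarts, seed = seed),
            class = "mrpSearch")
}

#' @export
print.mrpSearch <- function(x, ...) {
  cat("MRP parsimony search:", length(x$trees),
      "optimal topologies at length", x$score, "\n")
  cat("  start scores:", paste(x$start_scores, collapse = ", "), "\n")
  invisible(x)
}

#' Strict consensus of equally parsimonious trees
#'
#' Keeps exactly the clades present in every input tree. All trees must
#' share an identical tip set.
#' @param trees `multiPhylo` or list of `phylo` objects.
#' @return a single (possibly polytomous) `phylo`.
#' @export
strictConsensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  tipSets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(tipSets, identical, logical(1), tipSets[[1]])))
    stop("strict consensus requires identical tip sets")
  if (length(trees) == 1L) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = ape::is.rooted(trees[[1]]))
}
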