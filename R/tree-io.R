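#' Read a rooted phylogeny from Newick or NEXUS
#'
#' Thin, validating wrapper around [ape::read.tree()] /
#' [ape::read.nexus()]. Branch lengths are preserved exactly as written;
#' they may be absent entirely (a topology-only tree such as an MRP
#' supertree) but must not be present on only some edges. Unrooted input
#' is accepted and flagged via the `"rooted"` attribute so that
#' operations requiring a root can refuse it explicitly.
#'
#' @param path path to the tree file.
#' @param format `"newick"` or `"nexus"`.
#' @return an [ape::phylo] object with attribute `rooted` (`TRUE`,
#'   `FALSE`, or `NA` when the root is a basal polytomy so rooting is
#'   ambiguous).
#' @seealso [writePhyloTree()], [validatePhyloTree()]
#' @export
readPhyloTree <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  phy <- tryCatch(
    switch(format,
      newick = ape::read.tree(path),
      nexus  = ape::read.nexus(path)
    ),
    error = function(e) stop("failed to parse '", path, "' as ", format,
                             ": ", conditionMessage(e), call. = FALSE)
  )
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) == 1L) phy <- phy[[1L]] else {
      phy <- lapply(phy, annotateRooting)
      lapply(phy, validatePhyloTree)
      class(phy) <- "multiPhylo"
      return(phy)
    }
  }
  if (is.null(phy)) stop("failed to parse '", path, "' as ", format)
  phy <- annotateRooting(phy)
  validatePhyloTree(phy)
  phy
}

annotateRooting <- function(phy) {
  rootChildren <- sum(phy$edge[, 1] == ape::Ntip(phy) + 1L)
  attr(phy, "rooted") <-
    if (ape::is.rooted(phy)) TRUE
    else if (rootChildren > 2L) NA           # basal polytomy: ambiguous
    else FALSE
  phy
}

#' Validate the phylogeny contract
#'
#' Checks the invariants assumed throughout the package: unique tip
#' labels, branch lengths either on every edge or on none, and
#' non-negative where present.
#'
#' @param phy an [ape::phylo] object.
#' @return `phy`, invisibly; stops with an informative error otherwise.
#' @export
validatePhyloTree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!is.null(phy$edge.length)) {
    if (length(phy$edge.length) != nrow(phy$edge))
      stop("branch lengths must be present on all edges or none")
    if (anyNA(phy$edge.length))
      stop("branch lengths must be present on all edges or none (NA found)")
    if (any(phy$edge.length < 0))
      stop("negative branch length found")
  }
  invisible(phy)
}

#' Write a phylogeny to Newick or NEXUS
#'
#' @param phy an [ape::phylo] object.
#' @param path output file path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
writePhyloTree <- function(phy, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  switch(format,
    newick = ape::write.tree(phy, file = path),
    nexus  = ape::write.nexus(phy, file = path)
  )
  invisible(path)
}

#' Require branch lengths on a tree
#'
#' Operations that need edge lengths (likelihood, chronogram work) call
#' this instead of silently assuming unit lengths on a topology-only
#' tree such as the supertree.
#' @param phy an [ape::phylo] object.
#' @param what label used in the error message.
#' @return `phy`, invisibly.
#' @export
requireBranchLengths <- function(phy, what = "this operation") {
  if (is.null(phy$edge.length))
    stop("branch lengths required: ", what,
         " cannot run on a topology-only tree")
  invisible(phy)
}

#' Prune a tree to one representative tip per genus
#'
#' Keeps one tip per genus according to `representativeMap`, relabels it
#' with the genus name, and suppresses the unary nodes created by
#' pruning (branch lengths are merged additively, so patristic distances
#' among retained tips are unchanged). Tips absent from the map are
#' dropped. The default policy when a genus has several representatives
#' is keep-first-alphabetical by tip label.
#'
#' @param phy an [ape::phylo] object.
#' @param representativeMap named character vector: names are tip
#'   labels, values are genus names.
#' @return the pruned [ape::phylo] with genus tip labels and an
#'   attribute `"dropped_genera"`: genera in the map with no
#'   representative in the tree (reported with a warning, not an error).
#' @examples
#' phy <- ape::read.tree(text = "((Aname_sp1:1,Aname_sp2:1):1,Atrax_sp1:2);")
#' map <- c(Aname_sp1 = "Aname", Aname_sp2 = "Aname", Atrax_sp1 = "Atrax")
#' pruneToGenus(phy, map)$tip.label
#' @export
pruneToGenus <- function(phy, representativeMap) {
  stopifnot(inherits(phy, "phylo"), !is.null(names(representativeMap)))
  inTree <- names(representativeMap) %in% phy$tip.label
  missingGenera <- setdiff(unname(representativeMap[!inTree]),
                           unname(representativeMap[inTree]))
  if (length(missingGenera))
    warning("genera with no representative in the tree: ",
            paste(sort(unique(missingGenera)), collapse = ", "))
  map <- representativeMap[inTree]
  if (!length(map)) stop("no mapped tips present in the tree")
  # keep-first-alphabetical representative per genus
  ord <- order(names(map))
  map <- map[ord]
  keep <- names(map)[!duplicated(unname(map))]
  genus <- unname(map[keep])
  if (anyDuplicated(genus)) stop("representatives map to duplicate genera")
  if (length(keep) < 2L) stop("fewer than 2 genera retained")
  pruned <- ape::keep.tip(phy, keep)
  pruned$tip.label <- genus[match(pruned$tip.label, keep)]
  attr(pruned, "rooted") <- attr(phy, "rooted")
  attr(pruned, "dropped_genera") <- sort(unique(missingGenera))
  validatePhyloTree(pruned)
}

#' Patristic distances among tips
#'
#' All-pairs path-length matrix. Uses branch lengths when present,
#' otherwise errors (use `unit = TRUE` to count edges instead).
#'
#' @param phy an [ape::phylo] object.
#' @param unit count edges instead of summing branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
patristicDistances <- function(phy, unit = FALSE) {
  if (unit || is.null(phy$edge.length)) {
    if (!unit) requireBranchLengths(phy, "patristic distances")
    phy2 <- phy
    phy2$edge.length <- rep(1, nrow(phy$edge))
    return(stats::cophenetic(phy2))
  }
  stats::cophenetic(phy)
}
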