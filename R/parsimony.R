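#' Exact maximum-parsimony ancestral reconstruction
#'
#' Reconstructs ancestral states of an unordered multistate character by
#' unweighted (Fitch-cost) parsimony, using the unit-cost dynamic
#' program. This is exact on polytomous trees and with state-set tips:
#' a polymorphic tip contributes cost 0 for each of its observed states,
#' a missing tip for every state. For every node the full set of states
#' attainable in at least one most-parsimonious reconstruction is
#' returned, together with the tree length (minimum number of changes).
#'
#' @param phy a rooted [ape::phylo] object (polytomies allowed; branch
#'   lengths ignored).
#' @param stateSets named list of integer state sets per taxon (empty =
#'   missing), e.g. from [charStates()] or [traitAsStateSets()].
#' @param nStates number of states `k`; defaults to 1 + max observed.
#' @return an object of class `asrMP`: list with `node_sets` (list of
#'   MP state sets for every node, tips first in tip order, then
#'   internal nodes in ape numbering), `length` (tree length), `tree`,
#'   `n_states`.
#' @examples
#' phy <- ape::read.tree(text = "((A,B),(C,D));")
#' x <- list(A = 0L, B = 1L, C = 1L, D = 1L)
#' res <- mpReconstruct(phy, x)
#' res$length            # 1 change
#' res$node_sets[[5]]    # root set {1}
#' @export
mpReconstruct <- function(phy, stateSets, nStates = NULL) {
  stopifnot(inherits(phy, "phylo"))
  tips <- phy$tip.label
  if (!all(tips %in% names(stateSets)))
    stop("state sets missing for tips: ",
         paste(setdiff(tips, names(stateSets)), collapse = ", "))
  if (length(tips) < 3L) stop("fewer than 3 taxa")
  obs <- unlist(stateSets[tips])
  k <- if (is.null(nStates)) max(obs, 0L) + 1L else nStates
  if (k < 2L) k <- 2L
  nTip <- length(tips)
  nNode <- nTip + phy$Nnode
  root <- nTip + 1L

  # subtree cost c[v, s]: minimal changes in the subtree below v given
  # state s at v
  cost <- matrix(Inf, nNode, k)
  for (i in seq_len(nTip)) {
    s <- stateSets[[tips[i]]]
    if (!length(s)) cost[i, ] <- 0 else cost[i, s + 1L] <- 0
  }
  cost[(nTip + 1L):nNode, ] <- 0
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2L]; parent <- po$edge[e, 1L]
    contrib <- pmin(cost[child, ], min(cost[child, ]) + 1)
    cost[parent, ] <- cost[parent, ] + contrib
  }
  treeLen <- min(cost[root, ])

  # g[v, s]: minimal whole-tree cost given state s at v (preorder pass)
  g <- matrix(Inf, nNode, k)
  g[root, ] <- cost[root, ]
  pre <- rev(seq_len(nrow(po$edge)))
  for (e in pre) {
    child <- po$edge[e, 2L]; parent <- po$edge[e, 1L]
    contrib <- pmin(cost[child, ], min(cost[child, ]) + 1)
    rest <- g[parent, ] - contrib
    base <- min(rest)
    g[child, ] <- cost[child, ] + pmin(rest, base + 1)
  }
  nodeSets <- lapply(seq_len(nNode), function(v)
    which(g[v, ] <= treeLen + 1e-9) - 1L)
  structure(list(node_sets = nodeSets, length = treeLen, tree = phy,
                 n_states = k, method = "MP"),
            class = "asrMP")
}

#' @export
print.asrMP <- function(x, ...) {
  cat("Maximum-parsimony reconstruction:", ape::Ntip(x$tree), "tips,",
      x$tree$Nnode, "internal nodes\n")
  cat("  tree length (changes):", x$length, "\n")
  cat("  root MP state set: {",
      paste(x$node_sets[[ape::Ntip(x$tree) + 1L]], collapse = ","), "}\n")
  invisible(x)
}

#' Parsimony length of a character on a tree
#'
#' Minimum number of unordered changes, with polymorphic tips free to
#' take any observed state and missing tips any state.
#' @inheritParams mpReconstruct
#' @return integer tree length.
#' @export
parsimonyLength <- function(phy, stateSets, nStates = NULL) {
  mpReconstruct(phy, stateSets, nStates)$length
}
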