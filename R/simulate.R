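#' Simulate a birth-death genus-level chronogram
#'
#' Birth-death tree conditioned on the number of extant tips (via
#' [ape::rphylo()]), rescaled to unit root depth so that rates are
#' expressed per tree depth. Tips are labeled `g001, g002, ...`.
#'
#' @param nTaxa number of tips (>= 3).
#' @param birth,death per-lineage rates (death < birth).
#' @param seed integer seed.
#' @param rescale rescale to unit root depth (the default, so that
#'   character rates are per tree depth); `FALSE` keeps the natural
#'   birth-death time scale.
#' @return an ultrametric rooted [ape::phylo].
#' @export
simulateTree <- function(nTaxa, birth = 1, death = 0.2, seed = 1L,
                         rescale = TRUE) {
  if (nTaxa < 3L) stop("nTaxa must be >= 3")
  if (death >= birth)
    stop("death rate must be below birth rate to condition on ", nTaxa,
         " surviving tips")
  phy <- withSeed(seed, ape::rphylo(nTaxa, birth, death))
  if (rescale) {
    depth <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length / depth
  }
  phy$tip.label <- sprintf("g%03d", seq_len(nTaxa))
  attr(phy, "rooted") <- TRUE
  phy
}

#' Rate-perturbed phylogram analogue of a chronogram
#'
#' Multiplies every edge by an independent lognormal factor (mean 1),
#' emulating a phylogram whose branch lengths reflect heterogeneous
#' rates of change rather than time.
#'
#' @param phy a tree with branch lengths.
#' @param sigma lognormal standard deviation on the log scale.
#' @param seed integer seed.
#' @return a non-ultrametric copy of `phy`.
#' @export
perturbBranchRates <- function(phy, sigma = 0.5, seed = 1L) {
  requireBranchLengths(phy, "rate perturbation")
  factors <- withSeed(seed,
    stats::rlnorm(nrow(phy$edge), meanlog = -sigma^2 / 2, sdlog = sigma))
  phy$edge.length <- phy$edge.length * factors
  phy
}

# Gillespie simulation of one CTMC path along a single branch.
# Returns final state and (optionally) the event list.
simulateBranch <- function(Q, state, len, keepEvents = FALSE) {
  events <- if (keepEvents) list() else NULL
  t <- 0
  k <- nrow(Q)
  repeat {
    rate <- -Q[state + 1L, state + 1L]
    if (rate <= 0) break
    dt <- stats::rexp(1L, rate)
    if (t + dt > len) break
    t <- t + dt
    to <- sample.int(k, 1L, prob = pmax(Q[state + 1L, ], 0)) - 1L
    if (keepEvents) events[[length(events) + 1L]] <-
        list(time = t, from = state, to = to)
    state <- to
  }
  list(state = state, events = events)
}

#' Simulate a discrete character down a tree
#'
#' Gillespie simulation of the continuous-time Markov chain defined by
#' `Q` along every branch, from a root state drawn uniformly (or fixed).
#'
#' @param phy rooted tree with branch lengths.
#' @param Q rate matrix (states `0..k-1`).
#' @param rootState fixed root state, or `NULL` to draw uniformly.
#' @param seed integer seed.
#' @param history keep the per-edge event log (needed to simulate
#'   characters whose rates depend on this character's realized path).
#' @return named integer vector of tip states, with attributes
#'   `node_states` (all-node states, ape numbering) and, if requested,
#'   `history` (per-edge event lists, postorder edge order of `phy`).
#' @export
simulateCharacter <- function(phy, Q, rootState = NULL, seed = 1L,
                              history = FALSE) {
  requireBranchLengths(phy, "character simulation")
  k <- nrow(Q)
  nTip <- ape::Ntip(phy)
  nNode <- nTip + phy$Nnode
  withSeed(seed, {
    states <- integer(nNode)
    root <- nTip + 1L
    states[root] <- if (is.null(rootState)) sample.int(k, 1L) - 1L
                    else as.integer(rootState)
    hist <- if (history) vector("list", nrow(phy$edge)) else NULL
    # preorder: parents before children
    po <- ape::reorder.phylo(phy, "postorder")
    ord <- rev(seq_len(nrow(po$edge)))
    for (e in ord) {
      parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
      sim <- simulateBranch(Q, states[parent], po$edge.length[e], history)
      states[child] <- sim$state
      if (history) hist[[e]] <- sim$events
    }
    tipStates <- stats::setNames(states[seq_len(nTip)], phy$tip.label)
    attr(tipStates, "node_states") <- states
    if (history) {
      attr(tipStates, "history") <- hist
      attr(tipStates, "postorder_tree") <- po
    }
    tipStates
  })
}

#' Simulate a pair of binary characters under a paired model
#'
#' Joint Gillespie simulation on the 4-state chain (or 8-state hidden
#' chain) of a template from [enumerateModels()]; dual transitions
#' never occur because their rates are structurally zero.
#'
#' @param phy rooted tree with branch lengths.
#' @param template a `pairedTemplate`.
#' @param rates free-rate vector in `template$labels` order.
#' @param seed integer seed.
#' @return list with [binaryTrait()] objects `x` and `y` and the raw
#'   joint tip states (`joint`, 0-based observed states).
#' @export
simulateCorrelatedPair <- function(phy, template, rates, seed = 1L) {
  Q <- buildPairedQ(template, rates)
  tips <- simulateCharacter(phy, Q, rootState = NULL, seed = seed)
  obs <- if (template$hidden) tips %% 4L else tips
  x <- binaryTrait("x", stats::setNames(as.character(obs %/% 2L), names(obs)))
  y <- binaryTrait("y", stats::setNames(as.character(obs %% 2L), names(obs)))
  list(x = x, y = y, joint = obs)
}

#' Simulate a binary character whose rates track another character
#'
#' Given the realized history of a driver character (from
#' [simulateCharacter()] with `history = TRUE`) and a set of driver
#' states defining the "on" condition, simulates a binary responder
#' whose gain rate is `qHigh` and loss rate `qLow` while the driver is
#' "on", and vice versa while "off". The responder therefore tracks
#' the driver with rate ratio `qHigh / qLow`.
#'
#' @param driverTips result of `simulateCharacter(..., history = TRUE)`.
#' @param onStates driver states that switch the responder toward 1.
#' @param qHigh,qLow fast and slow transition rates.
#' @param seed integer seed.
#' @return named integer tip states of the responder (attribute
#'   `node_states` as in [simulateCharacter()]).
#' @export
simulateDependentBinary <- function(driverTips, onStates, qHigh, qLow,
                                    seed = 1L) {
  po <- attr(driverTips, "postorder_tree")
  hist <- attr(driverTips, "history")
  nodeStates <- attr(driverTips, "node_states")
  if (is.null(po) || is.null(hist))
    stop("driver must be simulated with history = TRUE")
  nTip <- ape::Ntip(po)
  nNode <- nTip + po$Nnode
  qFor <- function(on) {                       # 2x2 Q given driver on/off
    g <- if (on) qHigh else qLow               # gain rate 0 -> 1
    l <- if (on) qLow else qHigh               # loss rate 1 -> 0
    matrix(c(-g, g, l, -l), 2, 2, byrow = TRUE)
  }
  withSeed(seed, {
    y <- integer(nNode)
    root <- nTip + 1L
    rootOn <- nodeStates[root] %in% onStates
    y[root] <- stats::rbinom(1L, 1L, if (rootOn) 0.9 else 0.1)
    for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
      parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
      len <- po$edge.length[e]
      # piecewise-constant driver state along the edge
      times <- vapply(hist[[e]], `[[`, numeric(1), "time")
      tos <- vapply(hist[[e]], `[[`, numeric(1), "to")
      segStart <- c(0, times)
      segState <- c(nodeStates[parent], tos)
      segEnd <- c(times, len)
      s <- y[parent]
      for (i in seq_along(segStart)) {
        seg <- simulateBranch(qFor(segState[i] %in% onStates), s,
                              segEnd[i] - segStart[i])
        s <- seg$state
      }
      y[child] <- s
    }
    out <- stats::setNames(y[seq_len(nTip)], po$tip.label)
    attr(out, "node_states") <- y
    out
  })
}

#' Degrade a character matrix with missing and polymorphic cells
#'
#' Uniformly samples a fraction of cells to blank out (missing) and a
#' disjoint fraction to widen into polymorphic state sets (one random
#' extra state added).
#'
#' @param cm a `charMatrix`.
#' @param missingFraction,polymorphicFraction cell fractions in
#'   `[0, 1]`, summing to at most 1.
#' @param seed integer seed.
#' @return the degraded `charMatrix`.
#' @export
degrade <- function(cm, missingFraction = 0, polymorphicFraction = 0,
                    seed = 1L) {
  stopifnot(missingFraction >= 0, polymorphicFraction >= 0)
  if (missingFraction + polymorphicFraction > 1)
    stop("missing and polymorphic fractions sum to more than 1")
  nCell <- length(cm$cells)
  withSeed(seed, {
    nMiss <- stats::rbinom(1L, nCell, missingFraction)
    nPoly <- stats::rbinom(1L, nCell - nMiss, polymorphicFraction /
                             max(1 - missingFraction, .Machine$double.eps))
    picks <- sample.int(nCell, min(nMiss + nPoly, nCell))
    missIdx <- picks[seq_len(nMiss)]
    polyIdx <- setdiff(picks, missIdx)
    cells <- cm$cells
    for (i in missIdx) cells[[i]] <- integer(0)
    nStatesOf <- rep(cm$meta$n_states, each = nrow(cells))
    for (i in polyIdx) {
      s <- cells[[i]]
      k <- nStatesOf[i]
      extra <- setdiff(0:(k - 1L), s)
      if (length(s) && length(extra))
        cells[[i]] <- sort(c(s, extra[sample.int(length(extra), 1L)]))
    }
    characterMatrix(cells, taxa = cm$taxa, meta = cm$meta)
  })
}
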