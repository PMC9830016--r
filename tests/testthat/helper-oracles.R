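# Independent oracles used across the suite. These deliberately avoid
# the package's pruning/DP code paths: likelihoods are brute-force sums
# over all internal-state assignments with Matrix::expm transition
# probabilities, and parsimony quantities are exhaustive minimizations.

# transition probability matrix via Matrix::expm (independent of the
# package's eigendecomposition path)
oracleP <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# brute-force likelihood: enumerate every combination of internal-node
# states, multiply edge transition probabilities and tip indicators
oracleLogLik <- function(phy, stateSets, Q, prior = NULL) {
  k <- nrow(Q)
  nTip <- ape::Ntip(phy)
  nNode <- nTip + phy$Nnode
  if (is.null(prior)) prior <- rep(1 / k, k)
  tipAllowed <- lapply(phy$tip.label, function(tl) {
    s <- stateSets[[tl]]
    if (!length(s)) 0:(k - 1) else s
  })
  Ps <- lapply(seq_len(nrow(phy$edge)), function(e)
    oracleP(Q, phy$edge.length[e]))
  internals <- (nTip + 1):nNode
  grid <- do.call(expand.grid, rep(list(0:(k - 1)), length(internals)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- unlist(grid[g, ])
    nodeState <- function(v) assign[v - nTip]
    lik <- prior[assign[1] + 1]          # root = nTip + 1 is first internal
    # sum over tip states within allowed sets, product over edges
    for (e in seq_len(nrow(phy$edge))) {
      pa <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      from <- nodeState(pa)
      p <- if (ch <= nTip)
        sum(Ps[[e]][from + 1, tipAllowed[[ch]] + 1])
      else Ps[[e]][from + 1, nodeState(ch) + 1]
      lik <- lik * p
    }
    total <- total + lik
  }
  log(total)
}

# exhaustive most-parsimonious state sets: try every assignment of
# states to all nodes (tips constrained to their sets, missing free)
oracleMpSets <- function(phy, stateSets, k) {
  nTip <- ape::Ntip(phy)
  nNode <- nTip + phy$Nnode
  allowed <- c(
    lapply(phy$tip.label, function(tl) {
      s <- stateSets[[tl]]
      if (!length(s)) 0:(k - 1) else s
    }),
    rep(list(0:(k - 1)), phy$Nnode))
  grid <- do.call(expand.grid, allowed)
  cost <- apply(grid, 1, function(assign) {
    sum(assign[phy$edge[, 1]] != assign[phy$edge[, 2]])
  })
  minCost <- min(cost)
  opt <- grid[cost == minCost, , drop = FALSE]
  sets <- lapply(seq_len(nNode), function(v) sort(unique(opt[[v]])))
  list(sets = sets, length = minCost)
}

# exhaustive parsimony optimum over all unrooted topologies (phangorn
# fitch score), for small MRP matrices
oracleBestParsimony <- function(mrp) {
  pd <- mygacomp:::mrpToPhyDat(mrp)
  taxa <- rownames(mrp$mat)
  trees <- phangorn::allTrees(length(taxa), tip.label = taxa)
  scores <- vapply(trees, function(tr) phangorn::parsimony(tr, pd),
                   numeric(1))
  list(best = min(scores),
       trees = trees[scores == min(scores)])
}

# random character matrix with polymorphic and missing cells
randomCharMatrix <- function(nTaxa, nChar, maxStates = 3,
                             pMissing = 0.1, pPoly = 0.1) {
  taxa <- sprintf("t%02d", seq_len(nTaxa))
  nStates <- sample(2:maxStates, nChar, replace = TRUE)
  cells <- matrix(vector("list", nTaxa * nChar), nTaxa, nChar)
  for (j in seq_len(nChar)) for (i in seq_len(nTaxa)) {
    r <- runif(1)
    cells[[i, j]] <- if (r < pMissing) integer(0)
    else if (r < pMissing + pPoly && nStates[j] > 1)
      sort(sample(0:(nStates[j] - 1), 2))
    else sample(0:(nStates[j] - 1), 1)
  }
  meta <- data.frame(id = paste0("C", seq_len(nChar)),
                     label = paste0("C", seq_len(nChar)),
                     n_states = nStates,
                     ordered = sample(c(TRUE, FALSE), nChar, replace = TRUE),
                     stringsAsFactors = FALSE)
  characterMatrix(cells, taxa = taxa, meta = meta)
}

# binary traits directly from named 0/1 vectors
bt <- function(name, v) binaryTrait(name, vapply(v, as.character, ""))
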