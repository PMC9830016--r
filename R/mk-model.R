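#' Build an Mk rate matrix under a rate constraint
#'
#' Continuous-time Markov rate matrix for a k-state character. `ER` ties
#' all transitions to one rate; `SYM` gives each unordered state pair
#' its own rate (k(k-1)/2 free rates); `ARD` gives each ordered pair its
#' own rate (k(k-1)).
#'
#' @param k number of states.
#' @param constraint `"ER"`, `"SYM"` or `"ARD"`.
#' @param rates numeric vector of free rates, length [nFreeRates()].
#' @return `k x k` rate matrix with zero row sums.
#' @export
rateMatrix <- function(k, constraint = c("ER", "SYM", "ARD"), rates) {
  constraint <- match.arg(constraint)
  if (anyNA(rates) || any(rates < 0)) stop("rates must be non-negative numbers")
  if (length(rates) != nFreeRates(k, constraint))
    stop("expected ", nFreeRates(k, constraint), " rates for ", constraint)
  Q <- matrix(0, k, k, dimnames = list(0:(k - 1), 0:(k - 1)))
  idx <- rateIndexMatrix(k, constraint)
  Q[idx > 0] <- rates[idx[idx > 0]]
  diag(Q) <- -rowSums(Q)
  Q
}

# parameter-index matrix: entry (i,j) gives the free-rate index of the
# i->j transition (0 on the diagonal)
rateIndexMatrix <- function(k, constraint) {
  idx <- matrix(0L, k, k)
  if (constraint == "ER") {
    idx[] <- 1L; diag(idx) <- 0L
  } else if (constraint == "SYM") {
    p <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      p <- p + 1L; idx[i, j] <- p; idx[j, i] <- p
    }
  } else {
    p <- 0L
    for (i in 1:k) for (j in 1:k) if (i != j) { p <- p + 1L; idx[i, j] <- p }
  }
  idx
}

#' @rdname rateMatrix
#' @return `nFreeRates`: integer count of free rate parameters.
#' @export
nFreeRates <- function(k, constraint = c("ER", "SYM", "ARD")) {
  constraint <- match.arg(constraint)
  switch(constraint, ER = 1L, SYM = (k * (k - 1L)) %/% 2L,
         ARD = k * (k - 1L))
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)` with `k` free parameters and
#' sample size `n` (number of tips). Returns `Inf` when `n <= k + 1`.
#' @param logL maximized log-likelihood.
#' @param k number of free parameters.
#' @param n sample size.
#' @export
aicc <- function(logL, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# stationary distribution of a rate matrix (left null vector)
stationaryDistribution <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

# tip partial-likelihood matrix from state sets (missing = all states)
tipPartials <- function(phy, stateSets, k) {
  tips <- phy$tip.label
  L <- matrix(0, length(tips), k)
  for (i in seq_along(tips)) {
    s <- stateSets[[tips[i]]]
    if (is.null(s)) stop("no states for tip ", tips[i])
    if (!length(s)) L[i, ] <- 1 else L[i, s + 1L] <- 1
  }
  L
}

# postorder edge context reused across likelihood evaluations
pruningContext <- function(phy) {
  requireBranchLengths(phy, "likelihood computation")
  po <- ape::reorder.phylo(phy, "postorder")
  list(edge = po$edge, el = po$edge.length, nTip = ape::Ntip(phy))
}

# Felsenstein pruning (compiled); tipL: Ntip x k partials. Returns
# log-likelihood under root prior ("equal", "stationary", or numeric).
pruningLogLik <- function(phy, tipL, Q, rootPrior = "equal") {
  pruningLogLikCtx(pruningContext(phy), tipL, Q, rootPrior)
}

pruningLogLikCtx <- function(ctx, tipL, Q, rootPrior) {
  prior <- resolveRootPrior(rootPrior, Q)
  .pruningLogLikCpp(ctx$edge, ctx$el, ctx$nTip, tipL, Q, prior)
}

resolveRootPrior <- function(rootPrior, Q) {
  if (is.numeric(rootPrior)) {
    stopifnot(length(rootPrior) == nrow(Q))
    return(rootPrior / sum(rootPrior))
  }
  switch(rootPrior,
         equal = rep(1 / nrow(Q), nrow(Q)),
         stationary = stationaryDistribution(Q),
         stop("unknown root prior: ", rootPrior))
}

#' Mk log-likelihood of a multistate character
#'
#' Felsenstein pruning over `P(t) = exp(Qt)`. Polymorphic tips get
#' partial likelihood 1 on each observed state, missing tips on all
#' states; the root is combined with an equal or stationary prior.
#'
#' @param phy rooted [ape::phylo] with branch lengths.
#' @param stateSets named list of integer state sets per taxon.
#' @param Q rate matrix (e.g. from [rateMatrix()]).
#' @param rootPrior `"equal"`, `"stationary"`, or a numeric vector.
#' @return log-likelihood (scalar).
#' @export
mkLogLik <- function(phy, stateSets, Q, rootPrior = "equal") {
  pruningLogLik(phy, tipPartials(phy, stateSets, nrow(Q)), Q, rootPrior)
}

#' Fit an Mk model by maximum likelihood
#'
#' Bounded multi-start optimization of log-rates (quasi-Newton on the
#' log scale), with starting values spread around a parsimony-informed
#' initial rate. Reports AICc with `k` = number of free rates and `n` =
#' number of tips.
#'
#' @inheritParams mkLogLik
#' @param constraint `"ER"`, `"SYM"` or `"ARD"`.
#' @param nStarts number of optimizer starts (first start is the
#'   parsimony-informed initial value, the rest are seeded perturbations).
#' @param seed integer seed for the random restarts.
#' @param nStates number of states; defaults to 1 + max observed state.
#' @return object of class `mkFit`: `constraint`, `rates`, `Q`, `logL`,
#'   `k`, `n`, `AICc`, `converged`, `root_prior`.
#' @export
fitMkModel <- function(phy, stateSets, constraint = c("ER", "SYM", "ARD"),
                       rootPrior = "equal", nStarts = 5L, seed = 1L,
                       nStates = NULL) {
  constraint <- match.arg(constraint)
  requireBranchLengths(phy, "Mk fitting")
  tips <- phy$tip.label
  if (!all(tips %in% names(stateSets)))
    stop("state sets missing for some tips")
  obs <- unlist(stateSets[tips])
  k <- if (is.null(nStates)) max(obs, 0L) + 1L else nStates
  if (k < 2L) stop("character has a single state; rates unidentifiable")
  nFree <- nFreeRates(k, constraint)
  tipL <- tipPartials(phy, stateSets, k)

  # parsimony-informed initial rate: changes per unit branch length
  init <- max(parsimonyLength(phy, stateSets, k), 0.5) /
    max(sum(phy$edge.length), .Machine$double.eps)
  ctx <- pruningContext(phy)
  negLL <- function(logRates) {
    ll <- pruningLogLikCtx(ctx, tipL,
                           rateMatrix(k, constraint, exp(logRates)),
                           rootPrior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  withSeed(seed, {
    for (s in seq_len(max(1L, nStarts))) {
      start <- log(init) + if (s == 1L) rep(0, nFree) else
        stats::rnorm(nFree, 0, 1.5)
      fit <- tryCatch(
        stats::optim(start, negLL, method = "L-BFGS-B",
                     lower = log(init) - 18, upper = log(init) + 12,
                     control = list(factr = 1e4, maxit = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best))
    stop("Mk optimization failed for all starts (", constraint, ")")
  rates <- exp(best$par)
  Q <- rateMatrix(k, constraint, rates)
  logL <- -best$value
  structure(list(constraint = constraint, rates = rates, Q = Q, logL = logL,
                 k = nFree, n = length(tips), n_states = k,
                 AICc = aicc(logL, nFree, length(tips)),
                 converged = best$convergence == 0,
                 root_prior = rootPrior),
            class = "mkFit")
}

#' @export
print.mkFit <- function(x, ...) {
  cat("Mk fit (", x$constraint, ", ", x$n_states, " states): logL = ",
      formatC(x$logL, digits = 6, format = "g"), ", AICc = ",
      formatC(x$AICc, digits = 6, format = "g"),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' Marginal ancestral state probabilities under an Mk model
#'
#' Standard two-pass (re-rooting) marginal algorithm: a postorder pass
#' computes subtree partial likelihoods, a preorder pass propagates the
#' likelihood of the rest of the tree, and the per-node marginal is the
#' normalized product.
#'
#' @inheritParams mkLogLik
#' @return matrix (`Ntip + Nnode` rows, one per node in ape numbering)
#'   of marginal probabilities; rows sum to 1.
#' @export
marginalAsr <- function(phy, stateSets, Q, rootPrior = "equal") {
  requireBranchLengths(phy, "marginal reconstruction")
  k <- nrow(Q)
  nTip <- ape::Ntip(phy)
  nNode <- nTip + phy$Nnode
  L <- matrix(0, nNode, k)
  L[seq_len(nTip), ] <- tipPartials(phy, stateSets, k)
  L[(nTip + 1L):nNode, ] <- 1
  po <- ape::reorder.phylo(phy, "postorder")
  el <- po$edge.length
  Ps <- vector("list", nrow(po$edge))
  down <- vector("list", nrow(po$edge))       # P %*% L[child] per edge
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2L]; parent <- po$edge[e, 1L]
    Ps[[e]] <- ape::matexpo(Q * el[e])
    down[[e]] <- as.vector(Ps[[e]] %*% L[child, ])
    L[parent, ] <- L[parent, ] * down[[e]]
    m <- max(L[parent, ])
    if (m > 0) L[parent, ] <- L[parent, ] / m  # only ratios needed
  }
  prior <- resolveRootPrior(rootPrior, Q)
  A <- matrix(0, nNode, k)                     # "rest of tree" vectors
  A[nTip + 1L, ] <- prior
  for (e in rev(seq_len(nrow(po$edge)))) {
    child <- po$edge[e, 2L]; parent <- po$edge[e, 1L]
    sib <- L[parent, ] / pmax(down[[e]], .Machine$double.xmin)
    x <- A[parent, ] * sib
    A[child, ] <- as.vector(crossprod(Ps[[e]], x))
    m <- max(A[child, ])
    if (m > 0) A[child, ] <- A[child, ] / m
  }
  marg <- A * L
  sweep(marg, 1, pmax(rowSums(marg), .Machine$double.xmin), "/")
}

#' Select branch-length set and Mk model by AICc
#'
#' Fits ER, SYM and ARD on each supplied branch-length set (typically a
#' chronogram and a phylogram), and returns the minimum-AICc
#' combination together with the full AICc table and the marginal
#' ancestral probabilities of the winner. Ties within `1e-6` AICc are
#' broken deterministically: earlier branch-length set first, then
#' ER < SYM < ARD; a tie is recorded in the result.
#'
#' @param trees named list of rooted trees with branch lengths, e.g.
#'   `list(chronogram = ..., phylogram = ...)`; tip sets must agree.
#' @param stateSets named list of state sets per taxon.
#' @param constraints rate constraints to fit.
#' @inheritParams fitMkModel
#' @return object of class `asrML`: `table` (data frame of fits),
#'   `best` (the winning `mkFit`), `tree_id`, `constraint`,
#'   `marginals`, `tie`, `tree`.
#' @export
selectAsrModel <- function(trees, stateSets,
                           constraints = c("ER", "SYM", "ARD"),
                           rootPrior = "equal", nStarts = 5L, seed = 1L) {
  stopifnot(is.list(trees), length(trees) >= 1L, !is.null(names(trees)))
  fits <- list(); rows <- list()
  for (tn in names(trees)) {
    for (cn in constraints) {
      f <- fitMkModel(trees[[tn]], stateSets, cn, rootPrior,
                      nStarts = nStarts, seed = seed)
      fits[[paste(tn, cn, sep = ".")]] <- f
      rows[[length(rows) + 1L]] <-
        data.frame(tree = tn, constraint = cn, logL = f$logL, k = f$k,
                   AICc = f$AICc, converged = f$converged,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # deterministic preference order on ties: tree order, then ER<SYM<ARD
  tab$constraint <- factor(tab$constraint, levels = constraints)
  tab$tree <- factor(tab$tree, levels = names(trees))
  ord <- order(tab$AICc, tab$tree, tab$constraint)
  bestRow <- ord[1L]
  tie <- sum(tab$AICc <= tab$AICc[bestRow] + 1e-6) > 1L
  bestId <- paste(tab$tree[bestRow], tab$constraint[bestRow], sep = ".")
  best <- fits[[bestId]]
  phy <- trees[[as.character(tab$tree[bestRow])]]
  marg <- marginalAsr(phy, stateSets, best$Q, rootPrior)
  tab$deltaAICc <- tab$AICc - min(tab$AICc)
  structure(list(table = tab, best = best,
                 tree_id = as.character(tab$tree[bestRow]),
                 constraint = as.character(tab$constraint[bestRow]),
                 marginals = marg, tie = tie, tree = phy,
                 fits = fits),
            class = "asrML")
}

#' @export
print.asrML <- function(x, ...) {
  cat("Mk ancestral reconstruction, model selected by AICc\n")
  cat("  winner:", x$tree_id, "/", x$constraint,
      if (x$tie) "(AICc tie, deterministic preference applied)", "\n")
  print(x$table[, c("tree", "constraint", "logL", "k", "AICc", "deltaAICc")],
        row.names = FALSE)
  invisible(x)
}

# evaluate expr with a temporary RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
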