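#' One-tailed binomial sign test for pair counts
#'
#' Probability that a Binomial(n_pos + n_neg, 1/2) variable is at most
#' `min(n_pos, n_neg)` — the sign test applied to the positive and
#' negative phylogenetically independent pairs of a pairing scheme.
#' Neutral pairs never enter this computation. Returns 1 for an empty
#' test (no contrasting pairs).
#'
#' @param nPos,nNeg non-negative counts of positive and negative pairs.
#' @return the one-tailed p-value.
#' @examples
#' signTestP(6, 0)   # 0.015625
#' signTestP(7, 1)   # 9/256
#' @export
signTestP <- function(nPos, nNeg) {
  if (length(nPos) != 1L || length(nNeg) != 1L ||
      is.na(nPos) || is.na(nNeg) || nPos < 0 || nNeg < 0)
    stop("pair counts must be single non-negative numbers")
  n <- nPos + nNeg
  if (n == 0) return(1)
  stats::pbinom(min(nPos, nNeg), n, 0.5)
}

# per-tip ancestor walks and depths; parent vector indexed by node id
treePaths <- function(phy) {
  nTip <- ape::Ntip(phy)
  nNode <- nTip + phy$Nnode
  parent <- integer(nNode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- nTip + 1L
  parent[root] <- 0L
  anc <- vector("list", nTip)      # node ids from tip to root inclusive
  depth <- integer(nTip)
  for (i in seq_len(nTip)) {
    path <- i; v <- i
    while (v != root) { v <- parent[v]; path <- c(path, v) }
    anc[[i]] <- path
    depth[i] <- length(path) - 1L
  }
  list(anc = anc, depth = depth, root = root)
}

# node set and edge-count length of the path joining tips a and b
tipPairPath <- function(tp, a, b) {
  pa <- tp$anc[[a]]; pb <- tp$anc[[b]]
  inB <- pa %in% pb
  mrcaPos <- which(inB)[1L]
  mrca <- pa[mrcaPos]
  nodes <- c(pa[seq_len(mrcaPos)], pb[seq_len(which(pb == mrca)[1L] - 1L)])
  list(nodes = nodes, len = (mrcaPos - 1L) + (which(pb == mrca)[1L] - 1L))
}

# candidate pairs for a mode: data frame + list of path node sets
pairCandidates <- function(phy, x, y, mode) {
  tips <- phy$tip.label
  xv <- x$values[tips]; yv <- y$values[tips]
  elig <- which(xv %in% c("0", "1") & yv %in% c("0", "1"))
  if (length(elig) < 2L)
    return(list(df = data.frame(), paths = list()))
  tp <- treePaths(phy)
  combos <- utils::combn(elig, 2L)
  xa <- xv[combos[1L, ]]; xb <- xv[combos[2L, ]]
  ya <- yv[combos[1L, ]]; yb <- yv[combos[2L, ]]
  dx <- xa != xb; dy <- ya != yb
  keep <- if (mode == "PC1") dx & dy else dx | dy
  if (!any(keep)) return(list(df = data.frame(), paths = list()))
  combos <- combos[, keep, drop = FALSE]
  cls <- ifelse(dx[keep] & dy[keep],
                ifelse(xa[keep] == ya[keep], "positive", "negative"),
                "neutral")
  paths <- vector("list", ncol(combos))
  lens <- integer(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    pp <- tipPairPath(tp, combos[1L, j], combos[2L, j])
    paths[[j]] <- pp$nodes; lens[j] <- pp$len
  }
  list(df = data.frame(a = tips[combos[1L, ]], b = tips[combos[2L, ]],
                       ai = combos[1L, ], bi = combos[2L, ],
                       class = cls, path_len = lens,
                       stringsAsFactors = FALSE),
       paths = paths, n_nodes = ape::Ntip(phy) + phy$Nnode)
}

# one randomized greedy maximal matching over precomputed candidates
greedyScheme <- function(cand) {
  n <- nrow(cand$df)
  ord <- order(cand$df$path_len, stats::runif(n))
  used <- logical(cand$n_nodes)
  take <- integer(0)
  for (j in ord) {
    p <- cand$paths[[j]]
    if (!any(used[p])) { used[p] <- TRUE; take <- c(take, j) }
  }
  take
}

#' Find one phylogenetically independent pairing scheme
#'
#' Randomized greedy maximal matching of taxon pairs with node-disjoint
#' connecting paths: candidate pairs that qualify for the mode are
#' visited in seed-shuffled order of increasing path length and accepted
#' when their path shares no node with previously accepted pairs. Taxa
#' with ambiguous or missing values on either trait are ineligible. A
#' pair contrasting in both traits is `positive` when the states
#' co-occur concordantly (the taxon with x = 1 also has y = 1),
#' `negative` otherwise; pairs contrasting in exactly one trait are
#' `neutral` (admitted only in PC2 schemes). The scheme's p-value is
#' the sign test on (positive, negative).
#'
#' @param phy rooted tree covering the trait taxa (branch lengths not
#'   required).
#' @param x,y [binaryTrait()] objects.
#' @param mode `"PC1"` (both traits must contrast) or `"PC2"` (at least
#'   one trait contrasts).
#' @param seed integer seed for the randomized visiting order.
#' @return object of class `pairScheme`: `pairs` (data frame with
#'   columns a, b, class, path_len), `counts` (positive, negative,
#'   neutral), `p`, `mode`, `seed`.
#' @export
findPairingScheme <- function(phy, x, y, mode = c("PC1", "PC2"), seed = 1L) {
  mode <- match.arg(mode)
  cand <- pairCandidates(phy, x, y, mode)
  withSeed(seed, {
    schemeFromCandidates(cand, mode, seed)
  })
}

schemeFromCandidates <- function(cand, mode, seed) {
  if (!nrow(cand$df)) {
    return(structure(list(pairs = data.frame(), counts = c(positive = 0L,
                          negative = 0L, neutral = 0L), p = 1,
                          mode = mode, seed = seed),
                     class = "pairScheme"))
  }
  take <- greedyScheme(cand)
  pairs <- cand$df[take, c("a", "b", "class", "path_len")]
  counts <- c(positive = sum(pairs$class == "positive"),
              negative = sum(pairs$class == "negative"),
              neutral = sum(pairs$class == "neutral"))
  structure(list(pairs = pairs, counts = counts,
                 p = signTestP(counts[["positive"]], counts[["negative"]]),
                 mode = mode, seed = seed,
                 paths = cand$paths[take]),
            class = "pairScheme")
}

#' @export
print.pairScheme <- function(x, ...) {
  cat("pairScheme (", x$mode, "): ", nrow(x$pairs), " pairs, counts ",
      paste(x$counts, collapse = ":"), ", p = ",
      formatC(x$p, digits = 3, format = "g"), "\n", sep = "")
  invisible(x)
}

#' Pairwise-comparisons correlation test with max-p over schemes
#'
#' Generates `nSchemes` seeded pairing schemes and reports the *largest*
#' sign-test p-value across them — a conservative significance
#' threshold that is robust to the arbitrariness of any single maximal
#' pairing. The counts reported are those of the scheme attaining the
#' maximum (ties broken toward fewer pairs, then the earliest scheme).
#'
#' @inheritParams findPairingScheme
#' @param nSchemes number of alternative pairing schemes (the study
#'   default is 1000).
#' @return object of class `pairwiseTest`: `p` (max over schemes),
#'   `counts`, `scheme` (the reporting scheme), `per_scheme` (data
#'   frame of p and counts for every scheme), `mode`, `n_schemes`.
#' @export
pairwiseTest <- function(phy, x, y, mode = c("PC1", "PC2"),
                         nSchemes = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  if (nSchemes < 1L) stop("nSchemes must be >= 1")
  cand <- pairCandidates(phy, x, y, mode)
  schemes <- vector("list", nSchemes)
  withSeed(seed, {
    for (i in seq_len(nSchemes))
      schemes[[i]] <- schemeFromCandidates(cand, mode, seed + i - 1L)
  })
  per <- data.frame(
    scheme = seq_len(nSchemes),
    p = vapply(schemes, `[[`, numeric(1), "p"),
    positive = vapply(schemes, function(s) s$counts[["positive"]], integer(1)),
    negative = vapply(schemes, function(s) s$counts[["negative"]], integer(1)),
    neutral = vapply(schemes, function(s) s$counts[["neutral"]], integer(1)))
  pMax <- max(per$p)
  atMax <- which(per$p >= pMax - 1e-15)
  nPairs <- per$positive[atMax] + per$negative[atMax] + per$neutral[atMax]
  pick <- atMax[order(nPairs, atMax)][1L]
  structure(list(p = pMax, counts = schemes[[pick]]$counts,
                 scheme = schemes[[pick]], per_scheme = per,
                 mode = mode, n_schemes = nSchemes, seed = seed),
            class = "pairwiseTest")
}

#' @export
print.pairwiseTest <- function(x, ...) {
  cnt <- if (x$mode == "PC1") x$counts[c("positive", "negative")] else x$counts
  cat("pairwiseTest ", x$mode, ": p = ", formatPValue(x$p), " (",
      paste(cnt, collapse = ":"), ") over ", x$n_schemes,
      " schemes (max-p rule)\n", sep = "")
  invisible(x)
}

#' Check node-disjointness of a pairing scheme
#'
#' Structural verification that the connecting paths of all accepted
#' pairs are mutually node-disjoint (phylogenetic independence).
#' @param scheme a `pairScheme` produced by [findPairingScheme()].
#' @return logical.
#' @export
isNodeDisjoint <- function(scheme) {
  if (is.null(scheme$paths) || !length(scheme$paths)) return(TRUE)
  all_nodes <- unlist(scheme$paths)
  !anyDuplicated(all_nodes)
}
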