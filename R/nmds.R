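# pool-adjacent-violators on group means (weighted isotonic regression)
pavaFit <- function(means, weights) {
  n <- length(means)
  val <- means; w <- weights; size <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- means[i]; w[m] <- weights[i]; size[m] <- 1L
    while (m > 1L && val[m - 1L] > val[m]) {
      tw <- w[m - 1L] + w[m]
      val[m - 1L] <- (val[m - 1L] * w[m - 1L] + val[m] * w[m]) / tw
      w[m - 1L] <- tw
      size[m - 1L] <- size[m - 1L] + size[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], size[seq_len(m)])
}

# monotone (isotonic) regression of configuration distances on input
# dissimilarities, ties averaged (Kruskal's primary approach)
isotonicDhat <- function(dvec, delta) {
  grp <- match(dvec, sort(unique(dvec)))
  gm <- tapply(delta, grp, mean)
  gw <- tabulate(grp)
  fit <- pavaFit(as.numeric(gm), as.numeric(gw))
  fit[grp]
}

kruskalStress1 <- function(dhat, delta) {
  den <- sum(delta^2)
  if (den <= 0) return(1)
  sqrt(sum((dhat - delta)^2) / den)
}

#' Non-metric multidimensional scaling by isotonic majorization
#'
#' Minimizes Kruskal stress-1,
#' `sqrt(sum((f(d_ij) - delta_ij)^2) / sum(delta_ij^2))`, where `delta`
#' are configuration distances and `f` is the monotone (isotonic)
#' regression of `delta` on the input dissimilarities `d` (ties
#' averaged). Each run alternates the isotonic step with a Guttman
#' majorization update of the configuration; the iteration stops when
#' the stress decrease falls below `tol` (stress is non-increasing
#' within a run by construction — an update that would increase it is
#' rejected and the run reported converged). The best of `nStarts`
#' initializations is returned: the first start is the classical
#' (metric) MDS configuration, the rest are seeded random configurations.
#'
#' The final configuration is centered at the origin and rotated to its
#' principal axes, with each axis' sign fixed so that the
#' largest-magnitude coordinate is positive, making the orientation
#' reproducible.
#'
#' @param d a `gowerDist`, `dist` object or symmetric matrix (no
#'   undefined entries).
#' @param k embedding dimension (default 2).
#' @param nStarts number of initializations.
#' @param seed integer seed.
#' @param maxit,tol iteration cap and stress-decrease tolerance per run.
#' @return object of class `ordination`: `points` (taxa x k), `stress`,
#'   `stress_sequence` (per-iteration stress of the winning run),
#'   `converged`, `k`, `n_starts`, `seed`.
#' @export
nmds <- function(d, k = 2L, nStarts = 20L, seed = 1L, maxit = 300L,
                 tol = 1e-7) {
  if (inherits(d, "gowerDist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(d)
  if (anyNA(d[upper.tri(d)]))
    stop("undefined dissimilarities: NMDS refuses NA entries")
  taxa <- rownames(d)
  low <- which(lower.tri(d))
  dvec <- d[low]

  runOnce <- function(X0) {
    X <- X0
    delta <- as.matrix(stats::dist(X))[low]
    dhat <- isotonicDhat(dvec, delta)
    stress <- kruskalStress1(dhat, delta)
    seqStress <- stress
    converged <- FALSE
    for (it in seq_len(maxit)) {
      # Guttman transform with target dhat
      dm <- matrix(0, n, n); dm[low] <- dhat; dm <- dm + t(dm)
      delM <- matrix(0, n, n); delM[low] <- delta; delM <- delM + t(delM)
      ratio <- ifelse(delM > 0, dm / delM, 0)
      B <- -ratio
      diag(B) <- -rowSums(B)
      Xn <- (B %*% X) / n
      deltaN <- as.matrix(stats::dist(Xn))[low]
      dhatN <- isotonicDhat(dvec, deltaN)
      stressN <- kruskalStress1(dhatN, deltaN)
      if (stressN > stress + 1e-12) { converged <- TRUE; break }
      improved <- stress - stressN
      X <- Xn; delta <- deltaN; dhat <- dhatN; stress <- stressN
      seqStress <- c(seqStress, stress)
      if (improved < tol) { converged <- TRUE; break }
    }
    list(X = X, stress = stress, seq = seqStress, converged = converged)
  }

  best <- NULL
  withSeed(seed, {
    for (s in seq_len(max(1L, nStarts))) {
      X0 <- if (s == 1L) {
        cs <- suppressWarnings(stats::cmdscale(d, k = k))
        if (ncol(cs) < k) cbind(cs, matrix(stats::rnorm(n * (k - ncol(cs)),
                                                        0, 1e-4), n))
        else cs
      } else matrix(stats::runif(n * k, -0.5, 0.5), n, k)
      res <- runOnce(X0)
      if (is.null(best) || res$stress < best$stress) best <- res
    }
  })
  X <- scale(best$X, center = TRUE, scale = FALSE)
  if (k > 1L && n > k) {
    pc <- stats::prcomp(X, center = FALSE)
    X <- pc$x[, seq_len(k), drop = FALSE]
  }
  for (j in seq_len(ncol(X)))                  # reproducible orientation
    if (X[which.max(abs(X[, j])), j] < 0) X[, j] <- -X[, j]
  rownames(X) <- taxa
  colnames(X) <- paste0("axis", seq_len(ncol(X)))
  structure(list(points = X, stress = best$stress,
                 stress_sequence = best$seq, converged = best$converged,
                 k = k, n_starts = nStarts, seed = seed),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("NMDS ordination: ", nrow(x$points), " taxa in ", x$k,
      " dimensions; stress-1 = ", formatC(x$stress, digits = 4,
      format = "f"), if (!x$converged) " [not converged]",
      " (best of ", x$n_starts, " starts)\n", sep = "")
  invisible(x)
}
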