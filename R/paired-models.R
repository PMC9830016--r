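# Paired binary-character Markov models
#
# Observed state space for (x = behavior, y = morphology):
#   index 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1)
# Only single-character transitions have nonzero rate (dual transitions
# are structurally 0). Hidden-rate models duplicate the 4 observed
# states into two rate classes (A, B): index s and s + 4; class
# switches preserve the observed state and share one symmetric rate.

pairedStateIndex <- function(x, y) 2L * x + y + 1L
pairedStateX <- function(s) (s - 1L) %/% 2L
pairedStateY <- function(s) (s - 1L) %% 2L

# label of an x-transition rate: direction d ("01"/"10"), context = y
# value when x's rates depend on y; ER ties directions
xRateLabel <- function(d, yctx, dep, er) {
  base <- if (er) "x" else paste0("x", d)
  if (dep) paste0(base, ".y", yctx) else base
}
yRateLabel <- function(d, xctx, dep, er) {
  base <- if (er) "y" else paste0("y", d)
  if (dep) paste0(base, ".x", xctx) else base
}

# label matrix of the 4-state observed chain
observedLabelMatrix <- function(dependence, cx, cy) {
  xdep <- dependence %in% c("XD", "INT")   # x rates differ by y state
  ydep <- dependence %in% c("YD", "INT")   # y rates differ by x state
  lab <- matrix("", 4, 4)
  for (s in 1:4) {
    x <- pairedStateX(s); y <- pairedStateY(s)
    sx <- pairedStateIndex(1L - x, y)      # x flips
    sy <- pairedStateIndex(x, 1L - y)      # y flips
    lab[s, sx] <- xRateLabel(if (x == 0L) "01" else "10", y, xdep, cx == "ER")
    lab[s, sy] <- yRateLabel(if (y == 0L) "01" else "10", x, ydep, cy == "ER")
  }
  lab
}

makePairedTemplate <- function(dependence, cx, cy, hidden = FALSE) {
  lab4 <- observedLabelMatrix(dependence, cx, cy)
  if (!hidden) {
    labels <- unique(lab4[lab4 != ""])
    index <- matrix(match(lab4, labels, nomatch = 0L), 4, 4)
    id <- paste(dependence, cx, cy, sep = "_")
    nStates <- 4L
  } else {
    lab <- matrix("", 8, 8)
    for (cl in c("A", "B")) {
      off <- if (cl == "A") 0L else 4L
      blk <- ifelse(lab4 == "", "", paste0(lab4, ".", cl))
      lab[off + 1:4, off + 1:4] <- blk
    }
    for (s in 1:4) { lab[s, s + 4L] <- "kappa"; lab[s + 4L, s] <- "kappa" }
    labels <- unique(lab[lab != ""])
    index <- matrix(match(lab, labels, nomatch = 0L), 8, 8)
    id <- paste("HID", dependence, cx, cy, sep = "_")
    nStates <- 8L
  }
  structure(list(id = id, dependence = dependence, constraint_x = cx,
                 constraint_y = cy, hidden = hidden, labels = labels,
                 n_par = length(labels), n_states = nStates, index = index),
            class = "pairedTemplate")
}

#' @export
print.pairedTemplate <- function(x, ...) {
  cat("pairedTemplate", x$id, ":", x$dependence,
      paste0(x$constraint_x, "-", x$constraint_y),
      if (x$hidden) "(2 hidden rate classes)", "-", x$n_par,
      "free rates on", x$n_states, "states\n")
  invisible(x)
}

#' Enumerate the 20 paired-character model templates
#'
#' Sixteen "standard" models: four dependence structures (independent,
#' x-dependent, y-dependent, interdependent) crossed with four rate
#' constraints (ER-ER, ER-ARD, ARD-ER, ARD-ARD), plus hidden-rate-class
#' counterparts of the four independent models (two rate classes per
#' observed state, class-specific copies of all character rates and one
#' symmetric class-switch rate), for twenty models in total.
#'
#' @return named list of 20 `pairedTemplate` objects; the 16 standard
#'   templates first, then the 4 hidden ones.
#' @examples
#' length(enumerateModels())            # 20
#' sum(!sapply(enumerateModels(), `[[`, "hidden"))   # 16
#' @export
enumerateModels <- function() {
  deps <- c("IND", "XD", "YD", "INT")
  cons <- c("ER", "ARD")
  out <- list()
  for (d in deps) for (cx in cons) for (cy in cons)
    out[[length(out) + 1L]] <- makePairedTemplate(d, cx, cy)
  for (cx in cons) for (cy in cons)
    out[[length(out) + 1L]] <- makePairedTemplate("IND", cx, cy, hidden = TRUE)
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}

#' Rate matrix of a paired-model template
#'
#' @param template a `pairedTemplate` from [enumerateModels()].
#' @param rates numeric vector of free rates, in `template$labels` order.
#' @return the 4x4 (or 8x8 hidden) rate matrix; dual transitions (both
#'   characters changing at once) have rate 0 structurally.
#' @export
buildPairedQ <- function(template, rates) {
  stopifnot(inherits(template, "pairedTemplate"),
            length(rates) == template$n_par)
  if (any(rates < 0)) stop("negative rate")
  k <- template$n_states
  Q <- matrix(0, k, k)
  Q[template$index > 0] <- rates[template$index[template$index > 0]]
  diag(Q) <- -rowSums(Q)
  Q
}

# joint observed-state sets per taxon from two binary traits;
# ambiguous/missing expand to both values of that trait
jointStateSets <- function(x, y, taxa) {
  xs <- traitAsStateSets(x); ys <- traitAsStateSets(y)
  if (!all(taxa %in% names(xs)) || !all(taxa %in% names(ys)))
    stop("traits missing values for some tips")
  out <- lapply(taxa, function(tx) {
    grid <- expand.grid(x = xs[[tx]], y = ys[[tx]])
    sort(pairedStateIndex(grid$x, grid$y)) - 1L   # 0-based states
  })
  stats::setNames(out, taxa)
}

#' Fit one paired-character model by maximum likelihood
#'
#' Pruning-algorithm likelihood on the joint 4-state chain (8-state for
#' hidden templates: each observed tip state is compatible with both
#' rate classes), maximized by multi-start bounded optimization of log
#' rates. AICc uses the number of tips as sample size.
#'
#' @param phy rooted tree with branch lengths.
#' @param x,y [binaryTrait()] objects (x = behavior, y = morphology).
#' @param template a `pairedTemplate`.
#' @param rootPrior `"equal"`, `"stationary"`, or numeric vector over
#'   the template's states.
#' @param nStarts optimizer starts; @param seed seed for restarts.
#' @return object of class `pairedFit`: `template`, `rates`, `Q`,
#'   `logL`, `k`, `n`, `AICc`, `converged`.
#' @export
fitPairedModel <- function(phy, x, y, template, rootPrior = "equal",
                           nStarts = 3L, seed = 1L) {
  requireBranchLengths(phy, "paired-model fitting")
  tips <- phy$tip.label
  checkTraitVariation <- function(tr) {
    v <- tr$values[intersect(names(tr$values), tips)]
    known <- v[v %in% c("0", "1")]
    if (length(unique(known)) < 2L)
      stop("trait '", tr$name, "' invariant, model unidentifiable")
  }
  checkTraitVariation(x); checkTraitVariation(y)
  joint <- jointStateSets(x, y, tips)
  if (template$hidden)
    joint <- lapply(joint, function(s) c(s, s + 4L))
  tipL <- tipPartials(phy, joint, template$n_states)

  init <- max(parsimonyLength(phy, traitAsStateSets(x), 2L) +
              parsimonyLength(phy, traitAsStateSets(y), 2L), 1L) /
    max(sum(phy$edge.length), .Machine$double.eps)
  ctx <- pruningContext(phy)
  negLL <- function(logRates) {
    ll <- pruningLogLikCtx(ctx, tipL,
                           buildPairedQ(template, exp(logRates)), rootPrior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  withSeed(seed, {
    for (s in seq_len(max(1L, nStarts))) {
      start <- log(init) + if (s == 1L) rep(0, template$n_par) else
        stats::rnorm(template$n_par, 0, 1.5)
      fit <- tryCatch(
        stats::optim(start, negLL, method = "L-BFGS-B",
                     lower = log(init) - 18, upper = log(init) + 12,
                     control = list(factr = 1e7, maxit = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best)) stop("optimization failed for template ", template$id)
  logL <- -best$value
  n <- length(tips)
  structure(list(template = template, rates = exp(best$par),
                 Q = buildPairedQ(template, exp(best$par)),
                 logL = logL, k = template$n_par, n = n,
                 AICc = aicc(logL, template$n_par, n),
                 converged = best$convergence == 0),
            class = "pairedFit")
}

#' @export
print.pairedFit <- function(x, ...) {
  cat("pairedFit", x$template$id, ": logL =",
      formatC(x$logL, digits = 6, format = "g"), " AICc =",
      formatC(x$AICc, digits = 6, format = "g"),
      if (!x$converged) "[NOT CONVERGED]", "\n")
  invisible(x)
}

#' Compare dependence structures of paired-character evolution
#'
#' Fits all twenty templates from [enumerateModels()], selects the best
#' model within each of the four dependence categories by AICc (hidden
#' models compete inside the independent category), and reports the
#' category bests' delta-AICc relative to the overall best — the
#' Indep / x-dep / y-dep / Interdep summary of the correlation screen.
#'
#' @inheritParams fitPairedModel
#' @param templates model set (defaults to [enumerateModels()]).
#' @return object of class `modelComparison`: `table` (per-model fits),
#'   `categories` (data frame: category, best model id, AICc,
#'   deltaAICc), `best_id`, `failed` (ids of templates whose fit failed).
#' @export
compareDependence <- function(phy, x, y, rootPrior = "equal", nStarts = 3L,
                              seed = 1L, templates = enumerateModels()) {
  fits <- list(); failed <- character(0)
  for (tpl in templates) {
    f <- tryCatch(
      fitPairedModel(phy, x, y, tpl, rootPrior, nStarts = nStarts,
                     seed = seed),
      error = function(e) e)
    if (inherits(f, "error")) {
      if (grepl("invariant", conditionMessage(f))) stop(f)
      warning("fit failed for ", tpl$id, ": ", conditionMessage(f))
      failed <- c(failed, tpl$id)
    } else fits[[tpl$id]] <- f
  }
  if (!length(fits)) stop("all paired-model fits failed")
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(id = f$template$id, category = f$template$dependence,
               hidden = f$template$hidden, logL = f$logL, k = f$k,
               AICc = f$AICc, converged = f$converged,
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  cats <- c("IND", "XD", "YD", "INT")
  catBest <- do.call(rbind, lapply(cats, function(cat) {
    sub <- tab[tab$category == cat, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    b <- sub[which.min(sub$AICc), , drop = FALSE]
    data.frame(category = cat, best_id = b$id, AICc = b$AICc,
               stringsAsFactors = FALSE)
  }))
  catBest$deltaAICc <- catBest$AICc - min(catBest$AICc)
  structure(list(table = tab, categories = catBest,
                 best_id = catBest$best_id[which.min(catBest$AICc)],
                 failed = failed, fits = fits),
            class = "modelComparison")
}

#' @export
print.modelComparison <- function(x, ...) {
  cat("Paired-model comparison (delta-AICc of category bests):\n")
  print(x$categories, row.names = FALSE)
  if (length(x$failed)) cat("  failed fits:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}
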