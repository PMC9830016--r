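#' Default simulation configuration for a synthetic study bundle
#'
#' The defaults emulate the structure of a genus-level behavioral-niche
#' study: a 110-tip birth-death chronogram (unit root depth) with a
#' rate-perturbed phylogram copy; three overlapping input trees for
#' supertree construction; a 3-state retreat-method character and a
#' 6-state entrance-type character evolving under Mk/ER; 55
#' binary morphological characters of which a subset tracks burrowing
#' behavior with a 10-fold rate ratio; and 5% missing plus 5%
#' polymorphic cells.
#'
#' @param nTaxa tips in the true tree.
#' @param birth,death birth-death rates per unit time.
#' @param phylogramSigma lognormal sd of the branch-rate perturbation.
#' @param nInputTrees,overlapFraction,perturbMoves supertree inputs:
#'   how many overlapping trees, the fraction of taxa each covers, and
#'   the number of random NNI moves applied to each (0 = consistent).
#' @param nMorph total morphological characters.
#' @param nDependent how many of them evolve behavior-dependently.
#' @param rateRatio fast:slow rate ratio of dependent characters.
#' @param morphRateFast fast transition rate of dependent characters
#'   (per unit tree depth); the slow rate is `morphRateFast/rateRatio`.
#' @param morphRateIndependent symmetric rate of independent characters.
#' @param retreatRate,entranceRate per-state leaving rates of the two
#'   behavioral characters.
#' @param missingFraction,polymorphicFraction cell degradation levels.
#' @param seed master seed.
#' @return a named list (class `simConfig`).
#' @export
studySimConfig <- function(nTaxa = 110L, birth = 1, death = 0.2,
                           phylogramSigma = 0.5, nInputTrees = 3L,
                           overlapFraction = 0.7, perturbMoves = 0L,
                           nMorph = 55L, nDependent = 10L, rateRatio = 10,
                           morphRateFast = 2, morphRateIndependent = 0.75,
                           retreatRate = 1.5, entranceRate = 1.5,
                           missingFraction = 0.05,
                           polymorphicFraction = 0.05, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$nTaxa >= 3L, cfg$overlapFraction > 0,
            cfg$overlapFraction <= 1, cfg$nDependent <= cfg$nMorph,
            cfg$missingFraction >= 0, cfg$polymorphicFraction >= 0,
            cfg$missingFraction + cfg$polymorphicFraction <= 1,
            cfg$rateRatio >= 1)
  structure(cfg, class = "simConfig")
}

# overlapping taxon subsets covering the full tip set; the anchor tip
# (used for rooting) is placed in every subset
inputTreeSubsets <- function(tips, nTrees, fraction) {
  n <- length(tips)
  m <- max(3L, ceiling(fraction * n))
  anchor <- tips[1L]
  subsets <- lapply(seq_len(nTrees), function(i)
    unique(c(anchor, sample(tips, m))))
  covered <- unique(unlist(subsets))
  for (tx in setdiff(tips, covered)) {
    j <- sample.int(nTrees, 1L)
    subsets[[j]] <- c(subsets[[j]], tx)
  }
  subsets
}

#' Generate a complete synthetic study bundle
#'
#' One call produces every input the analysis pipeline needs, plus a
#' truth record of the generating process: a chronogram and phylogram,
#' overlapping input trees for supertree construction, and a character
#' matrix holding the two multistate behavioral characters
#' (`retreat_method`, `entrance_type`) and `nMorph` binary
#' morphological characters (`C1..`), a configurable subset of which
#' evolves behavior-dependently (fast toward presence while the
#' simulated lineage is an obligate burrower, slow otherwise).
#'
#' @param config a [studySimConfig()] list.
#' @return object of class `studyBundle`: `chronogram`, `phylogram`,
#'   `input_trees`, `matrix` (degraded), `matrix_true` (before
#'   degradation), `truth` (generating parameters, character classes,
#'   true node states of the behavioral characters).
#' @export
makeStudyBundle <- function(config = studySimConfig()) {
  cfg <- config
  chrono <- simulateTree(cfg$nTaxa, cfg$birth, cfg$death, seed = cfg$seed)
  phylo <- perturbBranchRates(chrono, cfg$phylogramSigma,
                              seed = cfg$seed + 1L)
  tips <- chrono$tip.label

  # behavioral characters (retreat: 3 states, entrance: 6 states)
  qR <- rateMatrix(3L, "ER", cfg$retreatRate / 2)
  qE <- rateMatrix(6L, "ER", cfg$entranceRate / 5)
  retreat <- simulateCharacter(chrono, qR, seed = cfg$seed + 2L,
                               history = TRUE)
  entrance <- simulateCharacter(chrono, qE, seed = cfg$seed + 3L)

  # morphological characters
  nDep <- cfg$nDependent
  depIdx <- seq_len(nDep)
  qInd <- rateMatrix(2L, "ER", cfg$morphRateIndependent)
  qHigh <- cfg$morphRateFast
  qLow <- cfg$morphRateFast / cfg$rateRatio
  burrowState <- retreatStates()[["obligate_burrower"]]
  morph <- vector("list", cfg$nMorph)
  for (j in seq_len(cfg$nMorph)) {
    morph[[j]] <- if (j %in% depIdx)
      simulateDependentBinary(retreat, burrowState, qHigh, qLow,
                              seed = cfg$seed + 100L + j)
    else
      simulateCharacter(chrono, qInd, seed = cfg$seed + 100L + j)
  }

  cells <- matrix(vector("list", cfg$nTaxa * (2L + cfg$nMorph)),
                  cfg$nTaxa, 2L + cfg$nMorph)
  for (i in seq_len(cfg$nTaxa)) {
    cells[[i, 1L]] <- unname(retreat[tips[i]])
    cells[[i, 2L]] <- unname(entrance[tips[i]])
    for (j in seq_len(cfg$nMorph))
      cells[[i, 2L + j]] <- unname(morph[[j]][tips[i]])
  }
  meta <- data.frame(
    id = c("retreat_method", "entrance_type", paste0("C", seq_len(cfg$nMorph))),
    label = c("retreat construction method", "retreat-entrance type",
              paste0("morphological character ", seq_len(cfg$nMorph))),
    n_states = c(3L, 6L, rep(2L, cfg$nMorph)),
    ordered = FALSE, stringsAsFactors = FALSE)
  cmTrue <- characterMatrix(cells, taxa = tips, meta = meta)
  cm <- degrade(cmTrue, cfg$missingFraction, cfg$polymorphicFraction,
                seed = cfg$seed + 4L)

  # overlapping input trees for supertree construction
  inputTrees <- withSeed(cfg$seed + 5L, {
    subsets <- inputTreeSubsets(tips, cfg$nInputTrees, cfg$overlapFraction)
    lapply(subsets, function(keep) {
      tr <- ape::keep.tip(chrono, keep)
      tr$edge.length <- NULL
      if (cfg$perturbMoves > 0L) {
        tr <- phangorn::rNNI(tr, moves = cfg$perturbMoves)
        tr <- ape::root(tr, outgroup = tips[1L], resolve.root = TRUE)
      }
      tr
    })
  })

  truth <- list(
    config = unclass(cfg),
    dependent_chars = paste0("C", depIdx),
    independent_chars = paste0("C", setdiff(seq_len(cfg$nMorph), depIdx)),
    dependent_driver = "burrowing",
    rates = list(retreat_per_pair = cfg$retreatRate / 2,
                 entrance_per_pair = cfg$entranceRate / 5,
                 morph_fast = qHigh, morph_slow = qLow,
                 morph_independent = cfg$morphRateIndependent),
    retreat_node_states = as.integer(attr(retreat, "node_states")),
    entrance_node_states = as.integer(attr(entrance, "node_states")),
    tip_order = tips)
  structure(list(chronogram = chrono, phylogram = phylo,
                 input_trees = inputTrees, matrix = cm,
                 matrix_true = cmTrue, truth = truth),
            class = "studyBundle")
}

#' @export
print.studyBundle <- function(x, ...) {
  cfg <- x$truth$config
  cat("studyBundle:", cfg$nTaxa, "taxa,", cfg$nMorph,
      "morphological characters (", length(x$truth$dependent_chars),
      "behavior-dependent),", length(x$input_trees), "input trees\n")
  invisible(x)
}

#' Write / read a truth record as JSON
#'
#' The truth record of a [makeStudyBundle()] result round-trips through
#' JSON so that downstream scoring can rely on archived generating
#' parameters.
#' @param truth the `truth` element of a `studyBundle`.
#' @param path JSON file path.
#' @return `writeTruthRecord`: `path` invisibly; `readTruthRecord`: the
#'   truth list.
#' @export
writeTruthRecord <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruthRecord
#' @export
readTruthRecord <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
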