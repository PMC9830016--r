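#' Format a p-value in the correlation-table style
#'
#' Two significant figures (e.g. `0.016`, `0.03`, `0.69`, `1`); full
#' precision belongs in the machine-readable output, not the display
#' table.
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
formatPValue <- function(p) {
  vapply(p, function(pi)
    format(signif(pi, 2), scientific = FALSE, trim = TRUE,
           drop0trailing = TRUE), character(1))
}

#' Assemble a study configuration
#'
#' Bundles the inputs and settings of a full analysis run for
#' [runStudy()].
#'
#' @param chronogram,phylogram rooted trees with branch lengths
#'   (chronogram: time-proportional; phylogram: change-proportional).
#' @param inputTrees list of rooted overlapping trees for supertree
#'   construction, or `NULL` to use `supertree` directly.
#' @param supertree optional pre-built supertree (topology-only is
#'   fine); ignored when `inputTrees` is given.
#' @param matrix a `charMatrix` holding the behavioral characters and
#'   the morphological characters.
#' @param features morphological character ids to screen against the
#'   behaviors (the hypothesis list).
#' @param behaviors behavior names to test (default: all five).
#' @param featureOneStates states counting as "present" when a feature
#'   is binarized (default `1`).
#' @param nSchemes pairing schemes per pairwise test.
#' @param alpha significance threshold gating the ML stage.
#' @param gate fit paired models only for feature/behavior cells
#'   significant in the pairwise stage (`FALSE` = fit all).
#' @param mlTree which branch-length set the ML correlation stage uses
#'   (`"chronogram"` or `"phylogram"`).
#' @param mlStarts,mpStarts optimizer / parsimony-search starts.
#' @param seed master seed.
#' @return list of class `studyConfig`.
#' @export
studyConfig <- function(chronogram, phylogram, matrix,
                        features, inputTrees = NULL, supertree = NULL,
                        behaviors = c("web_building", "opportunist",
                                      "burrowing", "entrance_modification",
                                      "trapdoor"),
                        featureOneStates = 1L, nSchemes = 1000L,
                        alpha = 0.05, gate = TRUE,
                        mlTree = c("chronogram", "phylogram"),
                        mlStarts = 3L, mpStarts = 10L, seed = 1L) {
  mlTree <- match.arg(mlTree)
  if (is.null(inputTrees) && is.null(supertree))
    stop("either inputTrees or supertree must be supplied")
  miss <- setdiff(features, matrix$meta$id)
  if (length(miss))
    stop("features not in the matrix: ", paste(miss, collapse = ", "))
  structure(as.list(environment()), class = "studyConfig")
}

#' Run the full behavioral-niche study
#'
#' Executes the whole pipeline: supertree construction (when input
#' trees are supplied), maximum-parsimony and maximum-likelihood
#' ancestral reconstruction of the two behavioral characters, the NMDS
#' morphospace of the morphological characters, and the correlation
#' screen of every feature/behavior pair — pairwise comparisons (PC1
#' and PC2, max-p over schemes) gating a 20-model maximum-likelihood
#' comparison summarized by delta-AICc.
#'
#' @param config a [studyConfig()].
#' @return object of class `studyReport`: `supertree`, `consensus`,
#'   `mrp_search`, `asr` (per behavioral character: `mp` and `ml`),
#'   `ordination`, `correlation` (the screen table), `log` (seeds and
#'   settings for reproducibility).
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "studyConfig"))
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- supertree -----------------------------------------------------
  search <- NULL
  if (!is.null(cfg$inputTrees)) {
    search <- stage("supertree", {
      mrp <- encodeMRP(cfg$inputTrees)
      parsimonySearch(mrp, nStarts = cfg$mpStarts, seed = cfg$seed)
    })
    consensus <- strictConsensus(search$trees)
    supertree <- search$trees[[1L]]   # config selects one resolution
  } else {
    supertree <- cfg$supertree
    consensus <- cfg$supertree
  }

  # ---- behaviors -----------------------------------------------------
  behaviors <- stage("behaviors", deriveBehaviors(cfg$matrix))
  behaviors <- behaviors[cfg$behaviors]

  # ---- ancestral reconstruction --------------------------------------
  asr <- stage("asr", {
    lapply(stats::setNames(nm = c("retreat_method", "entrance_type")),
           function(ch) {
      sets <- charStates(cfg$matrix, ch)
      stMP <- intersectTaxa(supertree, cfg$matrix)
      mp <- mpReconstruct(stMP$tree, sets,
                          nStates = cfg$matrix$meta$n_states[
                            match(ch, cfg$matrix$meta$id)])
      mlTrees <- list(chronogram = cfg$chronogram,
                      phylogram = cfg$phylogram)
      mlTrees <- lapply(mlTrees, function(tr)
        intersectTaxa(tr, cfg$matrix)$tree)
      ml <- selectAsrModel(mlTrees, sets, nStarts = cfg$mlStarts,
                           seed = cfg$seed)
      list(mp = mp, ml = ml)
    })
  })

  # ---- morphospace ---------------------------------------------------
  morphIds <- setdiff(cfg$matrix$meta$id,
                      c("retreat_method", "entrance_type"))
  ordination <- stage("nmds", {
    g <- gowerDissimilarity(cfg$matrix, morphIds)
    nmds(g, k = 2L, nStarts = 10L, seed = cfg$seed)
  })

  # ---- correlation screen --------------------------------------------
  correlation <- stage("correlation", {
    rows <- list()
    for (feat in cfg$features) {
      yTrait <- binarizeStates(charStates(cfg$matrix, feat),
                               cfg$featureOneStates, feat)
      for (bh in cfg$behaviors) {
        xTrait <- behaviors[[bh]]
        st <- intersectTaxa(supertree, cfg$matrix)$tree
        pc1 <- pairwiseTest(st, xTrait, yTrait, "PC1",
                            nSchemes = cfg$nSchemes, seed = cfg$seed)
        pc2 <- pairwiseTest(st, xTrait, yTrait, "PC2",
                            nSchemes = cfg$nSchemes, seed = cfg$seed)
        significant <- min(pc1$p, pc2$p) <= cfg$alpha
        deltas <- rep(NA_real_, 4L)
        if (!cfg$gate || significant) {
          mlPhy <- intersectTaxa(
            if (cfg$mlTree == "chronogram") cfg$chronogram
            else cfg$phylogram, cfg$matrix)$tree
          cmp <- tryCatch(
            compareDependence(mlPhy, xTrait, yTrait,
                              nStarts = cfg$mlStarts, seed = cfg$seed),
            error = function(e) NULL)
          if (!is.null(cmp))
            deltas <- cmp$categories$deltaAICc[
              match(c("IND", "XD", "YD", "INT"), cmp$categories$category)]
        }
        dirn <- if (pc1$counts[["positive"]] > pc1$counts[["negative"]])
          "positive" else if (pc1$counts[["positive"]] <
                              pc1$counts[["negative"]]) "negative" else "none"
        rows[[length(rows) + 1L]] <- data.frame(
          feature = feat, behavior = bh,
          PC1 = sprintf("%s (%d:%d)", formatPValue(pc1$p),
                        pc1$counts[["positive"]], pc1$counts[["negative"]]),
          PC2 = sprintf("%s (%d:%d:%d)", formatPValue(pc2$p),
                        pc2$counts[["positive"]], pc2$counts[["negative"]],
                        pc2$counts[["neutral"]]),
          PC1_p = pc1$p, PC2_p = pc2$p,
          PC1_pos = pc1$counts[["positive"]],
          PC1_neg = pc1$counts[["negative"]],
          dAICc_indep = deltas[1], dAICc_xdep = deltas[2],
          dAICc_ydep = deltas[3], dAICc_interdep = deltas[4],
          direction = dirn, significant = significant,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  logInfo <- list(seed = cfg$seed, n_schemes = cfg$nSchemes,
                  alpha = cfg$alpha, gate = cfg$gate, ml_tree = cfg$mlTree,
                  ml_starts = cfg$mlStarts, mp_starts = cfg$mpStarts,
                  behaviors = cfg$behaviors, features = cfg$features,
                  package_version = as.character(utils::packageVersion("mygacomp")))
  structure(list(supertree = supertree, consensus = consensus,
                 mrp_search = search, asr = asr, ordination = ordination,
                 correlation = correlation, log = logInfo),
            class = "studyReport")
}

#' @export
print.studyReport <- function(x, ...) {
  cat("studyReport\n")
  if (!is.null(x$mrp_search))
    cat("  supertree:", ape::Ntip(x$supertree), "tips,",
        length(x$mrp_search$trees), "optimal topologies\n")
  cat("  NMDS stress:", formatC(x$ordination$stress, digits = 4,
                                format = "f"), "\n")
  cat("  correlation screen:", nrow(x$correlation), "feature x behavior",
      "cells,", sum(x$correlation$significant), "significant\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the correlation table (display and full-precision columns),
#' NMDS coordinates, supertree and consensus Newick files, per-node
#' ancestral reconstruction tables, and a JSON run log.
#'
#' @param report a `studyReport` from [runStudy()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$correlation
  disp <- tab[, c("feature", "behavior", "PC1", "PC2", "dAICc_indep",
                  "dAICc_xdep", "dAICc_ydep", "dAICc_interdep",
                  "direction")]
  for (cc in grep("^dAICc", names(disp))) {
    v <- disp[[cc]]
    disp[[cc]] <- ifelse(is.na(v), "-", formatC(v, digits = 2, format = "f"))
  }
  utils::write.table(disp, file.path(dir, "correlation_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tab, file.path(dir, "correlation_full.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  coords <- data.frame(taxon = rownames(report$ordination$points),
                       report$ordination$points)
  utils::write.table(coords, file.path(dir, "nmds_coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writePhyloTree(report$supertree, file.path(dir, "supertree.nwk"))
  writePhyloTree(report$consensus, file.path(dir, "supertree_consensus.nwk"))
  for (ch in names(report$asr)) {
    ml <- report$asr[[ch]]$ml
    marg <- ml$marginals
    df <- data.frame(node = seq_len(nrow(marg)), marg)
    colnames(df) <- c("node", paste0("p_state", seq_len(ncol(marg)) - 1L))
    utils::write.table(df, file.path(dir, paste0("asr_", ch, "_ml.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mp <- report$asr[[ch]]$mp
    dfmp <- data.frame(
      node = seq_along(mp$node_sets),
      mp_states = vapply(mp$node_sets, paste, character(1), collapse = ","))
    utils::write.table(dfmp, file.path(dir, paste0("asr_", ch, "_mp.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
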