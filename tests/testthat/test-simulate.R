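test_that("simulated trees honor the tip-count and rescaling contracts", {
  for (seed in 1:5) {
    phy <- simulateTree(10, 1, 0, seed = seed)
    expect_equal(ape::Ntip(phy), 10L)
    expect_true(ape::is.ultrametric(phy, tol = 1e-8))
    expect_equal(max(ape::node.depth.edgelength(phy)), 1, tolerance = 1e-9)
  }
  expect_error(simulateTree(10, 1, 1.5, seed = 1), "death rate")
  expect_error(simulateTree(2, 1, 0, seed = 1), "nTaxa")
})

test_that("Yule mean root depth matches the harmonic-sum expectation", {
  lambda <- 1; n <- 10
  expected <- sum(1 / (lambda * 2:n))
  depths <- vapply(1:400, function(s)
    max(ape::node.depth.edgelength(
      simulateTree(n, lambda, 0, seed = s, rescale = FALSE))), numeric(1))
  expect_lt(abs(mean(depths) - expected) / expected, 0.1)
})

test_that("the phylogram copy is a lognormal perturbation with mean one", {
  phy <- simulateTree(80, 1, 0.2, seed = 2)
  pg <- perturbBranchRates(phy, 0.5, seed = 3)
  ratio <- pg$edge.length / phy$edge.length
  expect_false(ape::is.ultrametric(pg, tol = 1e-6))
  expect_lt(abs(mean(ratio) - 1), 0.15)
  expect_identical(pg$tip.label, phy$tip.label)
})

test_that("a zero rate matrix transmits the root state unchanged", {
  phy <- simulateTree(15, 1, 0, seed = 4)
  tips <- simulateCharacter(phy, matrix(0, 3, 3), rootState = 2L, seed = 1)
  expect_true(all(tips == 2L))
})

test_that("single-branch flip probability matches the closed form", {
  q <- 0.6; t <- 1.3
  phy <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2,
                                      byrow = TRUE),
                        edge.length = c(t, 1e-12), Nnode = 1L,
                        tip.label = c("A", "B")), class = "phylo")
  flips <- vapply(1:4000, function(s)
    simulateCharacter(phy, rateMatrix(2, "ER", q), rootState = 0L,
                      seed = s)[["A"]], numeric(1))
  pFlip <- 0.5 - 0.5 * exp(-2 * q * t)
  se <- sqrt(pFlip * (1 - pFlip) / 4000)
  expect_lt(abs(mean(flips) - pFlip), 4 * se)
})

test_that("long branches approach the stationary distribution", {
  phy <- simulateTree(200, 1, 0, seed = 6)
  phy$edge.length <- phy$edge.length * 60   # long-branch limit
  Q <- rateMatrix(2, "ARD", c(0.9, 0.3))    # stationary (0.25, 0.75)
  tips <- simulateCharacter(phy, Q, seed = 2)
  expect_lt(abs(mean(tips) - 0.75), 0.1)
})

test_that("independent pair simulations center the association near zero", {
  phy <- simulateTree(60, 1, 0, seed = 8)
  tpl <- enumerateModels()$IND_ER_ER
  phis <- vapply(1:100, function(s) {
    sim <- simulateCorrelatedPair(phy, tpl, c(1, 1), seed = s)
    xv <- as.integer(sim$x$values); yv <- as.integer(sim$y$values)
    if (sd(xv) == 0 || sd(yv) == 0) return(NA_real_)
    cor(xv, yv)
  }, numeric(1))
  expect_lt(abs(mean(phis, na.rm = TRUE)), 0.08)
})

test_that("dependent simulation produces strong positive association", {
  phy <- simulateTree(150, 1, 0.2, seed = 9)
  phis <- vapply(1:10, function(s) {
    drv <- simulateCharacter(phy, rateMatrix(2, "ER", 0.8), seed = s,
                             history = TRUE)
    y <- simulateDependentBinary(drv, 1L, qHigh = 2, qLow = 0.1,
                                 seed = 1000 + s)
    cor(as.integer(drv), as.integer(y))
  }, numeric(1))
  expect_gt(median(phis), 0.3)
})

test_that("degradation hits binomial cell counts and keeps the contract", {
  cm <- makeStudyBundle(studySimConfig(nTaxa = 100, seed = 5,
                                       missingFraction = 0,
                                       polymorphicFraction = 0))$matrix
  dg <- degrade(cm, 0.1, 0, seed = 3)
  nMiss <- sum(lengths(dg$cells) == 0L)
  nCell <- length(dg$cells)
  expect_lt(abs(nMiss - 0.1 * nCell), 4 * sqrt(nCell * 0.1 * 0.9))
  expect_s3_class(validateCharacterMatrix(dg), "charMatrix")
  expect_error(degrade(cm, 0.7, 0.5), "sum to more than 1")
  # zero fractions are the identity
  expect_equal(degrade(cm, 0, 0, seed = 1)$cells, cm$cells,
               ignore_attr = TRUE)
})

test_that("study bundles are reproducible and exercise the supertree path", {
  cfg <- studySimConfig(nTaxa = 30, nMorph = 8, nDependent = 3,
                        missingFraction = 0.02,
                        polymorphicFraction = 0.02, seed = 12)
  b1 <- makeStudyBundle(cfg)
  b2 <- makeStudyBundle(cfg)
  expect_identical(b1$matrix$cells, b2$matrix$cells)
  expect_identical(ape::write.tree(b1$chronogram),
                   ape::write.tree(b2$chronogram))
  # unperturbed overlapping input trees: every encoded clade is a clade
  # of the true tree, so the optimum is one step per column and the true
  # topology attains it (uniqueness needs enough overlap, tested in the
  # acceptance suite with hand-chosen subsets)
  mrp <- encodeMRP(b1$input_trees)
  res <- parsimonySearch(mrp, nStarts = 5, seed = 1)
  expect_equal(res$score, ncol(mrp$mat))
  pd <- subset(mygacomp:::mrpToPhyDat(mrp), b1$chronogram$tip.label)
  trueScore <- phangorn::parsimony(b1$chronogram, pd)
  expect_equal(unname(trueScore), res$score)
})

test_that("truth records round-trip through JSON", {
  b <- makeStudyBundle(studySimConfig(nTaxa = 20, nMorph = 5,
                                      nDependent = 2, seed = 3))
  f <- withr::local_tempfile(fileext = ".json")
  writeTruthRecord(b$truth, f)
  back <- readTruthRecord(f)
  expect_equal(back$dependent_chars, b$truth$dependent_chars)
  expect_equal(back$config$nTaxa, b$truth$config$nTaxa)
  expect_equal(back$retreat_node_states, b$truth$retreat_node_states)
  expect_equal(back$rates$morph_fast, b$truth$rates$morph_fast)
})
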