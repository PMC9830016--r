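test_that("the model set has the documented structure", {
  tpls <- enumerateModels()
  expect_length(tpls, 20L)
  hidden <- vapply(tpls, `[[`, logical(1), "hidden")
  expect_equal(sum(!hidden), 16L)
  expect_equal(sum(hidden), 4L)
  ids <- vapply(tpls, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)
  expect_identical(ids, vapply(enumerateModels(), `[[`, character(1), "id"))
  # hidden counterparts exist only for the independent category
  expect_true(all(vapply(tpls[hidden], `[[`, character(1),
                         "dependence") == "IND"))
  # free-parameter counts
  np <- stats::setNames(vapply(tpls, `[[`, integer(1), "n_par"), ids)
  expect_equal(np[["IND_ER_ER"]], 2L)
  expect_equal(np[["IND_ER_ARD"]], 3L)
  expect_equal(np[["IND_ARD_ER"]], 3L)
  expect_equal(np[["IND_ARD_ARD"]], 4L)
  expect_equal(np[["XD_ER_ER"]], 3L)     # dependent character doubled
  expect_equal(np[["YD_ER_ER"]], 3L)
  expect_equal(np[["INT_ARD_ARD"]], 8L)
  expect_equal(np[["HID_IND_ER_ER"]], 5L)    # 2x rates + class switch
  expect_equal(np[["HID_IND_ARD_ARD"]], 9L)
})

test_that("paired rate matrices forbid dual transitions and class-changing observations", {
  tpls <- enumerateModels()
  for (tpl in tpls) {
    Q <- buildPairedQ(tpl, runif(tpl$n_par, 0.1, 2))
    expect_equal(rowSums(Q), rep(0, tpl$n_states), tolerance = 1e-12)
    k <- 4L
    for (i in 1:4) for (j in 1:4) {
      xi <- (i - 1) %/% 2; yi <- (i - 1) %% 2
      xj <- (j - 1) %/% 2; yj <- (j - 1) %% 2
      if (xi != xj && yi != yj) {
        expect_equal(Q[i, j], 0)
        if (tpl$hidden) {
          expect_equal(Q[i + 4, j + 4], 0)
          expect_equal(Q[i, j + 4], 0)     # class switch + state change
          expect_equal(Q[i + 4, j], 0)
        }
      }
    }
  }
})

test_that("hidden-class relabeling leaves the likelihood unchanged", {
  set.seed(6)
  phy <- ape::rtree(8)
  tpl <- enumerateModels()$HID_IND_ARD_ARD
  rates <- runif(tpl$n_par, 0.1, 2)
  x <- bt("x", stats::setNames(sample(0:1, 8, TRUE), phy$tip.label))
  y <- bt("y", stats::setNames(sample(0:1, 8, TRUE), phy$tip.label))
  joint <- mygacomp:::jointStateSets(x, y, phy$tip.label)
  joint <- lapply(joint, function(s) c(s, s + 4L))
  tipL <- mygacomp:::tipPartials(phy, joint, 8L)
  Q <- buildPairedQ(tpl, rates)
  ll1 <- mygacomp:::pruningLogLik(phy, tipL, Q, "equal")
  # swap class A and B blocks
  perm <- c(5:8, 1:4)
  Q2 <- Q[perm, perm]
  ll2 <- mygacomp:::pruningLogLik(phy, tipL, Q2, "equal")
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("paired pruning equals brute-force enumeration, 4- and 8-state", {
  set.seed(44)
  tpls <- enumerateModels()
  for (rep in 1:10) {
    n <- 4
    phy <- ape::rtree(n)
    tpl <- tpls[[sample(length(tpls), 1)]]
    rates <- runif(tpl$n_par, 0.1, 2)
    Q <- buildPairedQ(tpl, rates)
    xv <- sample(c("0", "1", "ambiguous"), n, TRUE, prob = c(.4, .4, .2))
    yv <- sample(c("0", "1", "missing"), n, TRUE, prob = c(.4, .4, .2))
    x <- binaryTrait("x", stats::setNames(xv, phy$tip.label))
    y <- binaryTrait("y", stats::setNames(yv, phy$tip.label))
    joint <- mygacomp:::jointStateSets(x, y, phy$tip.label)
    if (tpl$hidden) joint <- lapply(joint, function(s) c(s, s + 4L))
    tipL <- mygacomp:::tipPartials(phy, joint, tpl$n_states)
    ll <- mygacomp:::pruningLogLik(phy, tipL, Q, "equal")
    oracle <- oracleLogLik(phy, joint, Q)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("independence-template likelihood factorizes into two Mk likelihoods", {
  set.seed(15)
  phy <- ape::rtree(12)
  qx01 <- 0.7; qx10 <- 1.3; qy01 <- 0.4; qy10 <- 0.9
  tpl <- enumerateModels()$IND_ARD_ARD
  rates <- stats::setNames(numeric(tpl$n_par), tpl$labels)
  rates[c("x01", "x10", "y01", "y10")] <- c(qx01, qx10, qy01, qy10)
  Q <- buildPairedQ(tpl, unname(rates[tpl$labels]))
  xs <- sample(0:1, 12, TRUE); ys <- sample(0:1, 12, TRUE)
  x <- bt("x", stats::setNames(xs, phy$tip.label))
  y <- bt("y", stats::setNames(ys, phy$tip.label))
  joint <- mygacomp:::jointStateSets(x, y, phy$tip.label)
  tipL <- mygacomp:::tipPartials(phy, joint, 4L)
  llJoint <- mygacomp:::pruningLogLik(phy, tipL, Q, "equal")
  Qx <- matrix(c(-qx01, qx01, qx10, -qx10), 2, 2, byrow = TRUE)
  Qy <- matrix(c(-qy01, qy01, qy10, -qy10), 2, 2, byrow = TRUE)
  llX <- mkLogLik(phy, stats::setNames(as.list(xs), phy$tip.label), Qx)
  llY <- mkLogLik(phy, stats::setNames(as.list(ys), phy$tip.label), Qy)
  expect_equal(llJoint, llX + llY, tolerance = 1e-8)
})

test_that("fits respect nesting and invariant traits are refused", {
  set.seed(26)
  phy <- simulateTree(40, 1, 0, seed = 5)
  tpl <- enumerateModels()$IND_ER_ER
  sim <- simulateCorrelatedPair(phy, tpl, c(0.8, 0.8), seed = 2)
  fInd <- fitPairedModel(phy, sim$x, sim$y, tpl, nStarts = 2, seed = 1)
  fInt <- fitPairedModel(phy, sim$x, sim$y,
                         enumerateModels()$INT_ARD_ARD, nStarts = 2,
                         seed = 1)
  expect_gte(fInt$logL, fInd$logL - 1e-6)
  flat <- binaryTrait("flat",
                      stats::setNames(rep("1", 40), phy$tip.label))
  expect_error(fitPairedModel(phy, flat, sim$y, tpl),
               "invariant, model unidentifiable")
})

test_that("the dependence comparison is zero-anchored over four categories", {
  set.seed(27)
  phy <- simulateTree(30, 1, 0, seed = 6)
  sim <- simulateCorrelatedPair(phy, enumerateModels()$IND_ER_ER,
                                c(0.9, 0.9), seed = 3)
  cmp <- compareDependence(phy, sim$x, sim$y, nStarts = 1, seed = 1)
  expect_equal(nrow(cmp$table), 20L)
  expect_setequal(cmp$categories$category, c("IND", "XD", "YD", "INT"))
  expect_true(all(cmp$categories$deltaAICc >= 0))
  expect_equal(sum(cmp$categories$deltaAICc == 0), 1L)
  # hidden models compete inside the independent category
  expect_true(all(cmp$table$category[cmp$table$hidden] == "IND"))
})
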