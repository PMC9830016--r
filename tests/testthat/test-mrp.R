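test_that("Baum-Ragan encoding matches hand application", {
  tr <- ape::read.tree(text = "((A,B),C);")
  mrp <- encodeMRP(list(tr), taxa = c("A", "B", "C", "D"))
  expect_equal(ncol(mrp$mat), 1L)
  col <- mrp$mat[, 1L]
  expect_equal(col[["A"]], 1L)
  expect_equal(col[["B"]], 1L)
  expect_equal(col[["C"]], 0L)
  expect_true(is.na(col[["D"]]))
  expect_equal(col[["MRP_outgroup"]], 0L)
})

test_that("a star tree encodes no informative columns", {
  star <- ape::read.tree(text = "(A,B,C);")
  mrp <- encodeMRP(list(star))
  expect_equal(ncol(mrp$mat), 0L)
  expect_error(parsimonySearch(mrp), "empty")
})

test_that("unrooted input trees are rejected with rooting advice", {
  un <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  expect_error(encodeMRP(list(un)), "root it first")
})

test_that("search on a single-tree matrix recovers it at length = #columns", {
  set.seed(2)
  tr <- ape::rtree(12, br = NULL)
  mrp <- encodeMRP(list(tr))
  res <- parsimonySearch(mrp, nStarts = 5, seed = 1)
  expect_equal(res$score, ncol(mrp$mat))
  expect_equal(length(res$trees), 1L)
  expect_equal(phangorn::RF.dist(res$trees[[1]], tr, check.labels = TRUE), 0)
  # monotone improvement: final score never above any start score
  expect_true(all(res$score <= res$start_scores))
})

test_that("duplicate input trees double the score, same optimum", {
  set.seed(4)
  tr <- ape::rtree(8, br = NULL)
  one <- parsimonySearch(encodeMRP(list(tr)), nStarts = 5, seed = 1)
  two <- parsimonySearch(encodeMRP(list(tr, tr)), nStarts = 5, seed = 1)
  expect_equal(two$score, 2L * one$score)
  expect_equal(phangorn::RF.dist(one$trees[[1]], two$trees[[1]],
                                 check.labels = TRUE), 0)
})

test_that("heuristic equals exhaustive optimum on small compatible inputs", {
  set.seed(9)
  for (rep in 1:3) {
    base <- ape::rtree(6, br = NULL)
    t1 <- ape::keep.tip(base, base$tip.label[1:5])
    t2 <- ape::keep.tip(base, base$tip.label[2:6])
    mrp <- encodeMRP(list(t1, t2))
    res <- parsimonySearch(mrp, nStarts = 5, seed = rep)
    oracle <- oracleBestParsimony(mrp)
    expect_equal(res$score, oracle$best)
  }
})

test_that("conflicting clade placements yield several optima and a consensus polytomy", {
  # two trees disagreeing on the position of E relative to (C,D) vs (A,B)
  t1 <- ape::read.tree(text = "((((A,B),E),(C,D)),O);")
  t2 <- ape::read.tree(text = "(((A,B),((C,D),E)),O);")
  mrp <- encodeMRP(list(t1, t2))
  res <- parsimonySearch(mrp, nStarts = 10, seed = 1)
  oracle <- oracleBestParsimony(mrp)
  expect_equal(res$score, oracle$best)
  expect_gte(length(res$trees), 2L)
  cons <- strictConsensus(res$trees)
  # strict consensus cannot be fully resolved under genuine conflict
  expect_lt(cons$Nnode, ape::Ntip(cons) - 1L)
})

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- ape::read.tree(text = "((((A,B),C),D),O);")
  expect_equal(phangorn::RF.dist(strictConsensus(c(t1, t1)), t1), 0)
  t2 <- ape::read.tree(text = "((((A,C),B),D),O);")
  cons <- strictConsensus(c(t1, t2))
  splits <- ape::prop.part(cons)
  sizes <- sort(lengths(splits))
  # the root, {A,B,C,D} and the {A,B,C} clade survive; {A,B}/{A,C} do not
  expect_equal(sizes, c(3L, 4L, 5L))
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(strictConsensus(c(t1, t3)), "identical tip sets")
})

test_that("random resolutions of a fixed clade intersect to that clade", {
  set.seed(21)
  star <- ape::read.tree(
    text = "((t1,t2,t3,t4),t5,t6,t7,t8,t9,t10);")
  trees <- lapply(1:30, function(i) ape::multi2di(star, random = TRUE))
  cons <- strictConsensus(trees)
  splits <- ape::prop.part(cons)
  labs <- attr(splits, "labels")
  hasFixed <- any(vapply(splits, function(s)
    setequal(labs[s], paste0("t", 1:4)), logical(1)))
  expect_true(hasFixed)
  # and nothing below that clade is resolved in the consensus
  expect_lte(cons$Nnode, 3L)
})

test_that("the MRP matrix exports through the character-matrix NEXUS path", {
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  mrp <- encodeMRP(list(tr))
  cm <- mrpAsCharacterMatrix(mrp)
  f <- withr::local_tempfile(fileext = ".nex")
  writeCharacterMatrix(cm, f)
  back <- readCharacterMatrix(f)
  expect_equal(back$cells, cm$cells, ignore_attr = TRUE)
})
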