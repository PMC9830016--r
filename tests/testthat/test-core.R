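test_that("Newick reading preserves structure and flags rooting", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  phy <- readPhyloTree(f)
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(depths[match("A", phy$tip.label)], 2.0)
  expect_true(isTRUE(attr(phy, "rooted")))

  writeLines("(A,B,C);", f)
  star <- readPhyloTree(f)
  expect_true(is.na(attr(star, "rooted")))   # basal polytomy: ambiguous

  writeLines("((A:1,A:1):1,C:2);", f)
  expect_error(readPhyloTree(f), "duplicate tip")
})

test_that("tree I/O round-trips topology and branch lengths", {
  set.seed(7)
  phy <- ape::rtree(50)
  f <- withr::local_tempfile(fileext = ".nwk")
  writePhyloTree(phy, f)
  back <- readPhyloTree(f)
  expect_equal(phangorn::RF.dist(phy, back, check.labels = TRUE), 0)
  d1 <- patristicDistances(phy); d2 <- patristicDistances(back)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
})

test_that("genus pruning keeps one representative, merges lengths, warns", {
  phy <- ape::read.tree(
    text = "(((Aname_sp1:1,Aname_sp2:1):2,Atrax_sp1:3):3,Out_sp:6);")
  map <- c(Aname_sp1 = "Aname", Aname_sp2 = "Aname", Atrax_sp1 = "Atrax",
           Out_sp = "Out", Ghost_sp = "Ghost")
  expect_warning(pr <- pruneToGenus(phy, map), "Ghost")
  expect_setequal(pr$tip.label, c("Aname", "Atrax", "Out"))
  # unary suppression is additive: Aname root-to-tip length unchanged
  expect_equal(max(ape::node.depth.edgelength(pr)), 6)
  d <- patristicDistances(pr)
  expect_equal(d["Aname", "Atrax"], 1 + 2 + 3)
})

test_that("pruning a subset preserves pairwise patristic distances", {
  phy <- simulateTree(110, 1, 0.2, seed = 3)
  keep <- phy$tip.label[1:89]
  map <- stats::setNames(paste0("G_", keep), keep)
  pr <- pruneToGenus(phy, map)
  dFull <- patristicDistances(phy)[keep, keep]
  dPruned <- patristicDistances(pr)
  rownames(dFull) <- colnames(dFull) <- paste0("G_", keep)
  expect_equal(dPruned[rownames(dFull), colnames(dFull)], dFull,
               tolerance = 1e-9)
})

test_that("character-matrix NEXUS and table I/O round-trip state sets", {
  set.seed(11)
  for (rep in 1:3) {
    cm <- randomCharMatrix(12, 8)
    f <- withr::local_tempfile(fileext = ".nex")
    writeCharacterMatrix(cm, f, "nexus")
    back <- readCharacterMatrix(f, "nexus")
    expect_equal(back$taxa, cm$taxa)
    expect_equal(back$cells, cm$cells, ignore_attr = TRUE)
    expect_equal(back$meta$ordered, cm$meta$ordered)

    ft <- withr::local_tempfile(fileext = ".tsv")
    writeCharacterMatrix(cm, ft, "table")
    backT <- readCharacterMatrix(ft, "table")
    expect_equal(backT$cells, cm$cells, ignore_attr = TRUE)
  }
})

test_that("cell tokens parse polymorphism and missing markers", {
  expect_equal(parseCellToken("0"), 0L)
  expect_equal(parseCellToken("0/1"), c(0L, 1L))
  expect_equal(parseCellToken("{01}"), c(0L, 1L))
  expect_equal(parseCellToken("(12)"), c(1L, 2L))
  expect_equal(parseCellToken("?"), integer(0))
  expect_equal(parseCellToken("-"), integer(0))
  expect_error(parseCellToken("x"), "cannot parse")
})

test_that("matrix validation rejects out-of-range states", {
  cells <- matrix(list(0L, 5L), 1, 2)
  meta <- data.frame(id = c("C1", "C2"), n_states = c(2L, 3L),
                     ordered = FALSE)
  expect_error(characterMatrix(cells, taxa = "t1", meta = meta),
               "outside 0")
})

test_that("tree/matrix intersection drops and reports mismatches", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- matrix("0", 3, 2, dimnames = list(c("A", "B", "E"), NULL))
  m[1, 2] <- "1"
  cm <- characterMatrix(m)
  expect_error(suppressMessages(intersectTaxa(phy, cm)), "fewer than 3")
  m2 <- rbind(m, C = c("1", "0"))
  expect_message(res <- intersectTaxa(phy, characterMatrix(m2)), "dropped")
  expect_setequal(res$tree$tip.label, c("A", "B", "C"))
  expect_equal(res$dropped_from_matrix, "E")
  expect_equal(res$dropped_from_tree, "D")
})
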