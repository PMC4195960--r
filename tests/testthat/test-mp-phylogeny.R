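test_that("two identical haplotypes at distance 2 give a star of length 2", {
  ps <- list(profileFrom("a", c("1000", "2000")),
             profileFrom("b", c("1000", "2000")))
  t <- buildMPTree(ps, emptyRootProfile())
  expect_equal(treeLength(t), 2L)
  expect_equal(nTips(t), 2L)
  # both leaves hang off one internal haplotype node
  expect_equal(max(t@edge) - t@nTips, 2L)
})

test_that("the classic three-leaf conflict resolves at length 3", {
  # leaves {1}, {1,2}, {2}: any tree needs one recurrent event
  ps <- list(profileFrom("A", "1000"),
             profileFrom("B", c("1000", "2000")),
             profileFrom("C", "2000"))
  t <- buildMPTree(ps, emptyRootProfile())
  expect_equal(treeLength(t), 3L)
  expect_true(t@exact)
  expect_equal(treeLength(t),
               phangornSteinerLength(ps, emptyRootProfile()))
})

test_that("exact search matches the independent Steiner oracle", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (i in 1:40) {
    nH <- sample(4:8, 1)
    sites <- sample(seq(1000, 16000, by = 7), 12)
    ps <- randomProfiles(nH, sites)
    root <- emptyRootProfile()
    t <- buildMPTree(ps, root)
    expect_true(t@exact)
    expect_equal(treeLength(t), phangornSteinerLength(ps, root),
                 info = sprintf("instance %d", i))
  }
})

test_that("every accepted tree reconstructs its leaf states exactly", {
  set.seed(43)
  for (i in 1:30) {
    nH <- sample(2:10, 1)
    sites <- sample(seq(500, 16500, by = 11), 10)
    ps <- randomProfiles(nH, sites)
    rootLabs <- as.character(sites[stats::runif(10) < 0.2])
    t <- buildMPTree(ps, profileFrom("(root)", rootLabs))
    # node state = root state symmetric-differenced with edge labels
    for (tip in seq_len(nTips(t))) {
      state <- sort(t@rootVariants)
      for (e in mitorho:::pathEdges(t, tip)) {
        el <- t@edgeLabels[[e]]
        for (lab in el$label)
          state <- if (lab %in% state) setdiff(state, lab)
                   else sort(c(state, lab))
      }
      observed <- sort(variantLabels(t@leafProfiles[[t@tipLabels[tip]]]))
      expect_equal(sort(state), observed)
    }
    # and the nodeStates slot agrees with the observed profiles
    for (tip in seq_len(nTips(t)))
      expect_setequal(t@nodeStates[[tip]],
                      variantLabels(t@leafProfiles[[t@tipLabels[tip]]]))
  }
})

test_that("tree length is the sum of edge mutations, order-invariant", {
  ps <- list(profileFrom("a", "1000"), profileFrom("b", "2000"),
             profileFrom("c", "3000"))
  t <- buildMPTree(ps, emptyRootProfile())
  expect_equal(treeLength(t), 3L)
  t2 <- buildMPTree(rev(ps), emptyRootProfile())
  expect_equal(treeLength(t2), treeLength(t))
  expect_equal(computeRho(t2), computeRho(t))
  # single leaf identical to root
  t0 <- buildMPTree(list(profileFrom("z")), emptyRootProfile())
  expect_equal(treeLength(t0), 0L)
})

test_that("exact-mode length never exceeds a spanning-tree length", {
  set.seed(47)
  for (i in 1:20) {
    nH <- sample(3:7, 1)
    sites <- sample(seq(100, 16000, by = 13), 10)
    ps <- randomProfiles(nH, sites)
    root <- emptyRootProfile()
    t <- buildMPTree(ps, root)
    # minimum spanning tree of the haplotype+root hamming graph
    labs <- lapply(c(list(root), ps), variantLabels)
    D <- outer(seq_along(labs), seq_along(labs), Vectorize(function(a, b)
      length(setdiff(labs[[a]], labs[[b]])) +
        length(setdiff(labs[[b]], labs[[a]]))))
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    mstLen <- sum(igraph::E(igraph::mst(g))$weight)
    expect_lte(treeLength(t), mstLen)
  }
})

test_that("heuristic mode is reported beyond the exact cap", {
  set.seed(53)
  sites <- seq(1000, 12000, by = 250)
  ps <- randomProfiles(15, sites, pMut = 0.5)
  t <- buildMPTree(ps, emptyRootProfile(), exactCap = 6L)
  expect_false(t@exact)
  expect_true(is.na(t@nCoOptimal))
  expect_equal(treeLength(t),
               sum(vapply(t@edgeLabels, nrow, 0L)))
})

test_that("region-specific subclades are maximal and non-nested", {
  ps <- list(profileFrom("sib1", c("5471", "12634", "14869"),
                         region = "Siberia"),
             profileFrom("sib2", c("5471", "12634", "14869", "900"),
                         region = "Siberia"),
             profileFrom("sib3", c("5471", "12634", "3736"),
                         region = "Siberia"),
             profileFrom("wa1", c("5471", "600"),
                         region = "western Asia"),
             profileFrom("eu1", "700", region = "Europe"))
  t <- buildMPTree(ps, emptyRootProfile())
  rs <- findRegionSpecificClades(t, "Siberia")
  expect_equal(rs$totalLeaves, 3L)
  # one maximal clade holding all three Siberians (they share 12634)
  expect_equal(nrow(rs$clades), 1L)
  expect_equal(rs$clades$leaves, "sib1 sib2 sib3")
  # none of the returned nodes is an ancestor of another
  if (nrow(rs$clades) > 1L) {
    for (i in seq_len(nrow(rs$clades)))
      for (j in seq_len(nrow(rs$clades)))
        if (i != j)
          expect_false(rs$clades$node[j] %in%
            mitorho:::tipsUnder(t, rs$clades$node[i]))
  }

  # no target leaves: empty result
  none <- findRegionSpecificClades(t, "Oceania")
  expect_equal(nrow(none$clades), 0L)
  expect_equal(none$totalLeaves, 0L)

  # all leaves in target: the root itself, covering n
  all <- findRegionSpecificClades(t, c("Siberia", "western Asia",
                                       "Europe"))
  expect_equal(nrow(all$clades), 1L)
  expect_equal(all$clades$node, mitorho:::rootNode(t))
  expect_equal(all$totalLeaves, nTips(t))

  # missing region class is an error
  bad <- c(ps, list(profileFrom("x", "800")))
  tb <- buildMPTree(bad, emptyRootProfile())
  expect_error(findRegionSpecificClades(tb, "Siberia"), "x")
})

test_that("back mutations are flagged on edges", {
  # B carries 1000 and loses it again in C's lineage under this rooting:
  # force a back mutation by making the root already carry the variant
  ps <- list(profileFrom("keeps", c("1000", "2000")),
             profileFrom("loses", "2000"))
  t <- buildMPTree(ps, profileFrom("(root)", "1000"))
  backs <- unlist(lapply(t@edgeLabels, function(el)
    el$label[el$back]))
  expect_equal(backs, "1000")
})
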