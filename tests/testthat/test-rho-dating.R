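test_that("rho is the mean root-to-leaf mutation count", {
  # all leaves identical to the root
  t0 <- buildMPTree(list(profileFrom("a"), profileFrom("b")),
                    emptyRootProfile())
  expect_equal(computeRho(t0), 0)

  # leaves at path distances 1, 2, 3 -> rho = 2
  ps <- list(profileFrom("a", "1000"),
             profileFrom("b", c("1000", "2000")),
             profileFrom("c", c("1000", "2000", "3000")))
  t <- buildMPTree(ps, emptyRootProfile())
  expect_equal(computeRho(t), 2)

  # invariant under leaf relabelling
  ps2 <- list(profileFrom("c", "1000"),
              profileFrom("a", c("1000", "2000")),
              profileFrom("b", c("1000", "2000", "3000")))
  expect_equal(computeRho(buildMPTree(ps2, emptyRootProfile())), 2)
})

test_that("sigma follows the branch-structure estimator", {
  # star, n = 4, one private mutation each: sigma = sqrt(4/16) = 0.5
  ps <- lapply(1:4, function(i)
    profileFrom(paste0("s", i), as.character(1000 * i)))
  t <- buildMPTree(ps, emptyRootProfile())
  expect_equal(computeSigma(t), 0.5)

  # a single leaf with 4 mutations: sigma = sqrt(4) = 2
  t1 <- buildMPTree(list(profileFrom("m", c("100", "200", "300", "400"))),
                    emptyRootProfile())
  expect_equal(computeSigma(t1), 2)

  # zero-mutation tree
  t0 <- buildMPTree(list(profileFrom("a"), profileFrom("b")),
                    emptyRootProfile())
  expect_equal(computeSigma(t0), 0)
})

test_that("rho and sigma match independent igraph oracles", {
  skip_if_not_installed("igraph")
  set.seed(71)
  for (i in 1:100) {
    nH <- sample(2:8, 1)
    sites <- sample(seq(100, 16500, by = 17), 12)
    ps <- randomProfiles(nH, sites)
    t <- buildMPTree(ps, emptyRootProfile())
    expect_equal(computeRho(t), igraphRho(t), tolerance = 1e-12)
    expect_equal(computeSigma(t), igraphSigma(t), tolerance = 1e-12)
  }
})

test_that("clock conversion is linear with untruncated 95% CIs", {
  e1 <- estimateAge(1, 0, clock("complete"))
  expect_equal(ageKya(e1)[["age"]], 3.624)
  e2 <- estimateAge(1, 0, clock("coding"))
  expect_equal(ageKya(e2)[["age"]], 4.61)

  # small rho, large sigma: negative lower bound survives
  e3 <- estimateAge(0.1, 0.2, clock("complete"))
  expect_lt(e3@ciLowYears, 0)
  expect_equal(e3@ciLowYears, (0.1 - 1.96 * 0.2) * 3624)

  # CI width is exactly 2 * 1.96 * sigma * rate
  expect_equal(e3@ciHighYears - e3@ciLowYears, 2 * 1.96 * 0.2 * 3624)

  expect_error(clock("complete", yearsPerSubstitution = -1), "positive")
  expect_error(estimateAge(-0.1, 0, clock("complete")), ">= 0")
})

test_that("doubling every distance doubles rho and age", {
  ps <- list(profileFrom("a", "1000"),
             profileFrom("b", c("2000", "3000")))
  t <- buildMPTree(ps, emptyRootProfile())
  ps2 <- list(profileFrom("a", c("1000", "1500")),
              profileFrom("b", c("2000", "3000", "4000", "5000")))
  t2 <- buildMPTree(ps2, emptyRootProfile())
  expect_equal(computeRho(t2), 2 * computeRho(t))
  e <- estimateAge(computeRho(t), computeSigma(t), clock("complete"))
  e2 <- estimateAge(computeRho(t2), computeSigma(t2), clock("complete"))
  expect_equal(e2@ageYears, 2 * e@ageYears)
})

test_that("rho equals the direct mean profile distance on exact trees", {
  set.seed(73)
  for (i in 1:20) {
    sites <- sample(seq(100, 16500, by = 19), 10)
    ps <- randomProfiles(sample(2:6, 1), sites)
    t <- buildMPTree(ps, emptyRootProfile())
    direct <- mean(vapply(ps, function(p)
      length(variantLabels(p)), 0))
    # with an empty root, the path count can only exceed the set
    # difference if recurrent events were forced; on exact trees rho is
    # never below the direct distance
    expect_gte(computeRho(t) + 1e-12, direct)
    if (treeLength(t) == length(unique(unlist(lapply(ps,
                                                     variantLabels)))))
      expect_equal(computeRho(t), direct)
  }
})

test_that("subclades are dated under both clocks with coding <= complete rho", {
  motifs <- motifFixture()
  h8b1 <- mitorho:::cumulativeMotif(motifs, "H8b1")
  ps <- list(
    profileFrom("y1", c(h8b1, "14869"), region = "Siberia"),
    profileFrom("y2", c(h8b1, "14869", "16111"), region = "Siberia"),
    profileFrom("y3", c(h8b1, "3736"), region = "Siberia"),
    profileFrom("y4", c(h8b1, "3736", "4100"), region = "Siberia"))
  t <- buildMPTree(ps, emptyRootProfile())
  d <- dateAllSubclades(t, motifs)
  expect_true(all(c("H8b1", "H8b1a", "H8b1b") %in% d$clade))
  expect_setequal(unique(d$clock), c("complete", "coding"))
  wide <- reshape(d[, c("clade", "clock", "rho")], idvar = "clade",
                  timevar = "clock", direction = "wide")
  expect_true(all(wide$rho.coding <= wide$rho.complete + 1e-12))

  # H8b1a: two leaves, one extra coding mutation between them
  h8b1a <- d[d$clade == "H8b1a" & d$clock == "complete", ]
  expect_equal(h8b1a$n, 2L)
  # y1 sits on the H8b1a founder, y2 one step below: rho = 0.5
  expect_equal(h8b1a$rho, 0.5)
  expect_equal(h8b1a$age_kya, 0.5 * 3.624)

  # a clade of one leaf identical to its founder dates to 0
  single <- dateAllSubclades(
    buildMPTree(list(profileFrom("z", h8b1, region = "Siberia")),
                emptyRootProfile()), motifs)
  z <- single[single$clade == "H8b1", ]
  expect_equal(z$age_kya, c(0, 0))
})
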