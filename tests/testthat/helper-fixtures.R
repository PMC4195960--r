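# shared fixtures, built in code

REF <- syntheticReference()

# profile from labels (canonical parsing through the package surface)
profileFrom <- function(id, labels = character(), region = NA_character_,
                        mask = "complete") {
  v <- if (length(labels)) parseVariantLabel(labels, REF)
       else mitorho:::emptyVariants()
  haplotypeProfile(id, v, regionClass = region, mask = mask)
}

emptyRootProfile <- function() profileFrom("(root)")

motifFixture <- function() {
  readMotifTable(system.file("extdata", "motifs_siberian.tsv",
                             package = "mitorho"), REF)
}

# random transition-only profiles over a small site pool; used by the
# parsimony and rho oracles
randomProfiles <- function(n, sites, pMut = 0.4) {
  lapply(seq_len(n), function(i) {
    labs <- as.character(sites[stats::runif(length(sites)) < pMut])
    profileFrom(sprintf("s%02d", i), labs)
  })
}

# independent parsimony oracle: exact branch-and-bound from phangorn on
# the binary presence/absence matrix, with the ancestral haplotype
# included as an ordinary taxon
phangornSteinerLength <- function(profiles, rootProfile) {
  labs <- lapply(c(list(rootProfile), profiles), variantLabels)
  all <- sort(unique(unlist(labs)))
  if (!length(all)) return(0L)
  M <- t(vapply(labs, function(l) as.integer(all %in% l),
                integer(length(all))))
  rownames(M) <- paste0("t", seq_len(nrow(M)))
  dat <- phangorn::phyDat(M, type = "USER", levels = c(0L, 1L))
  trees <- phangorn::bab(dat, trace = 0)
  if (inherits(trees, "phylo")) trees <- list(trees)
  min(vapply(trees, function(tr)
    as.integer(phangorn::parsimony(tr, dat)), 0L))
}

# random rooted CladeTree with arbitrary edge-label sets (not an MP
# search product): topology from ape::rtree, per-edge labels drawn from
# a site pool with occasional reuse so back mutations occur
randomCladeTree <- function(nTipsMax = 10) {
  n <- sample(2:nTipsMax, 1)
  ph <- ape::rtree(n)
  edge <- ph$edge
  pool <- as.character(sample(seq(100, 16500), 40))
  states <- vector("list", max(edge))
  states[[n + 1L]] <- character()
  labs <- vector("list", nrow(edge))
  for (e in order(edge[, 1])) {       # parents before children
    parent <- edge[e, 1]; child <- edge[e, 2]
    k <- stats::rpois(1, 1.2)
    lab <- unique(sample(pool, k, replace = TRUE))
    st <- states[[parent]]
    for (l in lab) st <- if (l %in% st) setdiff(st, l) else c(st, l)
    states[[child]] <- st
    labs[[e]] <- data.frame(label = lab,
                            back = lab %in% states[[parent]] & !(lab %in% st),
                            stringsAsFactors = FALSE)
  }
  tips <- paste0("t", seq_len(n))
  profs <- lapply(seq_len(n), function(i)
    haplotypeProfile(tips[i], mitorho:::labelsToVariants(states[[i]])))
  names(profs) <- tips
  methods::new("CladeTree", edge = edge, nTips = as.integer(n),
               tipLabels = tips, nodeStates = states,
               edgeLabels = labs, rootVariants = character(),
               leafProfiles = profs, mask = "complete", exact = FALSE,
               nCoOptimal = NA_integer_)
}

# independent rho/sigma oracles via igraph path/descendant counting
igraphRho <- function(tree) {
  m <- vapply(tree@edgeLabels, nrow, 0L)
  g <- igraph::graph_from_edgelist(tree@edge, directed = FALSE)
  dd <- igraph::distances(g, v = mitorho:::rootNode(tree),
                          to = seq_len(tree@nTips), weights = m)
  mean(dd)
}

igraphSigma <- function(tree) {
  m <- vapply(tree@edgeLabels, nrow, 0L)
  n <- tree@nTips
  g <- igraph::graph_from_edgelist(tree@edge, directed = TRUE)
  s2 <- 0
  for (e in seq_len(nrow(tree@edge))) {
    child <- tree@edge[e, 2]
    desc <- igraph::subcomponent(g, child, mode = "out")
    ne <- sum(as.integer(desc) <= n)
    s2 <- s2 + m[e] * (ne / n)^2
  }
  sqrt(s2)
}
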