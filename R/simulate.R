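#' Simulation configuration
#'
#' Defaults emulate the published dating model: a Poisson molecular clock
#' at one substitution per 3624 years on the whole molecule, a strong
#' transition bias (95\%), and occasional hotspot indels (0.1 events per
#' lineage, placed inside the 303-315 / 16180-16193 excluded ranges).
#' Explicit reversions are off by default: the clock model is a plain
#' Poisson process, and recurrent/back mutations already arise naturally
#' when independent edges draw the same site.
#'
#' @param nLeaves number of sampled lineages
#' @param tmrcaYears true root age in years
#' @param yearsPerSubstitution clock calibration
#' @param transitionFraction probability a substitution is a transition
#' @param hotspotIndelRate expected hotspot indels per lineage
#' @param backMutationRate expected explicit reversions per lineage
#' @param treeShape "star" (all lineages coalesce at the root) or "yule"
#'   (random birth-process topology rescaled to the TMRCA)
#' @param regionClass region label(s) painted on the leaves (recycled)
#' @param seed RNG seed, required
#' @return a \linkS4class{SimulationConfig}
#' @export
simulationConfig <- function(nLeaves, tmrcaYears,
                             yearsPerSubstitution = 3624,
                             transitionFraction = 0.95,
                             hotspotIndelRate = 0.1,
                             backMutationRate = 0,
                             treeShape = c("star", "yule"),
                             regionClass = "Siberia", seed) {
  treeShape <- match.arg(treeShape)
  methods::new("SimulationConfig", nLeaves = as.integer(nLeaves),
               tmrcaYears = as.numeric(tmrcaYears),
               yearsPerSubstitution = yearsPerSubstitution,
               transitionFraction = transitionFraction,
               hotspotIndelRate = hotspotIndelRate,
               backMutationRate = backMutationRate,
               treeShape = treeShape, regionClass = regionClass,
               seed = as.integer(seed))
}

HOTSPOT_RANGES <- rbind(c(303L, 315L), c(16180L, 16193L))

#' Simulate a clade with known truth
#'
#' Draws a rooted tree of the requested shape with the root at the true
#' TMRCA; on each edge, substitution events are a Poisson process with
#' rate 1/yearsPerSubstitution per year, sites drawn uniformly without
#' replacement within the edge, transitions vs transversions per the
#' transition fraction.  Hotspot indels and explicit reversions are drawn
#' per lineage on the terminal edges.  Leaf sequences are emitted by
#' applying the accumulated per-lineage state to the reference; the truth
#' table records the true number of substitution events on each
#' root-to-leaf path.  The same seed and configuration always reproduce
#' the same clade; the global RNG state is left untouched.
#'
#' @param cfg a \linkS4class{SimulationConfig}
#' @param ref a \linkS4class{ReferenceGenome}
#' @return a \linkS4class{SimulatedClade}
#' @export
simulateClade <- function(cfg, ref = syntheticReference()) {
  withr::with_seed(cfg@seed, simulateCladeImpl(cfg, ref))
}

simulateCladeImpl <- function(cfg, ref) {
  n <- cfg@nLeaves
  # tree: node 0 = root, 1..n = tips, higher = internal
  if (cfg@treeShape == "star" || n == 1L) {
    edges <- data.frame(parent = rep(0L, n), child = seq_len(n),
                        length_years = cfg@tmrcaYears)
  } else {
    ph <- ape::rphylo(n, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(ph))
    scale <- if (depth > 0) cfg@tmrcaYears / depth else 0
    # renumber: ape root (n+1) -> 0, other internals keep ids
    par <- ifelse(ph$edge[, 1] == n + 1L, 0L, ph$edge[, 1])
    chd <- ifelse(ph$edge[, 2] == n + 1L, 0L, ph$edge[, 2])
    edges <- data.frame(parent = as.integer(par), child = as.integer(chd),
                        length_years = ph$edge.length * scale)
  }
  nSites <- refLength(ref)
  rseq <- refSequence(ref)
  refBase <- substring(rseq, seq_len(nSites), seq_len(nSites))

  kids <- split(seq_len(nrow(edges)), edges$parent)
  events <- vector("list", nrow(edges))
  leafState <- vector("list", n)   # per-leaf named base vector (derived)
  leafSubCount <- integer(n)

  drawEdge <- function(state, lenYears) {
    k <- stats::rpois(1, lenYears / cfg@yearsPerSubstitution)
    ev <- data.frame(position = integer(), kind = character(),
                     from = character(), to = character(),
                     stringsAsFactors = FALSE)
    if (k > 0) {
      pos <- sample.int(nSites, k)
      for (p in pos) {
        cur <- state[[as.character(p)]] %||% refBase[p]
        if (stats::runif(1) < cfg@transitionFraction) {
          to <- unname(transitionPartner(cur))
        } else {
          to <- sample(setdiff(setdiff(c("A", "C", "G", "T"), cur),
                               transitionPartner(cur)), 1)
        }
        state[[as.character(p)]] <- to
        ev <- rbind(ev, data.frame(position = p, kind = "substitution",
                                   from = cur, to = to,
                                   stringsAsFactors = FALSE))
      }
    }
    list(state = state, events = ev, k = k)
  }

  walk <- function(node, state, count) {
    for (e in kids[[as.character(node)]]) {
      res <- drawEdge(state, edges$length_years[e])
      child <- edges$child[e]
      isTerminal <- child >= 1L && child <= n
      ev <- res$events
      st <- res$state
      kSub <- res$k
      if (isTerminal) {
        # explicit reversions (per lineage)
        nBack <- stats::rpois(1, cfg@backMutationRate)
        derived <- names(st)[vapply(names(st), function(p)
          st[[p]] != refBase[as.integer(p)], TRUE)]
        nBack <- min(nBack, length(derived))
        if (nBack > 0) {
          for (p in sample(derived, nBack)) {
            cur <- st[[p]]
            st[[p]] <- refBase[as.integer(p)]
            ev <- rbind(ev, data.frame(position = as.integer(p),
                                       kind = "back_mutation",
                                       from = cur,
                                       to = refBase[as.integer(p)],
                                       stringsAsFactors = FALSE))
            kSub <- kSub + 1L
          }
        }
        # hotspot indels (per lineage)
        nIndel <- stats::rpois(1, cfg@hotspotIndelRate)
        if (nIndel > 0) {
          for (i in seq_len(nIndel)) {
            rg <- HOTSPOT_RANGES[sample.int(nrow(HOTSPOT_RANGES), 1), ]
            p <- sample(rg[1]:rg[2], 1)
            type <- sample(c("insertion", "deletion"), 1)
            ev <- rbind(ev, data.frame(position = p, kind = type,
                                       from = if (type == "deletion")
                                         refBase[p] else "",
                                       to = if (type == "insertion")
                                         refBase[p] else "",
                                       stringsAsFactors = FALSE))
          }
        }
        events[[e]] <<- ev
        leafState[[child]] <<- st
        leafSubCount[child] <<- count + kSub
      } else {
        events[[e]] <<- ev
        walk(child, st, count + kSub)
      }
    }
  }
  walk(0L, list(), 0L)

  regions <- rep_len(cfg@regionClass, n)
  sampleIds <- sprintf("sim%02d", seq_len(n))
  sequences <- vapply(seq_len(n), function(i) {
    st <- leafState[[i]]
    subs <- if (length(st))
      makeVariants(as.integer(names(st)),
                   ifelse(isTransitionPair(refBase[as.integer(names(st))],
                                           unlist(st)),
                          "transition", "transversion"),
                   refBase[as.integer(names(st))], unlist(st))
    else emptyVariants()
    subs <- subs[subs$ref != subs$alt, , drop = FALSE]
    # indel events from the terminal edge
    eIdx <- which(edges$child == i)
    ev <- events[[eIdx]]
    idl <- ev[ev$kind %in% c("insertion", "deletion"), , drop = FALSE]
    if (nrow(idl)) {
      indelVars <- makeVariants(
        idl$position, idl$kind,
        ifelse(idl$kind == "deletion", idl$from, ""),
        ifelse(idl$kind == "insertion", idl$to, ""),
        ifelse(idl$kind == "insertion", 1L, 0L))
      # a site both substituted and deleted: deletion wins
      subs <- subs[!(subs$position %in%
                       indelVars$position[indelVars$kind == "deletion"]), ,
                   drop = FALSE]
      subs <- rbind(subs, indelVars)
    }
    applyVariants(ref, subs)
  }, "")
  names(sequences) <- sampleIds

  truth <- data.frame(sample_id = sampleIds,
                      n_substitutions = leafSubCount,
                      region_class = regions, stringsAsFactors = FALSE)
  methods::new("SimulatedClade", config = cfg, treeEdge = edges,
               events = events, sequences = sequences, truth = truth,
               referenceName = ref@name)
}

setMethod("show", "SimulatedClade", function(object) {
  cat("SimulatedClade:", object@config@nLeaves, "leaves,",
      object@config@treeShape, "tree, TMRCA",
      object@config@tmrcaYears, "years\n")
  cat("  mean true substitutions per lineage:",
      mean(object@truth$n_substitutions), "\n")
})

#' Write a simulated clade as FASTA + metadata + truth tables
#'
#' @param clade a \linkS4class{SimulatedClade}
#' @param dir output directory
#' @param population population label written to the metadata
#' @return invisibly, the paths written
#' @export
writeSimulatedClade <- function(clade, dir, population = "simulated") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "samples.fasta")
  x <- Biostrings::DNAStringSet(clade@sequences)
  Biostrings::writeXStringSet(x, fa, width = 70L)
  meta <- data.frame(sample_id = clade@truth$sample_id,
                     population = population,
                     region_class = clade@truth$region_class,
                     source = "simulated", stringsAsFactors = FALSE)
  mt <- file.path(dir, "samples.tsv")
  utils::write.table(meta, mt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- file.path(dir, "truth.tsv")
  utils::write.table(clade@truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fa, mt, tr))
}

#' Age-recovery experiment over a grid of simulated clades
#'
#' For each (TMRCA, n) cell, simulates star clades under the complete
#' clock, runs the full pipeline (variant calling, exclusion filter,
#' maximum-parsimony tree, rho dating) and reports the mean age bias,
#' relative bias, RMSE and the fraction of replicates whose 95\% CI
#' covers the true TMRCA.
#'
#' @param tmrcaGrid true TMRCAs in years
#' @param nGrid numbers of leaves
#' @param replicates replicates per cell
#' @param seed master seed; per-replicate seeds are derived from it
#' @param ref reference genome
#' @param treeShape passed to the simulator
#' @param yearsPerSubstitution clock used both to simulate and to date
#' @return data.frame: tmrca_years, n_leaves, mean_age_years, bias_years,
#'   rel_bias, rmse_years, coverage
#' @export
recoveryExperiment <- function(tmrcaGrid = c(2000, 5000, 10000),
                               nGrid = c(5, 10, 20), replicates = 300,
                               seed, ref = syntheticReference(),
                               treeShape = "star",
                               yearsPerSubstitution = 3624) {
  cells <- expand.grid(tmrca = tmrcaGrid, n = nGrid)
  seeds <- withr::with_seed(seed, matrix(
    sample.int(2147483646L, nrow(cells) * replicates),
    nrow = nrow(cells)))
  cl <- clock("complete", yearsPerSubstitution = yearsPerSubstitution)
  policy <- exclusionPolicy()
  rootProf <- haplotypeProfile("(root)")
  out <- lapply(seq_len(nrow(cells)), function(ci) {
    ages <- numeric(replicates)
    cover <- logical(replicates)
    for (r in seq_len(replicates)) {
      cfg <- simulationConfig(cells$n[ci], cells$tmrca[ci],
                              yearsPerSubstitution = yearsPerSubstitution,
                              treeShape = treeShape,
                              seed = seeds[ci, r])
      sim <- simulateClade(cfg, ref)
      profs <- lapply(names(sim@sequences), function(id)
        applyExclusionFilter(
          callVariants(sim@sequences[[id]], ref, sampleId = id,
                       regionClass = "Siberia"), policy))
      tr <- buildMPTree(profs, rootProf)
      est <- estimateAge(computeRho(tr), computeSigma(tr), cl)
      ages[r] <- est@ageYears
      cover[r] <- est@ciLowYears <= cells$tmrca[ci] &&
        cells$tmrca[ci] <= est@ciHighYears
    }
    data.frame(tmrca_years = cells$tmrca[ci], n_leaves = cells$n[ci],
               mean_age_years = mean(ages),
               bias_years = mean(ages) - cells$tmrca[ci],
               rel_bias = (mean(ages) - cells$tmrca[ci]) / cells$tmrca[ci],
               rmse_years = sqrt(mean((ages - cells$tmrca[ci])^2)),
               coverage = mean(cover))
  })
  do.call(rbind, out)
}
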