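#' Build a rooted maximum-parsimony tree of haplotype profiles
#'
#' Treats every variant label as a binary presence/absence character and
#' searches for a minimum-length Steiner tree connecting the observed
#' haplotypes and the designated ancestral haplotype.  Up to
#' \code{exactCap} distinct haplotypes the search is an exact
#' branch-and-bound over binary topologies (internal states optimised by
#' Fitch counting); beyond that a greedy stepwise-addition search with
#' nearest-neighbour-interchange rearrangement is used and the result is
#' flagged heuristic.  Identical sampled haplotypes are kept as separate
#' leaves attached at the same point.  Ties between co-optimal trees are
#' broken deterministically (canonical form with children ordered by
#' smallest descendant sample id).
#'
#' @param profiles list of \linkS4class{HaplotypeProfile}, all filtered
#'   with the same policy and mask
#' @param rootProfile \linkS4class{HaplotypeProfile} of the clade founder
#'   haplotype (often the reference itself, i.e. an empty variant set)
#' @param exactCap maximum number of distinct haplotypes for the exact
#'   search
#' @param maxStore maximum number of co-optimal binary topologies kept for
#'   canonicalisation; if more exist, \code{nCoOptimal} is reported as NA
#' @return a \linkS4class{CladeTree}
#' @examples
#' ref <- syntheticReference()
#' ps <- list(
#'   haplotypeProfile("a", parseVariantLabel("8473", ref)),
#'   haplotypeProfile("b", parseVariantLabel(c("8473", "12308"), ref)))
#' t <- buildMPTree(ps, haplotypeProfile("root"))
#' treeLength(t)
#' @export
buildMPTree <- function(profiles, rootProfile, exactCap = 12L,
                        maxStore = 256L) {
  if (methods::is(profiles, "HaplotypeProfile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("at least one profile required")
  masks <- vapply(profiles, maskName, "")
  if (length(unique(masks)) != 1L || masks[1] != maskName(rootProfile))
    stop("profiles filtered inconsistently: masks differ")
  ids <- vapply(profiles, sampleId, "")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  names(profiles) <- ids

  rootLabels <- variantLabels(rootProfile)
  leafLabels <- lapply(profiles, variantLabels)
  keys <- vapply(leafLabels, function(x)
    paste(sort(x), collapse = " "), "")
  haploKeys <- sort(unique(keys))
  haploLabels <- lapply(haploKeys, function(k)
    if (nzchar(k)) strsplit(k, " ")[[1]] else character())
  H <- length(haploKeys)

  taxaSets <- c(list(sort(rootLabels)), haploLabels)
  allLabels <- sort(unique(unlist(taxaSets)))
  pres <- matrix(FALSE, nrow = length(allLabels),
                 ncol = length(taxaSets))           # labels x taxa
  for (j in seq_along(taxaSets)) pres[, j] <- allLabels %in% taxaSets[[j]]
  varying <- rowSums(pres) > 0 & rowSums(pres) < ncol(pres)
  chars <- allLabels[varying]
  X <- t(pres[varying, , drop = FALSE])            # taxa x chars
  storage.mode(X) <- "integer"

  T <- H + 1L
  exact <- T <= (exactCap + 1L)
  if (T <= 3L) {
    # topology unique: star on the (at most 3) taxa
    topo <- if (T == 2L) cbind(0L, 1L) else rbind(c(0L, 3L), c(1L, 3L),
                                                  c(2L, 3L))
    topos <- list(topo)
    nOpt <- 1
    exact <- TRUE
  } else {
    # pattern-collapse identical character columns for the search
    pat <- apply(X, 2, paste, collapse = "")
    upat <- unique(pat)
    w <- as.integer(table(factor(pat, levels = upat)))
    Xp <- X[, match(upat, pat), drop = FALSE]
    if (ncol(Xp) == 0L) {
      Xp <- matrix(0L, nrow = T, ncol = 1L)
      w <- 0L
    }
    if (exact) {
      # provable shortcut: every varying character needs at least one
      # change, so a greedy tree whose length hits sum(w) is optimal
      # (typical for star-like clades where all mutations are private)
      g <- .cpp_mp_greedy(Xp, w)
      if (g$length == sum(w)) {
        topos <- list(g$tree)
        nOpt <- NA_real_
      } else {
        res <- .cpp_mp_exact(Xp, w, as.integer(maxStore), 5e6)
        if (isTRUE(res$aborted)) {
          # co-optimal plateau too large to enumerate: keep the best tree
          # seen (incumbent if any, else greedy) and flag heuristic
          topos <- if (length(res$trees) && res$length <= g$length)
            res$trees[1] else list(g$tree)
          nOpt <- NA_real_
          exact <- FALSE
        } else {
          topos <- res$trees
          nOpt <- res$n_optimal
        }
      }
    } else {
      res <- .cpp_mp_greedy(Xp, w)
      topos <- list(res$tree)
      nOpt <- NA_real_
    }
  }

  sampleOf <- split(ids, factor(keys, levels = haploKeys))
  cands <- lapply(topos, function(tp)
    assembleCladeTree(tp, T, chars, X, rootLabels, profiles, sampleOf,
                      masks[1]))
  hashes <- vapply(cands, treeHash, "")
  uniq <- !duplicated(hashes)
  tree <- cands[uniq][[order(hashes[uniq])[1]]]
  nDistinct <- sum(uniq)
  nCo <- if (is.na(nOpt)) NA_integer_
         else if (nOpt > length(topos)) NA_integer_
         else as.integer(nDistinct)
  tree@exact <- exact
  tree@nCoOptimal <- nCo
  methods::validObject(tree)
  tree
}

# Turn an unrooted binary topology (0-based: taxa 0..T-1, internals T..)
# into a rooted, collapsed CladeTree.  Taxon 0 is the root haplotype.
assembleCladeTree <- function(topo, T, chars, X, rootLabels, profiles,
                              sampleOf, mask) {
  nE <- nrow(topo)
  nodes <- sort(unique(as.vector(topo)))
  adj <- lapply(seq_len(max(nodes) + 1L), function(i) integer())
  for (e in seq_len(nE)) {
    u <- topo[e, 1] + 1L; v <- topo[e, 2] + 1L
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  nNodes <- max(nodes) + 1L
  S <- length(chars)

  # Fitch bottom-up sets, rooted at node 1 (taxon 0)
  sets <- matrix(0L, nrow = nNodes, ncol = S)   # 1={0},2={1},3={0,1}
  order <- integer(); parent <- rep(NA_integer_, nNodes)
  stack <- 1L
  seen <- rep(FALSE, nNodes); seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; parent[w] <- v; stack <- c(stack, w)
    }
  }
  for (v in rev(order)) {
    if (v <= T) {
      sets[v, ] <- bitwShiftL(1L, X[v, ])
    } else {
      kids <- setdiff(adj[[v]], parent[v])
      s <- sets[kids[1], ]
      for (k in kids[-1]) {
        inter <- bitwAnd(s, sets[k, ])
        s <- ifelse(inter > 0L, inter, bitwOr(s, sets[k, ]))
      }
      sets[v, ] <- s
    }
  }
  # top-down states: root taxon keeps its own state; children prefer the
  # parent's state when their Fitch set allows (deterministic, minimal)
  state <- matrix(0L, nrow = nNodes, ncol = S)
  for (v in order) {
    if (v == 1L) {
      state[v, ] <- X[1, ]
    } else if (v <= T) {
      state[v, ] <- X[v, ]
    } else {
      ps <- state[parent[v], ]
      inSet <- bitwAnd(sets[v, ], bitwShiftL(1L, ps)) > 0L
      state[v, ] <- ifelse(inSet, ps, ifelse(sets[v, ] == 2L, 1L, 0L))
    }
  }

  constant <- setdiff(rootLabels, chars)   # labels shared by all taxa
  stateSet <- function(v) sort(c(constant, chars[state[v, ] == 1L]))

  # build a mutable rooted node list, then collapse
  nodesEnv <- new.env()
  nodesEnv$n <- 0L
  newNode <- function(labels, tip = NA_character_) {
    nodesEnv$n <- nodesEnv$n + 1L
    list(id = nodesEnv$n, labels = labels, tip = tip, children = list())
  }
  build <- function(v) {
    nd <- newNode(stateSet(v),
                  tip = if (v > 1L && v <= T) as.character(v) else
                    NA_character_)
    kids <- setdiff(adj[[v]], parent[v])
    nd$children <- lapply(kids, build)
    nd
  }
  root <- build(1L)
  root$tip <- NA_character_

  # collapse child into parent when the edge carries no change and the
  # child is internal (or is a haplotype placeholder equal to its parent)
  collapse <- function(nd) {
    nd$children <- lapply(nd$children, collapse)
    out <- list()
    for (ch in nd$children) {
      if (setequal(ch$labels, nd$labels) &&
          (is.na(ch$tip) || length(ch$children) == 0L)) {
        if (!is.na(ch$tip)) {
          # haplotype equal to parent state: move its samples up
          nd$samples <- c(nd$samples, ch$tip)
        }
        nd$samples <- c(nd$samples, ch$samples)
        out <- c(out, ch$children)
      } else {
        out <- c(out, list(ch))
      }
    }
    nd$children <- out
    nd
  }
  root <- collapse(root)

  # expand haplotype placeholders into sample leaves; the root always
  # stays an internal node so the founder haplotype remains the root
  expand <- function(nd, isRoot = FALSE) {
    taxa <- c(nd$samples, nd$tip[!is.na(nd$tip)])
    nd$samples <- NULL; nd$tip <- NA_character_
    samples <- sort(unlist(lapply(taxa, function(tx)
      sampleOf[[as.integer(tx) - 1L]])))
    nd$children <- lapply(nd$children, expand)
    if (length(samples)) {
      if (!isRoot && length(nd$children) == 0L && length(samples) == 1L) {
        nd$tip <- samples
      } else {
        leaves <- lapply(samples, function(s) newNode(nd$labels, tip = s))
        nd$children <- c(nd$children, leaves)
      }
    }
    nd
  }
  root <- expand(root, isRoot = TRUE)

  # suppress unary internal chains below the root (can arise after
  # collapsing)
  suppress <- function(nd) {
    nd$children <- lapply(nd$children, suppress)
    while (length(nd$children) == 1L && is.na(nd$tip) &&
           setequal(nd$children[[1]]$labels, nd$labels)) {
      only <- nd$children[[1]]
      nd$tip <- only$tip
      nd$children <- only$children
    }
    nd
  }
  root$children <- lapply(root$children, suppress)

  # canonical child order: by smallest sample id in the subtree
  minTip <- function(nd) {
    if (!is.na(nd$tip)) return(nd$tip)
    min(vapply(nd$children, minTip, ""))
  }
  canon <- function(nd) {
    nd$children <- lapply(nd$children, canon)
    if (length(nd$children))
      nd$children <- nd$children[order(vapply(nd$children, minTip, ""))]
    nd
  }
  root <- canon(root)

  # number nodes ape-style and emit slots
  tipLabs <- character(); tipStates <- list()
  collectTips <- function(nd) {
    if (!is.na(nd$tip)) {
      tipLabs <<- c(tipLabs, nd$tip)
      tipStates[[length(tipLabs)]] <<- nd$labels
    }
    lapply(nd$children, collectTips)
    invisible(NULL)
  }
  collectTips(root)
  n <- length(tipLabs)
  edges <- matrix(integer(), ncol = 2)
  edgeLabs <- list(); nodeStates <- vector("list", n)
  for (i in seq_len(n)) nodeStates[[i]] <- tipStates[[i]]
  nextInternal <- n + 1L
  assign <- function(nd) {
    if (!is.na(nd$tip) && length(nd$children) == 0L)
      return(match(nd$tip, tipLabs))
    id <- nextInternal
    nextInternal <<- nextInternal + 1L
    nodeStates[[id]] <<- nd$labels
    kids <- nd$children
    if (!is.na(nd$tip)) stop("internal node with tip sample")  # safeguard
    for (ch in kids) {
      cid <- assign(ch)
      edges <<- rbind(edges, c(id, cid))
      gained <- setdiff(nodeStates[[cid]], nd$labels)
      lost <- setdiff(nd$labels, nodeStates[[cid]])
      lab <- c(gained, lost)
      edgeLabs[[nrow(edges)]] <<- data.frame(
        label = lab,
        back = c(rep(FALSE, length(gained)), rep(TRUE, length(lost))),
        stringsAsFactors = FALSE)
    }
    id
  }
  assign(root)

  methods::new("CladeTree", edge = edges, nTips = n, tipLabels = tipLabs,
               nodeStates = nodeStates, edgeLabels = edgeLabs,
               rootVariants = sort(rootLabels),
               leafProfiles = profiles[tipLabs], mask = mask,
               exact = FALSE, nCoOptimal = NA_integer_)
}

# order-independent fingerprint of a rooted labelled tree
treeHash <- function(tree) {
  kids <- split(seq_len(nrow(tree@edge)), tree@edge[, 1])
  rec <- function(node) {
    if (node <= tree@nTips) return(tree@tipLabels[node])
    ks <- kids[[as.character(node)]]
    sub <- sort(vapply(ks, function(e) {
      el <- tree@edgeLabels[[e]]
      paste0(paste(sort(paste0(el$label, ifelse(el$back, "!", ""))),
                   collapse = ","),
             "|", rec(tree@edge[e, 2]))
    }, ""))
    paste0("(", paste(sub, collapse = ";"), ")")
  }
  rec(rootNode(tree))
}

#' @describeIn buildMPTree number of leaves
#' @param x a CladeTree
#' @export
setMethod("nTips", "CladeTree", function(x) x@nTips)

#' @describeIn buildMPTree leaf sample ids
#' @export
setMethod("tipLabels", "CladeTree", function(x) x@tipLabels)

#' @rdname treeLength
#' @export
setMethod("treeLength", "CladeTree", function(x)
  sum(vapply(x@edgeLabels, nrow, 0L)))

setMethod("show", "CladeTree", function(object) {
  cat("CladeTree:", object@nTips, "leaves, length",
      treeLength(object), "\n")
  cat("  mask:", object@mask,
      "| search:", if (object@exact) "exact" else "heuristic",
      "| co-optimal trees:", object@nCoOptimal, "\n")
  cat("  root haplotype:",
      if (length(object@rootVariants))
        paste(object@rootVariants, collapse = " ") else "(reference)",
      "\n")
})

#' Convert a CladeTree to an ape phylo object
#'
#' Edge lengths are mutation counts; useful for plotting and Newick
#' round trips through ape.
#'
#' @param tree a \linkS4class{CladeTree}
#' @return an \code{ape::phylo}
#' @export
asPhylo <- function(tree) {
  nNode <- max(tree@edge) - tree@nTips
  # handle a root-only degenerate tree
  if (nrow(tree@edge) == 0L) stop("tree has no edges")
  ph <- list(edge = tree@edge, tip.label = tree@tipLabels,
             Nnode = nNode,
             edge.length = vapply(tree@edgeLabels, nrow, 0L))
  class(ph) <- "phylo"
  attr(ph, "order") <- NULL
  ph
}

#' Find maximal region-specific subclades
#'
#' Returns the maximal subtrees (including single leaves) all of whose
#' leaves carry a region class in \code{targetRegions}; no returned
#' subclade is nested inside another.
#'
#' @param tree a \linkS4class{CladeTree} whose leaf profiles carry region
#'   classes
#' @param targetRegions character vector of target region labels
#'   (default "Siberia")
#' @return list with \code{clades} (data.frame: node, n_leaves, leaves)
#'   and \code{totalLeaves}, the number of leaves covered
#' @export
findRegionSpecificClades <- function(tree, targetRegions = "Siberia") {
  regions <- vapply(tree@leafProfiles[tree@tipLabels], regionClass, "")
  if (anyNA(regions))
    stop("missing region_class on leaves: ",
         paste(tree@tipLabels[is.na(regions)], collapse = ", "))
  nNode <- max(tree@edge)
  inTarget <- rep(NA, nNode)
  inTarget[seq_len(tree@nTips)] <- regions %in% targetRegions
  kids <- split(tree@edge[, 2], tree@edge[, 1])
  post <- function(v) {
    ks <- kids[[as.character(v)]]
    if (!is.null(ks)) {
      for (k in ks) post(k)
      inTarget[v] <<- all(inTarget[ks])
    }
    invisible(NULL)
  }
  root <- rootNode(tree)
  post(root)
  p <- parentVector(tree)
  qual <- which(inTarget)
  maximal <- qual[vapply(qual, function(v)
    is.na(p[v]) || !inTarget[p[v]], TRUE)]
  rows <- lapply(maximal, function(v) {
    tp <- tipsUnder(tree, v)
    data.frame(node = v, n_leaves = length(tp),
               leaves = paste(sort(tree@tipLabels[tp]), collapse = " "),
               stringsAsFactors = FALSE)
  })
  clades <- do.call(rbind, c(list(data.frame(node = integer(),
                                             n_leaves = integer(),
                                             leaves = character(),
                                             stringsAsFactors = FALSE)),
                             rows))
  list(clades = clades, totalLeaves = sum(clades$n_leaves))
}
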