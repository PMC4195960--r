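#' Molecular clocks for rho dating
#'
#' Published whole-genome and coding-region calibrations: one substitution
#' per 3624 years on the complete mitogenome, one per 4610 years on the
#' coding region (nps 577-16023).  The coding clock must only be applied
#' to coding-masked trees/profiles.
#'
#' @param name "complete" or "coding"
#' @param yearsPerSubstitution override the calibration
#' @return a \linkS4class{Clock}
#' @export
clock <- function(name = c("complete", "coding"),
                  yearsPerSubstitution = NULL) {
  name <- match.arg(name)
  yps <- yearsPerSubstitution %||%
    switch(name, complete = 3624, coding = 4610)
  methods::new("Clock", name = name, yearsPerSubstitution = yps)
}

setMethod("show", "Clock", function(object) {
  cat(sprintf("Clock '%s': 1 substitution / %g years\n", object@name,
              object@yearsPerSubstitution))
})

#' Rho statistic and its standard error on a rooted clade tree
#'
#' \code{computeRho} is the mean number of mutations on the root-to-leaf
#' paths (the average divergence of the sampled lineages from the
#' ancestral haplotype); identical haplotypes sampled more than once each
#' count as a leaf.  \code{computeSigma} is the branch-structure standard
#' error: sigma^2 = sum over edges of m_e (n_e / n)^2, with m_e the
#' mutations on the edge and n_e the leaves descending through it.
#'
#' @param tree a \linkS4class{CladeTree}
#' @param node optional internal node: compute on the subclade rooted
#'   there (mutations counted from that node's haplotype)
#' @return numeric scalar
#' @name rhoDating
#' @examples
#' ref <- syntheticReference()
#' ps <- lapply(1:4, function(i)
#'   haplotypeProfile(paste0("s", i),
#'                    parseVariantLabel(as.character(1000 * i), ref)))
#' t <- buildMPTree(ps, haplotypeProfile("root"))
#' computeRho(t)    # 1: every leaf is one step from the root
#' computeSigma(t)  # sqrt(4 * (1/4)^2) = 0.5
NULL

#' @rdname rhoDating
#' @export
setMethod("computeRho", "CladeTree", function(tree, node = NULL) {
  node <- node %||% rootNode(tree)
  tips <- tipsUnder(tree, node)
  if (!length(tips)) stop("node has no descendant leaves")
  below <- edgesUnder(tree, node)
  m <- vapply(tree@edgeLabels, nrow, 0L)
  counts <- vapply(tips, function(tp)
    sum(m[intersect(pathEdges(tree, tp), below)]), 0)
  mean(counts)
})

#' @rdname rhoDating
#' @export
setMethod("computeSigma", "CladeTree", function(tree, node = NULL) {
  node <- node %||% rootNode(tree)
  tips <- tipsUnder(tree, node)
  n <- length(tips)
  below <- edgesUnder(tree, node)
  m <- vapply(tree@edgeLabels, nrow, 0L)
  ne <- vapply(below, function(e)
    length(intersect(tipsUnder(tree, tree@edge[e, 2]), tips)), 0L)
  sqrt(sum(m[below] * (ne / n)^2))
})

# indices of edges wholly inside the subtree rooted at node
edgesUnder <- function(tree, node) {
  if (node <= tree@nTips) return(integer())
  kids <- which(tree@edge[, 1] == node)
  unlist(c(list(kids), lapply(kids, function(e)
    edgesUnder(tree, tree@edge[e, 2]))))
}

#' Convert rho and sigma to a clade age under a clock
#'
#' Linear conversion: age = rho x years-per-substitution; the 95\% CI is
#' (rho +/- 1.96 sigma) times the rate, with the lower bound deliberately
#' not truncated at zero (small clades can print negative lower bounds).
#'
#' @param rho mean substitutions from the ancestral haplotype
#' @param sigma standard error of rho
#' @param clockObj a \linkS4class{Clock}
#' @param clade clade name for reporting
#' @param n number of mtDNAs
#' @return a \linkS4class{RhoEstimate}
#' @examples
#' estimateAge(1, 0, clock("complete"))   # 3.624 kya
#' estimateAge(1, 0, clock("coding"))     # 4.61 kya
#' @export
estimateAge <- function(rho, sigma, clockObj = clock("complete"),
                        clade = NA_character_, n = NA_integer_) {
  if (rho < 0 || sigma < 0) stop("rho and sigma must be >= 0")
  rate <- clockObj@yearsPerSubstitution
  methods::new("RhoEstimate", clade = clade, n = as.integer(n),
               rho = rho, sigma = sigma, clock = clockObj,
               ageYears = rho * rate,
               ciLowYears = (rho - 1.96 * sigma) * rate,
               ciHighYears = (rho + 1.96 * sigma) * rate)
}

#' @describeIn estimateAge age and CI in kya (thousands of years),
#'   full precision
#' @param x a RhoEstimate
#' @export
ageKya <- function(x) {
  c(age = x@ageYears, ci_low = x@ciLowYears,
    ci_high = x@ciHighYears) / 1000
}

setMethod("show", "RhoEstimate", function(object) {
  k <- ageKya(object)
  cat(sprintf(
    "RhoEstimate %s [%s clock]: n=%d rho=%.3f sigma=%.3f -> %.2f kya (%.2f; %.2f)\n",
    ifelse(is.na(object@clade), "", object@clade), object@clock@name,
    object@n, object@rho, object@sigma, k[1], k[2], k[3]))
})

#' Date every named subclade of a tree under both clocks
#'
#' For each haplogroup in the motif table that has member leaves (leaves
#' called to it or to any of its descendants), the clade node is the MRCA
#' of those leaves; rho/sigma are computed over the full subtree at that
#' node.  Complete-clock estimates come from the given tree; coding-clock
#' estimates are computed on a re-projection of the same data: the tree
#' rebuilt from coding-restricted profiles.
#'
#' @param tree a \linkS4class{CladeTree} built from complete-mask profiles
#' @param motifs a \linkS4class{MotifTable}
#' @param clocks list of \linkS4class{Clock} objects
#' @param calls optional precomputed haplogroup calls
#'   (\code{\link{assignHaplogroups}})
#' @param exactCap passed to the coding-tree rebuild
#' @return data.frame: clade, n, clock, rho, sigma, age_kya, ci_low_kya,
#'   ci_high_kya (full precision; the report writer rounds to 2 decimals)
#' @export
dateAllSubclades <- function(tree, motifs,
                             clocks = list(clock("complete"),
                                           clock("coding")),
                             calls = NULL, exactCap = 12L) {
  calls <- calls %||% assignHaplogroups(tree, motifs)
  wantCoding <- any(vapply(clocks, function(cl) cl@name == "coding", TRUE))
  codingTree <- NULL
  if (wantCoding) {
    mask <- regionMask("coding")
    profs <- lapply(tree@leafProfiles[tree@tipLabels], restrictRegion,
                    mask = mask)
    rootProf <- restrictRegion(
      haplotypeProfile("(root)", labelsToVariants(tree@rootVariants),
                       mask = tree@mask), mask)
    codingTree <- buildMPTree(profs, rootProf, exactCap = exactCap)
  }
  rows <- list()
  for (h in motifs@table$haplogroup) {
    members <- calls$sample_id[calls$haplogroup %in%
                                 motifDescendants(motifs, h)]
    if (!length(members)) next
    for (cl in clocks) {
      tr <- if (cl@name == "coding") codingTree else tree
      tips <- match(members, tr@tipLabels)
      node <- mrcaNode(tr, tips)
      n <- length(tipsUnder(tr, node))
      rho <- computeRho(tr, node)
      sigma <- computeSigma(tr, node)
      est <- estimateAge(rho, sigma, cl, clade = h, n = n)
      k <- ageKya(est)
      rows[[length(rows) + 1L]] <- data.frame(
        clade = h, n = n, clock = cl@name, rho = rho, sigma = sigma,
        age_kya = k[["age"]], ci_low_kya = k[["ci_low"]],
        ci_high_kya = k[["ci_high"]], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(clade = character(), n = integer(),
                      clock = character(), rho = numeric(),
                      sigma = numeric(), age_kya = numeric(),
                      ci_low_kya = numeric(), ci_high_kya = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$clade, out$clock), ]
}

# rebuild a variant data.frame from canonical labels without needing the
# reference (kinds and bases are encoded in the labels for indels and
# transversions; bare transitions keep empty base fields)
labelsToVariants <- function(labels) {
  if (!length(labels)) return(emptyVariants())
  rows <- lapply(labels, function(lab) {
    if (grepl("^[0-9]+$", lab)) {
      data.frame(position = as.integer(lab), kind = "transition",
                 ref = "", alt = "", insert_index = 0L, label = lab,
                 stringsAsFactors = FALSE)
    } else if (grepl("^[0-9]+[ACGT]$", lab)) {
      data.frame(position = as.integer(sub("[ACGT]$", "", lab)),
                 kind = "transversion", ref = "",
                 alt = substr(lab, nchar(lab), nchar(lab)),
                 insert_index = 0L, label = lab, stringsAsFactors = FALSE)
    } else if (grepl("^[0-9]+\\.[0-9]+[ACGT]$", lab)) {
      m <- regmatches(lab,
                      regexec("^([0-9]+)\\.([0-9]+)([ACGT])$", lab))[[1]]
      data.frame(position = as.integer(m[2]), kind = "insertion",
                 ref = "", alt = m[4],
                 insert_index = as.integer(m[3]), label = lab,
                 stringsAsFactors = FALSE)
    } else if (grepl("^[0-9]+d$", lab)) {
      data.frame(position = as.integer(sub("d$", "", lab)),
                 kind = "deletion", ref = "", alt = "",
                 insert_index = 0L, label = lab, stringsAsFactors = FALSE)
    } else stop("unrecognised canonical label: ", lab)
  })
  sortVariants(do.call(rbind, rows))
}
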