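#' @import methods
NULL

#' Reference genome in rCRS coordinates
#'
#' A single circular human mitochondrial genome treated as a linear
#' 1..16,569 sequence; all variant positions are 1-based coordinates on
#' this sequence.
#'
#' @slot name record name
#' @slot sequence upper-case DNA string (A, C, G, T, N only)
#' @slot length sequence length in nucleotide positions
#' @exportClass ReferenceGenome
setClass("ReferenceGenome",
         representation(name = "character", sequence = "character",
                        length = "integer"))

setValidity("ReferenceGenome", function(object) {
  if (length(object@sequence) != 1L) return("sequence must be a single string")
  if (nchar(object@sequence) != object@length)
    return("length slot disagrees with sequence")
  if (grepl("[^ACGTN]", object@sequence))
    return("sequence contains characters other than A,C,G,T,N")
  TRUE
})

#' A sample's variant profile
#'
#' The set of scored differences of one mitogenome from the reference,
#' plus sample metadata.  Variants live in a data.frame with columns
#' \code{position}, \code{kind} (transition/transversion/insertion/
#' deletion), \code{ref}, \code{alt}, \code{insert_index} and the
#' canonical \code{label}.
#'
#' @slot sampleId sample identifier
#' @slot population population name
#' @slot regionClass geographic region label (e.g. "Siberia")
#' @slot variants variant data.frame (see above)
#' @slot mask region mask applied: "complete" or "coding"
#' @exportClass HaplotypeProfile
setClass("HaplotypeProfile",
         representation(sampleId = "character", population = "character",
                        regionClass = "character", variants = "data.frame",
                        mask = "character"))

setValidity("HaplotypeProfile", function(object) {
  v <- object@variants
  need <- c("position", "kind", "ref", "alt", "insert_index", "label")
  if (!all(need %in% names(v))) return("variants lacks required columns")
  key <- paste(v$position, v$kind, v$insert_index)
  if (anyDuplicated(key)) return("duplicated (position, kind, insert_index)")
  if (!object@mask %in% c("complete", "coding"))
    return("mask must be 'complete' or 'coding'")
  TRUE
})

#' Site exclusion policy
#'
#' Sites removed before phylogenetic analysis: a set of positions excluded
#' outright, and ranges in which only point indels and transversions are
#' excluded (transitions there are kept).
#'
#' @slot excludedPoints positions removed regardless of variant kind
#' @slot conditionalRanges two-column matrix of inclusive ranges in which
#'   only insertions, deletions and transversions are removed
#' @exportClass ExclusionPolicy
setClass("ExclusionPolicy",
         representation(excludedPoints = "integer",
                        conditionalRanges = "matrix"))

setValidity("ExclusionPolicy", function(object) {
  r <- object@conditionalRanges
  if (ncol(r) != 2L) return("conditionalRanges must have two columns")
  if (nrow(r) && any(r[, 1] > r[, 2])) return("range start > end")
  if (nrow(r) > 1L) {
    o <- order(r[, 1])
    if (any(r[o, 1][-1] <= r[o, 2][-nrow(r)]))
      return("conditionalRanges overlap")
  }
  TRUE
})

#' Region mask
#'
#' @slot name "complete" or "coding"
#' @slot start first included position
#' @slot end last included position
#' @exportClass RegionMask
setClass("RegionMask",
         representation(name = "character", start = "integer",
                        end = "integer"))

setValidity("RegionMask", function(object) {
  if (!object@name %in% c("complete", "coding")) return("unknown mask name")
  if (object@start > object@end) return("start > end")
  TRUE
})

#' Rooted clade tree with mutation-labelled edges
#'
#' Nodes follow the ape convention: tips 1..nTips (matching
#' \code{tipLabels}), root nTips+1, further internal nodes above that.
#' Each node carries the full variant-label set of its haplotype state;
#' each edge carries the labels that change along it, with back mutations
#' (reversions toward the reference state) flagged.
#'
#' @slot edge two-column matrix (parent, child)
#' @slot nTips number of leaves
#' @slot tipLabels sample ids of the leaves
#' @slot nodeStates list of character vectors: variant labels per node
#' @slot edgeLabels list of data.frames (label, back) per edge
#' @slot rootVariants variant labels of the designated ancestral haplotype
#' @slot leafProfiles named list of HaplotypeProfile objects
#' @slot mask region mask of the profiles ("complete"/"coding")
#' @slot exact TRUE if the tree came from the exact branch-and-bound search
#' @slot nCoOptimal number of distinct co-optimal trees found (NA if more
#'   than the storage cap existed)
#' @exportClass CladeTree
setClass("CladeTree",
         representation(edge = "matrix", nTips = "integer",
                        tipLabels = "character", nodeStates = "list",
                        edgeLabels = "list", rootVariants = "character",
                        leafProfiles = "list", mask = "character",
                        exact = "logical", nCoOptimal = "integer"))

setValidity("CladeTree", function(object) {
  if (nrow(object@edge) != length(object@edgeLabels))
    return("edgeLabels must parallel edge rows")
  if (length(object@tipLabels) != object@nTips)
    return("tipLabels length != nTips")
  n <- object@nTips
  kids <- object@edge[, 2]
  if (n > 1L && !all(seq_len(n) %in% c(kids, n + 1L)))
    return("every tip must appear as a child (or be the root)")
  TRUE
})

#' Haplogroup motif table
#'
#' A rooted hierarchy of haplogroup names with the diagnostic variant set
#' that defines each branch relative to its parent.
#'
#' @slot table data.frame with columns haplogroup, parent, motif (list
#'   column of label character vectors), source
#' @slot root name of the root haplogroup
#' @exportClass MotifTable
setClass("MotifTable",
         representation(table = "data.frame", root = "character"))

setValidity("MotifTable", function(object) {
  tb <- object@table
  if (anyDuplicated(tb$haplogroup)) return("duplicate haplogroup names")
  isRoot <- tb$parent == ""
  if (sum(isRoot) != 1L) return("exactly one root record required")
  if (!all(tb$parent[!isRoot] %in% tb$haplogroup))
    return("parent of a record not present")
  if (any(lengths(tb$motif[!isRoot]) == 0L))
    return("non-root records need a non-empty defining set")
  TRUE
})

#' Molecular clock
#'
#' @slot name "complete" (whole-genome rate) or "coding" (coding-region rate)
#' @slot yearsPerSubstitution years per accumulated substitution
#' @exportClass Clock
setClass("Clock",
         representation(name = "character",
                        yearsPerSubstitution = "numeric"))

setValidity("Clock", function(object) {
  if (object@yearsPerSubstitution <= 0)
    return("yearsPerSubstitution must be positive")
  TRUE
})

#' Rho-based age estimate for one clade under one clock
#'
#' @slot clade clade name
#' @slot n number of mtDNAs (leaves)
#' @slot rho mean substitutions from the ancestral haplotype
#' @slot sigma standard error of rho from the branch structure
#' @slot clock the Clock used
#' @slot ageYears rho * yearsPerSubstitution
#' @slot ciLowYears lower 95\% bound (not truncated at zero)
#' @slot ciHighYears upper 95\% bound
#' @exportClass RhoEstimate
setClass("RhoEstimate",
         representation(clade = "character", n = "integer", rho = "numeric",
                        sigma = "numeric", clock = "Clock",
                        ageYears = "numeric", ciLowYears = "numeric",
                        ciHighYears = "numeric"))

setValidity("RhoEstimate", function(object) {
  if (object@rho < 0) return("rho must be >= 0")
  if (object@sigma < 0) return("sigma must be >= 0")
  if (object@ciLowYears > object@ageYears ||
      object@ageYears > object@ciHighYears)
    return("CI must bracket the age")
  TRUE
})

#' Simulation configuration for synthetic clades
#'
#' @slot nLeaves number of sampled lineages
#' @slot tmrcaYears true age of the clade root, in years
#' @slot yearsPerSubstitution clock rate used to draw Poisson substitutions
#' @slot transitionFraction probability a substitution is a transition
#' @slot hotspotIndelRate expected indel events per lineage, placed inside
#'   the 303-315 / 16180-16193 hotspots
#' @slot backMutationRate expected explicit reversion events per lineage
#' @slot treeShape "star" or "yule"
#' @slot regionClass region label(s) painted on the leaves
#' @slot seed RNG seed (required; same seed + config = identical clade)
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nLeaves = "integer", tmrcaYears = "numeric",
                        yearsPerSubstitution = "numeric",
                        transitionFraction = "numeric",
                        hotspotIndelRate = "numeric",
                        backMutationRate = "numeric",
                        treeShape = "character", regionClass = "character",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nLeaves < 1L) return("nLeaves must be >= 1")
  if (object@tmrcaYears < 0) return("tmrcaYears must be >= 0")
  if (object@yearsPerSubstitution <= 0) return("clock rate must be positive")
  if (object@transitionFraction < 0 || object@transitionFraction > 1)
    return("transitionFraction must lie in [0, 1]")
  if (object@hotspotIndelRate < 0 || object@backMutationRate < 0)
    return("rates must be >= 0")
  if (!object@treeShape %in% c("star", "yule"))
    return("treeShape must be 'star' or 'yule'")
  if (is.na(object@seed)) return("seed is required")
  TRUE
})

#' A simulated clade with known truth
#'
#' @slot config the SimulationConfig used
#' @slot treeEdge data.frame (parent, child, length_years) of the true tree;
#'   node 0 is the root, tips are 1..nLeaves
#' @slot events list of per-edge event data.frames
#' @slot sequences named character vector of leaf sequences
#' @slot truth data.frame: sample_id, n_substitutions (true root-to-leaf
#'   substitution events), region_class
#' @slot referenceName name of the reference used
#' @exportClass SimulatedClade
setClass("SimulatedClade",
         representation(config = "SimulationConfig", treeEdge = "data.frame",
                        events = "list", sequences = "character",
                        truth = "data.frame", referenceName = "character"))
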