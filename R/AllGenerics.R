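#' @rdname accessors
#' @export
setGeneric("refLength", function(x) standardGeneric("refLength"))

#' @rdname accessors
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("regionClass", function(x) standardGeneric("regionClass"))

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname accessors
#' @export
setGeneric("variantLabels", function(x) standardGeneric("variantLabels"))

#' @rdname accessors
#' @export
setGeneric("maskName", function(x) standardGeneric("maskName"))

#' @rdname accessors
#' @export
setGeneric("nTips", function(x) standardGeneric("nTips"))

#' @rdname accessors
#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))

#' Total number of mutations on all edges of a clade tree
#'
#' Parallel and back mutations each count once per occurrence, so the
#' value is the parsimony length of the tree.
#'
#' @param x a \linkS4class{CladeTree}
#' @return integer mutation count
#' @export
setGeneric("treeLength", function(x) standardGeneric("treeLength"))

#' @rdname rhoDating
#' @export
setGeneric("computeRho", function(tree, node = NULL)
  standardGeneric("computeRho"))

#' @rdname rhoDating
#' @export
setGeneric("computeSigma", function(tree, node = NULL)
  standardGeneric("computeSigma"))
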