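#' Classify the geographic origin of a clade by phylogenetic nesting
#'
#' Walks up the ancestors of the clade's root node; the first ancestor
#' whose *other* descendant leaves (those outside the clade examined so
#' far) carry region classes is informative.  Under the default unanimity
#' rule, if those outside leaves (ignoring leaves from the target regions
#' themselves) all share one region class, that class is the origin; two
#' or more distinct classes at the first informative ancestor give
#' "ambiguous"; reaching the tree root without signal gives "uncertain".
#' The majority rule instead accepts a class reaching
#' \code{majorityThreshold} of the outside leaves.
#'
#' @param tree a \linkS4class{CladeTree} including comparative lineages
#'   with region classes on every leaf
#' @param node the clade root node to classify
#' @param targetRegions region classes of the population under study
#'   (ignored as evidence; default "Siberia")
#' @param rule "unanimity" or "majority"
#' @param majorityThreshold fraction required under the majority rule
#' @return one-row data.frame: node, origin, evidence
#' @export
classifyOriginByNesting <- function(tree, node, targetRegions = "Siberia",
                                    rule = c("unanimity", "majority"),
                                    majorityThreshold = 0.75) {
  rule <- match.arg(rule)
  if (node > max(tree@edge) || node < 1L)
    stop("clade node not in tree")
  regions <- vapply(tree@leafProfiles[tree@tipLabels], regionClass, "")
  if (anyNA(regions)) stop("missing region_class on some leaves")
  p <- parentVector(tree)
  inside <- tipsUnder(tree, node)
  cur <- node
  while (!is.na(p[cur])) {
    anc <- p[cur]
    others <- setdiff(tipsUnder(tree, anc), inside)
    classes <- setdiff(unique(regions[others]), targetRegions)
    if (length(classes)) {
      tab <- table(factor(regions[others],
                          levels = sort(unique(regions[others]))))
      tab <- tab[!names(tab) %in% targetRegions]
      evid <- paste0("node", anc, ": ",
                     paste(names(tab), tab, sep = "=", collapse = ", "))
      if (length(classes) == 1L)
        return(data.frame(node = node, origin = classes,
                          evidence = evid, stringsAsFactors = FALSE))
      if (rule == "majority") {
        frac <- tab / sum(tab)
        top <- names(frac)[which.max(frac)]
        if (max(frac) >= majorityThreshold)
          return(data.frame(node = node, origin = top,
                            evidence = evid, stringsAsFactors = FALSE))
      }
      return(data.frame(node = node, origin = "ambiguous",
                        evidence = evid, stringsAsFactors = FALSE))
    }
    inside <- tipsUnder(tree, anc)
    cur <- anc
  }
  data.frame(node = node, origin = "uncertain",
             evidence = "reached tree root without signal",
             stringsAsFactors = FALSE)
}

#' Summarise origin calls over the analysed genomes
#'
#' Each genome inherits the origin of the clade it belongs to; a genome
#' in more than one called clade is an error.
#'
#' @param calls data.frame with columns \code{clade}, \code{origin},
#'   \code{n} (leaves in the clade) and \code{samples} (space-separated
#'   sample ids)
#' @param regionSpecific optional result of
#'   \code{\link{findRegionSpecificClades}}, echoed into the summary
#' @return list with \code{total} genomes, \code{table} (origin, count,
#'   fraction), \code{calls}, and optionally \code{nRegionSpecific} /
#'   \code{regionSpecificLeaves}
#' @export
summarizeOrigins <- function(calls, regionSpecific = NULL) {
  if (nrow(calls) == 0L)
    return(list(total = 0L,
                table = data.frame(origin = character(), count = integer(),
                                   fraction = numeric(),
                                   stringsAsFactors = FALSE),
                calls = calls))
  ids <- unlist(strsplit(calls$samples, " "))
  if (anyDuplicated(ids))
    stop("genome assigned to more than one clade: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  agg <- stats::aggregate(list(count = calls$n),
                          by = list(origin = calls$origin), FUN = sum)
  agg <- agg[order(agg$origin), , drop = FALSE]
  total <- sum(agg$count)
  agg$fraction <- agg$count / total
  out <- list(total = total, table = agg, calls = calls)
  if (!is.null(regionSpecific)) {
    out$nRegionSpecific <- nrow(regionSpecific$clades)
    out$regionSpecificLeaves <- regionSpecific$totalLeaves
  }
  out
}
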