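#' Read a haplogroup motif table
#'
#' Tab-separated with columns \code{haplogroup}, \code{parent} (empty for
#' the root), \code{motif} (space-separated variant labels defining the
#' branch relative to its parent) and optionally \code{source}.  Lines
#' starting with '#' are comments.  The bundled fixture
#' \code{inst/extdata/motifs_siberian.tsv} carries the published
#' diagnostics of the Siberian-specific subclades plus synthetic
#' placeholder motifs for the unpublished ancestral path steps (marked in
#' its \code{source} column).
#'
#' @param path motif table path
#' @param ref a \linkS4class{ReferenceGenome} used to parse the labels
#' @return a \linkS4class{MotifTable}
#' @export
readMotifTable <- function(path, ref) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("haplogroup", "parent", "motif")
  if (!all(need %in% names(tb)))
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  if (!"source" %in% names(tb)) tb$source <- NA_character_
  tb$parent[is.na(tb$parent)] <- ""
  tb$motif[is.na(tb$motif)] <- ""
  motifs <- lapply(tb$motif, function(m) {
    labs <- strsplit(trimws(m), "\\s+")[[1]]
    labs <- labs[nzchar(labs)]
    if (length(labs)) parseVariantLabel(labs, ref)$label else character()
  })
  out <- data.frame(haplogroup = tb$haplogroup, parent = tb$parent,
                    source = tb$source, stringsAsFactors = FALSE)
  out$motif <- motifs
  motifTable(out)
}

#' @rdname readMotifTable
#' @param table data.frame with columns haplogroup, parent, and a list
#'   column motif of canonical label vectors
#' @export
motifTable <- function(table) {
  if (!"source" %in% names(table))
    table$source <- rep(NA_character_, nrow(table))
  root <- table$haplogroup[table$parent == ""]
  methods::new("MotifTable", table = table, root = root)
}

setMethod("show", "MotifTable", function(object) {
  cat("MotifTable:", nrow(object@table), "haplogroups, root",
      object@root, "\n")
})

# cumulative defining set along the root -> haplogroup path; repeated
# labels toggle (a motif naming a label again reverts it)
cumulativeMotif <- function(motifs, haplogroup) {
  tb <- motifs@table
  path <- character()
  h <- haplogroup
  while (h != "") {
    i <- match(h, tb$haplogroup)
    if (is.na(i)) stop("haplogroup not in table: ", h)
    path <- c(path, h)
    h <- tb$parent[i]
  }
  cum <- character()
  for (h in rev(path)) {
    m <- tb$motif[[match(h, tb$haplogroup)]]
    for (lab in m)
      cum <- if (lab %in% cum) setdiff(cum, lab) else c(cum, lab)
  }
  sort(cum)
}

motifDepth <- function(motifs, haplogroup) {
  tb <- motifs@table
  d <- 0L
  h <- haplogroup
  while (h != "") {
    h <- tb$parent[match(h, tb$haplogroup)]
    d <- d + 1L
  }
  d
}

# haplogroup and all its descendants in the hierarchy
motifDescendants <- function(motifs, haplogroup) {
  tb <- motifs@table
  out <- haplogroup
  repeat {
    more <- tb$haplogroup[tb$parent %in% out & !tb$haplogroup %in% out]
    if (!length(more)) break
    out <- c(out, more)
  }
  out
}

#' Assign a haplogroup from diagnostic motifs
#'
#' Scores every haplogroup in the table by (matched - missing), where
#' matched and missing are counted over the cumulative defining set on
#' the root-to-haplogroup path, and returns the best-scoring haplogroup;
#' ties go to the deeper haplogroup, then to the lexicographically
#' smaller name.  Control-region and coding-region diagnostics count
#' equally.
#'
#' @param profile a \linkS4class{HaplotypeProfile} (filtered)
#' @param motifs a \linkS4class{MotifTable}
#' @return one-row data.frame: sample_id, haplogroup, matched, missing,
#'   extra (private variants not on the defining path)
#' @export
assignHaplogroup <- function(profile, motifs) {
  tb <- motifs@table
  if (nrow(tb) == 0L) stop("empty motif table")
  labs <- variantLabels(profile)
  best <- NULL
  for (i in seq_len(nrow(tb))) {
    h <- tb$haplogroup[i]
    cum <- cumulativeMotif(motifs, h)
    matched <- sum(cum %in% labs)
    missing <- length(cum) - matched
    score <- matched - missing
    depth <- motifDepth(motifs, h)
    cand <- list(h = h, matched = matched, missing = missing,
                 score = score, depth = depth, cum = cum)
    if (is.null(best) || score > best$score ||
        (score == best$score && depth > best$depth) ||
        (score == best$score && depth == best$depth && h < best$h))
      best <- cand
  }
  data.frame(sample_id = sampleId(profile), haplogroup = best$h,
             matched = best$matched, missing = best$missing,
             extra = sum(!labs %in% best$cum),
             stringsAsFactors = FALSE)
}

#' Assign haplogroups for all leaves of a tree
#'
#' @param tree a \linkS4class{CladeTree}
#' @param motifs a \linkS4class{MotifTable}
#' @return data.frame of per-sample calls (see
#'   \code{\link{assignHaplogroup}})
#' @export
assignHaplogroups <- function(tree, motifs) {
  do.call(rbind, lapply(tree@leafProfiles[tree@tipLabels],
                        assignHaplogroup, motifs = motifs))
}
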