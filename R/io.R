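#' Load a single-record reference FASTA
#'
#' Reads a reference mitogenome and validates it: exactly one record,
#' bases restricted to A, C, G, T, N.  Coordinates throughout the package
#' are 1-based positions on this sequence.
#'
#' @param path path to a single-record FASTA file
#' @return a \linkS4class{ReferenceGenome}
#' @examples
#' ref <- loadReference(system.file("extdata", "synthetic_rCRS.fasta",
#'                                  package = "mitorho"))
#' refLength(ref)
#' @export
loadReference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stop("reference FASTA must contain exactly one record, found ",
         length(seqs))
  s <- toupper(as.character(seqs[[1]]))
  if (grepl("[^ACGTN]", s))
    stop("reference contains characters other than A,C,G,T,N")
  methods::new("ReferenceGenome", name = names(seqs)[1], sequence = s,
               length = nchar(s))
}

#' @describeIn loadReference length of the reference in positions
#' @param x object
#' @export
setMethod("refLength", "ReferenceGenome", function(x) x@length)

#' @describeIn loadReference the reference sequence as a character string
#' @export
setMethod("refSequence", "ReferenceGenome", function(x) x@sequence)

setMethod("show", "ReferenceGenome", function(object) {
  cat("ReferenceGenome", object@name, "(", object@length, "np )\n")
})

#' Read sample mitogenomes with their metadata
#'
#' @param fastaPath FASTA of complete mitogenomes
#' @param metaPath tab-separated metadata with columns sample_id,
#'   population, region_class and optionally source
#' @return list with \code{sequences} (named character vector, FASTA
#'   order preserved) and \code{samples} (data.frame, matched to the
#'   sequences)
#' @export
readSamples <- function(fastaPath, metaPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE,
                            comment.char = "#")
  need <- c("sample_id", "population", "region_class")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (!"source" %in% names(meta)) meta$source <- NA_character_
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicated record ids in FASTA")
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing))
    stop("FASTA ids missing from metadata: ",
         paste(missing, collapse = ", "))
  out <- toupper(as.character(seqs))
  names(out) <- ids
  list(sequences = out,
       samples = meta[match(ids, meta$sample_id), , drop = FALSE])
}

#' Parse a variant label in rCRS-style nomenclature
#'
#' The dialect follows forensic/PhyloTree usage: a bare number is a
#' transition at that position ("16189"); number plus base is a
#' substitution to that base, with the kind (transition or transversion)
#' derived from the reference base ("16182C"); "pos.iB" is an insertion of
#' base B at insert slot i after pos ("315.1C"); "posd" is a deletion
#' ("523d").  Base suffixes are case-insensitive.
#'
#' @param label variant label(s)
#' @param ref a \linkS4class{ReferenceGenome}
#' @return a variant data.frame (one row per label) with columns
#'   position, kind, ref, alt, insert_index, label
#' @examples
#' ref <- syntheticReference()
#' parseVariantLabel("16189", ref)
#' parseVariantLabel(c("315.1C", "523d"), ref)
#' @export
parseVariantLabel <- function(label, ref) {
  rows <- lapply(label, parseOneLabel, ref = ref)
  sortVariants(do.call(rbind, c(list(emptyVariants()), rows)))
}

parseOneLabel <- function(label, ref) {
  s <- refSequence(ref)
  n <- refLength(ref)
  refBase <- function(pos) substr(s, pos, pos)
  checkPos <- function(pos) {
    if (is.na(pos) || pos < 1L || pos > n)
      stop("position out of range in label '", label, "'")
    pos
  }
  if (grepl("^[0-9]+$", label)) {
    pos <- checkPos(as.integer(label))
    rb <- refBase(pos)
    if (rb == "N") stop("reference base at ", pos, " is N")
    makeVariants(pos, "transition", rb, unname(transitionPartner(rb)))
  } else if (grepl("^[0-9]+[ACGTacgt]$", label)) {
    pos <- checkPos(as.integer(sub("[ACGTacgt]$", "", label)))
    alt <- toupper(substr(label, nchar(label), nchar(label)))
    rb <- refBase(pos)
    if (rb == "N") stop("reference base at ", pos, " is N")
    if (alt == rb)
      stop("label '", label, "' names the reference base")
    kind <- if (isTransitionPair(rb, alt)) "transition" else "transversion"
    makeVariants(pos, kind, rb, alt)
  } else if (grepl("^[0-9]+\\.[0-9]+[ACGTacgt]$", label)) {
    m <- regmatches(label,
                    regexec("^([0-9]+)\\.([0-9]+)([ACGTacgt])$", label))[[1]]
    pos <- checkPos(as.integer(m[2]))
    idx <- as.integer(m[3])
    if (idx < 1L) stop("insert index must be >= 1 in '", label, "'")
    makeVariants(pos, "insertion", "", toupper(m[4]), idx)
  } else if (grepl("^[0-9]+[dD]$", label)) {
    pos <- checkPos(as.integer(sub("[dD]$", "", label)))
    makeVariants(pos, "deletion", refBase(pos), "")
  } else {
    stop("unparseable variant label: '", label, "'")
  }
}

#' Format variants to canonical labels
#'
#' The inverse of \code{\link{parseVariantLabel}}: transitions print as the
#' bare position, transversions as position plus derived base, insertions
#' as "pos.iB" and deletions as "posd".
#'
#' @param v a variant data.frame (as in a \linkS4class{HaplotypeProfile})
#' @return character vector of canonical labels
#' @export
formatVariantLabel <- function(v) {
  makeVariants(v$position, v$kind, v$ref, v$alt, v$insert_index)$label
}

#' Construct a haplotype profile
#'
#' @param sampleId sample identifier
#' @param variants variant data.frame (e.g. from
#'   \code{\link{parseVariantLabel}} or \code{\link{callVariants}})
#' @param population population name
#' @param regionClass geographic region label
#' @param mask region mask already applied ("complete" or "coding")
#' @return a \linkS4class{HaplotypeProfile}
#' @export
haplotypeProfile <- function(sampleId, variants = emptyVariants(),
                             population = NA_character_,
                             regionClass = NA_character_,
                             mask = "complete") {
  methods::new("HaplotypeProfile", sampleId = sampleId,
               population = population, regionClass = regionClass,
               variants = sortVariants(variants), mask = mask)
}

#' @rdname accessors
#' @param x object
#' @name accessors
#' @aliases sampleId,HaplotypeProfile-method
#' @export
setMethod("sampleId", "HaplotypeProfile", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("regionClass", "HaplotypeProfile", function(x) x@regionClass)

#' @rdname accessors
#' @export
setMethod("variantTable", "HaplotypeProfile", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("variantLabels", "HaplotypeProfile",
          function(x) x@variants$label)

#' @rdname accessors
#' @export
setMethod("maskName", "HaplotypeProfile", function(x) x@mask)

setMethod("show", "HaplotypeProfile", function(object) {
  cat("HaplotypeProfile", object@sampleId,
      sprintf("[%s, %s, mask=%s]\n", object@population,
              object@regionClass, object@mask))
  cat(" ", nrow(object@variants), "variants:",
      paste(utils::head(object@variants$label, 12), collapse = " "),
      if (nrow(object@variants) > 12) "...\n" else "\n")
})

# profiles compare equal iff their label sets are equal
profilesEqual <- function(a, b) {
  setequal(variantLabels(a), variantLabels(b))
}

#' Write the report bundle of a pipeline run
#'
#' Writes the variant-profile table, plain and annotated Newick trees,
#' the dating report, haplogroup calls, region-specific subclades and the
#' origin summary.  Output is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param profiles list of \linkS4class{HaplotypeProfile}
#' @param trees named list of \linkS4class{CladeTree}
#' @param dating dating report data.frame from
#'   \code{\link{dateAllSubclades}} (or NULL)
#' @param calls haplogroup call data.frame (or NULL)
#' @param regionSpecific result of \code{\link{findRegionSpecificClades}}
#'   (or NULL)
#' @param originSummary result of \code{\link{summarizeOrigins}} (or NULL)
#' @param outDir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeOutputs <- function(profiles, trees = list(), dating = NULL,
                         calls = NULL, regionSpecific = NULL,
                         originSummary = NULL, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  paths <- character()
  wtsv <- function(df, file) {
    p <- file.path(outDir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  prof <- data.frame(
    sample_id = vapply(profiles, sampleId, ""),
    population = vapply(profiles, function(p) p@population, ""),
    region_class = vapply(profiles, regionClass, ""),
    mask = vapply(profiles, maskName, ""),
    variants = vapply(profiles, function(p)
      paste(variantLabels(p), collapse = " "), ""),
    stringsAsFactors = FALSE)
  wtsv(prof, "profiles.tsv")
  for (nm in names(trees)) {
    t <- trees[[nm]]
    p1 <- file.path(outDir, paste0("tree_", nm, ".nwk"))
    writeLines(cladeNewick(t, annotated = FALSE), p1)
    p2 <- file.path(outDir, paste0("tree_", nm, "_annotated.nwk"))
    writeLines(cladeNewick(t, annotated = TRUE), p2)
    paths <- c(paths, p1, p2)
  }
  if (!is.null(dating)) {
    d <- dating
    for (cc in c("age_kya", "ci_low_kya", "ci_high_kya"))
      if (cc %in% names(d)) d[[cc]] <- round(d[[cc]], 2)
    for (cc in c("rho", "sigma"))
      if (cc %in% names(d)) d[[cc]] <- round(d[[cc]], 4)
    wtsv(d, "dating.tsv")
  }
  if (!is.null(calls)) wtsv(calls, "haplogroup_calls.tsv")
  if (!is.null(regionSpecific)) wtsv(regionSpecific$clades,
                                     "region_specific_clades.tsv")
  if (!is.null(originSummary)) {
    wtsv(originSummary$table, "origin_summary.tsv")
    if (!is.null(originSummary$calls))
      wtsv(originSummary$calls, "origin_calls.tsv")
  }
  invisible(paths)
}

# Newick serialisation; annotated form carries edge mutation labels in
# BEAST-style comment blocks ("[&mut={8473,16189!}]"), back mutations
# suffixed "!".  Edge length = number of mutations on the edge.
cladeNewick <- function(tree, annotated = FALSE) {
  root <- rootNode(tree)
  kids <- split(seq_len(nrow(tree@edge)), tree@edge[, 1])
  rec <- function(node, edgeIdx) {
    if (node <= tree@nTips) {
      lab <- tree@tipLabels[node]
    } else {
      ks <- kids[[as.character(node)]]
      lab <- paste0("(", paste(vapply(ks, function(e)
        rec(tree@edge[e, 2], e), ""), collapse = ","), ")")
    }
    if (is.null(edgeIdx)) return(paste0(lab, ";"))
    el <- tree@edgeLabels[[edgeIdx]]
    ann <- ""
    if (annotated && nrow(el)) {
      labs <- paste0(el$label, ifelse(el$back, "!", ""))
      ann <- paste0("[&mut={", paste(labs, collapse = ","), "}]")
    }
    paste0(lab, ann, ":", nrow(el))
  }
  rec(root, NULL)
}
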