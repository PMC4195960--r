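#' Site exclusion policy constructor
#'
#' Default values are the standard mitogenome-phylogeny rule: np 16519 is
#' removed outright, and within nps 16180-16193, 303-315, 522-524 and
#' 573-576 only point indels and transversions are removed (transitions
#' in those ranges are kept).
#'
#' @param excludedPoints positions excluded for all variant kinds
#' @param conditionalRanges two-column matrix of inclusive ranges where
#'   only indels and transversions are excluded
#' @return an \linkS4class{ExclusionPolicy}
#' @export
exclusionPolicy <- function(excludedPoints = 16519L,
                            conditionalRanges = rbind(c(16180L, 16193L),
                                                      c(303L, 315L),
                                                      c(522L, 524L),
                                                      c(573L, 576L))) {
  storage.mode(conditionalRanges) <- "integer"
  methods::new("ExclusionPolicy",
               excludedPoints = as.integer(excludedPoints),
               conditionalRanges = conditionalRanges)
}

#' Region mask constructor
#'
#' The coding region is fixed at nps 577-16023 by the standard mtDNA
#' convention; the complete mask covers the whole genome.
#'
#' @param name "complete" or "coding"
#' @param start,end override the mask bounds
#' @param ref reference (used only for the complete-mask end)
#' @return a \linkS4class{RegionMask}
#' @export
regionMask <- function(name = c("complete", "coding"), start = NULL,
                       end = NULL, ref = NULL) {
  name <- match.arg(name)
  if (name == "coding") {
    start <- start %||% 577L
    end <- end %||% 16023L
  } else {
    start <- start %||% 1L
    end <- end %||% (if (is.null(ref)) 16569L else refLength(ref))
  }
  methods::new("RegionMask", name = name, start = as.integer(start),
               end = as.integer(end))
}

#' Apply a variant set to a reference sequence
#'
#' Substitutions replace the reference base; deletions remove positions;
#' insertions add bases after their anchor position in insert-index
#' order.  Used by the simulator and by round-trip consistency tests.
#'
#' @param ref a \linkS4class{ReferenceGenome}
#' @param variants a variant data.frame
#' @return the mutated sequence as a character string
#' @export
applyVariants <- function(ref, variants) {
  chars <- strsplit(refSequence(ref), "")[[1]]
  subs <- variants[variants$kind %in% c("transition", "transversion"), ]
  if (nrow(subs)) chars[subs$position] <- subs$alt
  dels <- variants[variants$kind == "deletion", ]
  ins <- variants[variants$kind == "insertion", ]
  if (nrow(dels) == 0L && nrow(ins) == 0L)
    return(paste(chars, collapse = ""))
  keep <- rep(TRUE, length(chars))
  if (nrow(dels)) keep[dels$position] <- FALSE
  # splice insertions from right to left so positions stay valid
  out <- chars
  out[!keep] <- ""
  if (nrow(ins)) {
    for (p in sort(unique(ins$position), decreasing = TRUE)) {
      rows <- ins[ins$position == p, ]
      add <- paste(rows$alt[order(rows$insert_index)], collapse = "")
      out[p] <- paste0(out[p], add)
    }
  }
  paste(out, collapse = "")
}

#' Score a sample mitogenome against the reference
#'
#' Computes the variant set of a minimal-cost global alignment (mismatch
#' 1, gap open 3, gap extend 1).  Sequences of reference length with a
#' plausible mismatch count are compared position-wise; otherwise a
#' banded affine-gap alignment is used.  Indels are normalised to their
#' 3'-most equivalent placement, so e.g. a C inserted anywhere in the
#' 303-309 C-run is reported as 309.1C.  Sites where either sequence has
#' an ambiguity code (N or other IUPAC, treated as N) yield no variant.
#'
#' @param seq sample sequence (character string)
#' @param ref a \linkS4class{ReferenceGenome}
#' @param sampleId,population,regionClass metadata attached to the profile
#' @param minLength minimum accepted sequence length (near-complete
#'   mitogenomes expected)
#' @param onShort "error" or "warn" for sequences below \code{minLength}
#' @param maxFastMismatch fall back to alignment if a length-matched
#'   comparison shows more raw mismatches than this
#' @param bandPad extra half-width of the alignment band beyond the
#'   length difference
#' @return a \linkS4class{HaplotypeProfile} (mask "complete")
#' @examples
#' ref <- syntheticReference()
#' v <- parseVariantLabel("8473", ref)
#' p <- callVariants(applyVariants(ref, v), ref, sampleId = "s1")
#' variantLabels(p)
#' @export
callVariants <- function(seq, ref, sampleId = "sample",
                         population = NA_character_,
                         regionClass = NA_character_,
                         minLength = 15000L, onShort = c("error", "warn"),
                         maxFastMismatch = 300L, bandPad = 30L) {
  onShort <- match.arg(onShort)
  seq <- toupper(seq)
  seq <- gsub("[^ACGTN]", "N", seq)   # other IUPAC codes treated as N
  if (nchar(seq) < minLength) {
    msg <- paste0("sequence ", sampleId, " is ", nchar(seq),
                  " bp, below minimum ", minLength)
    if (onShort == "error") stop(msg) else warning(msg)
  }
  rseq <- refSequence(ref)
  variants <- NULL
  if (nchar(seq) == nchar(rseq)) {
    d <- which(charToRaw(seq) != charToRaw(rseq))
    if (length(d) == 0L) {
      variants <- emptyVariants()
    } else if (length(d) <= maxFastMismatch) {
      rb <- substring(rseq, d, d)
      ab <- substring(seq, d, d)
      ok <- rb != "N" & ab != "N"
      variants <- makeVariants(
        d[ok],
        ifelse(isTransitionPair(rb[ok], ab[ok]), "transition",
               "transversion"),
        rb[ok], ab[ok])
    }
  }
  if (is.null(variants))
    variants <- alignAndCall(seq, ref, bandPad)
  haplotypeProfile(sampleId, variants, population, regionClass, "complete")
}

# alignment path: trim the shared prefix/suffix, banded affine global
# alignment of the middle, then variant extraction with 3'-most indel
# normalisation.  The band spans the diagonal offsets between 0 and the
# length difference, plus `bandPad` for offsetting indels, so memory
# stays proportional to the unshared middle times a small width.
alignAndCall <- function(seq, ref, bandPad) {
  rseq <- refSequence(ref)
  rawR <- charToRaw(rseq)
  rawS <- charToRaw(seq)
  n <- length(rawR); m <- length(rawS)
  k <- min(n, m)
  eqFwd <- rawR[seq_len(k)] == rawS[seq_len(k)]
  pre <- if (all(eqFwd)) k else which(!eqFwd)[1] - 1L
  eqRev <- rev(rawR)[seq_len(k)] == rev(rawS)[seq_len(k)]
  suf <- if (all(eqRev)) k else which(!eqRev)[1] - 1L
  # back off so the DP sees the full local context and keep the trims
  # from overlapping
  pre <- max(0L, pre - 8L)
  suf <- max(0L, min(suf - 8L, k - pre))
  midR <- substr(rseq, pre + 1L, n - suf)
  midS <- substr(seq, pre + 1L, m - suf)
  if (nchar(midR) == 0L && nchar(midS) == 0L) {
    op <- integer(); len <- integer()
  } else if (nchar(midR) == 0L) {
    op <- 1L; len <- nchar(midS)
  } else if (nchar(midS) == 0L) {
    op <- 2L; len <- nchar(midR)
  } else {
    aln <- .cpp_banded_align(midR, midS, 1L, 3L, 1L, as.integer(bandPad))
    op <- aln$op; len <- aln$len
  }
  op <- c(if (pre > 0L) 0L, op, if (suf > 0L) 0L)
  len <- c(if (pre > 0L) pre, len, if (suf > 0L) suf)
  aln <- list(op = op, len = len)
  rchars <- strsplit(rseq, "")[[1]]
  schars <- strsplit(seq, "")[[1]]
  i <- 0L; j <- 0L   # consumed so far in ref / sample
  pos <- integer(); kind <- character(); rb <- character()
  ab <- character(); idx <- integer()
  for (k in seq_along(aln$op)) {
    op <- aln$op[k]; len <- aln$len[k]
    if (op == 0L) {                      # match/mismatch block
      rs <- rchars[(i + 1L):(i + len)]
      ss <- schars[(j + 1L):(j + len)]
      d <- which(rs != ss & rs != "N" & ss != "N")
      if (length(d)) {
        pos <- c(pos, i + d)
        kind <- c(kind, ifelse(isTransitionPair(rs[d], ss[d]),
                               "transition", "transversion"))
        rb <- c(rb, rs[d]); ab <- c(ab, ss[d])
        idx <- c(idx, rep(0L, length(d)))
      }
      i <- i + len; j <- j + len
    } else if (op == 2L) {               # deletion of ref i+1 .. i+len
      sh <- shiftDeletion(rchars, i + 1L, i + len)
      pos <- c(pos, sh[1]:sh[2])
      kind <- c(kind, rep("deletion", len))
      rb <- c(rb, rchars[sh[1]:sh[2]])
      ab <- c(ab, rep("", len)); idx <- c(idx, rep(0L, len))
      i <- i + len
    } else {                             # insertion after ref position i
      insSeq <- schars[(j + 1L):(j + len)]
      sh <- shiftInsertion(rchars, i, insSeq)
      pos <- c(pos, rep(sh$anchor, len))
      kind <- c(kind, rep("insertion", len))
      rb <- c(rb, rep("", len)); ab <- c(ab, sh$seq)
      idx <- c(idx, seq_len(len))
      j <- j + len
    }
  }
  makeVariants(pos, kind, rb, ab, idx)
}

# right-shift a deletion window [from, to] while ref allows
shiftDeletion <- function(rchars, from, to) {
  n <- length(rchars)
  while (to < n && rchars[from] == rchars[to + 1L]) {
    from <- from + 1L
    to <- to + 1L
  }
  c(from, to)
}

# right-shift an insertion (after `anchor`) while its first base matches
# the next reference base
shiftInsertion <- function(rchars, anchor, insSeq) {
  n <- length(rchars)
  while (anchor < n && insSeq[1L] == rchars[anchor + 1L]) {
    anchor <- anchor + 1L
    insSeq <- c(insSeq[-1L], insSeq[1L])
  }
  list(anchor = anchor, seq = insSeq)
}

#' Apply the site exclusion policy to a profile
#'
#' Removes all variants at the excluded points; inside the conditional
#' ranges removes only insertions, deletions and transversions, keeping
#' transitions.  Idempotent.
#'
#' @param profile a \linkS4class{HaplotypeProfile}
#' @param policy an \linkS4class{ExclusionPolicy}
#' @return the filtered profile
#' @examples
#' ref <- syntheticReference()
#' p <- haplotypeProfile("s1",
#'        parseVariantLabel(c("16519", "16189", "309.1C", "263"), ref))
#' variantLabels(applyExclusionFilter(p, exclusionPolicy()))
#' @export
applyExclusionFilter <- function(profile, policy = exclusionPolicy()) {
  v <- profile@variants
  drop <- v$position %in% policy@excludedPoints
  if (nrow(policy@conditionalRanges)) {
    inRange <- rep(FALSE, nrow(v))
    for (r in seq_len(nrow(policy@conditionalRanges))) {
      rg <- policy@conditionalRanges[r, ]
      inRange <- inRange | (v$position >= rg[1] & v$position <= rg[2])
    }
    drop <- drop | (inRange & v$kind %in%
                      c("insertion", "deletion", "transversion"))
  }
  methods::initialize(profile, variants = v[!drop, , drop = FALSE])
}

#' Restrict a profile to a region mask
#'
#' Keeps variants with \code{start <= position <= end} and records the
#' mask name on the profile, so coding-clock dating runs on
#' coding-restricted profiles.
#'
#' @param profile a \linkS4class{HaplotypeProfile}
#' @param mask a \linkS4class{RegionMask}
#' @return the restricted profile
#' @export
restrictRegion <- function(profile, mask = regionMask("coding")) {
  v <- profile@variants
  keep <- v$position >= mask@start & v$position <= mask@end
  methods::initialize(profile, variants = v[keep, , drop = FALSE],
                      mask = mask@name)
}
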