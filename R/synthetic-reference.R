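#' Synthetic rCRS-like reference genome
#'
#' Builds, deterministically and without touching the R RNG, a synthetic
#' 16,569-np reference that stands in for the revised Cambridge Reference
#' Sequence.  It shares the rCRS coordinate system and the local sequence
#' features the pipeline's site rules depend on: the 303-315 C-tract
#' interrupted by 310T, an rCRS-like 16180-16193 poly-A/C stretch with
#' 16182A/16189T, short tracts at 522-524 and 573-576, and non-C bases
#' flanking each hotspot so right-normalised indels stay inside the
#' excluded ranges.  The bundled fixture
#' \code{inst/extdata/synthetic_rCRS.fasta} is this exact sequence.
#'
#' This is a synthetic stand-in: base identities elsewhere are arbitrary
#' (drawn from a fixed linear congruential generator with mtDNA-like base
#' composition), so analyses of real GenBank mitogenomes should load the
#' true rCRS instead.
#'
#' @return a \linkS4class{ReferenceGenome} of length 16,569
#' @examples
#' ref <- syntheticReference()
#' substr(refSequence(ref), 303, 316)  # C-tract with 310T
#' @export
syntheticReference <- function() {
  n <- 16569L
  # Park-Miller LCG, fixed seed; independent of R's RNG state
  m <- 2147483647
  a <- 48271
  x <- 20140217
  draws <- numeric(n)
  for (i in seq_len(n)) {
    x <- (a * x) %% m
    draws[i] <- x / m
  }
  # approximate human mtDNA composition
  bases <- c("A", "C", "G", "T")
  cum <- cumsum(c(0.31, 0.31, 0.13, 0.25))
  seq <- bases[findInterval(draws, cum) + 1L]

  plant <- function(seq, start, str) {
    s <- strsplit(str, "")[[1]]
    seq[start:(start + length(s) - 1L)] <- s
    seq
  }
  seq <- plant(seq, 303L, "CCCCCCCTCCCCC")    # 303-309 C, 310 T, 311-315 C
  seq <- plant(seq, 316L, "G")                 # stop right-shift at 316
  seq <- plant(seq, 522L, "CAC")               # 522-524
  seq <- plant(seq, 525L, "A")
  seq <- plant(seq, 573L, "CCCC")              # 573-576
  seq <- plant(seq, 577L, "G")
  seq <- plant(seq, 16180L, "AAAACCCCCTCCCC")  # 16180-16193, 16189 T
  seq <- plant(seq, 16194L, "T")
  seq <- plant(seq, 16519L, "T")
  methods::new("ReferenceGenome", name = "synthetic_rCRS",
               sequence = paste(seq, collapse = ""), length = n)
}

#' Write a reference genome to FASTA
#'
#' @param ref a \linkS4class{ReferenceGenome}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeReference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(refSequence(ref))
  names(x) <- ref@name
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
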