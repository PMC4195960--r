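---
title: "Rho dating and maximum-parsimony phylogeny of mitogenomes: methods"
author: "mitorho authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rho dating and maximum-parsimony phylogeny of mitogenomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorho)
```

## The analysis chain

`mitorho` implements the standard analysis chain used in mitogenome
phylogeography: complete mitochondrial genomes are scored as variant sets
against the rCRS coordinate frame, hypervariable sites are excluded by a
fixed policy, the remaining haplotypes are connected into a rooted
maximum-parsimony (MP) tree, named subclades are recognised from
diagnostic motifs, each subclade is dated with the rho statistic under
one or two molecular clocks, and the geographic origin of a clade of
interest is inferred from how it nests among labelled comparative
lineages.

Every stage is also exercised against a clade simulator with known
truth, so the whole chain can be validated without any external data.

## Variant scoring and nomenclature

A sample is compared to the reference by a minimal-cost global alignment
(mismatch 1, gap open 3, gap extend 1).  Because complete mitogenomes
diverge from the reference by well under 1%, two shortcuts keep this
exact and fast: sequences of exactly reference length with a plausible
mismatch count are compared position-wise, and everything else goes
through a banded affine-gap alignment whose band half-width is at least
the length difference plus a margin — for indels of a few bases in an
otherwise near-identical sequence the optimal path cannot leave that
band.  Gap placement among equal-cost alternatives is normalised to the
3'-most position, the convention used for mtDNA homopolymer tracts (a C
inserted anywhere in the 303–309 run is reported as `309.1C`).

Variant labels follow the forensic/PhyloTree dialect: a bare position is
a transition (`16189`), position plus base is a substitution to that
base with the kind derived from the reference base (`16182C`), `pos.iB`
is an insertion (`315.1C`), and `posd` a deletion (`523d`).  Formatting
then parsing a variant is the identity, which the tests check by
property over 1000 random variants.  The genome is treated as linear
1..16569; the control-region junction is never aligned circularly, which
is safe because mtDNA numbering is anchored to the rCRS frame.

Ambiguity codes never produce variants: `N` (and any other IUPAC code,
which is treated as `N`) simply silences the site.

## The exclusion policy

Positions known to mutate too fast to carry phylogenetic signal are
removed before tree building: np 16519 outright, and within nps
16180–16193, 303–315, 522–524 and 573–576 only point indels and
transversions — transitions in those windows are kept (so `16189` stays
while `16183C` and `309.1C` go).  The policy object is configurable but
defaults to exactly this rule, and its application is idempotent.  Only
the printed rule is implemented; additional hotspot transitions
sometimes excluded by curators (e.g. 16182/16183 read-through artifacts)
are deliberately not filtered.

## Maximum-parsimony trees

Each variant label is a binary presence/absence character; the MP tree
is a minimum Steiner tree on the hypercube connecting the observed
haplotypes and the designated ancestral haplotype (the clade founder,
often the reference itself).  Up to 12 distinct haplotypes (default,
configurable) the search is exact: a branch-and-bound over unrooted
binary topologies by stepwise addition, with Fitch counting for the
length bound, seeded by a greedy tree refined with
nearest-neighbour interchange.  Two shortcuts keep the exact mode
honest and fast:

* every varying character costs at least one change, so a greedy tree
  whose length equals the number of varying characters is provably
  optimal — the typical case for young star-like clades where almost all
  mutations are private;
* when the co-optimal plateau is too large to enumerate (more than five
  million partial evaluations), the search stops, keeps the best tree
  seen, and the result is flagged heuristic rather than exact.

Above the cap a greedy stepwise-addition search plus NNI is used and
flagged as heuristic.  Internal states are assigned by the standard
Fitch second pass preferring the parent state, which makes the labelled
tree deterministic; co-optimal binary topologies are canonicalised
(children ordered by smallest descendant sample id) and deduplicated, and
the number of distinct co-optimal trees is reported.  Edges carry the
variants that change along them; a change that reverts a site toward the
reference state is flagged as a back mutation (rendered with a `!`
suffix, mirroring the underline convention of published trees).
Identical sampled haplotypes each remain a leaf, attached at the same
point with zero-length edges, because the dating statistics count
mtDNAs, not distinct haplotypes.

The test suite verifies exactness against an independent implementation
(phangorn's branch-and-bound on the same binary characters, with the
founder included as an ordinary taxon) over hundreds of random
instances, and verifies that reconstructed leaf states always equal the
observed profiles.

## Haplogroup assignment

The motif table is a rooted hierarchy; each record's defining set is
expressed relative to its parent, and the cumulative set along the
root-to-clade path (with repeated labels toggling, so back mutations in
motifs are representable) is what a member profile should carry.  A
profile is scored against every haplogroup by matched minus missing
cumulative-set variants, counting control-region and coding-region
diagnostics equally and penalising misses 1:1; the best score wins, with
ties broken toward the deeper clade and then lexicographically.  This is
the simplest rule consistent with motif-based clade definitions, and it
is monotone: completing a clade's defining set can never move the call
to a strict ancestor of that clade.

The bundled motif fixture carries the published diagnostics of the
Siberian-specific subclades (e.g. U7a4b = 16150; U2e1i = 16214, 16258,
2626, 5814, 13914, 14587; U2e2 = 8473; U8a2 = 827, 1700; U5a2a1f = 709;
N1a1a1a1a = 16189).  The full ancestral-path motifs of the reference
phylogeny are not reproduced: the intermediate records carry synthetic
placeholder motifs, clearly marked in the fixture's `source` column, so
the fixture supports testing the assignment logic but must not be used
to call real data.

## Rho dating

For a clade with *n* sampled mtDNAs, rho is the mean number of
mutations on the root-to-leaf paths (events, so a mutation plus its
reversion counts twice — the convention of tree-based rho software).
Its standard error comes from the branch structure:
sigma² = Σ over edges of *m*ₑ (*n*ₑ/*n*)², with *m*ₑ the mutations on
the edge and *n*ₑ the leaves descending through it.  Ages are linear in
rho: age = rho × years-per-substitution, with the 95% CI
(rho ± 1.96 sigma) × rate.  Two calibrations are built in: one
substitution per 3624 years for the complete molecule and one per 4610
years for the coding region (nps 577–16023 by the standard convention —
the source literature names only "the coding-region rate", so the
bounds are fixed here as a design choice).  Coding-clock estimates are
computed on a re-projection: the same samples' coding-restricted
profiles are re-built into their own tree, which guarantees the
coding rho can never exceed the complete rho.

Two reporting choices follow the conventions of published tables: the
lower CI bound is *not* truncated at zero (small clades legitimately
print negative lower bounds), and kya values are rounded to two decimals
only at the report-writing layer, never internally.  Published tables of
this kind sometimes show mildly asymmetric CIs, which a symmetric
rho ± 1.96 sigma linear conversion cannot produce; the symmetric linear
rule is what this package implements, and residual differences against
such tables are expected and documented rather than fitted.  Likewise
the coding clock counts all coding substitutions, not synonymous ones
only.

A purifying-selection-corrected (nonlinear) conversion is deliberately
not applied; the clock is exactly the linear rate stated above.

## Phylogeographic origin by nesting

The origin of a clade is read off the tree by the parsimony principle:
walk up from the clade's root; at the first ancestor whose *other*
descendants carry region labels, those labels are the evidence.  Leaves
from the target regions themselves (default "Siberia") are ignored as
evidence.  Under the default unanimity rule a single non-target region
class becomes the origin call; two or more distinct classes give
"ambiguous"; exhausting all ancestors gives "uncertain".  A majority
variant (configurable threshold) is available because expert judgment in
the literature is looser than unanimity; the default stays strict
because it is the most defensible automatic proxy.  Origin labels are
taken per clade and inherited by member genomes, and the summary reports
counts and fractions per label; expert-curated splits from the
literature (e.g. a 37/29/34% western Asia / Europe / ambiguous tally)
rest on per-sample annotations an automatic rule cannot see, so exact
agreement with such tallies is not a goal.

## The simulator and what passing tests mean

`simulateClade()` draws a rooted star or Yule tree with the root at the
true TMRCA, then substitutions on each edge as a Poisson process at rate
1/(years per substitution), sites uniform without replacement within an
edge, 95% transitions by default.  Hotspot indels (default 0.1 events
per lineage) are placed uniformly inside the 303–315 and 16180–16193
windows — exactly the events the exclusion policy must absorb.  Explicit
reversions default to zero events per lineage: the clock model is a
plain Poisson process, and recurrent or back mutations already arise
naturally whenever two edges draw the same site; the explicit knob
exists for targeted tests of back-mutation handling.  Site-rate
heterogeneity beyond the indel hotspots is deliberately absent, because
the dating model being validated assumes a homogeneous clock.  Region
labels are painted on simulated leaves so the phylogeographic stages can
be tested deterministically.

The recovery experiment runs the full pipeline (calling, filtering,
tree, dating) over a grid of star clades — TMRCA 2, 5 and 10 kya by
n = 5, 10 and 20, 300 replicates per cell — and checks that the mean
age is unbiased within 10% and that the 95% CI covers the truth in
90–98% of replicates per cell.  These sizes keep the whole experiment
within a few minutes on one core while leaving Monte-Carlo error well
below the tolerances.  What a pass shows: the estimator chain is
internally calibrated for data generated under its own assumptions.
What it does not show: robustness to rate heterogeneity among sites,
selection, heteroplasmy, sequencing error, or non-random sampling of
real populations — none of which the simulator emulates.

## Numerical and degenerate-input choices

* Alignment cost ties are resolved by a fixed traceback preference and
  then 3'-normalisation, so calling is deterministic.
* A clade consisting of a single sample identical to its founder dates
  to 0 ± 0; the founder always remains the tree root even when sampled.
* Sequences shorter than 15 kb are rejected (or downgraded to a warning
  by configuration) as incomplete mitogenomes.
* Exact-search taxa are capped at 12 distinct haplotypes by default;
  the flag on the tree object records whether the result is exact.
* All report writers are deterministic; identical inputs give
  byte-identical bundles.
* The bundled reference is a synthetic rCRS-like sequence (correct
  length, coordinate frame and hotspot-tract structure, arbitrary bases
  elsewhere, deterministically generated); analyses of real GenBank
  mitogenomes must load the true rCRS instead.

## Known limitations

* The MP search optimises over binary presence/absence characters, so a
  site that mutates to two different derived bases in one clade is
  approximated by two characters only if both labels occur; triallelic
  sites within a clade are rare at these time depths but not impossible.
* Heteroplasmy and mixed bases are not modelled; ambiguity codes are
  silenced, not interpreted.
* The origin classifier is a reproducible proxy for expert judgment,
  not a replacement: it sees only leaf region labels and tree shape.
* Rho dating inherits the known statistical weaknesses of the rho
  statistic (sensitivity to sampling and to rate heterogeneity); this
  package reproduces the published procedure rather than improving on
  it.
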