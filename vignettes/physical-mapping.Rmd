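---
title: "Clone-based physical mapping and paired-end structural comparison with BACmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-based physical mapping and paired-end structural comparison with BACmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BACmap)
```

## The problem

Before cheap long reads, chromosome-scale order in large plant genomes came
from clone-based physical maps: libraries of bacterial artificial
chromosomes (BACs) carrying ~75-225 kb inserts, fingerprinted by
restriction digestion, clustered into contigs by fingerprint similarity,
and anchored to a draft sequence through BAC end sequences (BES). The same
clone resource supports two further analyses that this package implements
as one pipeline:

* **minimum tiling path (MTP) selection** — choosing an ordered subset of
  clones that covers each chromosome with as few clones and as little
  overlap as possible, and extending coverage into assembly gaps with
  clones that have only one usable end sequence; and
* **paired-end structural comparison** — aligning the BES of a second
  genome's library (for instance a crop's wild relative) against the
  reference and reading insertions, deletions, inversions and
  translocations out of discordant span and orientation.

Real maps of this kind are built from hundreds of thousands of clones on a
~1 Gb genome. The package reproduces the *method* at desk scale: a
synthetic-data module generates a reference genome with assembly gaps, a
rearranged sister genome with a known truth set, and BAC libraries with
the statistical structure the analysis assumes, so that every stage runs
and is testable with no external data.

## The simulation model

`makeReference()` draws i.i.d. bases at a set GC fraction (default 0.35,
typical of legume genomes). `makeRandomGaps()`/`injectGaps()` mask
intervals with N following the draft-assembly convention: a run of exactly
1000 N is a scaffold-join gap, 100 N a gap of unknown size, any other run
a sized gap; `writeAGP()` serializes the same structure as AGP v2.0.

`deriveVariantGenome()` plants insertions (novel random sequence),
deletions, inversions (reverse complement in place) and reciprocal
translocations (equal-length block swaps). Events must be separated by at
least twice the maximum insert so that no clone can overlap two events —
a simulation constraint that keeps truth labels unambiguous, not a claim
about real genomes. Truth events stay in reference coordinates (the frame
in which all calls are made); variant-genome coordinates are returned as
bookkeeping.

### Clone inserts: partial digest plus size selection

A BAC insert is a fragment of a *partial* restriction digest: each
recognition site is retained independently with probability
`partialDigestProb`, so the fragment from a given site ends at the first
retained site downstream. Under this Bernoulli model the fragment length
is geometric and memoryless, which has a consequence worth spelling out:
no retention probability can concentrate accepted lengths around the
150 kb library mean — conditioning a memoryless law on \[75, 225\] kb
always leaves a decreasing density with its mass near 75 kb. Real
protocols solve this on a pulsed-field gel by excising the target size
fraction, and the simulator does the same: candidate fragments are
accepted only inside \[`insertMin`, `insertMax`\] and are additionally
thinned with a Gaussian weight centred on `insertMean` with standard
deviation `sizeSelectSD` (default 20 kb). The defaults
(`partialDigestProb = 0.02`, so the unconditioned fragment mean for a
6-cutter sits well above the window and the window itself is roughly
uniformly proposed) give accepted inserts of ~148 kb with ~20 kb spread.
That concentration is not cosmetic: the paired-end span window can only
resolve structural events larger than the insert-length spread, so a
library without size selection would blur the detectability threshold
that the structural scan relies on.

Three reference libraries are simulated with HindIII (AAGCTT), BstYI
(RGATCY) and EcoRI (GAATTC), clone counts proportional to a 5.4x/12x/
10.9x coverage design; the query library uses HindIII, as is typical for
a single-enzyme library of a wild relative. Only a fraction of clones
(`fingerprintedFrac`, default 0.6) is fingerprinted, mirroring the usual
practice of fingerprinting library subsets — this is what makes clone
pool A (map members) a strict subset of pool B (all clones with BES) and
gives the four-MTP comparison its substance.

`extractBES()` returns the first and last `besLen` (600) bases of each
insert, the right end reverse-complemented, so a correctly placed pair
points *toward* each other. With probability `besSingleEndProb` (default
0.024, the observed fraction of single-end clones in libraries of this
type) only one end, chosen uniformly, survives.

`fingerprintClones()` performs a complete digest of the insert, perturbs
each fragment size multiplicatively by Normal(1, `sizingCV`) and drops
fragments below `bandDetectMin` (600 bp), the practical detection floor
of agarose fingerprinting.

## Fingerprint assembly

Two fingerprints are compared by `matchBands()`: greedy one-to-one
matching on the sorted band lists, two bands matching when they differ by
at most `tolerance` (7 bp). The evidence that two clones overlap is the
classical Sulston probability of coincidence: with $n_L \le n_H$ the two
band counts, each of the $n_L$ bands finds a chance partner among $n_H$
bands with probability

$$q = 1 - \left(1 - \frac{2\,\mathrm{tol}}{G}\right)^{n_H},$$

where $G$ is the number of distinguishable band positions (`gelSpace`,
3600), and the score is the binomial upper tail $P(X \ge m)$ at the
observed match count $m$. Low scores mean the sharing is unlikely by
chance. `clusterContigs()` joins every pair scoring at or below `cutoff`
(default $10^{-12}$, the conventional stringent setting) and takes
connected components — single-linkage joining, as fingerprint-mapping
software does at a fixed cutoff. Components of one clone are singletons.
A shared-band-bucket prefilter skips pairs that cannot reach even a
handful of matches; tests assert it is equivalent to exhaustive scoring.

Clone order within a contig comes from greedy seriation: seed with the
best-matching pair, repeatedly append the unplaced clone with the highest
match count to either end, and set each clone's consensus-band (CB)
offset to its neighbour's offset plus the neighbour's unshared band
count. This defines CB units in spirit (one unit per band) rather than
reproducing any particular software's full consensus-band algorithm; all
ties break on lexicographic clone id, making the result deterministic and
invariant to input order up to mirror image.

One interaction deserves honesty: the match tolerance is *absolute*
(7 bp) while sizing noise is *multiplicative*, so at the default
`sizingCV = 0.005` only bands below roughly 2 kb match reliably and the
assembled map is singleton-heavy. The package keeps both conventions
because each is standard in its own domain; planted-map recovery is
demonstrated (and tested) at `sizingCV = 0`, where the assembly recovers
true overlap chains with no false joins, and noise sensitivity is itself
a documented behaviour, tunable through `tolerance`/`sizingCV`.

## Anchoring and contig merging

`alignBES()` matches each read and its reverse complement exactly against
the (gapped) reference through a preprocessed dictionary; reads with no
match or more than one distinct locus are discarded. Synthetic reads have
no sequencing error, so exact matching is lossless here; dropping
ambiguity rather than placing reads randomly keeps every placement
deterministic and conservative. `placeClones()` classifies each clone as
`no_end`, `one_end`, `both_diff_chrom` or `both_same_chrom`, records the
outermost span, and compares the strands of the left and right hit *by
coordinate* (F/R labels are not trusted): `toward` is the expected
geometry, `same_direction` and `opposite` are the discordant classes.

A contig anchors to a chromosome when at least 2 placed members exist and
at least 80% of them agree on one chromosome (both thresholds are
arguments); its position is the median span midpoint and its orientation
the sign of the Spearman correlation between contig order and reference
position. Anchored contigs that are adjacent on a chromosome with at most
`maxJoinGap` (150 kb, the mean insert) between their span extents merge,
transitively, concatenating clone orders with orientation respected.

## Tiling paths

Placed-clone spans on a chromosome are unioned into *coverage islands*
(overlap of at least 1 bp; abutting half-open spans do not merge); breaks
between islands are the map's internal gaps. Within an island,
`pickMTP()` solves a shortest-path problem: one node per clone, an edge
$u \to v$ whenever $v$ starts strictly inside $u$ and extends past it,
with weight $W + \mathrm{overlap}(u,v)$ where the constant $W = 10^7$
exceeds any possible overlap. Minimising total weight therefore minimises
clone count first and total overlap second — a lexicographic objective
encoded in a single scalar weight, whose exactness the tests assert
against brute-force enumeration. Because every edge increases both start
and end, the graph is a DAG and the optimum is computed by dynamic
programming in start order (equivalent to Dijkstra on this graph), with
ties broken on the lexicographic clone-id sequence so the chosen path is
unique and reproducible. Clones with identical spans are deduplicated to
the smallest id before the search.

Four path variants mirror the two-pools-times-two-BES-sets design: pool A
(clones in the fingerprint map) or pool B (all clones with BES), each
with paired ends only or additionally extended by unpaired-end clones.
`augmentWithUnpaired()` credits a one-end clone into a gap when its
single hit lies within `edgeWindow` (150 kb) of the gap edge on the
covered side and its strand points into the gap; the credited extension
runs `assumedInsert` (150 kb) from the hit's inner edge into the gap,
truncated at the far side, and only the longest extension per gap is
kept, preserving minimality. Coverage accounting is pure interval union,
so nothing is double-counted; a gap counts as remaining only if no
credited extension enters it. "Gaps" in the per-path statistics are
inter-island breaks; uncovered chromosome ends appear in the coverage
table instead — the least surprising reading where the convention is
unstated.

## Structural-difference scan

For same-chromosome pairs the span classes are: `in_range` (75-225 kb),
`too_short` (insertion candidate, estimated size `expectedInsert` − span),
`too_long` (deletion candidate, span − `expectedInsert`), and `artifact`
(span > 1.5 Mb, excluded). The size estimator uses the library mean
because a clone's own insert length is unobservable; it is therefore
exact only on average, with the insert-length spread as its error.
Interchromosomal pairs are translocation candidates.

When orientation is abnormal (`same_direction`/`opposite`) and the span
is not an artifact, the call is an **inversion**, even if the span is
also outside the window. The alternative — letting the span verdict win —
misclassifies clones straddling an inversion breakpoint, whose span is
`inv_size + insert − 2d` for breakpoint offset `d` and thus frequently
lands outside the window; orientation is the specific discordant-pair
signature of an inversion and takes precedence here (the span class is
still recorded on the call).

Candidate calls are collapsed into loci by interval union per type, each
locus contributing its maximum size estimate once; genome flux is the
locus-size total over insertions and deletions — a lower bound, since an
indel smaller than `spanMax − insertMean` (or `insertMean − spanMin`),
i.e. ~75 kb at defaults, leaves the span inside the window and is
invisible. Note the asymmetry for insertions: an insertion larger than
the insert length cannot be spanned at all (one read lands in novel
sequence), so detectable insertions occupy a band between ~75 kb and the
insert length. `evaluateAgainstTruth()` scores a locus as a true positive
when it overlaps a same-type truth interval; translocation read loci are
first extended by the expected insert in the read's pointing direction,
because the breakpoint lies within one insert of either read.

## Markers

`tallyMarkers()` counts, per genetic marker, distinct clones hit and
distinct contigs of those clones (singleton clones add clones but no
contig). Markers hitting two or more clones are multiple-hit markers
(MHM), subclassified `multi_contig` (two or more contigs — the reading
under which the published class counts are internally consistent),
`single_contig_multi_clone`, or `multi_singleton`. `markerTable()` bins
contig counts as 0/1/2/>2 and clone counts as 1/2-4/5-9/>=10, the only
partition consistent with the conventional report layout.

## Numerical conventions

* Coordinates are 0-based, half-open everywhere internally; AGP output
  and printed tables convert to 1-based inclusive.
* Every simulation operation is a pure function of (inputs, seed): the
  RNG state is saved and restored around each draw, and the pipeline
  derives per-stage seeds from the master seed, so reruns are
  byte-identical.
* Reported percentages round half-up (`percentOf()`), the convention
  that matches how such tables are conventionally printed.
* All ties (clustering labels, seriation, path choice, identical spans,
  anchor chromothreshold ties) break on lexicographic ids.

## Problem sizes and what the tests show

The packaged study uses a 2 x 5 Mb genome, ~670 reference clones (10x
clone coverage in three libraries), ~670 query clones, 10 scaffold-join
gaps, and the planted event set of `defaultSVEvents()` (120-200 kb
indels, two 100 kb inversions, one 150 kb translocation, and 20 kb
indels that must stay invisible). The test suite checks, among others:
exact Sulston-score values and Monte-Carlo band-placement agreement;
tiling-path equality with brute-force enumeration on 200 random islands;
no false joins and >= 95% co-contiging of substantially overlapping
clones at noise-free settings; deletion/translocation precision and
recall >= 0.9 with 20 kb recall <= 0.1; monotonicity of the four path
variants; and byte-identical pipeline reruns.

Passing these tests shows the *algorithms* behave as specified on data
satisfying the generator's assumptions. The generator deliberately omits:
repetitive DNA and segmental duplication (the main cause of ambiguous BES
placements and chimeric joins in real maps), cloning bias and chimeric
clones, sequencing error in BES, gel-calling artifacts beyond Gaussian
sizing noise, and polyploid homeology (which confounds real translocation
calls). Results on real libraries will be correspondingly noisier, and
the exact-unique alignment policy would need to be replaced by a mapper
with mismatch tolerance and a repeat-aware multi-hit policy.
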