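---
title: "Calling and genotyping structural variants from whole-genome assembly alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and genotyping structural variants from whole-genome assembly alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svnet)
```

## The problem

High-quality genome assemblies make it possible to call structural
variants (SVs) by aligning whole assemblies against a reference rather
than mapping reads.  Doing this across a *population* of assemblies
raises three problems that read-based callers do not have:

1. a whole-genome aligner reports many local alignments, including
   paralogous ones, and large SVs are scattered across fragmented
   alignment pieces;
2. the same SV called independently from different samples has slightly
   different breakpoints, so per-sample callsets must be merged into one
   non-redundant site list; and
3. a sample in which an SV was *not* called is not automatically
   reference-genotype — the locus may be unaligned, diverged or missing
   from the assembly, so every merged site must be re-genotyped in every
   sample before the callset is usable for population genetics.

`svnet` implements the full path: alignment normalization, chain/net
construction, SV calling (six classes), cross-sample merging,
re-genotyping, mechanism annotation, and simulators plus benchmark
metrics that make the pipeline verifiable end-to-end on synthetic data.

## Chains and nets

All alignments are normalized to blocks with 0-based half-open
coordinates and query coordinates on the forward strand.  *Chains* are
maximal collinear runs of blocks on one (reference, query, strand)
triple, built by best-predecessor dynamic programming: block $i$ joins
chain end $j$ when $\mathrm{dp}_j - w(\mathrm{gap}_{ji}) > 0$, where $w$
is a concave, piecewise-linear gap cost with separate tables for
one-sided and two-sided gaps.  The DP kernel is exact (quadratic, in
C++) rather than the heuristic ordered-map search common in chaining
tools; at the block counts this package targets (up to tens of
thousands per genome pair) the exact kernel is both faster and free of
tie-break ambiguity.

The default cost table (`gap_cost_model()`) rises quickly for small gaps
and plateaus at 1,000 score units for gaps beyond 10 Mb.  The plateau is
the load-bearing choice: a deletion of tens of kilobases must remain a
*gap inside one chain* — that gap is exactly the SV signal — so its
cost must stay below the alignment score accumulated on either side.
With the default unit block scores, any gap is bridgeable once roughly
a kilobase of aligned sequence flanks it.

*Nets* organize chains hierarchically under single reference coverage:
chains are inserted best-first, claim the reference bases their blocks
newly cover (at least `min_space = 1` base), and a chain landing inside
the gap of an already-placed chain becomes a *child fill* of that gap.
Child fills are classified by query placement relative to the parent's
local query gap: same sequence and strand → `syn`; same sequence,
opposite strand, within `max_dist` (default 1 Mb) → `inv`; anything
else → `tra`.  `filter_synnet()` keeps top fills and `syn` children
always; under the `top_plus_rearrangement` policy it additionally keeps
`inv`/`tra` fills covering at least half their parent gap (both knobs
configurable — the retention rule for paralogous secondary alignments
is a design choice of this package, stated here rather than inherited
from any reference implementation).  `project_single_coverage()` then
trims the retained fills so that no base of either genome is aligned
twice, higher-scoring chains winning ties; this single-coverage segment
set is the substrate for SNV calling and for all genotyping.

## Variant calling

Within a retained chain, each inter-segment gap is read off directly:

| ref gap $d_r$ | query gap $d_q$ | call |
|---|---|---|
| $>0$ | $0$ | deletion of $d_r$ |
| $0$ | $>0$ | insertion of $d_q$ |
| $>0$ | $>0$, $\min < 20$ | deletion *and* insertion (unbalanced substitution) |
| $>0$ | $>0$, $\min \ge 20$ | complex locus (CPX) |

The 20 bp boundary (`cpx_min`) keeps small-indel recall at loci where a
few bases were replaced, while refusing to call alignment no-man's-land
as indels; CPX calls are reported in a separate stream and excluded
from merging and genotyping.  Events of 50 bp and larger are class
`sv`, smaller ones `indel`.

Inversions and translocations are emitted per retained `inv`/`tra`
fill.  Tandem duplications are called from reference multi-coverage: a
secondary chain mapping a distinct query interval onto a reference unit
already covered at reciprocal overlap ≥ 0.8.  A tandem duplication
necessarily also leaves an insertion-shaped gap in the top chain (the
extra copy's bases); the caller suppresses insertion calls whose
breakpoint lies within 50 bp of a called duplication unit boundary and
whose length matches the unit within 20%, so one biological event is
reported once, as DUP.  Chain gaps explained by a child fill (an
inversion sitting in its parent's gap, say) are likewise suppressed.

## Merging and re-genotyping

Deletions, inversions, duplications and translocations merge by
single-linkage clustering over the relation "reciprocal overlap ≥ 0.9"
after coordinate sorting (translocations additionally require the same
donor chromosome).  Insertions — which have zero reference span — merge
when breakpoints differ by ≤ 12 bp, lengths by ≤ 20% and inserted
sequences align end-to-end at ≥ 50% identity.  The cluster
representative is the member of median length (ties: smaller start);
representatives are always actual member calls, never synthetic
coordinates.  Single-linkage closure means chains of pairwise-mergeable
events can merge transitively; with well-separated events this never
triggers, and the idempotence property (`merge(merge(X)) == merge(X)`)
is part of the test suite.

Re-genotyping classifies every merged site in every sample as
`ALT`/`REF`/`MISSING` from the ±2 kb local alignment window:

* **Deletions**: ALT when the window contains a reference-side gap with
  reciprocal overlap ≥ 0.5 against the site; REF when aligned columns
  cover the site with residual gap ≤ half the site length; MISSING
  otherwise.  The REF criterion is this package's own choice — some
  explicit continuity rule is needed and none is standard.
* **Insertions**: the single-coverage alignment restricted to the
  window *is* a global alignment of the window, so the pipeline reads
  the insertion run directly from it and verifies length (±20%) and
  inserted-sequence identity (≥ 50%, exact-match fast path).  When that
  evidence is absent or ambiguous, `genotype_insertion()` realigns the
  two windows globally (unit substitution scores, affine gap open 16 /
  extend 4 — the classic Stretcher parameterization) and applies the
  same decision rule.  The two routes agree whenever the whole-genome
  alignment covers the window; the realignment route costs
  $O(\mathrm{window}^2)$ per site-sample pair and is therefore the
  fallback, not the default.
* **Small indels** (< 50 bp): ALT on an indel of matching sign and
  length (±20%) within 12 bp of the site; REF on continuous alignment.
* **DUP/INV/TRA**: ALT by call membership; REF when the window aligns
  continuously; MISSING otherwise.  (No realignment-based genotyper is
  defined for these classes; membership plus coverage is the decision.)

Genotypes are written as homozygous diploid (`1/1`, `0/0`, `./.`) —
assemblies are haploid consensus sequences.  Windows overlapping runs
of ≥ 10 N in the query return MISSING rather than an error.

## Mechanism annotation

Deletion/insertion sequences are compared to (i) their immediate flanks
(window of one SV length each side): identity ≥ 0.8 over ≥ 0.8 of the
SV length labels the site TANDEM (expansion or contraction); (ii) a TE
library and (iii) a CDS library by local alignment: best hit covering
≥ 0.5 of the SV at identity ≥ 0.8 labels TE or GENE.  All thresholds
are exposed; precedence TANDEM > TE > GENE decides the primary label,
all passing labels are kept in `MECH_ALL`.  The aligner is
`Biostrings::pairwiseAlignment` with an exact-containment fast path,
which is ample at desk scale; large libraries can be pre-screened with
an external mapper and the hits fed back in.

## The simulators, and what they do and do not emulate

`make_genome()` draws iid nucleotides at a configurable GC content
(default 0.42) and implants copies of a small random repeat library up
to a target repeat fraction.  `simulate_svs()` places events uniformly
at random, largest first, rejecting overlaps, keeping a minimum
spacing (default 500 bp) and a 1 kb margin from chromosome ends, and
avoiding N runs; sizes are log-uniform within the configured range
(real SV size spectra are heavy-tailed, and a uniform draw would make
the mean event enormous).  Insertions are TE-derived with probability
0.3 by default, sampled from the planted library.  `simulate_population()`
builds the 0/1 genotype matrix — each of the first $n-1$ genomes
carries each event with probability 0.5, genome $n$ carries all — and
`simulate_divergence()` adds iid substitutions and geometric small
indels (mean 3 bp) shared by all population genomes, emulating a
reference that diverges from the population backbone.  Divergence edits
within 20 bp of an event carried by a genome are dropped for that
genome, and duplicated units are inserted un-diverged, so planted truth
coordinates stay exact; this is what lets the benchmarks assert exact
recovery rather than fuzzy agreement.

`edits_to_alignment()` emits the *exact* alignment implied by an edit
script, so every downstream module can be tested without running an
external aligner.  This is the deliberate boundary of what the
synthetic data shows: passing benchmarks demonstrate that chaining,
netting, calling, merging and genotyping are correct *given a faithful
alignment*.  They do not exercise aligner failure modes — repeat-induced
mis-mapping, soft-clipped breakpoints, chimeric contigs — and accuracy
on real assemblies is bounded by the aligner's, not the pipeline's.
Nested TE insertions and heterozygous (phased diploid) assemblies are
out of scope.

## Benchmark protocols and problem sizes

`benchmark_detection()` and `benchmark_population()` are the two
evaluation protocols, sized to run on one CPU in minutes: a 5 Mb
two-chromosome reference with ~1,000 planted DEL/INS/DUP of
50–10,000 bp and 21 genomes for the population design (with 2%
substitutions + 0.2% indels and ~300 extra 5–49 bp indels in the
divergent variant), and 300 deletions (50 bp–4 kb), 200 insertions
(50 bp–2 kb), 20 duplications and 5 inversions for the detection
design.  Truth matching uses 80% reciprocal overlap for detection and
50% for the population design; insertions match by the ±12 bp /
±20%-length rule, since reciprocal overlap is undefined for zero-span
events.  Sites reported by more than 19/21 of samples are excluded as
pre-existing background — unless the reference is the genome the
events were planted on, in which case no background exists and the
filter is bypassed.  Completeness is TP over planted events, accuracy
TP over predictions, error FP over predictions; per-sample genotyping
accuracy/error/missing are computed over true-positive sites against
the planted matrix.  `scripts/acceptance.R` reruns all three protocols
from scratch and writes the headline numbers as JSON.

## Numerical and degenerate-input choices

* Chaining ties (equal DP gain) prefer the predecessor with the
  smaller total gap; block order is canonicalized before the DP, so
  chaining is independent of input order.
* Coordinates are validated against declared sequence sizes at parse
  time; AXT minus-strand records need explicit query sizes because the
  format omits them.
* Merging an empty callset, netting an empty chain list and genotyping
  an empty window are all defined (empty results / MISSING), never
  errors; zero-length intervals in reciprocal overlap are errors.
* PAF records without a `cg:Z` cigar are kept for chaining but excluded
  from base-level operations and counted in a parser attribute.
* All generators are pure functions of their seed; the RNG state of the
  caller is saved and restored around every simulation call.
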