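---
title: "Mapping balanced translocation breakpoints from mate-pair data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping balanced translocation breakpoints from mate-pair data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mateSV)
```

## The problem

An apparently balanced translocation (ABT) is a reciprocal exchange of
segments between two non-homologous chromosomes with no visible net gain or
loss of material. Karyotyping localizes the two breakpoints to a band
(megabases); clinical interpretation — is a gene disrupted? is a regulatory
landscape broken? is the event even related to the phenotype? — needs the
breakpoints to the nucleotide. Whole-genome mate-pair sequencing (WG-MPS)
gets there in two stages: long-insert read pairs first localize each
junction to a window of tens to hundreds of base pairs, and a sequence read
across the junction then resolves it to the base, exposing the
microhomology, small deletions/duplications and untemplated insertions that
are the fingerprints of the repair mechanism that formed the translocation.

mateSV implements this pipeline end to end, together with a deterministic
simulator that generates mate-pair data with full ground truth, so every
stage is validated by recovery rather than by inspection.

## Data model

All coordinates inside the package are 1-based and inclusive at both ends,
so a printed junction interval like `chr1:18163342–18163563` has width
`end − start + 1 = 222`. BED and BEDPE files are converted from their
0-based half-open disk convention exactly once, at the reader/writer
boundary. Genomes are `Biostrings::DNAStringSet` objects over A/C/G/T/N; an
`N` never matches anything, including another `N` — the conservative choice
for microhomology calling. Everything else — aligned pairs, SV predictions,
refined junctions, annotation tracks, reports — is a tibble, so the
pipeline composes with ordinary dplyr verbs.

## The mate-pair signal and its simulation

A mate-pair library circularizes 2–4 kb fragments and sequences 100 bp from
either end, so one pair of reads brackets a long genomic span. The
simulator draws inserts from a truncated normal (mean 3000 bp, sd 400 bp,
hard bounds 2000–4000 bp) and places fragments uniformly on the *derivative*
genome; each fragment is reported as one post-alignment record against the
reference. Fragments wholly inside one reference segment give concordant
pairs; fragments spanning a derivative junction give pairs whose mates map
to the two partner chromosomes. Reads whose alignment would cross the
junction itself are not emitted (an aligner would clip or split them), which
makes the expected number of junction-spanning pairs per junction

$$\lambda \;=\; n_\text{pairs}\,\frac{\mu_I - 2\ell}{G}
  \;=\; c\,\frac{\mu_I - 2\ell}{\mu_I},$$

with $\mu_I$ the mean insert, $\ell$ the read length, $G$ the genome size
and $c = n_\text{pairs}\mu_I/G$ the physical coverage. The suite verifies
this expectation to within three standard deviations over twenty seeds.

Two nuisance processes are modelled because the pipeline must remove them:
PCR duplicates (exact coordinate copies appended at a configurable rate,
default 5%) and multimapping reads (declared repeat spans are filled with a
tiled motif, and reads starting inside them carry a non-unique flag with
probability $1 - 1/\text{copies}$).

The default physical coverage is 20×. At that depth $\lambda \approx 19$,
which places simulated junction support in the 12–26 read-pair range
reported for sequenced ABT junctions, comfortably above the ≥ 5-pair filter.
Mate orientation after alignment is convention-dependent; both the
processed mate-pair dialect (`outward`: fragment-start mate on the minus
strand) and the paired-end dialect (`inward`) are supported, and the
detector reads the convention from the configuration rather than assuming
an aligner.

## Engineering junctions with realistic micro-features

`rearrangement()` describes a reciprocal translocation by its two cut
positions plus junction features: requested microhomology per junction,
untemplated insertion per junction (mutually exclusive with microhomology),
and a per-chromosome indel (positive = deletion, negative = duplication).
Microhomology is engineered by rewriting reference bases so the two partner
references genuinely share the run — the downstream placement ambiguity is
mathematically real, not cosmetic. A repair loop then mutates
junction-adjacent bases to break chance homology extensions, so that
wherever the request is jointly feasible the realized signature equals the
request exactly.

Not every request is feasible. In a fully balanced junction the two
derivatives juxtapose the same two reference positions, so both junctions
physically share one microhomology string — requesting 3 bp at one junction
and 7 bp at the other is contradictory. Similarly a duplication no longer
than the microhomology at the same junction can be absorbed into an
equivalent microhomology reading of the identical derivative sequence.
The truth record therefore always stores the *realized* features, computed
by direct maximal extension at the known engineered coordinates (a code
path independent of the anchor-search refinement), plus an `engineered_ok`
flag stating whether realized equals requested at the engineered placement.
Recovery is scored against realized truth, which is the only
well-defined ground truth the derivative sequences support.

## Detection: classify and cluster

After removing pairs with any non-unique mate and collapsing coordinate
duplicates (the support threshold is applied *after* deduplication —
duplicates are not independent evidence), each pair is classified:
`interchromosomal`, else `orientation_anomaly` against the library
convention, else `insert_anomaly` outside the configured bounds, else
concordant. Discordant pairs are clustered by single linkage within groups
of identical chromosome pair and orientation (mixed orientations are never
merged — that is what separates der(A)-junction pairs from der(B)-junction
pairs), with linkage distance defaulting to the upper insert bound: a pair
cannot span farther than its insert.

Each cluster's junction interval is the intersection of per-pair
constraints. A fragment-start mate at position $p$ confines its breakpoint
to $[p + \ell - 1,\; p + I_{\max} - \ell - 1]$; a fragment-end mate at $q$
confines the partner resume point to $[q + 2\ell - I_{\max},\; q]$.
Intersecting over the cluster tightens the interval as support grows
(monotonicity is property-tested), and the truth breakpoint is contained by
construction; if noise ever empties the intersection the cluster falls back
to the span of inner read ends. Both regimes occur in practice — published
junction windows range from tens of base pairs to over a kilobase.

## Refinement: split alignment of the junction sequence

The sequence across a junction (in this package extracted from the
simulated derivative, standing in for a junction-spanning amplicon) is
anchored on both partners: its first `anchor` bases (default 20) must match
the prefix partner uniquely, its last `anchor` bases the suffix partner
uniquely — a repeat-mediated ambiguous anchor raises an explicit
"unanchored junction" error rather than a guess. Both alignments are then
extended maximally. With window length $n$, maximal prefix extension $L$
and maximal suffix extension $R$:

* $L + R > n$: the overlap of length $L + R - n$ is **microhomology**; the
  breakpoint is ambiguous over $L + R - n + 1$ placements. The refinement
  reports the maximal-prefix placement together with the ambiguity width;
  leftmost normalization is then a subtraction, and tests compare
  leftmost-normalized breakpoints.
* $L + R = n$: a **blunt** junction.
* $L + R < n$: the middle $n - L - R$ bases are an **untemplated
  insertion**.

Extension is exact by default (the input stands in for Sanger-grade
sequence); a mismatch-tolerant mode (at most one mismatch per 50 bp,
never ending on a mismatch) handles error-bearing input. For windows up to
300 bp the suite checks the split alignment against an oracle that
enumerates every prefix/insert/suffix decomposition of the window.

## Reconciliation: two junctions, one event

The two derivative junctions of a reciprocal translocation are refined
independently and then reconciled per original chromosome. Each junction is
fixed at its canonical placement — the maximal prefix extension, with the
coupled resume point `suffix_start_min + mh` (microhomology slides both
sides of one junction together). Bases between the two canonical
breakpoints are a deletion; bases retained by both canonical retentions are
a duplication. This cross-derivative comparison is what distinguishes a
duplication (evidence from both derivatives) from microhomology (evidence
within one junction), and microhomology never shortens a reported indel.
Indel strings are read from the reference plus strand.

The per-chromosome breakpoint interval spans from the last base retained by
one derivative to the first base retained by the other: a $k$ bp deletion
prints a $k+2$ bp interval, a balanced junction a 2 bp interval, and a
$k$ bp duplication its own $k$ bp span. An alternative, placement-free
convention (bases retained under *no* placement) was considered and
rejected: it shrinks a deletion by the partner junction's microhomology
length, which contradicts how published junction tables report a deletion
and its microhomology side by side.

## Filtering and family comparison

Three filters reduce predictions to credible, patient-specific candidates,
each emitting a disposition for every input (the report partitions the
input; `filter_report()` retrieves it):

* **Support**: at least 5 independent read pairs, counted after
  deduplication.
* **Known variants**: an intrachromosomal prediction is removed when a
  same-type catalogue record overlaps ≥ 80% of it. The fraction is measured
  of the prediction (`of_a`) because the source phrasing ("variants
  overlapping by ≥ 80%") does not state reciprocity; reciprocal mode is a
  flag. Interchromosomal predictions are never matched by interval records.
* **Family**: the affected member's predictions are retained only if no
  same-type prediction exists in any other member within a positional
  tolerance (default: the clustering distance) on both partners. Tolerance
  rather than exact matching, because interval estimates jitter between
  members even for the identical event — the refined breakpoints, not the
  cluster intervals, are what must agree exactly.

Family concordance is then assessed on the refined junctions:
`compare_family()` returns `identical` only when breakpoints,
microhomology, insertion and indel strings all match exactly, and
enumerates every differing field otherwise.

## Annotation and mechanism

Gene disruption is assessed at the midpoint of the refined breakpoint
interval (those intervals are ≤ 7 bp in practice, so midpoint error is
negligible; intervals straddling an exon boundary are flagged ambiguous),
with exon/intron indices in transcription order — strand-aware, so intron 1
of a minus-strand gene lies at the high-coordinate end. Repeat annotation is
strict interval overlap with labels passed through; conserved non-coding
elements (CNEs) are collected in a closed ±1 Mb window ("up to 1 Mb" read
as inclusive) as a long-range position-effect screen.

Mechanism classification turns a narrative argument into a reproducible
rule with documented, tunable thresholds: a shared stretch of ≥ 50 bp at
≥ 90% identity (local alignment) within 500 bp of both partner breakpoints
supports NAHR; failing that, junction microhomology ≥ 2 bp indicates
microhomology-mediated repair (MHMR/MMEJ); blunt junctions, 1 bp homology,
untemplated insertions or small indels indicate NHEJ. The defaults are
declared parameters, not inferred constants — the underlying qualitative
argument carries no numbers — and classification is monotone in the
microhomology threshold by construction.

## What the simulator does and does not emulate

It emulates: multi-chromosome references; reciprocal translocations with
engineered microhomology (0–10 bp), per-chromosome deletions/duplications
(0–10 bp) and untemplated insertions; truncated-normal 2–4 kb inserts read
as 100 bp pairs in either orientation convention; PCR duplicates;
repeat-driven multimapping; decoy intrachromosomal SVs with a partially
overlapping known-variant catalogue.

It does not emulate: raw reads with quality strings (records are
post-alignment, coordinates truthful — alignment itself is out of scope);
GC or coverage bias; chimeric library artefacts; inversions or complex
multi-way rearrangements at the junction level (they are classified but not
refined); heterozygosity (the derivative genome is sequenced as if
homozygous, which only rescales coverage for breakpoint purposes). Passing
tests therefore demonstrate correctness of the algorithms under clean
alignments, not robustness to every artefact of a real library.

## Numerical and design choices

* Problem sizes used by the test-suite recovery experiments: a
  3 × 2 Mb genome at 10× physical coverage over 25 seeds for end-to-end
  breakpoint recovery; 200 random rearrangement specs on 2 × 30 kb genomes
  for signature recovery and oracle equivalence; 1000 random predictions
  for filter/brute-force agreement.
* Seeds: every stochastic operation derives its stream from the
  configuration seed with small fixed offsets; reruns are byte-identical,
  and `with_seed()` never disturbs the caller's RNG state.
* The clustering union-find is exercised against a brute-force
  connected-components oracle for up to 200 pairs.
* Junction windows default to 400 bp — at least twice the largest feature
  plus anchor margin; windows reaching past a chromosome end are truncated
  with a warning.
* Anchor length 20 bp balances uniqueness (expected chance hits
  $\approx G/4^{20} \ll 1$ for genomes well beyond this package's scale)
  against tolerance of features near the window edge.
* `run_pipeline()` is deterministic given the seed and rewrites
  byte-identical intermediates; a stage failure aborts with the failing
  stage named and earlier outputs retained.

## Limitations

Only the prefix+suffix ("cis") junction orientation is refined; inverted
junctions would need reverse-complement split alignment. The known-variant
filter matches by type and interval only, with no size-similarity
requirement. Mechanism calls are rule-based proxies, not probabilistic
assignments. The SAM adapter ingests plain-text SAM only — BAM/CRAM belong
to the alignment stage, which this package deliberately starts after.
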