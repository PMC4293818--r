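---
title: "Designing taxon-specific mini-barcodes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing taxon-specific mini-barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibarcodes)
```

## The strategy

Chloroplast genomes of congeneric plants diverge slowly (a few tenths of a
percent between close relatives) and unevenly: most of the genome is nearly
invariant while a handful of regions — typically single-copy introns and
spacers, and fast-evolving genes such as *ycf1* — concentrate the
differences. A taxon-specific mini-barcode is designed in three computable
steps, each implemented by one layer of this package:

1. compare two aligned congeneric plastomes and characterise their
   differences (`classify_substitutions()`, `detect_indels()`,
   `detect_inversions()`);
2. scan the pair with sliding-window nucleotide diversity and call the
   hotspots (`sliding_pi()`, `find_hotspots()`) — these are the candidate
   marker regions, which are then sequenced in a multi-species,
   multi-accession panel (a wet-lab step this package deliberately does not
   model: hotspot coordinates go out, marker alignments come back in);
3. evaluate each candidate marker's species-discrimination power and find
   the shortest window that retains it (`near_neighbour()`, `window_pm()`,
   `shortest_minibarcode()`).

The package consumes alignments and never produces them. A pairwise genome
alignment is expected from any standard aligner (e.g. `mafft --auto
two_genomes.fasta > pair.fasta`, optionally adjusted by hand); marker panels
are expected as per-marker multiple alignments plus a two-column
sample-to-species TSV. Producing those inputs is documented here as a recipe
rather than wrapped as code because external aligner calls, versions and
manual adjustment are not reproducible computation.

## Genome comparison

**Substitutions.** Every alignment column where both genomes carry an
unambiguous A/C/G/T and the bases differ is one substitution event. Any
other symbol — IUPAC ambiguity, N, a gap — makes the column missing data for
this purpose, matching the pairwise-deletion convention used for distances.
Events are classified as transitions (purine↔purine, pyrimidine↔pyrimidine)
or transversions, and collapsed onto six strand-symmetric classes
{C>T, T>C, C>A, A>C, C>G, A>T}, written reference-base-first; each class
also stands for its complement (G>A is reported as C>T, T>G as A>C, and so
on). Swapping which genome is the reference therefore maps each class to its
reverse and leaves the totals unchanged, a property the tests assert.

**Indels.** An indel event is a maximal run of gap columns in exactly one
genome (columns gapped in both are removed at load). Gap runs touching
either end of the alignment are missing sequence ends, not mutational
events, and are excluded with a message. Polarity (insertion vs deletion) is
deliberately not asserted: without an outgroup the direction is unknowable,
so events carry only the identity of the gap-holding sequence and reports
phrase polarity relative to the designated reference.

**Microinversions.** Short plastome inversions ride on hairpins: an inverted
repeat (the stem) flanks a loop, and the mutation reverse-complements the
loop. The detector takes each maximal run of 5–60 consecutive
mismatching/gapped columns, accepts it when the reverse complement of the
reference segment equals the other genome's segment (0 mismatches by
default), and then measures the stem by greedy outward extension over
complementary flank positions. An accepted event must have a stem of at
least 3 bp; the stem requirement is what separates a hairpin microinversion
from a coincidental reverse-complement match. Columns inside accepted loops
are excluded from substitution counting by default (`mask_inversions =
TRUE`): read column-by-column, an inverted loop would otherwise masquerade
as a dense cluster of substitutions and inflate the spectrum. The flag
exists because reasonable analysts differ on this, and the package makes the
choice explicit and reversible.

## Nucleotide diversity and hotspots

Nucleotide diversity is the mean over all unordered sequence pairs of the
proportion of differing sites, each pair compared only at columns where both
sequences have unambiguous bases (pairwise deletion). Two estimator choices
are deliberate and exposed:

* **No `n/(n−1)` correction by default.** With the two-genome comparison
  that drives hotspot discovery, the correction doubles every value, which
  is incompatible with the conventional scale of two-sequence π tracks;
  `corrected = TRUE` restores the unbiased estimator for users who want it.
* **Pairwise deletion for π, complete deletion for haplotypes.** Distances
  should use all the data each pair shares; haplotype identity needs one
  common site set, so haplotype counting first drops every column containing
  a gap or ambiguity in any sample.

The sliding scan uses 600-column windows advanced by 25 columns — wide
enough to smooth single-site noise at plastome divergence levels, fine
enough to localise a hotspot to a few hundred bp. Windows are defined on
alignment columns (gap columns count toward the span, never toward the
compared sites), the last partial window is dropped, and a track shorter
than one window degrades to a single full-length window with a warning.
Hotspots are maximal runs of consecutive windows with π strictly above the
threshold (default 0.012, a level only a few plastome regions exceed within
a genus), spanning the first window's start to the last window's end;
because a 600-column span can reach across a sub-window gap between two
runs, overlapping hotspot intervals are merged so the reported intervals are
always disjoint.

Marker variability tables report aligned length, variable sites (≥2 distinct
unambiguous bases), parsimony-informative sites (≥2 distinct unambiguous
bases each in ≥2 samples), percentages to 2 decimals, π, indel events
(distinct (start, length) gap runs, counted once however many samples share
them), and haplotypes.

## K2P nearest-neighbour discrimination

Distances use Kimura's two-parameter model: with transition proportion P and
transversion proportion Q over the compared sites,
d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q). The distance is undefined — stored as
`NA`, never fabricated — when a pair shares no comparable site or a log
argument is non-positive (saturation). Undefined distances are excluded from
nearest-neighbour minima; a sample with no defined distance cannot be
classified and fails.

A sample is discriminated when its nearest-neighbour set — every other
sample at the minimum defined distance — is non-empty and entirely
conspecific. A tie that includes even one heterospecific sample fails under
this default (`tie_rule = "all"`), the conservative reading of
"the closest distance belongs to a conspecific individual"; the permissive
variant (`tie_rule = "any"`) is available behind a flag. Pm is the
percentage of discriminated samples; a species is discriminated only when
all of its samples are.

The window machinery slides a fixed-length column window along the marker
(step 1 column: a coarser step would be a search-granularity choice, not a
marker-length choice, and 1 is exhaustive), computes the K2P matrix inside
each window from cumulative per-pair counts, and evaluates the
nearest-neighbour rule. Gap columns inside a window count toward its nominal
length — windows are alignment slices, exactly what a primer pair would
amplify off the alignment coordinates.

`shortest_minibarcode()` computes the full-length discriminated-sample count
first, then scans lengths 50, 60, 70, … and returns the first length whose
best window matches the full-length **count**. The comparison is on integer
counts, not floating-point percentages, so 11/12 discriminated never fails a
91.666…%-formatting comparison. The Pm-versus-length curve is recorded as
observed; monotonicity in length is plausible but not assumed, and the tests
do not rely on it. Within one length, ties between equally good windows are
broken toward the smallest start.

## The simulators and what they do (and do not) show

`simulate_genome_pair()` plants substitutions, indels and hairpin
microinversions into a uniform-random ancestor at non-overlapping positions
(rejection sampling with 1 bp clearance), so recovery of the planted truth
can be asserted exactly. Substitutions are transitions with probability
kappa/(kappa + 2); inversion loops are drawn over {A, C} so the
reverse-complemented copy mismatches at every column, and the flank beyond
each planted stem is forced non-complementary so the recovered stem length
equals the planted one. Defaults mirror a congeneric plastome pair at ~0.3%
divergence: 156 kb, 464 substitutions with kappa = 2.9 (transition fraction
≈ 0.59), 156 indels (~63% single-base, a >10 bp tail, one 34 bp event), and
three microinversions with 19/18/14 bp loops and 3/44/11 bp stems.

`simulate_marker_dataset()` uses a star phylogeny: one consensus per species
mutated from a common ancestor at `between_divergence` (optionally confined
to a diagnostic block), individuals mutated from their consensus at
`within_divergence`, no indels. Defaults — 8 species × 3 accessions, 800 bp,
between 0.02, within 0.001 — produce the pronounced barcode gap
(between/within = 20) that a usable barcoding marker exhibits. A star tree
with homogeneous rates is sufficient to create that gap; it does not emulate
rate heterogeneity across sites, recombination-free but structured
coalescent variation within species, shared indel polymorphism, or the
quadripartite (IR-mirrored) architecture of real plastomes. Passing tests on
simulated data therefore validate the *machinery* — counting, distances,
search — not the biological claim that any particular real marker
discriminates a genus; real divergence hotspots are also localized features
of real genomes, whereas the simulator scatters substitutions uniformly, so
simulated hotspot counts are stochastic clumping, not signal.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere the user sees them (R's
  native indexing, and what GFF-style files and reports use); columns and
  ungapped reference positions are clearly distinguished in outputs.
* Parsing is case-insensitive; sequences are uppercased once at load.
* Ambiguity codes are retained in the containers but treated as missing by
  every analysis.
* Shared-gap columns are dropped once, at load, so maximal-gap-run and
  window logic never meets a both-gapped column; the operation is
  idempotent.
* Ts/Tv ratios are reported to 2 decimals with an explicit `undefined` flag
  when a stratum has no transversions, rather than `Inf` or silent omission.
* Test and validation problem sizes (alignments up to a few hundred columns
  and a dozen samples for exhaustive-oracle comparisons; 50 kb genome pairs
  for planted-truth recovery; 156 kb for the end-to-end reproduction script)
  were chosen so the exhaustive brute-force oracles remain feasible while
  still exercising every code path at realistic divergences.

## Known limitations

* Discrimination is distance-based only; tree-based (NJ) and
  character/diagnostic-site barcoding criteria are out of scope.
* Indel polarity requires an outgroup and is not inferred.
* The hotspot-to-marker hand-off is manual by design: the package reports
  hotspot coordinates, and the user supplies the marker panel alignments.
* The microinversion detector targets short, hairpin-flanked loops; large
  structural rearrangements and IR boundary shifts are not modelled.
* π from a two-genome comparison estimates divergence, not within-species
  diversity; its gap handling is switchable (pairwise-deletion default)
  because conventions differ between the field's diversity tools.
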