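---
title: "From polar snow-algal reads to biogeography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From polar snow-algal reads to biogeography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowbiogeo)
```

## The analysis in one paragraph

Red-snow blooms on polar glaciers and snow fields are produced by a small
number of cryophilic green algae. Because the nuclear ITS2 region evolves
quickly, exact (100%-identity) dereplication of ITS2 amplicons yields
*phylotypes* — unique sequences with abundances — that are fine-grained
enough to ask a biogeographic question: is a phylotype confined to one polar
region (endemic), shared among Arctic regions, or present in both polar
hemispheres (bipolar / cosmopolitan)? The package implements the whole chain
needed to answer that question reproducibly: paired-read processing into
phylotypes, 98%-identity OTU clustering, ITS2 secondary-structure quality
control with compensatory-base-change (CBC) species delimitation, the
endemic / Arctic-shared / entire-Arctic / bipolar classification with
read-share accounting, and permutation-based community statistics. A
ground-truth metacommunity simulator generates surveys with known structure
so that every stage can be validated quantitatively.

## Read processing

**Demultiplexing** uses exact dual-index matching: a read pair is assigned to
a sample only when its `i7+i5` combination equals a declared pair exactly.
No index error correction is attempted — with two independent indices, a
single-base tolerance would re-admit most index-hopping artifacts, which is
precisely what exact matching guards against.

**Quality truncation** cuts each read immediately before its first base with
Phred quality below `qmin` (default 3). The default is deliberately
permissive; merging and the downstream singleton filter do most of the
error control.

**Merging** scans all ungapped overlaps of the forward read against the
reverse-complemented reverse read. An overlap qualifies if it spans at least
`min_overlap` (default 16 nt) with a mismatch fraction at most
`max_mismatch_frac` (default 0.25); the best qualifying overlap (lowest
mismatch fraction, ties to the longer overlap) defines the consensus. At a
mismatch the higher-quality base wins (quality ties keep the forward base),
and the consensus quality is the maximum of the two — the standard behaviour
of read mergers. Failures are values, not errors; they are counted in the
ledger.

**Filtering** removes reads with any ambiguous base, reads shorter than 50
nt (strictly), and reads matching a contaminant reference by local alignment
over at least 60 columns at 90% identity or better. The contaminant screen is
a tool-independent replacement for a dedicated spike-in mapper: a PhiX-like
contaminant is detected by any 60-nt near-exact match, while true amplicons
never align to it at that level.

**Primer trimming** matches the forward primer at the 5' end and the
reverse-complemented reverse primer at the 3' end, IUPAC-aware, allowing up
to 4 mismatches. Reads in which either primer cannot be found are discarded:
an amplicon without recoverable primers is a fragment or artifact.

**Dereplication** collapses exactly identical sequences into phylotypes with
per-sample counts, sorted by total abundance (ties broken by sequence,
C-locale), which makes the downstream greedy clustering deterministic.
Phylotypes seen exactly once overall are removed after the chimera screen —
a singleton cannot be distinguished from a sequencing error.

Every stage writes to a QC ledger and the identity
`reads in = reads out + discards` is asserted at each stage, so read
accounting can never silently drift.

## Alignment conventions

All identities in the package are computed from one pairwise alignment
engine (affine gaps: a gap of length $k$ costs `gap_open` $+ k\,\cdot$
`gap_extend`; defaults +1/−2/10/1). Identity is the fraction of matching
columns among non-terminal-gap columns, with internal gap columns counted as
mismatches; coverage of a sequence is the fraction of its bases inside the
terminal-gap-free core. This approximates the conventions of the common
greedy clustering tools. The engine is verified in two independent ways: an
exhaustive enumeration of all alignments for short sequences, and score
agreement with `Biostrings::pairwiseAlignment` under the same scoring on
longer pairs.

For equal-length sequences within a few percent of each other, the optimal
global alignment under these parameters is gapless (a gap would cost at
least 22 while at most 3 per rescued mismatch can be gained), so Hamming
identity equals alignment identity. The clustering and chimera code uses
this as a fast path; alignments are still computed whenever lengths differ
or the Hamming identity falls within a slack band (default 0.02) of the
decision threshold, so no decision is ever made on the fast path that the
alignment criterion could overturn.

## OTU clustering

Greedy centroid clustering scans phylotypes in abundance order; each joins
the first centroid (in creation order) with identity > 0.98 and both
coverages > 0.80, otherwise it founds a centroid. Two invariants are
asserted in the tests rather than trusted: every member is within the radius
of its centroid, and no two centroids satisfy the joining criterion against
each other. Furthest-neighbour (complete-linkage) clustering at 99% is used
when building reference databases from Sanger-style long reads; it carries
the complete-linkage certificate — the minimum pairwise identity inside
every cluster is at least the threshold — which the tests verify by brute
force.

## De novo chimera screen

PCR chimeras are rarer than their templates, so candidate parents are
restricted to phylotypes at least `min_skew` (default 2) times more abundant
than the query. For each ordered parent pair the two-segment model asks: how
many query positions are explained by parent A up to a crossover and parent
B after it? The query is flagged when the best model beats the best single
parent by at least `min_gain` (default 0.02) *and* the model itself explains
at least `min_model_id` (default 0.9) of the query. The last gate matters:
without it, a sufficiently divergent sequence would be "chimeric" simply
because two weak parents explain slightly more than one weak parent. A real
PCR chimera is explained almost perfectly by its two parents, so the floor
costs no sensitivity (detection of constructed chimeras is ≥ 95% in the
acceptance tests, with zero false positives on chimera-free sets).

Pair models are searched among the `max_model_parents` (default 12)
candidates with the highest single-parent identity; a chimera's true parents
are by construction among its best single matches, so the cap changes
nothing except the running time on large candidate sets.

## ITS2 secondary structure

The built-in folder maximises canonical base pairs (AU/GC/GU, minimum
hairpin loop 3) by dynamic programming with a deterministic traceback (each
5' base pairs with its smallest qualifying partner among optimal choices).
Base-pair maximisation is *not* a thermodynamic model; its role is a
reproducible default, and the tests verify it against exhaustive enumeration
of all nested structures for short sequences. Curated structures — the
equivalent of the manual refinement step a human would perform — can be
supplied as Vienna dot-bracket records and take precedence, matched to OTU
representatives by exact sequence.

Helices are the branch stems of the basal loop (the loop closed by the
single outermost pair, or the open exterior loop), numbered I–IV in 5'
order. The three eukaryotic hallmarks are checked mechanically: exactly four
helices; a U–U mismatch in an internal loop of helix II (columns of the two
unpaired strands are matched positionally); and a YGGY motif (Y ∈ {C, U}) on
the 5' strand of helix III overlapping the apex window. Because the precise
extent of "near the apex" is a judgment call, the window is a parameter: the
5'-strand positions within `apex_window` (default 10) bases of the apical
loop, extended to include any YGGY match overlapping it.

A CBC between two structures is an aligned pair, base-paired in both, where
both nucleotides differ while canonical pairing (including GU) is retained;
a hemi-CBC changes exactly one side. Species delimitation builds a graph
over OTUs with an edge wherever no CBC falls inside the delimitation window
and takes connected components — same-species evidence is treated as
transitive, since the underlying species concept gives no guidance for
non-transitive cases.

## Taxonomic assignment

Queries are assigned by best local alignment against a user-supplied
reference set with BLAST-like gates: E-value < 1e−8, identity > 90%, and
alignment length strictly greater than 200 (ITS2) or 150 (18S) columns. The
E-value uses the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with
declared ungapped nucleotide constants (λ = 1.28, K = 0.46); only the gate
matters, so the constants are declared rather than fitted. Ties are broken
by E-value and then lexicographic reference id, which makes assignment
invariant to database order. In the pipeline the OTU representative is
assigned and its label propagated to members — the standard
representative-sequence practice — and OTUs assigned to no algal group are
excluded from the biogeographic analysis.

## Biogeographic classification and read shares

A taxon's presence set is the set of regions where its summed count reaches
`min_count` (default 1 — any read confers presence, since no presence
threshold is part of the method). Under the two-pole scheme (Arctic:
Svalbard, Greenland, Alaska; Antarctic: Antarctica) the four categories are
mutually exclusive and exhaustive: *endemic* (exactly one region), *bipolar*
(at least one region from each pole), *entire-Arctic* (all Arctic regions,
no Antarctic), *arctic-shared* (the rest). Endemism is evaluated at region
level; site-level presence is available through the community matrix for
users who need it.

Per region, the summary reports the endemic unique fraction (taxa present
only there / taxa present there) and the bipolar read share (reads belonging
to bipolar taxa / all reads there). Overall values are reported both as the
arithmetic mean over regions and as pooled (read- or taxon-weighted) totals:
the two genuinely differ, and which one a survey reports is ambiguous, so
both are always emitted.

## Community statistics

Shannon–Wiener uses natural logarithms (via `vegan::diversity`); Bray–Curtis
is $\sum|x_i-y_i| / \sum(x_i+y_i)$ (matrices via `vegan::vegdist`); UPGMA is
average-linkage `hclust` with labels pre-sorted so tie handling is
deterministic (heights follow the `hclust` convention: a two-leaf merge at
distance 0.4 has height 0.4, i.e. ultrametric leaf depth 0.2). PERMANOVA is
the one-way distance-based pseudo-F; the Mantel statistic is the Pearson
correlation of lower triangles (Spearman behind a flag). Both use the
+1 permutation rule $p = (\#\{T_{perm} \ge T_{obs}\} + 1)/(B + 1)$, are
seed-deterministic, emit their seed, and accept an explicit permutation
matrix so small-$n$ exhaustive enumeration can be checked exactly. The
implementations are cross-checked against `vegan::adonis2` and
`vegan::mantel` statistics in the tests, and their null p-value distributions
pass a Kolmogorov–Smirnov uniformity check over 500 simulated datasets.
Geographic distance is the haversine great-circle distance on a 6371-km
sphere; region-level distance is the mean over cross-region site pairs,
since no canonical definition exists.

Pairwise region contrasts are separate one-way tests without multiplicity
correction by default (a Bonferroni flag exists), matching common practice
for this design.

## The simulator and what passing tests mean

`build_metacommunity()` generates templates from a hand-designed 216-nt
ITS2-like scaffold whose declared structure carries all three hallmarks. A
group/species/OTU hierarchy descends from it: group ancestors diverge by
~10% through loop mutations and compensatory stem swaps (structure
preserved); species within a group differ by a planted CBC at a fixed
helix-III apex-window pair; OTU ancestors within a species differ by > 2%
(enforced explicitly against all previously generated ancestors); second
templates within an OTU differ by < 2%. Default composition: 36 endemic
templates (14 Antarctica, 8 Svalbard, 4 Greenland, 10 Alaska), 4
Arctic-shared, 2 entire-Arctic, 4 bipolar — endemic-majority unique
composition with bipolar-dominated read shares, the regime such surveys
observe. Per-region read-share targets default to bipolar shares of 12.3%
(Antarctica), 47.8% (Svalbard), 68.4% (Greenland) and 27.2% (Alaska);
within-category abundances are log-normal (σ = 1.2) renormalised so expected
shares hit the targets exactly.

`simulate_reads()` samples multinomial reads per sample (default 20,000),
forms chimeras by splicing two sampled templates at a uniform crossover
(default rate 2%), applies substitution errors at a uniform per-base rate
(default 0.1%) to each 150-nt mate, and decorates amplicons with the ITS2
PCR primers and per-sample dual indices. The model is deliberately
substitution-only with flat qualities: indels would make exact dereplication
meaningless as a unit, and learned quality profiles are out of scope. Passing
tests therefore demonstrate correctness of the pipeline's logic and its
robustness to uniform substitution noise and chimera formation — not
robustness to indel-rich platforms, amplification bias, or structured error
profiles of real instruments.

**Why recovery is scored against realized truth.** At 0.1% error and 20,000
reads per sample, recurrent error variants are a substantial fraction of the
realized unique sequences — exactly as in real surveys, where unique-sequence
counts vastly exceed biological template counts. The configured
template-level fractions are therefore not what a perfect observer of the
reads would compute. `evaluate_recovery()` scores the pipeline against the
*realized* ground truth: every non-chimeric realized unique sequence with at
least two reads (the same abundance rule the pipeline applies), classified
by its true region presence. Pipeline-vs-truth differences then isolate
pipeline error (demultiplexing, merging, chimera screening, clustering)
from sampling and sequencing noise, and the zero-noise case degenerates to
the template-level truth exactly. The configured template-level values are
reported alongside for context.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on a 4-region × 3-sample survey
at 20,000 read pairs per sample (240,000 pairs), which finishes in a few
minutes on one core; unit tests use miniature surveys (hundreds of reads)
and short random sequences where exhaustive oracles are feasible (alignment
≤ 5 nt against full enumeration, folding ≤ 12 nt, permutation tests at
n = 4–6 against all permutations). Permutation defaults are 999 in analysis
and 199 in calibration loops. All stochastic components take explicit seeds,
restore the caller's RNG state, and record the seed in their output.

Known limitations: the folder ignores thermodynamics and pseudoknots;
helices with internal multifurcations report no apical loop and are skipped
by the apex-window logic; the chimera model is two-segment (multi-parent
chimeras are detected only insofar as a two-parent model explains them); the
three-tier reference-database search of real surveys is modelled as a single
labelled FASTA; and the E-value constants are nominal, not calibrated.
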