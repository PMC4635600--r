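---
title: "Calling miRNA precursors from small RNA-seq without conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling miRNA precursors from small RNA-seq without conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plant and algal microRNAs are excised from hairpin-folded precursor RNAs by
Dicer-like (DCL) enzymes. In small RNA sequencing libraries the mature miRNA
appears as a sharp stack of near-identical reads, while the rest of the
precursor is covered sparsely, buried in a background of degradation
products and other small RNAs. Most discovery tools lean on cross-species
sequence conservation or on structural priors tuned to animal precursors;
both fail for organisms such as *Chlamydomonas reinhardtii*, whose
precursors are long (up to several hundred nucleotides), structurally
heterogeneous (extra sub-hairpins, bulges, multiple mature/star duplexes per
precursor) and largely species-specific.

`hairpinr` calls precursors from nothing but strand-specific alignments
(SAM) and a reference genome (FASTA), in three stages:

1. **Clustering** — expression contigs above a read threshold, gap-merged,
   length-filtered, and extended by flanks into candidate clusters.
2. **Structure analysis** — a search over precursor windows within each
   cluster for the secondary structure minimising the per-nucleotide
   minimum free energy (MFE/nt), followed by structure filters and an
   empirical shuffle-based significance test.
3. **Verification** — read-coverage analysis demonstrating processing into
   at least one mature/star duplex with the 2-nt 3' overhang signature of
   DCL cleavage.

## Stage 1: candidate clusters

Reads are collapsed to `(chrom, start, end, strand, multiplicity)` tuples.
Maximal intervals of nonzero coverage on one strand form contigs;
neighbouring contigs closer than `cluster_gap_size` (default 10 nt, strict
`<`) merge transitively; merged contigs with summed read multiplicity below
`cluster_min_reads` (default 10, inclusive) or longer than
`cluster_max_length` (default 2000 nt, strict `>`) are discarded. Survivors
are extended by `cluster_flank_size` (F = 200 nt) on both sides, clamped to
the chromosome. The flank must be large enough that a full precursor fits
between the flank boundaries; 200 nt suits most plants and algae.

One ordering subtlety: the read threshold is applied *after* gap merging,
so two weak adjacent islands that together carry enough reads survive as
one contig. `find_contigs()` still exposes a `min_reads` argument for
standalone use; the pipeline calls it with `min_reads = 1`. Both behaviours
are pinned by tests.

## Stage 2: secondary structure

### Window search

Precursor boundaries are unknown, so for each cluster we fold windows whose
start lies in the 5' flank and whose end lies in the 3' flank, and keep the
window minimising MFE/nt. Because MFE/nt initially decreases roughly like
1/L with window length L, normalising by length is what makes windows of
different sizes comparable.

A full grid at fine resolution is needlessly expensive: thermodynamic
folding is cubic in window length, and the energy surface over window
boundaries is smooth for genuine hairpins. The pipeline therefore scans a
coarse lattice at `window_step` (default 20 nt, anchors always included),
then re-scans at `window_refine_step` (default 5 nt) resolution within one
coarse step of the winning boundaries, and takes the optimum over
everything folded. This reaches 5-nt boundary resolution at roughly 4% of
the folding cost of a flat 5-nt grid. Setting `window_refine_step = 0`
disables refinement; setting `window_step` to the refine value recovers the
flat grid. Clusters whose flank span exceeds 3000 nt are skipped with a
warning (cost guard). Windows shorter than `2 * min_duplex_length` cannot
contain a duplex and are never folded.

Ties and near-ties are resolved deterministically (lower MFE/nt, then
longer window, then smaller start); a second window within
`uniqueness_tolerance` (0.01 kcal/mol/nt) of the optimum over a different
genomic interval flags the candidate `unique_optimum = FALSE` — recorded in
the calls, not used for rejection, since near-degenerate boundary choices
for one hairpin are common.

### Folding backends

The default backend is ViennaRNA's `RNAfold` (nearest-neighbour
thermodynamics, kcal/mol), invoked in batch over a temporary FASTA and
required to emit pure nested dot-brackets — pseudoknot annotation is
rejected at the adapter. A bundled fallback (`fold_backend = "pairmax"`) is
a weighted base-pair-maximization dynamic program in C++ (GC −3, AU −2,
GU −1 pseudo-energies, minimum loop 3 nt). The fallback keeps the entire
pipeline and test suite runnable with no external program, but its energies
are **not** free energies: the organism presets' MFE/nt thresholds are
calibrated for thermodynamic energies and happen to be permissive for
pairmax pseudo-energies, whose discrimination then rests on the terminal
loop and double-strand filters. Published analyses should use the
thermodynamic backend.

### Structure filters

Three statistics gate a selected window (all computed from the dot-bracket):

* **MFE/nt** must be at or below `min_mfe_per_nt`;
* **N_term**, the number of terminal (hairpin) loops — occurrences of `(`
  followed, ignoring dots, by `)` — must satisfy `N_term <
  max_hairpin_count` (default 4). Long plant precursors often acquire small
  spurious sub-hairpins when windows grow, and a strict single-hairpin rule
  would discard genuine precursors prematurely;
* **L_ds,max**, the longest double-stranded segment, must be at least
  `min_double_strand_length`. A segment is a contiguous run of positions on
  one side of a helix whose first and last positions are paired, whose
  partners progress strictly without crossing, and which contains at most
  two defects, a defect being an unpaired position or a partner-strand
  discontinuity. The run length counts the interruptions ("allowing for two
  mismatches" describes a segment length, not a pair count). Both scanners
  are verified exactly against brute-force reference implementations on
  hundreds of random structures.

Two presets bundle the thresholds: `plants` (`min_mfe_per_nt = -0.2`,
`min_double_strand_length = 18`) and `algae` (`-0.4`, `24`). Algal
precursors have markedly longer double-stranded segments and lower MFE/nt
than land-plant precursors; the preset values were chosen once to reflect
that contrast and are deliberately user-overridable — they are calibration
decisions, not universal constants. `profile_precursors()` exists precisely
so users can re-derive thresholds from a known precursor set (for example a
miRBase export) by inspecting the feature distributions it returns.

### Significance

Candidates passing all three filters are tested against sequence
composition: the window sequence is shuffled `permutation_count` times
(default 100; Fisher–Yates mono-nucleotide shuffling), every shuffle is
folded, and the p-value is the add-one empirical estimator

> p = (1 + #{null MFE/nt ≤ observed MFE/nt}) / (n + 1),

a discretisation of the integral of the null density below the observation.
The pseudocount prevents p = 0 at finite n; ties count against the
candidate. No distributional assumption is made (the null is close to
normal, but that is an observation, never an input). Each sequence gets its
own null, so sequence-specific base composition is controlled exactly.
Di-nucleotide shuffling (`shuffle_method = "dinucleotide"`, an
Altschul–Erickson Eulerian-path shuffle) is available but makes no
practical difference for sequences beyond ~100 nt, where both schemes give
the same MFE/nt null. Candidates with `p <= max_pvalue` (default 0.05)
proceed. No multiple-testing correction is applied across clusters — the
cutoff is a fixed per-candidate filter, not a family-wise claim; users
needing FDR control can apply `p.adjust` to the reported p-values.

## Stage 3: mature/star verification

Verification asks whether coverage looks like DCL processing. Reads
intersecting the precursor are grouped into *stacks* sharing exact start
and end ("sharp edges"; `edge_tolerance` up to 2 nt optionally merges
near-identical stacks, default 0 because DCL ends are homogeneous and
exactness is testable). A stack is a candidate mature locus iff its share
of all precursor-mapped read multiplicity exceeds `min_coverage` (strict
`>`, default 0.10) and `min_duplex_length <= L < max_duplex_length`
(defaults 20 and 25, half-open, covering the canonical 20–24 nt products).
Overlapping weaker stacks are suppressed greedily by support (ties to the
5'-most); disjoint accepted stacks make a multi-mature precursor, each
mature getting its own star, with accepted duplex arms mutually
non-overlapping.

For each mature locus at inclusive positions (m5, m3) the star follows from
the 2-nt 3' overhang rule: star 5' end = partner(m3 − 2), star 3' end =
partner(m5) + 2. If an anchor is unpaired, the nearest paired position up
to 3 nt inward substitutes; anchors unpaired beyond that (e.g. a stack in
the terminal loop) fail with "no star". On perfect stems the construction
is an involution — the star of the star is the mature, exactly — which is
enforced by property tests. The duplex then passes five named checks:
paired fraction of the mature ≥ `min_paired_fraction` (0.67); no fold-back
(no mature position pairs within the mature); fewer than 4 adjacent
unpaired mature positions in the interior (1-based positions 3…L−3,
enabled by `allow_three_mismatches`); fewer than 3 adjacent unpaired
positions touching the duplex ends (positions 1–2 and L−2…L, enabled by
`allow_two_terminal_mismatches`); and length bounds on both arms. The
boundary convention for "interior" versus "terminal" runs is ambiguous in
the field; the convention above is fixed and pinned by tests. Star
*expression* is never required — star reads are usually scarce, and
requiring them is a known source of false negatives.

Verification reads may come from a different alignment than clustering
(`verify_reads` / `--verify-sam`), enabling independent cross-verification.

One hairpin typically seeds two clusters — its mature and star stacks lie
further apart than the merge gap — and both select near-identical optimal
windows. After verification, overlapping same-strand precursor calls are
therefore collapsed to a single representative (most duplexes, then lowest
p-value, then lowest MFE/nt, with a deterministic tie-break), so the call
table reports each locus once.

## Reproducibility and parallelism

`seed` (default 42) is set once at entry to the folding stage; shuffles are
drawn serially in cluster order and folding is deterministic, so identical
inputs, configuration and seed give byte-identical call tables.
`worker_count` only chunks the folding batches (and never the RNG), so
results are independent of it — both properties are tested. The stages
serialize their outputs (`clusters.tsv`, `candidates.tsv`, then
`calls.csv`/`calls.bed`/`calls.gtf`/`report.json`) so any stage can restart
from its upstream intermediate.

## The synthetic-data generator

`build_genome()` and `simulate_reads()` generate the ground-truthed data
the package is tested on: a random background genome with implanted
hairpins (GC-biased 60-nt arms, 8-nt loop, 1 arm defect by default — a
strong but not perfect stem typical of algal precursors), a mature locus on
the 5' arm and a star derived by the overhang rule; mature stacks of 100
reads and star stacks of 10 (star ≈ 10% of mature, scarce but present),
2000 uniformly placed 18–26-nt background reads as a degradation mimic, and
up to 10% of stack reads jittered by 1 nt. Implants are spaced at least
twice the flank apart so clustering yields one cluster per expressed arm.
The default benchmark (100-kb genome, 20 precursors) runs the full pipeline
in minutes on one core — a desk-scale stand-in for genome-scale data.

What the generator does *not* emulate: transcript-shaped background (its
background is uniform, real degradation follows gene models), sequencing
errors, isomiR end heterogeneity beyond the simple jitter, multi-mapping
artefacts, and genuine structural edge cases such as loop-spanning stacks
on imperfect stems. Passing the synthetic benchmark therefore demonstrates
the machinery is correct, not that the thresholds are optimal for any
particular organism.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; conversion happens only at
  file boundaries (SAM/GTF are 1-based, BED is 0-based).
* `mfe_per_nt = mfe / length` exactly; comparisons use the full double
  precision, tie-breaks are lexicographic and deterministic.
* Unfoldable sequences (e.g. homopolymers) fold to the all-dot structure
  with MFE 0 and are removed by the MFE/nt filter.
* Empty inputs propagate as empty typed tibbles, never as errors; a
  precursor with zero verification reads is never called.
* Up to 10% of shuffles may fail to fold before the null is abandoned.
* Merged stacks, clusters and calls are always re-sorted by genomic
  position, so output order never depends on processing order.

## Known limitations

* Dot-bracket structures only: pseudoknotted precursors are out of reach.
* Each alignment record counts once; no fractional weighting of
  multi-mapping reads (secondary alignments are included by default,
  `primary_only = TRUE` restricts).
* Expression is reported as raw read support, not normalised.
* The coarse-to-fine window search can in principle settle on a local
  optimum of the 5-nt lattice if two distant windows have near-identical
  MFE/nt; such cases are flagged by `unique_optimum = FALSE`.
* The pairmax fallback is a development and testing device, not a model of
  RNA thermodynamics.
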