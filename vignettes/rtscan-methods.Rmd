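---
title: "Methods: folding-energy landscapes and the ribosome termination structure model"
author: "rtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: folding-energy landscapes and the RTS model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Bacterial operons place coding sequences a few nucleotides apart, and a
ribosome terminating at a stop codon can re-initiate translation on the
next cistron. rtscan implements a genome-scale analysis of the *ribosome
termination structure* (RTS): a stable mRNA secondary structure immediately
downstream of stop codons that can insulate a gene against uncontrolled
re-initiation. The pipeline asks three quantitative questions:

1. How stable is the mRNA, window by window, around every stop codon
   (the *local folding energy*, LFE)?
2. Is the native stability stronger than expected from amino-acid
   sequence, codon usage and nucleotide composition alone (the *folding
   bias*, delta-LFE, measured against a synonymous-codon-shuffle null)?
3. Does a gene carry an RTS under an explicit rule-based model, and how
   does RTS presence stratify with operon topology?

## Coordinates and windows

All positions use a stop-anchored axis: p = 0 is the first nucleotide
after the stop codon; p = −3 opens at the stop itself; minus-strand genes
are read on the reverse complement. A window is indexed by the position of
its 5′-most nucleotide ("opening" position). Landscapes by default span
p ∈ [−100, +100] with 40-nt windows and step 1. Internally all gene
coordinates are 0-based half-open on the forward strand; GFF3 (1-based
inclusive) is converted at the boundary, which keeps the window arithmetic
free of off-by-one cases.

Windows that would run past a contig end are dropped, never padded;
windows with more than 10% ambiguous bases are skipped. A position enters
a delta-LFE profile only where the native window and all randomized
replicates are available.

## Folding engines

Energies come from an engine abstraction. The production engine drives
ViennaRNA's `RNAfold` (Turner parameters, default settings, 37 °C) as a
single batched subprocess, so a 200-gene landscape costs one process
launch, and reports kcal·mol⁻¹·window⁻¹. A dependency-free fallback
(`pairmax_engine()`) implements a Nussinov-style dynamic program with
fixed per-pair energies (GC −3, AU −2, GU −1; minimum hairpin loop 3 nt).
The fallback honours the same contract (deterministic, never positive)
but its absolute energies are *not* Turner energies: every
threshold-bearing analysis (the −6 kcal·mol⁻¹·window⁻¹ RTS depth rule,
pinned window values) is engine-pinned to the Vienna engine, and all
result objects record which engine produced them. Published Vienna
versions drift by small amounts on individual windows; pinned expectations
carry a ±0.2 kcal/mol tolerance for that reason.

## The randomization null

The null model preserves everything attributable to protein sequence and
composition: within each CDS, synonymous codons are permuted uniformly
within their amino-acid family (translation, codon multiset and nucleotide
content all invariant); within each region covered by no CDS, nucleotides
are permuted. Nucleotides covered by two or more CDSs are frozen
byte-for-byte, as are codons containing `N` and the terminal stop codon
(a lone stop has no within-gene synonymous partner, and freezing it keeps
the position axis anchored). Minus-strand CDSs are shuffled in mRNA sense
and reverse-complemented back, so synonymous families are defined
biologically; the alternative (genomic-sense shuffling) is not exposed.
Windows straddling a CDS/intergenic boundary are simply extracted from the
fully randomized genome, so each segment is randomized under its own
scheme. Replicates use deterministic substreams of one master seed;
R = 20 replicates is the default.

Delta-LFE is defined as native ΔG minus the replicate mean of randomized
ΔG. Negative values mean the native mRNA folds more stably than the null.
(Texts describing this quantity sometimes write the subtraction in the
opposite order while still plotting negative minima for
stabler-than-expected structure; this package fixes the
native-minus-randomized convention throughout.)

## The RTS model

A gene is called RTS-positive when three conditions hold (defaults in
`rts_config()`):

1. **Topology** — no annotated downstream neighbour in the gene's
   direction of transcription, or the neighbour is on the opposite
   strand, or the intergenic distance is ≥ 25 nt. Genes with no
   neighbour are treated like opposite-strand cases: with no coupled
   downstream cistron, re-initiation insulation is unconstrained.
2. **Run** — at least 5 consecutive opening positions within [−10, +20]
   with strictly negative delta-LFE. The run's openings must all lie in
   the range (the covered sequence then spans −10…+59 at width 40). The
   longest qualifying run is selected; ties resolve to the 5′-most.
3. **Depth** — within the selected run, the *native* window energy
   reaches −6 kcal·mol⁻¹·window⁻¹ or lower.

Strictness choices the model text leaves open: delta-LFE < 0 is strict
(ties are measure-zero with real energies); the depth condition is
evaluated on the selected run only. Genes whose profile does not cover the
whole opening range are reported uncallable and excluded from fractions.
The caller is verified against a brute-force interval-enumeration oracle
and is monotone in all three thresholds.

The downstream neighbour itself is the nearest other CDS in the gene's
transcription direction on the same contig (either strand), skipping genes
wholly nested inside the query; the intergenic distance counts nucleotides
between CDS end (stop included) and neighbour start, negative for
overlaps. Defining the neighbour in mRNA sense (rather than always
rightward on the forward strand) is what makes every topology quantity
invariant under reverse-complementing the genome.

## Reporter-library calculations

The synthetic-operon library embeds a 24-nt variable region between the
upstream reporter's amber stop (plus a fixed `ACTAGT` hexamer) and a fixed
downstream reporter prefix. The clone score is the MFE of a single window
opening +9 nt from the stop's first nucleotide, width 37 — with the
default flanks that window is exactly the variable 24-mer plus the fixed
13-nt suffix `AAGGGCGAGGAGC`. Widths of 30-50 are supported for sweeps.
Reads are filtered like the experimental pipeline: any in-frame stop codon
(offsets 0, 3, …, 21 in the reporter frame) rejects a read; an in-frame
ATG/GTG/TTG is required. Bins are summarised by the read-count-weighted
mean ΔG with a seeded multinomial-bootstrap percentile interval (default
99%, 10⁴ resamples); the bootstrap was chosen because no interval method
is prescribed for this quantity and resampling is assumption-light. Bin
weights are read counts; relative frequencies would give the same mean.
The theoretical library simulator draws uniform-composition sequences
under three schemes (filtered 37-mers; filtered 24-mers plus the fixed
suffix; unfiltered 37-mers); its acceptance rate has the closed form
(1 − p_stop)^k − (1 − p_stop − p_start)^k because in-frame codons are
disjoint, and the simulator is tested against it.

## Exact small-n statistics

Sorted-bin and clone comparisons in this setting involve n as small as 6,
where asymptotic Spearman p-values are meaningless. `spearman_exact()`
enumerates all n! rank permutations (n ≤ 9), computes the null law of
S = Σd², and doubles the smaller S-tail (capped at 1). This convention
reproduces the exact references: p = 2/720 ≈ 0.0028 for a perfect n = 6
monotone relation, and p = 2·6/720 ≈ 0.017 for S = 2, n = 6. With ties or
larger n it falls back to the large-sample test with a warning. One-sample
and two-sample location tests wrap `stats::wilcox.test()`; following the
landscape-statistics convention, delta-LFE values may pool all R
randomization replicates per gene, and the result object records both the
pooled n and the gene count so the pseudo-replication stays visible — it
is reported, not silently corrected. Formatted p-values floor at 10⁻³⁰
("<1e-30"); raw values are kept.

## The synthetic-genome generator

Real genome downloads are deliberately out of band: the generator builds
genomes with known ground truth so every stage is testable offline. Genes
are laid out as alternating CDS and intergenic spacer on one contig:
codons drawn from a usage model (uniform within synonymous families by
default; an approximate E. coli preset ships), lengths 50-300 codons,
intergenic distances 40-150 nt (so genes are topology-eligible under the
25-nt rule), intergenic GC 25% — bacterial intergenic sequence is AT-rich,
which also keeps baseline downstream structure weak. A configurable
fraction of genes is flipped to the minus strand (whole units are
reverse-complemented after construction, preserving distances in mRNA
sense), and consecutive same-strand genes are grouped into operons.

Planted hairpins are `stem_len` G·C pairs around a GAAA tetraloop
(`GGG…GAAA…CCC`), written *over* intergenic sequence at a fixed opening
offset downstream of the stop (default +5), so intergenic distances stay
as configured; a hairpin that cannot fit its spacer is a configuration
error, not a silent truncation. Because a gene's CDS and its downstream
spacer travel together in one unit, the planted offset is exact in mRNA
sense on both strands.

Two calibration facts follow from the construction. First, a generated
genome with no hairpins *is* a draw from the randomization null: given
each region's multiset, native and shuffled window contents are
identically distributed, so the delta-LFE expectation is *exactly* zero
at every position. The calibration test asserts this as a grand-mean
band (|mean over genes and positions| ≤ 0.3 kcal·mol⁻¹·window⁻¹ at 200
genes, R = 20) plus a per-position band at the same tolerance. The two
bands are not equivalent: with a per-gene delta-LFE SD around 2
kcal·mol⁻¹·window⁻¹, the per-position mean at 200 genes has a standard
error near 0.15, and because adjacent windows share 39 of 40
nucleotides the mean profile is a smooth correlated wiggle whose
extremes routinely graze ±0.35 while carrying no reproducible sign
pattern across seeds. The grand mean is the statistically meaningful
zero check at this sample size; the per-position band documents the
wiggle amplitude.

Second, the generator does **not** emulate real genomes in other
respects: no Shine-Dalgarno signals, no terminators, no codon-context
correlations, no length/GC heterogeneity between genes. Passing
recovery tests therefore demonstrates that the pipeline measures what it
claims on known truth — not that any particular real genome has RTSs.

A related measurement fact constrains the RTS caller's false-positive
behaviour. The depth condition scans 31 overlapping windows per gene,
and even AT-rich (25% GC) random intergenic sequence clears the −6
kcal·mol⁻¹·window⁻¹ threshold in some window of that region for roughly
a quarter of genes — random sequence does occasionally contain genuinely
stable structure, and the negative-delta-LFE run condition is only
weakly binding because neighbouring windows are almost identical. On
half-planted benchmark genomes the caller therefore reaches sensitivity
1.0 with a false-positive rate near 0.35 (and ~0.25 on fully null
genomes): planted and background genes separate cleanly, but the
background rate is a property of the three-condition model itself under
these energies, set by the threshold, the window count of the run
region, and the intergenic composition — not an adjustable artefact of
this implementation.

## Window-scan geometry and localization

A fixed-width window scan localizes a short structured element at the
*centre* of the minimizing window. Every 40-nt window that fully contains
a 28-nt hairpin is near-minimal, so the mean landscape has a ~13-position
plateau (openings [−7, +5] for a hairpin opening at +5) whose interior
minimum sits where the hairpin is centred in the window — the
opening-label argmin is displaced 5′-ward of the element's opening by
about (width − element length)/2. `landscape_minimum()` exposes both
label conventions: `"open"` (the RTS-model axis) and `"center"`
(opening + (width−1)/2), the latter estimating the element's centre
directly. The planted-recovery test asserts centre recovery within ±3 nt;
recovering the *opening* instead would require knowing the element length,
which a scan does not observe. For the same reason a reported landscape
minimum "at position x" should be read as "window opening x", with the
underlying element centred near x + 20.

## Problem sizes and numerical choices

- Landscape tests run 200 genes × (1 + 20 genomes) over 81 and 71
  positions respectively (≈ 3 × 10⁵ foldings each), batched through one
  RNAfold call; the full ±100 range changes only the position count.
- Randomization substreams derive as (seed × 1000003 + replicate) mod
  2³¹−1; every user-facing entry point takes one seed.
- Bootstrap CIs use 10⁴ resamples; simulator tests use 10³ sequences
  against 3-standard-error bands; the start-codon probability DP is exact
  and is checked against full enumeration (L ≤ 9) and 10⁶-draw
  simulation (L = 50).
- Quantile grouping uses right-closed quantile breaks with the outer
  breaks widened to ±∞ so extreme values are never dropped.

## Known limitations

- MFE only: no partition-function ensembles, suboptimal structures,
  pseudoknots or co-transcriptional folding.
- The fallback engine is for plumbing and CI, not for thermodynamic
  conclusions.
- Multi-part CDSs are merged to their genomic span (effectively single
  part in bacteria); circular genomes are not wrapped — windows at contig
  edges are dropped.
- The 20-replicate pooled-n testing convention inflates the nominal
  sample size; the result objects expose both counts so users can judge.
- Operon grouping in the generator is a layout convenience, not a
  transcription-unit simulation.
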