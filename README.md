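# rtscan

Genome-wide detection and quantification of the **ribosome termination
structure (RTS)** — a stable mRNA secondary structure immediately
downstream of bacterial stop codons that insulates operonic genes against
translation re-initiation.

Bacterial operons place cistrons a handful of nucleotides apart, and a
terminating ribosome can re-initiate on the next gene in any reading frame
at AUG/GUG/UUG. rtscan is for computational biologists studying how mRNA
structure regulates that process: it turns a genome (FASTA) and its CDS
annotation (GFF3) into folding-energy landscapes around every stop codon,
a selection statistic against a composition-preserving null, and per-gene
RTS calls stratified by operon topology — plus the synthetic-operon
reporter-library calculations used to validate the structure's effect on
re-initiation, and a synthetic-genome generator with planted hairpins so
the whole pipeline is testable offline with known ground truth.

## The quantities it computes

- **LFE** (local folding energy): minimum free energy of a 40-nt window,
  in kcal·mol⁻¹·window⁻¹, from ViennaRNA's `RNAfold` (Turner parameters,
  default settings), indexed by the window's 5′ opening position *p*
  relative to the first nucleotide after the stop codon (*p* = 0).
- **ΔLFE** (folding bias):
  `ΔLFE(p) = ΔG_native(p) − (1/R) Σ_r ΔG_rand,r(p)`,
  where the R = 20 randomized genomes permute synonymous codons within
  each CDS and nucleotides within each intergenic region (overlapping-CDS
  bytes, N-containing codons and terminal stops frozen). Negative ΔLFE ⇔
  the native mRNA folds more stably than its composition predicts.
- **RTS call**: a gene is RTS⁺ when (1) its downstream neighbour is ≥ 25
  nt away, on the opposite strand, or absent; (2) ≥ 5 consecutive window
  openings in [−10, +20] have ΔLFE < 0; and (3) the native ΔG reaches
  ≤ −6 kcal·mol⁻¹·window⁻¹ inside that run.
- **Clone ΔG_fold**: the single 37-nt window opening +9 nt from the first
  nucleotide of a reporter clone's UAG stop — for the standard construct,
  exactly the 24-nt variable region plus the fixed `AAGGGCGAGGAGC` suffix.
  Bins of a sorted library are summarised by the read-count-weighted mean
  ΔG_fold with a 99% bootstrap CI.
- **Exact small-n Spearman**: the rank statistic S = Σd² with a two-sided
  p-value from full enumeration of all n! rank permutations (n ≤ 9), e.g.
  p = 2/720 ≈ 0.0028 for a perfect monotone relation at n = 6.

## Worked example

```r
library(rtscan)
engine <- vienna_engine()

# a 40-gene synthetic genome; half the genes get a stem-12 GC hairpin
# planted 5 nt downstream of their stop codon
cfg <- synth_config(n_genes = 40,
                    hairpin = list(fraction = 0.5, stem_len = 12, offset = 5))
gen <- make_genome(cfg, seed = 101)

profiles <- dlfe_profiles(gen$genes, gen$genome, engine,
                          R = 10, seed = 101, p_range = c(-30, 30))
topology <- pair_topology(gen$genes)
calls    <- call_rts_all(profiles, topology)
frac     <- rts_fraction(calls)
truth    <- gen$truth$hairpin_planted[match(calls$gene_id, gen$truth$gene_id)]
land     <- aggregate_landscape(profiles)

cat(sprintf("RTS fraction: %.2f (%d of %d callable genes)\n",
            frac$fraction, frac$n_present, frac$n_callable))
cat(sprintf("sensitivity %.2f, false-positive rate %.2f\n",
            mean(calls$present[truth]), mean(calls$present[!truth])))
cat(sprintf("landscape minimum %.2f kcal/mol/window at opening %+d\n",
            min(land$mean), landscape_minimum(land)))
spearman_exact(c(1, 2, 3, 4, 5, 6), c(-9.1, -7.9, -6.4, -5.0, -3.2, -2.8))
```

This prints:

```
RTS fraction: 0.68 (27 of 40 callable genes)
sensitivity 1.00, false-positive rate 0.35
landscape minimum -15.57 kcal/mol/window at opening -4
Spearman rank correlation (exact enumeration): rho = 1, n = 6, p = 0.00278
```

Reading the numbers: every planted hairpin is recovered (sensitivity
1.00). The mean-ΔLFE landscape bottoms out at **opening** −4 — a 40-nt
window localizes a 28-nt hairpin at the window's *centre*, so the
minimizing opening sits ≈ (40 − 28)/2 nt 5′-ward of the hairpin's +5
start; `landscape_minimum(land, "center")` reports the hairpin-centre
estimate directly. The 0.35 false-positive rate is a property of the
three-condition model on AT-rich intergenic sequence (31 overlapping
windows get several chances to dip below −6 kcal·mol⁻¹·window⁻¹); see the
methods vignette. The exact Spearman p for a perfect n = 6 monotone
relation is 2/720 ≈ 0.0028.

A thin command-line front end wraps the same functions
(`inst/scripts/rtscan`): `synth-genome`, `landscape`, `rts-call`,
`classify-pairs`, `library`, `library-sim`, `clone-dg`.

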