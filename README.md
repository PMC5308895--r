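# captrans

Translatome analysis of transcription start sites from CapSeq polysome
profiling.

## What it does

When cells are stressed (e.g. glucose-starved), translation is reprogrammed,
and part of that reprogramming happens at the level of *which* transcription
start site (TSS) a gene uses: transcript isoforms from alternative promoters
(APs) of the same gene can differ sharply in how well they are translated.
`captrans` implements the computational side of an experiment that measures
this genome-wide: capped 5' ends of mRNAs (CapSeq reads, which pinpoint TSSs
at single-base resolution) are sequenced separately from three sucrose-gradient
pools — polysome-free (F), light polysomes (L, 2–5 ribosomes) and heavy
polysomes (H, ≥6 ribosomes) — in control and stressed cells, with two capped
RNA spikes (GFP, luciferase) added to every pool for normalization.

For every promoter the package computes, with a pseudo-count ψ (default 0.5)
added to each normalized fraction count:

- **Ribosome occupancy** — RO = ((L+ψ) + (H+ψ)) / (F+ψ), a proxy for
  translation efficiency of the transcripts from that promoter;
- **RO effect** — RO_stress / RO_control, the translational stress response;
- **mRNA change** — (F+L+H)_stress / (F+L+H)_control, the transcript-level
  response;

and makes the categorical calls built on them:

- promoters **translationally affected** by stress (RO effect ≥2-fold, in
  every replicate);
- **differentially translated AP pairs**: within-gene promoter pairs whose
  ROs differ ≥2-fold in every replicate, called independently per condition,
  with gene-level summaries and the overlap (Venn) between conditions, the
  mRNA differential effect, same-ORF flags and spliced 5'UTR lengths;
- **TOP promoters** (5' terminal oligopyrimidine: summit 5-mer CYYYY) and
  initiating-nucleotide/trinucleotide stratification of RO effects;
- **metagene TSS profiles** (z-normalized coverage in ±200 nt windows).

A separate module fits eIF4E–capped-RNA dissociation constants from
intrinsic-fluorescence titrations with the depletion-corrected 1:1 binding
isotherm (protein at 300 nM is comparable to the Kd, so the hyperbolic
approximation would be biased), with multi-start least squares and bootstrap
confidence intervals.

Everything is exercisable without any download: `sim_config()` /
`simulate_genome_and_annotation()` / `simulate_capseq_counts()` generate a
complete synthetic CapSeq experiment (genome, annotation, stranded 5'-end
coverage, spikes) with known ground truth, including an exact
"expectation mode" for oracle testing.

## Worked example

```r
library(captrans)
library(data.table)

cfg <- sim_config(n_genes = 120, seed = 42)
ann <- simulate_genome_and_annotation(cfg)
sim <- simulate_capseq_counts(cfg, ann)

ex     <- spike_normalize(sim$experiment)
counts <- quantify_promoters(ex, ann$promoters)
fracs  <- filter_expressed(fraction_matrix(counts), min_reads = 500)
stats  <- translation_stats(fracs)

table(call_affected(stats)$direction)
#> repressed unaffected
#>         6        151

summ <- ap_summary(call_differential_pairs(fracs))
sprintf("genes with a differential AP pair: %d (control), %d (stress); +%.1f%%",
        summ$genes_control, summ$genes_stress, summ$percent_increase_genes)
#> "genes with a differential AP pair: 7 (control), 8 (stress); +14.3%"

## TOP promoters are strongly repressed under stress
tops <- attr(counts, "summits")[!is.na(summit)]
tops[, pentamer := mapply(context_at, chrom, summit, strand,
                          MoreArgs = list(genome = ann$genome, k = 5))]
tops[, is_top := classify_top(pentamer)]
m <- merge(stats, tops[, .(promoter_id, is_top)], by = "promoter_id")
sprintf("median log2 RO effect: TOP %.2f vs non-TOP %.2f",
        median(m[is_top == TRUE, log2_ro_effect]),
        median(m[is_top == FALSE, log2_ro_effect]))
#> "median log2 RO effect: TOP -2.39 vs non-TOP -0.14"
```

The 6 repressed promoters and the −2.39 median log2 RO effect of
TOP promoters reflect the simulation's planted biology (TOP repression
fold 4, pyrimidine-initiated transcripts repressed); non-TOP promoters sit
near −0.14 (mild repression from the planted C/T nucleotide effects).

Binding titrations:

```r
curve <- simulate_titration(kd = 561, f0 = 1, finf = 0.4, protein_conc = 300,
                            ligand_concs = 10^seq(log10(1.25), 4, length.out = 12),
                            noise_sd = 0.01, seed = 1)
fit_kd(curve, n_boot = 500)
#> binding_fit: Kd = 566.9 nM (f0 = 1, finf = 0.4065, SSE = 0.000645)
#>   bootstrap 95% CI: [483, 668.9] nM (500 replicates)
```

The fitted 566.9 nM recovers the simulated 561 nM dissociation constant
within the noise of a 12-point titration; the CI covers it.

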