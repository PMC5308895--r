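---
title: "Models and methods: TSS-resolved translatome analysis with captrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: TSS-resolved translatome analysis with captrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captrans)
library(data.table)
```

# The measurement and its model

CapSeq sequences only the capped 5' ends of mRNAs, so each read start is a
transcription start site (TSS) observation. Sequencing the three polysome
pools — polysome-free (F), light (L, 2–5 ribosomes) and heavy (H, ≥6) — of
control and stressed cells turns TSS usage into a translational readout per
promoter. Two in-vitro-capped spike RNAs (GFP, luciferase) added in equal
known amounts to every pool calibrate per-sample depth.

The coverage model is deliberately minimal: a track is a sparse map
(chromosome, strand, 0-based position) → read mass, the in-memory form of a
stranded bedGraph pair. All coordinates in the package are 0-based
half-open; the 5' end of a minus-strand feature is its rightmost base. Input
coverage is assumed deduplicated and restricted to the first aligned base.

## Normalization

Per sample $s$ and spike $k$ with input mass $m_k$ and observed reads
$r_{sk}$, the raw factor is $m_k / r_{sk}$; a sample's factor is the
geometric mean over its spikes, and factors are rescaled so that their
geometric mean across samples is 1 (the data determine only relative
depths, so one global constant is arbitrary). Zero spike reads are an
error, named per sample. An optional per-fraction multiplier can be
supplied for gradients loaded unequally; the default pathway assumes
equivalent-volume loading plus spikes, which already makes fraction masses
comparable.

## Ribosome occupancy and derived statistics

With pseudo-count $\psi$ (default 0.5) added to every normalized fraction
count,

$$\mathrm{RO} = \frac{(L+\psi)+(H+\psi)}{F+\psi},\qquad
\mathrm{RO\ effect} = \frac{\mathrm{RO}_{stress}}{\mathrm{RO}_{control}},\qquad
\Delta\mathrm{mRNA} = \frac{(F+L+H)_{stress}+3\psi}{(F+L+H)_{control}+3\psi}.$$

The pseudo-count guarantees finite, positive ratios for empty fractions and
is negligible for well-expressed promoters; it can be switched off, in
which case RO is exactly scale-invariant. Displayed statistics use
replicate-mean counts; every categorical call is evaluated on per-replicate
counts, because a "both replicates" rule on means would be meaningless.

Calls, all with inclusive two-fold defaults:

* a promoter is *repressed* (resp. *induced*) when its RO effect is ≤ 0.5
  (≥ 2) in **every** replicate;
* a within-gene promoter pair is *differentially translated* in a condition
  when $\max(\mathrm{RO}_i/\mathrm{RO}_j,\ \mathrm{RO}_j/\mathrm{RO}_i) \ge 2$
  in every replicate of that condition, each condition judged
  independently; pair flags are symmetric under swapping the promoters.

Two readings of "the increase in differential AP translation" exist —
counting genes with at least one flagged pair, or counting flagged pairs —
and `ap_summary()` reports both (`percent_increase_genes`,
`percent_increase_pairs`) plus the pair- and gene-level condition overlap,
so the choice is explicit rather than silent.

## Expression threshold

`apply_threshold()` keeps a promoter when its total normalized mass, summed
over the three fractions and both conditions, reaches `min_reads` (default
500, inclusive) in **every** replicate. Whether such a cutoff should use
raw or normalized reads, pooled or per replicate, is underdetermined in
general; the per-replicate normalized reading is the strictest coherent
one and is the default, with the threshold and input both explicit
arguments so other conventions are one call away.

## Promoter–transcript assignment and 5'UTR lengths

A promoter is the *annotated* promoter of a transcript when its summit (the
promoter's maximal-mass base; ties resolve to the 5'-most base,
strand-aware) lies within 100 nt of the transcript 5' end on the same
chromosome and strand; failing that it is *exonic* when the summit falls in
exonic sequence upstream of the CDS start; otherwise *unassigned*. Among
eligible transcripts the nearest 5' end wins. The 5'UTR length is the
spliced exonic distance from the summit (inclusive) to the CDS start
(exclusive); it is undefined when the summit lies downstream of the CDS
start. Two promoters share an ORF when their assigned transcripts have the
same genomic CDS start.

## Sequence context and the metagene profile

Initiating contexts are read on the sense strand starting at the TSS base
(reverse-complemented for minus-strand TSSs). A promoter is TOP when its
summit 5-mer is `C[CT][CT][CT][CT]`; classification reads the genome at the
summit only, with no allowance for start heterogeneity within the peak —
the literal reading of a summit-initiated pyrimidine tract.
`stratify_ro_by_context()` summarizes log2 RO effects per first nucleotide
and per initiating trinucleotide (median, 5/95 percentiles, n) over TSSs
with at least `min_reads` support (default 50 normalized reads — a
read-support floor has to exist for per-TSS ratios to be meaningful, and
50 keeps the coefficient of variation of a ratio of Poisson counts under
~20%).

The metagene profile cuts a strand-oriented ±200 nt window (401 offsets,
downstream positive) around each TSS, drops windows with fewer than 10
covered bases, z-normalizes each remaining window to mean 0 / sd 1, and
sums. Zero-variance windows (uniform coverage) are also dropped: their
z-score is undefined, and a flat window carries no positional signal.

## Binding isotherm and Kd fitting

Intrinsic-fluorescence titrations are modeled with the depletion-corrected
1:1 isotherm. With total protein $P$, total ligand $L$ and dissociation
constant $K_d$, the bound fraction of protein is the physical root of the
mass-action quadratic, evaluated in the numerically stable form

$$\theta = \frac{2L}{\,b + \sqrt{b^2 - 4PL}\,},\qquad b = P + L + K_d,$$

which avoids catastrophic cancellation and tends to the hyperbolic
$L/(L+K_d)$ as $P \to 0$. The depletion-corrected form is the default
because at $P = 300$ nM — comparable to the Kd range of interest — the
hyperbolic approximation is systematically biased; the hyperbolic model
remains available as an option. The signal is $f_0 + (f_\infty - f_0)\theta$
with the sign of the amplitude free (quench or enhancement).

`fit_kd()` minimizes least squares over $(K_d, f_0, f_\infty)$ with
Levenberg–Marquardt iterations from seven Kd starts log-spaced across the
titrated range, and errors (carrying the best SSE) rather than returning a
spurious Kd when nothing converges or the fitted amplitude is zero (flat
curve). The bootstrap CI resamples residuals inflated by $\sqrt{n/(n-p)}$
($p = 3$ fitted parameters; raw least-squares residuals understate the
noise) and uses the expanded percentile interval (t-based adjusted quantile
levels) — both standard small-sample corrections, without which a
percentile interval at a 12-point titration undercovers. `compare_kds()`
reports a two-sided bootstrap p-value from paired draws of the two fits'
Kd distributions, with +1 smoothing so p is never exactly 0.

# The synthetic-data generator

`sim_config()` defines the study conditions; the defaults emulate the
structure of the real experiment:

| parameter | default | emulates |
|---|---|---|
| `promoters_per_gene_dist` | 75/17/8% for 1/2/3 | mostly single-promoter genes (~3/4) |
| `tss_per_promoter` | 3 | multi-TSS promoter peaks |
| `nt_freq` | A/C/G/T = 34/23/30/13% | observed initiating-nucleotide mix |
| `frac_top_promoters` | 0.045 | the TOP promoter class (~400 of ~9000) |
| `top_repression_fold` | 4 | strong translational repression of TOP mRNAs under stress |
| `nucleotide_effect` | A,G = 1; C = 0.6; T = 0.7 | pyrimidine-initiated transcripts repressed, purine-initiated refractory |
| `global_mrna_drop` | 0.15 | ~15% drop of total mRNA under stress |
| `spike_truth` | GFP 0.25, LUC 0.001 | the two spike input masses (ng) |
| `noise_model` | 0.05 | negative-binomial overdispersion of counts |
| `depth_sdlog` | 0.2 | per-sample depth variation, so normalization is non-trivially exercised |
| `n_replicates` | 2 | two biological replicates |

Per-fraction sequencing depths are not publicly stated for the real
experiment, so `baseline_expression_dist` (log-normal, median 2000 reads
per promoter per sample trio) and `spike_yield` (1e5 reads per input-mass
unit) are invented defaults, labeled as such here.

Counts are negative-binomial with variance $\mu + \phi\mu^2$
(`noise_model` $=\phi$; 0 gives Poisson); *expectation mode* emits the
real-valued expectations themselves so downstream recovery can be checked
to machine precision. Spike counts are Poisson in sampled mode: spikes are
identical aliquots added to every tube, so they carry counting noise but no
biological replicate variance — handling and depth variation is already
modeled by the per-sample log-normal depth factor.

Each TSS's stress RO is its promoter's basal RO (log-normal per gene)
times the nucleotide effect of its own initiating base and the TOP
repression of its promoter; fraction masses split as
$F : (L+H) = 1 : \mathrm{RO}$ with the polysomal mass divided equally
between light and heavy. Promoter-level truth is the exact expectation of
the per-TSS mixture. Differential AP pairs are planted by multiplying the
second promoter's basal RO by `diff_pair_fold` in a `frac_diff_pairs`
fraction of multi-promoter genes. Initiating contexts are planted into an
otherwise random genome — full 5-mers at summits (CYYYY for TOP promoters,
guaranteed non-CYYYY otherwise, so the TOP truth flag is exact), single
bases at non-summit TSSs, with TSSs spaced ≥6 nt so plantings never
collide. A fixed seed reproduces all outputs byte-for-byte; annotation and
counts use separate RNG substreams so the annotation is invariant to how
counts are drawn.

What the generator does **not** emulate: read scatter around TSSs (reads
land exactly on TSS positions, so real peak-shape effects and the metagene
profile of genuine CapSeq data are out of reach — metagene behavior is
validated on explicitly constructed tracks instead), sequencing error,
alignment artifacts, UMI duplication, antisense or intergenic background,
and correlated biological replicate structure beyond NB overdispersion.
Passing tests therefore demonstrate correctness of the computations under
the stated model, not robustness to every artifact of real libraries.

# Numerical and degenerate-input choices

* Summit ties break to the 5'-most base, strand-aware; an all-zero promoter
  has no summit (error in `find_summit()`, `NA` through
  `quantify_promoters()`).
* Threshold comparisons are inclusive (≥), matching "two-fold or more".
* Empty promoter sets give empty (not error) global sums; an empty usable
  region set is an error for the metagene, which cannot return a profile.
* The isotherm quadratic uses the stable root form above; fits bound
  Kd > 0.
* `coverage_track()` sums duplicate positions and drops zero masses, giving
  every track a unique canonical file form (sorted, merged runs) so
  write∘read is the identity.

# Problem sizes

The shipped tests run the full pipeline on simulations of 8–400 genes
(up to ~1600 TSSs), 100 random count matrices of up to 200 promoters for
the brute-force oracle comparisons, exhaustive checks over all 1024
5-mers, and 100-repeat coverage simulations with 200 bootstrap refits per
Kd fit — sizes chosen so the whole suite completes in a few minutes on one
CPU while every statistical check retains enough resolution to fail
loudly.

# Known limitations

* Fold-change rules only, as in the analysis this package reproduces: no
  dispersion modeling, no p-values, no multiple-testing correction for the
  promoter and pair calls. The calls are exactly the stated deterministic
  rules.
* Promoter annotation is an input; there is no peak calling.
* The 100 nt assignment window and the summit-only TOP rule are literal
  conventions; promoters with heterogeneous starts may be mis-typed.
* `compare_kds()` treats the two bootstrap distributions as independent;
  curves measured on the same instrument session may share systematic
  error that the p-value ignores.
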