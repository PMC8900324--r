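---
title: "Protocol signatures in run-on sequencing: models, metrics and simulation"
author: "runonSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protocol signatures in run-on sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runonSig)
suppressPackageStartupMessages(library(GenomicRanges))
```

## Scope and model

Nuclear run-on assays (GRO-seq, PRO-seq) sequence RNAs attached to engaged
RNA polymerases. Which enrichment protocol and which library preparation a
dataset used leaves systematic, measurable traces in the data: 5' peak
position and shape near transcription start sites, high-frequency texture in
per-base coverage, mature-mRNA (exonic) carryover, terminal sequence content
(poly(A) tails from circularization preps, C-runs from template-switch
reverse transcription), and read-length distributions. `runonSig` quantifies
those traces with formula-defined QC statistics, extracts a per-gene
protocol signature with a wavelet decomposition, classifies enrichment
protocols with a linear SVM under leave-one-out cross-validation, and
provides a mechanistic read simulator plus a synthetic cohort generator so
that every stage is testable without external data.

## QC statistics

**Pausing index.** For a gene with TSS-anchored pause region and gene body,

$$\mathrm{PI} \;=\; \frac{N_\text{pause}/L_1}{N_\text{body}/L_2},$$

with the pause region spanning offsets $[-50, +250)$ from the TSS
($L_1 = 300$ bp) and the body from $+250$ to the annotated cleavage site
($L_2$ = gene length $- 250$). We treat the printed region bounds as
half-open offsets: a closed $[-50, +250]$ interval would contain 301
positions and contradict $L_1 = 300$. A read is assigned to a region by its
5' end on the gene's strand, which makes the assignment unambiguous at the
pause/body boundary; genes under 2 kb are excluded, and a body without reads
yields an undefined (NA) index. An alternate windowing
(`pauseWindows(20, 80, polyAOffset = 1000)`) reproduces the
featureCounts-style variant.

**Exon/intron ratio.** Mature-mRNA contamination is scored per gene as
$\log_2(\mathrm{RPKM}_\text{exon}/\mathrm{RPKM}_\text{intron})$, with the
first exon in transcription order excluded (its initiation peak is nascent
signal, not contamination) and low-signal genes (whole-gene RPKM < 1)
removed; a library is summarized by the median. The log base is 2 — the
ratio is reported on a fold-change-style scale.

**Gene/intergenic ratio, short-read TSS ratio, sequence signatures,
complexity.** Genic reads are those overlapping the strand-agnostic union
of annotated genes by at least 1 bp (the usual read-distribution
convention), while the pausing index, TPM and exon/intron counting are
strand-aware. The short-read metric keeps reads of at most 30 nt and asks
what fraction have their 5' end within 20 bp of a same-strand TSS. Prep
signatures count reads ending in at least 8 consecutive A, or carrying at
least 3 C in the final 5 nt; these thresholds are package choices (the
phenomena they detect are qualitative figure observations, with no numeric
thresholds attached). Complexity is the fraction of distinct read placements
and the number of distinct covered bases.

## Wavelet protocol signature

Per-gene coverage $x$ is normalized to $c_i = (x_i - \min x)/(\max x -
\min x)$ and decomposed once with the symlet-5 filter bank into
approximation (consistent polymerase signal shape) and detail
(high-frequency texture) coefficients. Genes are restricted to stably,
highly transcribed ones — CV $< 0.55$ and mean TPM $> 150$ across the
cohort (a wider tier, CV $< 0.85$ / TPM $> 100$, is available through the
same thresholds) — so that biological variability does not mask technical
texture. CV uses the population standard deviation; TPM counts sense-strand
read 5' ends over the full annotated gene body, matching the full-transcript
coverage the wavelet consumes.

Per gene, the samples-by-coefficients detail matrix is mean-centered
(no variance scaling — the coefficients share units) and projected onto its
first two principal components; each component is oriented so its
largest-magnitude loading is positive, making scores reproducible. Genes are
then categorized by whether a threshold on PC1 alone separates the
protocols, a line in the (PC1, PC2) plane does, or neither; separability is
decided exactly (candidate separating directions from point-pair geometry),
not by a fitted classifier.

### Boundary handling

The default boundary mode is anti-symmetric reflection (`antireflect`):
the signal is continued through each endpoint by point symmetry, which
extends constant and linear trends exactly. We prefer it over mirror
padding because coverage signals routinely end on a slope, and mirror
padding turns every sloped end into an artificial kink whose energy leaks
into the detail band — under anti-symmetric extension a pure ramp has
vanishing detail coefficients, under mirror padding it does not. Mirror
(`symmetric`) and circular (`periodization`) modes are available; the
periodization variant is the orthonormal one on which
$\lVert x\rVert^2 = \lVert cA\rVert^2 + \lVert cD\rVert^2$ holds exactly
(even lengths), and perfect reconstruction holds in all modes to floating
point. Gene coverage vectors keep their native length; no resampling is
performed, and a gene is skipped (never imputed) if any sample's coverage
is constant.

## Protocol classification

The per-gene (PC1, PC2) scores feed a linear-kernel SVM
(`e1071::svm`, cost $C = 1$, the toolkit defaults including its internal
feature standardization; no additional user-level scaling is applied to the
scores). Evaluation is leave-one-out across samples: $n$ samples give
exactly $n$ folds, PCA being computed once on all samples before fold
evaluation (refitting PCA inside each fold is a possible variant; the
package follows the simpler fixed-scores order, and its tests quantify the
null behavior of that choice). A sample's protocol call is the modal
prediction across genes, with exact vote ties broken by the summed SVM
decision values and flagged.

Two properties of this design deserve explicit caution:

* **Null behavior of LOOCV.** With balanced classes, holding out a sample
  leaves its class in the training minority (8 vs 9 in an 18-sample
  cohort); a soft-margin classifier then leans toward the majority class,
  which is the *wrong* class for the held-out sample. On signature-free
  data the mean per-gene accuracy therefore sits systematically *below*
  0.5 (roughly 0.3-0.45 in this package's null simulations), not at 0.5.
  The package's null tests assert against this empirically derived band.
* **Standardization vs rotation.** The SVM's internal per-feature
  standardization is not rotation-equivariant; exact rotation invariance of
  accuracies holds when `scale = FALSE` is requested, and is tested there.

## Run-on read simulator

The simulator implements the run-on chemistry on a 2000-nt template with
equal base proportions: initiation polymerases load around the TSS
(Normal, rounded, reflected onto the template), elongating polymerases sit
uniformly in the body (positions 251-1750 by default), and each polymerase
extends base by base; at every occurrence of the labeled base (C,
biotin-11-CTP) extension halts with probability `pBio`, otherwise a 100-nt
cap or the template end stops it. With equal base proportions the run-on
length is approximately geometric with per-base rate `pBio/4` (mean
$4/p$). Reads then pass exponential size selection — a cutoff drawn with
mean 25 nt, retained when length ≥ cutoff, so
$P(\text{retained}\mid L) = 1 - e^{-L/25}$ — and a 25-nt mappability floor
(the usual trimming minimum for short-read alignment).

Read spans follow the biology of the enrichment. Initiation-polymerase
reads span TSS to termination: a short nascent RNA survives hydrolysis
intact, so its 5' end is the TSS. Elongating-polymerase reads span
polymerase position to termination: a long nascent transcript is
fragmented, and only the biotin-labeled 3' fragment is enriched, so its 5'
end carries no TSS information. (A TSS-anchored span for *all* reads would
make the short-read TSS ratio identically 1 and pin every coverage peak to
the TSS — it cannot express the phenomena of interest.) A third component,
background handling fragments (4000 reads, uniform positions, exponential
lengths of mean 30 nt), represents sample-degradation products and is
independent of the run-on chemistry.

Initiation loading is centered *at* the TSS (mean 0, sd 10 nt, folded to
the template side), following the polymerase-loading convention of
probabilistic models of run-on data in which promoter-proximal density is
generated by loading at the start site. This placement matters: mappable
TSS-proximal short reads then require enough run-on to clear the 25-nt
mappability floor but not so much that they exceed 30 nt, which is exactly
the regime in which the short-read TSS ratio attains its maximum at
*intermediate* biotin ratios — too little biotin yields reads too long to
be short, too much yields TSS fragments too short to map. The simulator
emits both full-read coverage and the 3'-end (single-base polymerase
position) density; peak-shift statements are read from the 3'-end density,
which is the single-base convention of precision run-on data.

## Synthetic cohort generator

`generateCohort()` builds a deterministic genome (default 100 genes of
2-4 kb, 2-5 exons, one chromosome, lognormal expression weights fixed per
genome) and per-library reads from a four-component mixture: a Gaussian 5'
peak at the protocol's offset from the TSS, a uniform gene-body component,
an exon-restricted contamination component, and intergenic background. A
multiplicative sinusoidal texture with protocol-specific period (6 bp for
GRO-mode, 3 bp for PRO-mode, amplitude 0.4) is applied to the genic
sampling intensity, phase-locked to genomic coordinates so all samples of a
protocol share the pattern — this is what "systematic high-frequency
texture" means here, and the periods are deliberately inside the passband
of a single-level symlet-5 detail band. Each injected signature is
recoverable by exactly one measuring module: peak offsets by the metagene
argmax, contamination weights by the exon/intron median, tail rates by the
prep-signature scores, texture by the wavelet classifier.

Defaults were fixed once, as the generator's study conditions: 9 + 9
samples (the LOOCV setting of an 18-library cohort), 300k reads per
library with 10% lognormal depth jitter, GRO/PRO peak offsets +20/+80 bp
(width 30 bp), contamination weights 0.15/0.08 (GRO carries more mature
mRNA), intergenic weights 0.05/0.10 (GRO is relatively more genic), short
fragment rates 0.02/0.10, and prep tail rates of 0.5 for the CIRC and TSRT
signatures. The texture amplitude (0.4) was calibrated so that the wavelet
detail band separates the protocols at this depth with a comfortable
margin. Coverage tracks are always rebuilt from the emitted reads, so
coverage and reads cannot disagree.

What the generator does *not* emulate: real genome sequence (read
sequences are i.i.d. background plus prep tails, so mappability,
GC-dependence and sequence-driven biases are out of reach), PCR duplicate
structure, replicate batch effects, and biological differential
transcription. Passing tests on generated cohorts therefore demonstrate
that the pipeline recovers the signatures it targets at realistic depths
and noise — not that real libraries are this cleanly separable.

## Metagenes

TSS-anchored profiles average CPM-scaled sense and antisense coverage
across genes (equal weight per gene, then equal weight per library; the
alternative, pooling base-wise counts before normalizing, weights genes by
expression and is deliberately not the default). Gene filters: length at
least 2 kb, at most 1% of upstream-window bases covered on the gene's
strand (window 2 kb, or 1 kb for the narrower variant), TPM at least 0.01.
"Covered" is a sense-strand statement; an upstream neighbor on the
opposite strand does not disqualify a gene. Peak positions are the argmax
of the sense profile with ties broken toward the TSS.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive internally (Bioconductor convention);
BED/bedGraph input is 0-based half-open and converted on import. Constant
coverage cannot be minmax-normalized and raises an error; callers skip such
genes. TPM with all-zero counts, empty short-read sets, empty metagene
filters, and single-class label sets all raise errors rather than returning
silently degenerate values. An all-genic library yields an infinite
gene/intergenic ratio (sentinel), and a gene body without reads an NA
pausing index. All stochastic components run from explicit integer seeds;
cohort samples use seeds derived deterministically from one master seed so
any library can be regenerated in isolation.

## Problem sizes used by the test-suite and acceptance runs

The shipped tests exercise the full pipeline on generated cohorts of 8-100
genes at depths of 25k-300k reads per library, and the simulator at its
default 19k reads per condition; these sizes recover every calibrated
signature while keeping the whole suite comfortably reproducible on a
single CPU.

## Known limitations

* Only single-level decomposition and the symlet-5 wavelet are
  implemented; the analysis is defined at one pass, and deeper stacks are
  out of scope.
* The classifier targets the two-class GRO/PRO distinction; library-prep
  (four-class) classification is out of scope.
* The LOOCV null bias discussed above means "chance level" for this design
  is below 0.5; comparisons against a naive 0.5 baseline overstate the
  distance from chance.
* Read sequences in the generator carry prep tails appended beyond the
  genomic interval (untrimmed-library emulation); sequence length and
  interval width differ by design for tailed reads.
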