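# runonSig

Quality metrics and protocol-signature analysis for nascent transcription
run-on sequencing libraries (GRO-seq / PRO-seq), for genomics analysts who
need to ask: *which enrichment protocol and library preparation produced
this dataset, and how do those choices distort what I measure?*

Run-on protocols leave systematic technical traces: the position and shape
of the 5' coverage peak near transcription start sites, high-frequency
texture in per-base coverage, mature-mRNA (exonic) carryover, terminal
sequence content (poly(A) tails from circularization preps, C-runs from
template-switch reverse transcription), and the read-length distribution.
`runonSig` turns each trace into a statistic, and the coverage texture into
a classifier.

## What it computes

**QC statistics** (per library, from strand-specific coverage and reads):

- Promoter-proximal pausing index per gene:
  `PI = (N_pause / L1) / (N_body / L2)`, pause region offsets `[-50, +250)`
  from the TSS (`L1 = 300` bp), body from `+250` to the annotated cleavage
  site; genes under 2 kb removed, reads assigned by their sense-strand 5'
  end.
- Exon/intron contamination: per-gene
  `log2(RPKM_exon / RPKM_intron)` (first exon excluded, whole-gene
  RPKM >= 1), summarized by the median.
- Gene/intergenic read ratio, short-read TSS ratio (reads <= 30 nt whose 5'
  end is within 20 bp of a same-strand TSS), positional nucleotide
  composition, poly(A)/terminal-C prep signatures, and library complexity.

**Wavelet protocol signature and classifier:** per-gene coverage is
minmax-normalized (`c_i = (x_i - min x) / (max x - min x)`), decomposed once
with a symlet-5 filter bank, and the detail coefficients reduced per gene to
(PC1, PC2) scores across samples; a linear SVM evaluated by leave-one-out
cross-validation (one fold per sample) classifies GRO vs PRO, and a
majority-rules vote across genes calls each sample's protocol. Genes are
pre-selected for stability (CV < 0.55, mean TPM > 150 across the cohort).

**Run-on read simulator:** a mechanistic model of the run-on reaction on a
2000-nt template — polymerases load around the TSS, extension halts at each
labeled base (biotin-11-CTP) with probability `pBio`, reads pass exponential
size selection (mean cutoff 25 nt, `P(retained | L) = 1 - exp(-L/25)`) and a
mappability floor — reproducing, among other things, the non-monotone
dependence of the TSS short-read fraction on the biotin ratio.

**Metagenes:** TSS-anchored, CPM-normalized average sense/antisense
profiles with the standard gene filters (length >= 2 kb, clean 2-kb
upstream window, TPM >= 0.01).

**Synthetic cohort generator:** seeded, fully labeled cohorts of run-on
libraries with controllable protocol and prep signatures, so every stage of
the pipeline is testable without downloads.

## Worked example

```r
library(runonSig)

# a labeled 18-sample synthetic cohort (9 GRO-mode + 9 PRO-mode, 10 genes)
gen <- generateCohort(cohortConfig(nGenes = 10, depthPerSample = 3e4, seed = 3))
lib <- gen$cohort[[1]]
lib
#> RunOnLibrary GRO_LIG_01 [GRO-LIG]
#>   reads: 30441 | totalReads: 30441

exonIntronRatio(lib, gen$genes)$median     # mature-mRNA contamination
#> [1] 0.4553975
geneIntergenicRatio(lib, gen$genes)        # genic enrichment
#> [1] 19.21315

# wavelet features -> per-gene LOOCV SVM -> majority-rules protocol calls
res <- classifyCohort(gen$cohort, gen$genes)
res$loocv
#> LOOCVResult: 10 genes, 18 folds | mean per-gene accuracy: 0.978
res$sampleCallAccuracy
#> [1] 1

# TSS metagenes recover the injected 5' peak shift (GRO +20 vs PRO +80)
buildMetagene(lib, gen$genes, upstream = 500, downstream = 1500)
#> MetageneProfile: positions -500..1500, 10 genes, 1 sample(s); sense peak at +44 bp
buildMetagene(gen$cohort[["PRO_LIG_01"]], gen$genes, 500, 1500)
#> MetageneProfile: positions -500..1500, 10 genes, 1 sample(s); sense peak at +100 bp
```

The per-gene accuracy (0.978) is the fraction of leave-one-out folds in
which the SVM recovers the protocol from that gene's (PC1, PC2) wavelet
scores; majority voting across genes calls all 18 samples correctly. The
two metagene peaks differ by ~60 bp, recovering the configured protocol
offset difference; the residual shift of each peak comes from read-length
smoothing and is common to both protocols.

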