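# diurnalTE

Diurnal (24-h) rhythms in gene expression can be generated at different
layers: rhythmic transcription, rhythmic mRNA stability, or rhythmic
translation. Ribosome profiling makes the layers separable: intronic
(pre-mRNA) reads proxy transcription, exonic reads measure mRNA
abundance, and CDS-mapping ribosome-protected fragments (RPFs) measure
translation. The motivating system is the IRP/IRE network in mouse
liver, where iron regulatory proteins (IRP1/*Aco1*, IRP2/*Ireb2*) bind
iron-responsive elements: 5′ IREs (e.g. *Ftl1*, *Fth1*, *Alas2*)
repress translation rhythmically — constant mRNA, strongly rhythmic
ribosome occupancy with a trough at the light–dark transition (ZT12) —
while the 3′ IRE of *Tfrc* drives rhythmic mRNA stability; both follow
feeding–fasting cycles rather than the circadian clock proper.

`diurnalTE` is a Bioconductor-style R package for this kind of
analysis, for computational biologists working with matched
RPF/mRNA/pre-mRNA count time courses (or wanting a fully testable
in-silico version of one):

- **quantify** — upper-quartile normalization, RPKM, per-animal
  translation efficiency `TE = log2((RPF + c) / (mRNA + c))`, condition
  means; read-length filters (24–35 nt footprints, 21–60 nt total RNA).
- **rhythm** — cosinor fitting
  `y(t) = m + a·cos(2πt/24) + b·sin(2πt/24)` with amplitude
  `A = √(a² + b²)`, acrophase `φ = (24/2π)·atan2(b, a)`, peak-to-trough
  fold-change `2^(2A)`, F-test p-values with BH/Šidák adjustment, and
  classification of the rhythm-generating layer
  (TRANSCRIPTIONAL / POST_TRANSCRIPTIONAL / TRANSLATIONAL / MIXED /
  NONE) from the intron/exon/TE fits.
- **differential** — two-timepoint knockout-versus-control TE contrasts
  (pooled-variance t-tests; one-way ANOVA with Šidák post hoc),
  derepression-pattern calls (light-phase-only, dark-phase-only,
  constitutive), and western-blot quantification against a loading
  control.
- **clustering** — z-scored TE-profile k-means (k-means++ seeded Lloyd,
  best of n restarts, default k = 15) with average-linkage hierarchical
  ordering inside each cluster and neighbourhood queries.
- **synthetic_data** — a negative-binomial generator whose gene classes
  encode the regulatory model (clock- vs feeding-driven rhythms per
  layer, knockout derepression, feeding-regime modulation, a
  transcriptome-like constant background) together with a ground-truth
  ledger, so every stage is testable without sequencing data.
- **cli_io** — TSV/YAML I/O, `runPipeline()` end-to-end orchestration,
  and a thin script wrapper (`inst/scripts/run-pipeline.R`).

## Worked example

Simulate the two-timepoint knockout cohort (ZT5/ZT12 × WT, *Aco1*-KO,
*Ireb2*-KO, *Bmal1*-KO × 3 animals), compute per-animal TE, and test a
ferritin-like gene for derepression in the *Ireb2* knockout:

```r
library(diurnalTE)

sim <- simulateExperiment(koCohortConfig(seed = 5))
te  <- translationEfficiency(normalizeCounts(sim$counts$rpf),
                             normalizeCounts(sim$counts$rna_exon))
ctr <- rbind(teContrast(te, "Ftl1_like_g01",  5, "Ireb2KO"),
             teContrast(te, "Ftl1_like_g01", 12, "Ireb2KO"))
ctr[, c("gene", "zt", "ko", "delta", "t", "p")]
#>            gene zt      ko  delta     t       p
#> 1 Ftl1_like_g01  5 Ireb2KO 2.1894 7.054 0.00213
#> 2 Ftl1_like_g01 12 Ireb2KO 0.0484 0.287 0.78854
derepressionProfile(ctr)$pattern
#> [1] "LIGHT_PHASE_ONLY"
```

The knockout lifts this gene's TE by ~2.2 log2 units at ZT5 while the
two genotypes are near-identical at ZT12 — loss of the repressor
matters only in the light phase, implying a second, redundant repressive
activity at dark onset. A 24-h cosinor on the same gene's footprint
series from the around-the-clock design shows the translational rhythm
itself:

```r
sim2 <- simulateExperiment(simConfig(seed = 5))   # 12 timepoints x 2
y    <- log2(rpkm(sim2$counts$rpf)["Ftl1_like_g01", ] + 0.5)
cosinorFit(SummarizedExperiment::colData(sim2$counts$rpf)$zt, y,
           gene = "Ftl1_like_g01")
#> CosinorFit [Ftl1_like_g01]: period 24 h, n = 24
#>   mesor 5.259, amplitude 0.864 (log2), peak ZT23.98, fold 3.31
#>   p = 3.07e-07, q = NA
```

The fitted peak sits just before ZT0, i.e. the trough is at ~ZT12 (the
light–dark transition) and ribosome occupancy swings ~3.3-fold while
the gene's mRNA stays flat. `runPipeline()` chains quantification,
rhythm or contrast analysis, and clustering, writes schema-tagged TSV
tables plus a JSON run summary, and reports truth-recovery accuracy on
simulated input.

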