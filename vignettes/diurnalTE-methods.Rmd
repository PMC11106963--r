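---
title: "Dissecting diurnal regulation with diurnalTE: models, defaults, and design choices"
author: "diurnalTE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting diurnal regulation with diurnalTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diurnalTE)
```

## The question and the decomposition

A transcript can acquire a 24-h rhythm at three layers: transcription,
mRNA stability, or translation. With matched count tables for intronic
pre-mRNA, exonic mRNA, and CDS-mapping ribosome footprints (RPF), the
layers separate cleanly:

* rhythmic **pre-mRNA** implies rhythmic transcription;
* rhythmic **mRNA over flat pre-mRNA** implies a post-transcriptionally
  generated rhythm (stability), the *Tfrc* pattern;
* rhythmic **translation efficiency** (TE, the normalized RPF/mRNA
  ratio) implies translational control, the *Ftl1*/*Fth1*/*Alas2*
  pattern of the hepatic IRP/IRE system.

`classifyRegulatoryMode()` applies exactly this logic to cosinor fits
of the four layers, flagging genes as TRANSCRIPTIONAL,
POST_TRANSCRIPTIONAL, TRANSLATIONAL, MIXED, or NONE.

## Quantification

Counts are normalized by the upper-quartile method: genes with zero
counts in every sample are dropped, each sample's 75th percentile of
the remaining counts is taken, and factors are centred to geometric
mean 1. Two conventions matter enough to pin down:

* the percentile is type 7 (linear interpolation between order
  statistics), because upper-quartile factors differ across percentile
  conventions;
* because the factors are geometric-mean centred, rescaling one
  library's counts rescales the whole normalized matrix by a common
  constant `c^(1/n)`; all *relative* values (the quantities every
  downstream stage consumes) are invariant, and the tests assert
  invariance in that form.

RPKM uses the raw library size (total mapped reads), not the
normalization factors: `rpkm = 1e9 · count / (library_size ·
length_bp)`, with the assay-appropriate length (CDS for footprints,
exonic for mRNA, intronic for pre-mRNA).

TE is computed per animal as `log2((rpf_norm + c)/(rna_norm + c))`
with pseudocount `c = 0.5` normalized counts — negligible for
expressed genes, but it keeps knockout-ablated genes finite. RPF and
RNA libraries are paired on `(genotype, ZT, replicate)`, i.e. the same
animal. Because CDS and exonic lengths do not cancel in the ratio, TE
is a relative quantity: comparable across samples for one gene, across
genes only qualitatively.

## Rhythm model

Rhythms are fit as a single 24-h harmonic on the log2 scale
(`log2(RPKM + 0.5)`, or log2 TE):

$$y(t) = m + a\cos(2\pi t/24) + b\sin(2\pi t/24)$$

with amplitude $A=\sqrt{a^2+b^2}$ (half peak-to-trough in log2 units),
acrophase $\varphi = (24/2\pi)\,\mathrm{atan2}(b,a)$, and linear
peak-to-trough fold-change $2^{2A}$, so a "tenfold amplitude" protein
corresponds to $A = \log_2(10)/2$. The p-value is the F-test of the
harmonic pair against the intercept-only model, df $(2, n-3)$;
replicates enter as independent observations, preserving degrees of
freedom. A constant series is reported flat with $p = 1$. The
single-harmonic form is the minimal model consistent with smooth
once-peaking diurnal profiles and gives closed-form amplitude and
phase; multi-harmonic model selection is out of scope.

A gene is *called* rhythmic when its BH-adjusted q-value (adjusted
across the genes of one layer) passes $\alpha = 0.05$ **and** its
fold-change reaches 1.5 — the fold floor deliberately leaves the
"modest rhythmicity" regime (< 1.5-fold, e.g. the *Aco1*/*Ireb2*
mRNAs themselves) uncalled. Both thresholds are arguments.

Two-timepoint designs cannot identify a rhythm; the pipeline refuses
to fit them and routes such designs to the contrast stage. This is a
hard error, not a silent skip.

## Knockout contrasts and derepression patterns

Per gene and timepoint, knockout vs control TE is tested with the
pooled-variance (Student's) unpaired two-tailed t-test — the
convention of standard prism-style analyses; `anovaSidak()` provides
the one-way-ANOVA-with-Šidák variant used for multi-group protein
quantifications. Batch runs (`teContrasts()`) apply BH across all
contrasts of the run; single-gene derepression calls use the
unadjusted per-gene tests, matching how individual transcripts are
assessed in practice. A timepoint shows derepression when the adjusted
p passes $\alpha$ **and** the effect reaches `min_delta` (default 0.5
log2) — the magnitude floor exists because significance alone would
call trivially small shifts. The two-timepoint pattern is then
LIGHT_PHASE_ONLY (ZT5 only — the IRP2-knockout ferritin signature,
evidence for a redundant dark-onset repressor), DARK_PHASE_ONLY,
CONSTITUTIVE, or NONE. For abundance contrasts of 3′-IRE genes the
floor applies to |delta| and the sign is reported raw.

## Clustering

TE condition-means (replicate means per genotype × timepoint) are
z-scored per gene (sample sd, n−1; zero-variance genes dropped and
listed) and partitioned by k-means with k = 15, the configuration the
within-cluster sum-of-squares curve supports for this kind of data;
`kmeansWss()`/`elbowK()` expose the curve. The implementation is Lloyd
iteration from k-means++ seeds, best of `n_init = 10` restarts,
deterministic given the seed; an emptied cluster is re-seeded from the
point farthest from its centroid. These policies (seeding, restart
count, empty-cluster handling, tie-breaking) are pinned in-package
rather than delegated so that partitions are bit-reproducible; the
implementation is cross-checked in the tests against `stats::kmeans`
on well-separated data and against exhaustive enumeration of all
2-partitions at small n. Within each cluster, genes are ordered by
average-linkage hierarchical clustering on Euclidean distances
(`stats::hclust`; ties resolve by input index), giving the
deterministic leaf order that neighbourhood queries
(`clusterNeighbors()`) traverse.

Note what z-scoring implies for interpretation: it removes mesor and
amplitude, so two classes with proportional TE profiles (e.g. a strong
and a weak version of the same regulatory pattern) are *identical* to
the clustering by construction. Co-clustering recovery should
therefore be judged against profile *shapes*, not raw class labels.

## The synthetic experiment generator

`simulateExperiment()` draws the three count layers around analytic
means: per gene, layer and sample,
$\log_2 \mathrm{rpkm}(t) = \log_2(\mathrm{baseline}) +
A\cos(2\pi(t-\varphi)/24)$ after feeding-regime and knockout
modification, and
$\mu = \mathrm{rpkm}\cdot \mathrm{length}/10^3 \cdot
\mathrm{library}/10^6$. Counts are negative-binomial with
$\mathrm{Var} = \mu + \mu^2/\theta$ and shared dispersion $\theta = 20$
(noise model and value are generator choices — no quantitative noise
model is available for the reference data — and both are explicit in
the config); `noise = "off"` yields `round(mu)` for exact oracle
tests, and `expectedRpkm()` exposes the noise-free surface itself.
Identical configs, including the seed, give bit-identical output.

Default study conditions: around-the-clock design with 12 timepoints
at 2-h spacing × 2 replicates, or the knockout cohort with ZT5/ZT12 ×
{WT, Aco1KO, Ireb2KO, Bmal1KO} × 3 animals (eight conditions); equal
library sizes of 10⁷ reads so RPKM targets are exact; night-restricted
feeding (dark-phase intake fraction 1), under which configured
amplitudes are realized unchanged.

The default panel encodes the qualitative biology per class
(`defaultGenePanel()` for the full parameter list): ferritin-like
classes with flat RNA and a 2-fold-amplitude TE rhythm, baseline
log2 TE −2.5 (within the −4..−1 range typical of strongly repressed 5′
IRE transcripts); an Alas2-like class at half amplitude and milder
baseline; a Tfrc-like class with flat intron and a 0.75-log2 mRNA
rhythm peaking ZT18 that footprints track; a sub-threshold
Slc40a1-like class (1.41-fold, deliberately below the 1.5-fold call
floor); flat high-TE Aco2/Epas1-like classes; a clock-driven Dbp-like
class with 16-fold pre-mRNA and mRNA rhythms; marker classes for the
IRP-encoding genes themselves with maximal footprint RPKM 150 (Aco1)
and 25 (Ireb2) and a modest 1.3-fold mRNA rhythm peaking ZT10; and a
constant background class.

Choices worth justifying explicitly:

* **Trough anchoring.** The translational classes anchor the TE
  *trough* at ZT12, the light–dark transition where IRE-mediated
  repression peaks; with a single harmonic this places the fitted peak
  at ZT0, whereas the physiological maximum of translation lies in the
  light phase as a broad plateau. A pure cosine cannot represent both
  a ZT5 plateau maximum and a ZT12 trough; the trough is the quantity
  the analyses track, so it is the anchored feature. The same applies
  to the simulated IRP2 protein curve: its empirical trough is an
  early-light plateau (~ZT0–4), which the peak-ZT12 cosine centres at
  ZT0, and the default blot-quantification design samples the model
  curve's trough (ZT0) and peak (ZT12), five animals each, lognormal
  noise of CV 0.2 on target and loading bands. Recovery is judged on
  the peak/trough ratio, not the trough's clock position.
* **Background composition.** Percentile-based normalization presumes
  a dominant stable background, as real transcriptomes provide. The
  constant class therefore outnumbers each signal class 200:1 with
  baselines spread over 10 log2 units (2100 genes by default). With a
  small panel of mostly-regulated genes, upper-quartile factors absorb
  condition-dependent composition shifts and bias knockout TE deltas —
  a real phenomenon this choice keeps at realistic (negligible)
  magnitude.
* **Feeding regimes.** Feeding-driven rhythms scale with
  `|2·dark_fraction − 1|` and invert by 12 h under day-feeding;
  clock-driven rhythms ignore the regime but flatten in the
  clock-deficient (Bmal1KO) genotype. Presets span night-restricted
  (1.0), ad libitum (0.76), damped (0.56), arrhythmic (0.51) and
  day-fed (0.0) intake fractions. The default is night-restricted so
  that class amplitudes mean what they say; ad libitum would scale
  every feeding-driven amplitude by 0.52.
* **Self-knockouts.** A genotype that disrupts a marker gene's own ORF
  scales its footprints by 0.05 while leaving 70% of its mRNA — the
  knockout allele still produces a transcript.

The generator emulates mean structure, NB noise, and design geometry.
It does **not** emulate read-level artifacts (mappability, UMI
saturation), count correlation between layers of the same animal
beyond the shared mean, batch effects, or inter-animal variability
beyond NB dispersion; passing recovery tests therefore demonstrates
correctness of the analysis logic under the stated statistical model,
not robustness to every failure mode of real libraries.

## Numerical choices and degenerate inputs

* Cosinor needs ≥ 4 distinct timepoints (df ≥ 1 for the F-test);
  identical timestamps are an error; an acrophase that rounds to the
  period maps to 0.
* Zero pooled variance in a t-test returns `t = 0, p = 1` for equal
  means and `p = 0` otherwise; an all-constant ANOVA returns `F = 0`
  and unit p-values.
* An upper quartile of zero (possible only for pathologically sparse
  input) is an error naming the offending samples.
* Phase differences are reported on the shortest signed arc in
  `(−12, 12]`, so a 12-h inversion is +12 by convention.
* All randomness flows from explicit integer seeds; the pipeline
  derives nothing from the clock or the session.

## Problem sizes

The shipped test-suite and acceptance computations run the default
conditions end to end: 2100-gene panels, 24–72 libraries per layer,
100-fold seeded replication for recovery rates, 10,000-gene null
panels for test-size calibration, and 200-fold replication for phase
recovery — sizes chosen so the whole suite completes in a couple of
minutes on a laptop while keeping Monte-Carlo error well inside the
asserted bounds.

## Known limitations

* TE cross-gene comparisons inherit the CDS/exon length offset; the
  package reports them, as the field does, only qualitatively.
* The single-harmonic cosinor under-fits plateaued or biphasic
  profiles; its phase remains meaningful, its fold-change is a lower
  bound for such shapes.
* Upper-quartile normalization (by specification type-7 on raw counts
  of not-all-zero genes) is one of several UQ conventions; factors
  from other tools will differ by small constants.
* The derepression pattern is a two-timepoint classification; it says
  nothing about timepoints that were not sampled.
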