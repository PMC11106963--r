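## Synthetic-data generator: encodes the regulatory model the analysis
## assumes (rhythms generated at the transcriptional, mRNA-stability or
## translational layer; clock- vs feeding-driven; IRP knockout effects),
## so the whole pipeline can be exercised and its recovery quantified
## without any sequencing data.

.LAYERS <- c("rna_intron", "rna_exon", "rpf")
.MIN_FOLD_TRUTH <- 1.5  # fold threshold used to derive the truth mode

#' Default gene panel of the liver simulation
#'
#' Eleven classes reproducing the qualitative contrasts of the IRP/IRE
#' system in mouse liver:
#' \describe{
#'   \item{Ftl1_like, Fth1_like}{flat pre-mRNA and mRNA, feeding-driven
#'     translation-efficiency rhythm of 1.0 log2 units with trough at the
#'     light-dark transition (ZT12); strongly repressed baseline
#'     (log2 TE -2.5). Knockout of IRP2 derepresses TE by +2 log2 at ZT5
#'     only; Fth1_like additionally gains +0.5 log2 in IRP1 knockouts at
#'     both timepoints.}
#'   \item{Alas2_like}{as above with half the rhythm amplitude (0.5) and a
#'     milder baseline (log2 TE -1.0); +1.0 log2 IRP2-KO derepression at
#'     ZT5.}
#'   \item{Tfrc_like}{3' IRE pattern: flat pre-mRNA, feeding-driven mRNA
#'     rhythm (0.75 log2, peak ZT18) tracked by footprints (flat TE);
#'     mRNA destabilized in IRP2 knockouts at ZT5 (-0.5 log2) and in IRP1
#'     knockouts at both timepoints (-0.4 log2).}
#'   \item{Slc40a1_like}{weak TE rhythm (0.25 log2, sub-threshold for the
#'     1.5-fold rhythm call); IRP1-KO derepression at both timepoints.}
#'   \item{Aco2_like, Epas1_like}{flat, high basal translation
#'     (log2 TE -0.25).}
#'   \item{Dbp_like}{clock-driven transcriptional rhythm: pre-mRNA and
#'     mRNA oscillate with 2.0 log2 amplitude (16-fold), flat TE.}
#'   \item{Aco1_marker, Ireb2_marker}{the IRP-encoding genes themselves:
#'     maximal footprint RPKM 150 and 25, modest clock-driven mRNA rhythm
#'     (1.3-fold peak-to-trough, peak ZT10); their own knockout scales
#'     footprints by 0.05 and RNA by 0.7.}
#'   \item{Flat_filler}{constant background genes, 200 per configured
#'     gene-per-class unit, with baselines spread over 10 log2 units ---
#'     the stable, expression-spread bulk of a transcriptome that makes
#'     percentile-based normalization well behaved.}
#' }
#' @return Named list of [GeneClassSpec].
#' @export
defaultGenePanel <- function() {
  markerAmp <- log2(1.3) / 2       # 1.3-fold peak-to-trough
  classes <- list(
    geneClassSpec("Ftl1_like", intronRpkm = 2, exonRpkm = 200,
                  baselineLog2TE = -2.5,
                  rpfRhythm = rhythmSpec(1.0, 0, "feeding"),
                  koEffects = list(
                    Ireb2KO = list(dTE = c("5" = 2, "12" = 0))),
                  lengths = c(cds = 600, exon = 900, intron = 1200)),
    geneClassSpec("Fth1_like", intronRpkm = 2, exonRpkm = 150,
                  baselineLog2TE = -2.5,
                  rpfRhythm = rhythmSpec(1.0, 0, "feeding"),
                  koEffects = list(
                    Ireb2KO = list(dTE = c("5" = 2, "12" = 0)),
                    Aco1KO = list(dTE = c("5" = 0.5, "12" = 0.5))),
                  lengths = c(cds = 550, exon = 850, intron = 1500)),
    geneClassSpec("Alas2_like", intronRpkm = 1, exonRpkm = 50,
                  baselineLog2TE = -1.0,
                  rpfRhythm = rhythmSpec(0.5, 0, "feeding"),
                  koEffects = list(
                    Ireb2KO = list(dTE = c("5" = 1, "12" = 0))),
                  lengths = c(cds = 1700, exon = 2200, intron = 8000)),
    geneClassSpec("Tfrc_like", intronRpkm = 5, exonRpkm = 30,
                  baselineLog2TE = -0.5,
                  exonRhythm = rhythmSpec(0.75, 18, "feeding"),
                  rpfRhythm = rhythmSpec(0.75, 18, "feeding"),
                  koEffects = list(
                    Ireb2KO = list(dRNA = c("5" = -0.5, "12" = 0)),
                    Aco1KO = list(dRNA = c("5" = -0.4, "12" = -0.4))),
                  lengths = c(cds = 2300, exon = 5000, intron = 10000)),
    geneClassSpec("Slc40a1_like", intronRpkm = 2, exonRpkm = 40,
                  baselineLog2TE = -0.5,
                  rpfRhythm = rhythmSpec(0.25, 0, "feeding"),
                  koEffects = list(
                    Aco1KO = list(dTE = c("5" = 0.6, "12" = 0.6)),
                    Ireb2KO = list(dTE = c("5" = 0.15, "12" = 0))),
                  lengths = c(cds = 1700, exon = 2500, intron = 9000)),
    geneClassSpec("Aco2_like", intronRpkm = 3, exonRpkm = 80,
                  baselineLog2TE = -0.25,
                  lengths = c(cds = 2300, exon = 2900, intron = 12000)),
    geneClassSpec("Epas1_like", intronRpkm = 1, exonRpkm = 20,
                  baselineLog2TE = -0.25,
                  lengths = c(cds = 2600, exon = 3200, intron = 15000)),
    geneClassSpec("Dbp_like", intronRpkm = 10, exonRpkm = 60,
                  baselineLog2TE = 0,
                  intronRhythm = rhythmSpec(2.0, 10, "clock"),
                  exonRhythm = rhythmSpec(2.0, 10, "clock"),
                  rpfRhythm = rhythmSpec(2.0, 10, "clock"),
                  lengths = c(cds = 1000, exon = 1500, intron = 4000)),
    geneClassSpec("Aco1_marker", intronRpkm = 4,
                  exonRpkm = 150 / 2^markerAmp, baselineLog2TE = 0,
                  exonRhythm = rhythmSpec(markerAmp, 10, "clock"),
                  rpfRhythm = rhythmSpec(markerAmp, 10, "clock"),
                  selfKO = "Aco1KO",
                  lengths = c(cds = 2700, exon = 3400, intron = 20000)),
    geneClassSpec("Ireb2_marker", intronRpkm = 1,
                  exonRpkm = 25 / 2^markerAmp, baselineLog2TE = 0,
                  exonRhythm = rhythmSpec(markerAmp, 10, "clock"),
                  rpfRhythm = rhythmSpec(markerAmp, 10, "clock"),
                  selfKO = "Ireb2KO",
                  lengths = c(cds = 2900, exon = 3600, intron = 25000)),
    geneClassSpec("Flat_filler", intronRpkm = 2, exonRpkm = 20,
                  baselineLog2TE = 0,
                  lengths = c(cds = 1200, exon = 1800, intron = 6000),
                  sizeFactor = 200, spreadLog2 = 10))
  names(classes) <- vapply(classes, function(x) x@name, "")
  classes
}

#' Configure a simulated experiment
#'
#' Defaults describe the around-the-clock design: 12 timepoints at 2-h
#' spacing, 2 replicates, wild type only, night-restricted feeding,
#' negative-binomial noise with dispersion 20, equal library sizes of
#' 1e7 reads.
#'
#' @param nGenesPerClass Genes per class (default 10).
#' @param timepoints ZT hours (default `seq(0, 22, by = 2)`).
#' @param nReplicates Animals per genotype x timepoint (default 2).
#' @param librarySize Reads per library (default 1e7).
#' @param dispersion NB dispersion: `var = mu + mu^2/dispersion`
#'   (default 20).
#' @param noise `"nb"` or `"off"` (counts are then `round(mu)`).
#' @param seed Integer seed.
#' @param genotypes Subset of `WT`, `Aco1KO`, `Ireb2KO`, `Bmal1KO`.
#' @param feeding A [FeedingRegime] (default night-restricted).
#' @param geneClasses List of [GeneClassSpec] (default
#'   [defaultGenePanel()]).
#' @param amplitudeScale Global rhythm-amplitude multiplier (default 1).
#' @return A [SimConfig].
#' @examples
#' simConfig(seed = 1)
#' koCohortConfig(seed = 1)
#' @export
simConfig <- function(nGenesPerClass = 10, timepoints = seq(0, 22, by = 2),
                      nReplicates = 2, librarySize = 1e7, dispersion = 20,
                      noise = c("nb", "off"), seed = 1L,
                      genotypes = "WT",
                      feeding = feedingRegime("night_restricted"),
                      geneClasses = defaultGenePanel(),
                      amplitudeScale = 1) {
  new("SimConfig", nGenesPerClass = as.integer(nGenesPerClass),
      timepoints = timepoints, nReplicates = as.integer(nReplicates),
      librarySize = librarySize, dispersion = dispersion,
      noise = match.arg(noise), seed = as.integer(seed),
      genotypes = genotypes, feeding = feeding,
      geneClasses = unname(geneClasses), amplitudeScale = amplitudeScale)
}

#' @rdname simConfig
#' @details `koCohortConfig()` describes the knockout cohort: ZT5 and
#'   ZT12, 3 animals per arm, all four genotypes (eight conditions).
#' @param ... Passed on to [simConfig()].
#' @export
koCohortConfig <- function(timepoints = c(5, 12), nReplicates = 3,
                           genotypes = c("WT", "Aco1KO", "Ireb2KO",
                                         "Bmal1KO"), ...) {
  simConfig(timepoints = timepoints, nReplicates = nReplicates,
            genotypes = genotypes, ...)
}

#' Modulate a rhythm by the feeding regime
#'
#' Feeding-driven rhythms scale with the rhythmicity of food intake and
#' invert under day-feeding: the realized amplitude is
#' `amplitude * |2*darkFraction - 1|`, and the phase shifts by 12 h when
#' `darkFraction < 0.5`. Clock-driven and arrhythmic genes are untouched.
#'
#' @param amplitude Log2 amplitude.
#' @param phase Peak phase, ZT hours.
#' @param regime A [FeedingRegime].
#' @param driver `"clock"`, `"feeding"`, or `"none"`.
#' @return `list(amplitude=, phase=)` after modulation.
#' @examples
#' applyFeedingRegime(1, 12, feedingRegime("day_fed"), "feeding")
#' @export
applyFeedingRegime <- function(amplitude, phase, regime, driver) {
  driver <- match.arg(driver, c("clock", "feeding", "none"))
  stopifnot(is(regime, "FeedingRegime"))
  if (driver != "feeding")
    return(list(amplitude = amplitude, phase = phase))
  d <- regime@darkFraction
  list(amplitude = amplitude * abs(2 * d - 1),
       phase = if (d >= 0.5) phase else (phase + 12) %% 24)
}

## Realized (amplitude, phase) of one layer for one genotype after the
## feeding regime and the clock knockout.
.realizedRhythm <- function(rhythm, genotype, config) {
  r <- applyFeedingRegime(rhythm$amplitude * config@amplitudeScale,
                          rhythm$phase, config@feeding, rhythm$driver)
  if (rhythm$driver == "clock" && genotype == "Bmal1KO")
    r$amplitude <- 0
  r
}

.koDelta <- function(effect, field, zt) {
  v <- effect[[field]]
  if (is.null(v)) return(0)
  d <- v[as.character(zt)]
  ifelse(is.na(d), 0, unname(d))
}

## Noise-free log2 RPKM of one gene class at given (zt, genotype) pairs.
## layer is one of "rna_intron", "rna_exon", "rpf".
.classLog2Rpkm <- function(cls, layer, zt, genotype, config) {
  key <- c(rna_intron = "intron", rna_exon = "exon", rpf = "rpf")[[layer]]
  base <- log2(cls@baselineRpkm[[key]])
  out <- numeric(length(zt))
  for (g in unique(genotype)) {
    sel <- genotype == g
    r <- .realizedRhythm(cls@rhythms[[key]], g, config)
    y <- base + r$amplitude * cos(2 * pi * (zt[sel] - r$phase) / 24)
    eff <- cls@koEffects[[g]]
    if (!is.null(eff)) {
      if (key %in% c("exon", "rpf"))
        y <- y + .koDelta(eff, "dRNA", zt[sel])
      if (key == "rpf")
        y <- y + .koDelta(eff, "dTE", zt[sel])
    }
    if (!is.na(cls@selfKO) && g == cls@selfKO)
      y <- y + if (key == "rpf") log2(0.05) else log2(0.7)
    out[sel] <- y
  }
  out
}

.sampleSheet <- function(config) {
  grid <- expand.grid(replicate = seq_len(config@nReplicates),
                      zt = config@timepoints,
                      genotype = config@genotypes,
                      stringsAsFactors = FALSE)
  sheets <- lapply(.LAYERS, function(layer) {
    short <- c(rna_intron = "pre", rna_exon = "rna", rpf = "rpf")[[layer]]
    data.frame(
      sample_id = sprintf("%s_ZT%02g_R%d_%s", grid$genotype, grid$zt,
                          grid$replicate, short),
      assay = layer, genotype = grid$genotype, zt = grid$zt,
      replicate = grid$replicate, library_size = config@librarySize,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, sheets)
}

.classSize <- function(cls, config) {
  as.integer(config@nGenesPerClass * cls@sizeFactor)
}

.geneIds <- function(cls, config) {
  sprintf("%s_g%02d", cls@name, seq_len(.classSize(cls, config)))
}

## Deterministic per-gene log2 baseline offsets spanning spreadLog2.
.geneOffsets <- function(cls, config) {
  n <- .classSize(cls, config)
  if (n == 1 || cls@spreadLog2 == 0) return(numeric(n))
  cls@spreadLog2 * ((seq_len(n) - 1) / (n - 1) - 0.5)
}

.geneTable <- function(config) {
  tabs <- lapply(config@geneClasses, function(cls) {
    data.frame(
      gene_id = .geneIds(cls, config),
      class = cls@name,
      cds_len = cls@lengths[["cds"]],
      exon_len = cls@lengths[["exon"]],
      intron_len = cls@lengths[["intron"]],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(tabs, list(make.row.names = FALSE)))
}

#' Noise-free expected RPKM surfaces of a simulated design
#'
#' The analytic means the generator draws around; used as the oracle for
#' mean-correctness and rhythm-encoding checks.
#'
#' @param config A [SimConfig].
#' @return List with `rpkm` (list of gene x sample matrices per layer:
#'   `rpf`, `rna_exon`, `rna_intron`), `samples` and `genes` tables.
#' @export
expectedRpkm <- function(config) {
  stopifnot(is(config, "SimConfig"))
  samples <- .sampleSheet(config)
  genes <- .geneTable(config)
  mats <- lapply(.LAYERS, function(layer) {
    sh <- samples[samples$assay == layer, ]
    rows <- lapply(config@geneClasses, function(cls) {
      y <- .classLog2Rpkm(cls, layer, sh$zt, sh$genotype, config)
      n <- .classSize(cls, config)
      2^(matrix(rep(y, each = n), nrow = n) + .geneOffsets(cls, config))
    })
    m <- do.call(rbind, rows)
    dimnames(m) <- list(genes$gene_id, sh$sample_id)
    m
  })
  names(mats) <- .LAYERS
  list(rpkm = mats, samples = samples, genes = genes)
}

.lengthFor <- function(genes, layer) {
  switch(layer, rpf = genes$cds_len, rna_exon = genes$exon_len,
         rna_intron = genes$intron_len)
}

#' Simulate a full ribosome-profiling experiment
#'
#' Draws gene x sample count matrices for the three layers (footprints,
#' exonic mRNA, intronic pre-mRNA) around the analytic mean
#' `mu = rpkm * length_bp/1e3 * library_size/1e6`, where the log2 RPKM of
#' each gene follows its class baseline plus a 24-h cosine after
#' feeding-regime and knockout modification. With `noise = "nb"` counts
#' are negative-binomial (`var = mu + mu^2/dispersion`); with
#' `noise = "off"` they are `round(mu)`. Identical configs (including
#' seed) give bit-identical output.
#'
#' @param config A [SimConfig].
#' @return List with `counts` (named list of [CountMatrix]: `rpf`,
#'   `rna_exon`, `rna_intron`), `samples`, `genes`, and `truth` (the
#'   ground-truth ledger: class, expected regulatory mode under the
#'   1.5-fold rule, realized per-layer amplitude and phase for wild type,
#'   and whether knockout effects apply).
#' @examples
#' sim <- simulateExperiment(simConfig(nGenesPerClass = 2, seed = 7))
#' sim$counts$rpf
#' head(sim$truth)
#' @export
simulateExperiment <- function(config) {
  stopifnot(is(config, "SimConfig"))
  exp <- expectedRpkm(config)
  set.seed(config@seed)
  counts <- lapply(.LAYERS, function(layer) {
    len <- rep(.lengthFor(exp$genes, layer), length.out = nrow(exp$genes))
    mu <- exp$rpkm[[layer]] * (len / 1e3) * (config@librarySize / 1e6)
    cts <- if (config@noise == "nb") {
      matrix(stats::rnbinom(length(mu), mu = mu, size = config@dispersion),
             nrow = nrow(mu), dimnames = dimnames(mu))
    } else round(mu)
    sh <- exp$samples[exp$samples$assay == layer, ]
    countMatrix(cts, sh[, c("genotype", "zt", "replicate", "library_size")],
                lengthBp = len, assayType = layer,
                geneData = exp$genes[, c("class"), drop = FALSE])
  })
  names(counts) <- .LAYERS
  list(counts = counts, samples = exp$samples, genes = exp$genes,
       truth = .simTruth(config), config = config)
}

## Phasor helpers: a rhythm (A, phi) as a complex number.
.toPhasor <- function(r) r$amplitude * exp(1i * 2 * pi * r$phase / 24)
.fromPhasor <- function(z) {
  list(amplitude = Mod(z), phase = (24 * Arg(z) / (2 * pi)) %% 24)
}

#' @rdname simulateExperiment
#' @details `simTruth()` returns the truth ledger alone. The TE rhythm of
#'   a class is the phasor difference between its footprint and mRNA
#'   rhythms; the expected regulatory mode applies the pipeline's
#'   1.5-fold rule to the realized wild-type amplitudes.
#' @export
simTruth <- function(config) .simTruth(config)

.simTruth <- function(config) {
  thrA <- log2(.MIN_FOLD_TRUTH) / 2
  rows <- lapply(config@geneClasses, function(cls) {
    intron <- .realizedRhythm(cls@rhythms$intron, "WT", config)
    exon <- .realizedRhythm(cls@rhythms$exon, "WT", config)
    rpf <- .realizedRhythm(cls@rhythms$rpf, "WT", config)
    te <- .fromPhasor(.toPhasor(rpf) - .toPhasor(exon))
    fl <- c(transcriptional = intron$amplitude >= thrA,
            post_transcriptional = exon$amplitude >= thrA &&
              intron$amplitude < thrA,
            translational = te$amplitude >= thrA)
    mode <- if (!any(fl)) "NONE" else if (sum(fl) > 1) "MIXED"
            else toupper(names(fl)[fl])
    data.frame(
      gene_id = .geneIds(cls, config),
      class = cls@name, mode = mode,
      intron_amp = intron$amplitude, intron_phase = intron$phase,
      exon_amp = exon$amplitude, exon_phase = exon$phase,
      rpf_amp = rpf$amplitude, rpf_phase = rpf$phase,
      te_amp = te$amplitude, te_phase = te$phase,
      baseline_log2_te = cls@baselineLog2TE,
      ko_effect = paste(names(cls@koEffects), collapse = ";"),
      self_ko = cls@selfKO,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate a western-blot protein time series
#'
#' Band intensity follows `baseline * R^(cos(2*pi*(t - peakPhase)/24)/2)`
#' so that the peak-to-trough ratio of the noise-free curve is exactly
#' `R`, multiplied by lognormal noise of the given coefficient of
#' variation (mean 1). Loading-control intensities are constant up to the
#' same noise. Defaults describe the IRP2 blot series: ~tenfold
#' peak-to-trough with peak at the light-dark transition, quantified at
#' the model curve's trough (ZT0; the observed early-light trough
#' plateau, which a single harmonic with peak ZT12 centres at ZT0) and
#' peak (ZT12) in five animals each.
#'
#' @param protein Protein label.
#' @param ratio Peak/trough ratio `R >= 1` (use 1 for a flat protein such
#'   as IRP1).
#' @param peakPhase Peak phase, ZT hours.
#' @param baseline Baseline intensity at mid-amplitude.
#' @param cv Lognormal noise coefficient of variation (0 disables noise).
#' @param timepoints ZT hours sampled.
#' @param nPerTimepoint Animals per timepoint.
#' @param seed Integer seed.
#' @return A [ProteinSeries].
#' @examples
#' irp2 <- simulateProteinSeries(seed = 1)
#' normalizeBlot(irp2)$ratio
#' @export
simulateProteinSeries <- function(protein = "IRP2", ratio = 10,
                                  peakPhase = 12, baseline = 1, cv = 0.2,
                                  timepoints = c(0, 12),
                                  nPerTimepoint = 5, seed = 1L) {
  if (ratio < 1) stop("peak/trough ratio must be >= 1")
  set.seed(as.integer(seed))
  t <- rep(timepoints, each = nPerTimepoint)
  mu <- baseline * ratio^(cos(2 * pi * (t - peakPhase) / 24) / 2)
  noise <- function(n) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log1p(cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  new("ProteinSeries", protein = protein, timepoints = t,
      intensity = mu * noise(length(t)),
      loading = baseline * noise(length(t)))
}
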