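#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.ASSAY_TYPES <- c("rpf", "rna_exon", "rna_intron")
.GENOTYPES <- c("WT", "Aco1KO", "Ireb2KO", "Bmal1KO")
.SAMPLE_COLS <- c("genotype", "zt", "replicate", "library_size")

#' CountMatrix: gene-level counts for one assay
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying integer counts for
#' a single assay layer (ribosome footprints, exonic mRNA, or intronic
#' pre-mRNA), sample metadata (`genotype`, `zt`, `replicate`,
#' `library_size`) in `colData`, and the assay-appropriate feature length
#' (`length_bp`) in `rowData`.
#'
#' @slot assayType One of `"rpf"`, `"rna_exon"`, `"rna_intron"`.
#' @seealso [countMatrix()], [upperQuartileFactors()], [rpkm()]
#' @export
setClass("CountMatrix",
         contains = "SummarizedExperiment",
         representation(assayType = "character"))

setValidity("CountMatrix", function(object) {
  msg <- character()
  if (length(object@assayType) != 1L ||
      !object@assayType %in% .ASSAY_TYPES)
    msg <- c(msg, sprintf("assayType must be one of %s",
                          paste(.ASSAY_TYPES, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  miss <- setdiff(.SAMPLE_COLS, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, sprintf("colData lacks column(s): %s",
                          paste(miss, collapse = ", ")))
  if (!"length_bp" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData lacks 'length_bp'")
  else if (any(rowData(object)$length_bp <= 0))
    msg <- c(msg, "feature lengths must be > 0")
  if ("library_size" %in% colnames(colData(object)) &&
      any(colData(object)$library_size <= 0))
    msg <- c(msg, "library sizes must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param sampleData `data.frame` with one row per sample and columns
#'   `genotype`, `zt`, `replicate`, `library_size` (extra columns kept).
#' @param lengthBp Numeric vector of feature lengths in bp, one per gene.
#' @param assayType One of `"rpf"`, `"rna_exon"`, `"rna_intron"`.
#' @param geneData Optional `data.frame` of extra per-gene columns.
#' @return A [CountMatrix].
#' @examples
#' cm <- countMatrix(
#'   matrix(0:5, 2, 3, dimnames = list(c("g1", "g2"), paste0("s", 1:3))),
#'   data.frame(genotype = "WT", zt = c(0, 12, 0), replicate = c(1, 1, 2),
#'              library_size = 1e7),
#'   lengthBp = c(1000, 2000), assayType = "rpf")
#' rpkm(cm)
#' @export
countMatrix <- function(counts, sampleData, lengthBp, assayType,
                        geneData = NULL) {
  assayType <- match.arg(assayType, .ASSAY_TYPES)
  counts <- as.matrix(counts)
  rd <- DataFrame(length_bp = lengthBp, row.names = rownames(counts))
  if (!is.null(geneData))
    rd <- cbind(rd, DataFrame(geneData))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(sampleData, row.names = colnames(counts)),
    rowData = rd)
  new("CountMatrix", se, assayType = assayType)
}

#' NormalizedCounts: upper-quartile normalized values
#'
#' Same shape as the [CountMatrix] it was derived from, with the assay
#' `"normalized"` holding `count / factor` and the per-sample scaling
#' factors (geometric mean 1) stored in the `normFactors` slot.
#'
#' @slot assayType Assay layer of the parent counts.
#' @slot normFactors Per-sample factors, geometric mean 1 (within 1e-9).
#' @seealso [normalizeCounts()], [translationEfficiency()]
#' @export
setClass("NormalizedCounts",
         contains = "SummarizedExperiment",
         representation(assayType = "character", normFactors = "numeric"))

setValidity("NormalizedCounts", function(object) {
  msg <- character()
  f <- object@normFactors
  if (length(f) != ncol(object))
    msg <- c(msg, "one factor per sample required")
  if (any(f <= 0))
    msg <- c(msg, "factors must be > 0")
  else if (abs(mean(log(f))) > 1e-9)
    msg <- c(msg, "factors must have geometric mean 1 (within 1e-9)")
  if (!"normalized" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'normalized' is required")
  if (length(msg)) msg else TRUE
})

#' CosinorFit: a single-gene 24-h harmonic fit
#'
#' Least-squares fit of `y = mesor + a*cos(2*pi*t/P) + b*sin(2*pi*t/P)`.
#' Amplitude is `sqrt(a^2 + b^2)` on the fitted (log2) scale; `peakPhase`
#' is the acrophase in ZT hours; `foldChange = 2^(2*amplitude)` is the
#' linear-scale peak-to-trough ratio; the p-value comes from the F-test of
#' the two harmonic terms against the intercept-only model, df (2, n - 3).
#'
#' @slot gene Gene id (may be `NA`).
#' @slot mesor,coefA,coefB Fitted mean and harmonic coefficients (log2).
#' @slot amplitude Half peak-to-trough on the log2 scale, `>= 0`.
#' @slot phase Peak phase in ZT hours, in `[0, period)`.
#' @slot period Fitted period in hours (24 by default).
#' @slot pvalue,qvalue F-test p-value and (optional) multiplicity-adjusted
#'   q-value; `qvalue` is `NA` until set (see [adjustPvalues()]).
#' @slot foldChange Linear peak-to-trough ratio `2^(2*amplitude)`.
#' @slot n Number of observations used.
#' @seealso [cosinorFit()], [fitRhythms()], [callRhythmic()]
#' @aliases mesor amplitude peakPhase foldChange pvalue qvalue qvalue<-
#' @export
setClass("CosinorFit",
         representation(gene = "character", mesor = "numeric",
                        coefA = "numeric", coefB = "numeric",
                        amplitude = "numeric", phase = "numeric",
                        period = "numeric", pvalue = "numeric",
                        qvalue = "numeric", foldChange = "numeric",
                        n = "integer"))

setValidity("CosinorFit", function(object) {
  msg <- character()
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@foldChange < 1) msg <- c(msg, "foldChange must be >= 1")
  if (object@phase < 0 || object@phase >= object@period)
    msg <- c(msg, "phase must lie in [0, period)")
  if (object@pvalue < 0 || object@pvalue > 1)
    msg <- c(msg, "pvalue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ProteinSeries: western-blot band intensities over time
#'
#' Replicate target-band and loading-control intensities at ZT timepoints,
#' as produced by densitometry of immunoblots (e.g. IRP2 with a VINCULIN
#' loading control).
#'
#' @slot protein Protein label.
#' @slot timepoints ZT hours, one per lane.
#' @slot intensity Target band intensities, `> 0`.
#' @slot loading Loading-control intensities, `> 0`.
#' @seealso [simulateProteinSeries()], [normalizeBlot()]
#' @export
setClass("ProteinSeries",
         representation(protein = "character", timepoints = "numeric",
                        intensity = "numeric", loading = "numeric"))

setValidity("ProteinSeries", function(object) {
  msg <- character()
  n <- length(object@timepoints)
  if (length(object@intensity) != n || length(object@loading) != n)
    msg <- c(msg, "timepoints, intensity and loading must have equal length")
  if (any(object@intensity <= 0) || any(object@loading <= 0))
    msg <- c(msg, "intensities must be > 0")
  if (length(msg)) msg else TRUE
})

#' FeedingRegime: fraction of food intake in the dark phase
#'
#' Feeding-driven rhythms scale with how rhythmic food intake is:
#' realized amplitude is multiplied by `|2*darkFraction - 1|` and the
#' phase flips by 12 h when most food is eaten in the light phase
#' (day-feeding). Presets: `night_restricted` (1.0), `ad_libitum`
#' (0.76), `damped` (0.56), `arrhythmic` (0.51), `day_fed` (0.0).
#'
#' @slot name Regime label.
#' @slot darkFraction Fraction of food intake during the dark phase, in
#'   `[0, 1]`.
#' @seealso [feedingRegime()], [applyFeedingRegime()]
#' @export
setClass("FeedingRegime",
         representation(name = "character", darkFraction = "numeric"))

setValidity("FeedingRegime", function(object) {
  if (object@darkFraction < 0 || object@darkFraction > 1)
    "darkFraction must lie in [0, 1]" else TRUE
})

.FEEDING_PRESETS <- c(night_restricted = 1.0, ad_libitum = 0.76,
                      damped = 0.56, arrhythmic = 0.51, day_fed = 0.0)

#' Construct a feeding regime
#'
#' @param name Either a preset name (`"night_restricted"`, `"ad_libitum"`,
#'   `"damped"`, `"arrhythmic"`, `"day_fed"`) or a free label if
#'   `darkFraction` is given.
#' @param darkFraction Fraction of food intake during the dark phase; if
#'   missing, looked up from the presets.
#' @return A [FeedingRegime].
#' @examples
#' feedingRegime("day_fed")
#' feedingRegime("custom", darkFraction = 0.9)
#' @export
feedingRegime <- function(name = "night_restricted", darkFraction = NULL) {
  if (is.null(darkFraction)) {
    if (!name %in% names(.FEEDING_PRESETS))
      stop("unknown feeding regime preset: ", name)
    darkFraction <- unname(.FEEDING_PRESETS[name])
  }
  new("FeedingRegime", name = name, darkFraction = darkFraction)
}

#' GeneClassSpec: generative parameters for one gene class
#'
#' Encodes where in gene expression a diurnal rhythm is generated for a
#' class of simulated genes: baseline RPKM per layer (intron = pre-mRNA,
#' exon = mRNA, rpf = footprints), a per-layer cosine rhythm with its
#' driver (circadian clock, feeding, or none), the baseline log2
#' translation efficiency tying the rpf baseline to the exon baseline
#' (`rpf = exon * 2^baselineLog2TE * cdsLen/exonLen` on the count scale;
#' on the RPKM scale `rpf = exon * 2^baselineLog2TE`), knockout effects,
#' and feature lengths.
#'
#' @slot name Class label.
#' @slot baselineRpkm Named numeric `c(intron=, exon=, rpf=)`, all `> 0`.
#' @slot baselineLog2TE Baseline log2 TE; consistent with the rpf baseline.
#' @slot rhythms Named list (`intron`, `exon`, `rpf`) of
#'   `list(amplitude (log2, >= 0), phase (ZT h in [0,24)), driver)` with
#'   driver one of `"clock"`, `"feeding"`, `"none"`.
#' @slot koEffects Named list by genotype, each
#'   `list(dTE = c("5" = ..., "12" = ...), dRNA = c(...))`: per-timepoint
#'   log2 shifts of TE (applied to footprints) and of mRNA abundance
#'   (applied to exon and footprints).
#' @slot selfKO Genotype whose knockout disrupts this gene's own ORF
#'   (footprints scaled by 0.05, exon/intron RNA by 0.7), or `NA`.
#' @slot lengths Named numeric `c(cds=, exon=, intron=)` in bp.
#' @slot sizeFactor Multiplier on the configured genes-per-class for
#'   this class (lets a background class dominate the panel the way
#'   constant genes dominate a transcriptome).
#' @slot spreadLog2 Total log2 range of deterministic per-gene baseline
#'   offsets across the class (same offset on every layer, so rhythms
#'   and TE are untouched); 0 gives identical genes.
#' @seealso [geneClassSpec()], [defaultGenePanel()]
#' @export
setClass("GeneClassSpec",
         representation(name = "character", baselineRpkm = "numeric",
                        baselineLog2TE = "numeric", rhythms = "list",
                        koEffects = "list", selfKO = "character",
                        lengths = "numeric", sizeFactor = "numeric",
                        spreadLog2 = "numeric"))

setValidity("GeneClassSpec", function(object) {
  msg <- character()
  lay <- c("intron", "exon", "rpf")
  if (!setequal(names(object@baselineRpkm), lay) ||
      any(object@baselineRpkm <= 0))
    msg <- c(msg, "baselineRpkm needs positive intron/exon/rpf entries")
  if (!setequal(names(object@rhythms), lay))
    msg <- c(msg, "rhythms needs intron/exon/rpf entries")
  for (l in intersect(names(object@rhythms), lay)) {
    r <- object@rhythms[[l]]
    if (r$amplitude < 0)
      msg <- c(msg, sprintf("%s amplitude must be >= 0", l))
    if (r$phase < 0 || r$phase >= 24)
      msg <- c(msg, sprintf("%s phase must lie in [0, 24)", l))
    if (!r$driver %in% c("clock", "feeding", "none"))
      msg <- c(msg, sprintf("%s driver must be clock/feeding/none", l))
  }
  if (all(c("exon", "rpf") %in% names(object@baselineRpkm))) {
    expect <- object@baselineRpkm[["exon"]] * 2^object@baselineLog2TE
    if (abs(log2(object@baselineRpkm[["rpf"]]) - log2(expect)) > 1e-8)
      msg <- c(msg, "rpf baseline must equal exon * 2^baselineLog2TE")
  }
  if (!setequal(names(object@lengths), c("cds", "exon", "intron")) ||
      any(object@lengths <= 0))
    msg <- c(msg, "lengths needs positive cds/exon/intron entries")
  bad <- setdiff(names(object@koEffects), .GENOTYPES)
  if (length(bad))
    msg <- c(msg, sprintf("unknown genotype in koEffects: %s",
                          paste(bad, collapse = ", ")))
  if (object@sizeFactor < 1 ||
      object@sizeFactor != round(object@sizeFactor))
    msg <- c(msg, "sizeFactor must be a positive integer")
  if (object@spreadLog2 < 0) msg <- c(msg, "spreadLog2 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a gene class specification
#'
#' The footprint baseline is derived from the exon baseline and
#' `baselineLog2TE`, so the two cannot drift apart.
#'
#' @param name Class label.
#' @param intronRpkm,exonRpkm Baseline RPKM of the intron and exon layers.
#' @param baselineLog2TE Baseline log2 translation efficiency (RPKM scale).
#' @param intronRhythm,exonRhythm,rpfRhythm Each
#'   `list(amplitude=, phase=, driver=)`; defaults are flat
#'   (`amplitude = 0`).
#' @param koEffects Named list by genotype of
#'   `list(dTE = c(...), dRNA = c(...))` per-timepoint log2 shifts, names
#'   of the numeric vectors being ZT hours.
#' @param selfKO Genotype that knocks this gene itself out, or `NA`.
#' @param lengths Named numeric `c(cds=, exon=, intron=)` in bp.
#' @param sizeFactor,spreadLog2 See the slots of [GeneClassSpec-class].
#' @return A [GeneClassSpec].
#' @export
geneClassSpec <- function(name, intronRpkm, exonRpkm, baselineLog2TE = 0,
                          intronRhythm = flatRhythm(),
                          exonRhythm = flatRhythm(),
                          rpfRhythm = flatRhythm(),
                          koEffects = list(), selfKO = NA_character_,
                          lengths = c(cds = 1000, exon = 1500,
                                      intron = 5000),
                          sizeFactor = 1, spreadLog2 = 0) {
  new("GeneClassSpec", name = name, sizeFactor = sizeFactor,
      spreadLog2 = spreadLog2,
      baselineRpkm = c(intron = unname(intronRpkm), exon = unname(exonRpkm),
                       rpf = unname(exonRpkm) * 2^baselineLog2TE),
      baselineLog2TE = baselineLog2TE,
      rhythms = list(intron = intronRhythm, exon = exonRhythm,
                     rpf = rpfRhythm),
      koEffects = koEffects, selfKO = selfKO, lengths = lengths)
}

#' @rdname geneClassSpec
#' @param amplitude Log2 amplitude (half peak-to-trough), `>= 0`.
#' @param phase Peak phase in ZT hours.
#' @param driver `"clock"`, `"feeding"`, or `"none"`.
#' @export
rhythmSpec <- function(amplitude, phase, driver = "clock") {
  list(amplitude = amplitude, phase = phase, driver = driver)
}

#' @rdname geneClassSpec
#' @export
flatRhythm <- function() list(amplitude = 0, phase = 0, driver = "none")

#' SimConfig: design and noise model of a simulated experiment
#'
#' @slot nGenesPerClass Genes simulated per class.
#' @slot timepoints ZT hours of collection, each in `[0, 24)`.
#' @slot nReplicates Animals per genotype and timepoint.
#' @slot librarySize Total mapped reads per library.
#' @slot dispersion Negative-binomial dispersion; the count variance is
#'   `mu + mu^2 / dispersion`.
#' @slot noise `"nb"` for negative-binomial counts, `"off"` for
#'   `round(mu)`.
#' @slot seed Integer seed; identical configs give bit-identical output.
#' @slot genotypes Subset of `WT`, `Aco1KO`, `Ireb2KO`, `Bmal1KO`.
#' @slot feeding A [FeedingRegime].
#' @slot geneClasses List of [GeneClassSpec].
#' @slot amplitudeScale Global multiplier on all rhythm amplitudes
#'   (e.g. to emulate the damped rhythms of non-hepatic organs).
#' @seealso [simConfig()], [koCohortConfig()], [simulateExperiment()]
#' @export
setClass("SimConfig",
         representation(nGenesPerClass = "integer", timepoints = "numeric",
                        nReplicates = "integer", librarySize = "numeric",
                        dispersion = "numeric", noise = "character",
                        seed = "integer", genotypes = "character",
                        feeding = "FeedingRegime", geneClasses = "list",
                        amplitudeScale = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (any(object@timepoints < 0) || any(object@timepoints >= 24))
    msg <- c(msg, "timepoints must lie in [0, 24)")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@librarySize <= 0) msg <- c(msg, "librarySize must be > 0")
  if (!object@noise %in% c("nb", "off"))
    msg <- c(msg, "noise must be 'nb' or 'off'")
  bad <- setdiff(object@genotypes, .GENOTYPES)
  if (length(bad))
    msg <- c(msg, sprintf("unknown genotype(s): %s",
                          paste(bad, collapse = ", ")))
  if (!length(object@geneClasses) ||
      !all(vapply(object@geneClasses, is, TRUE, "GeneClassSpec")))
    msg <- c(msg, "geneClasses must be a non-empty list of GeneClassSpec")
  nm <- vapply(object@geneClasses, function(x) x@name, "")
  if (anyDuplicated(nm)) msg <- c(msg, "gene class names must be unique")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: k-means partition with within-cluster dendrogram order
#'
#' @slot assignments Named integer vector, gene -> cluster id in `1..k`.
#' @slot centroids `k x n_conditions` matrix of cluster centers.
#' @slot wss Total within-cluster sum of squares of the chosen k.
#' @slot wssCurve Named numeric, WSS by k (at least the chosen k).
#' @slot leafOrders List of character vectors: per-cluster gene order from
#'   average-linkage hierarchical clustering.
#' @slot k Number of clusters.
#' @slot seed Seed the partition was computed under.
#' @seealso [kmeansCluster()], [hierarchicalWithin()], [clusterNeighbors()]
#' @aliases clusterAssignments clusterCentroids wssCurve leafOrder
#' @export
setClass("ClusterResult",
         representation(assignments = "integer", centroids = "matrix",
                        wss = "numeric", wssCurve = "numeric",
                        leafOrders = "list", k = "integer",
                        seed = "integer"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by gene")
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > object@k))
    msg <- c(msg, "cluster ids must lie in 1..k")
  leaves <- unlist(object@leafOrders, use.names = FALSE)
  if (length(leaves) &&
      !setequal(leaves, names(object@assignments)) ||
      anyDuplicated(leaves))
    msg <- c(msg, "leaf orders must contain every gene exactly once")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @rdname featureLength
#' @export
setMethod("featureLength", "SummarizedExperiment",
          function(object) {
            stats::setNames(rowData(object)$length_bp, rownames(object))
          })

#' @rdname assayType
#' @export
setMethod("assayType", "CountMatrix", function(object) object@assayType)

#' @rdname assayType
#' @export
setMethod("assayType", "NormalizedCounts", function(object) object@assayType)

#' @rdname librarySize
#' @export
setMethod("librarySize", "SummarizedExperiment",
          function(object) {
            stats::setNames(colData(object)$library_size, colnames(object))
          })

#' @rdname normFactors
#' @export
setMethod("normFactors", "NormalizedCounts",
          function(object) stats::setNames(object@normFactors,
                                           colnames(object)))

#' @describeIn CosinorFit-class fitted mean (log2 scale)
#' @export
setMethod("mesor", "CosinorFit", function(object) object@mesor)

#' @describeIn CosinorFit-class log2 amplitude (half peak-to-trough)
#' @export
setMethod("amplitude", "CosinorFit", function(object) object@amplitude)

#' @describeIn CosinorFit-class peak phase (acrophase) in ZT hours
#' @export
setMethod("peakPhase", "CosinorFit", function(object) object@phase)

#' @describeIn CosinorFit-class linear peak-to-trough ratio
#' @export
setMethod("foldChange", "CosinorFit", function(object) object@foldChange)

#' @describeIn CosinorFit-class F-test p-value
#' @export
setMethod("pvalue", "CosinorFit", function(object) object@pvalue)

#' @describeIn CosinorFit-class adjusted p-value (NA until set)
#' @export
setMethod("qvalue", "CosinorFit", function(object) object@qvalue)

#' @describeIn CosinorFit-class set the adjusted p-value
#' @export
setMethod("qvalue<-", "CosinorFit", function(object, value) {
  object@qvalue <- value
  object
})

#' @rdname ClusterResult-class
#' @export
setMethod("clusterAssignments", "ClusterResult",
          function(object) object@assignments)

#' @rdname ClusterResult-class
#' @export
setMethod("clusterCentroids", "ClusterResult",
          function(object) object@centroids)

#' @rdname ClusterResult-class
#' @export
setMethod("wssCurve", "ClusterResult", function(object) object@wssCurve)

#' @rdname ClusterResult-class
#' @export
setMethod("leafOrder", "ClusterResult", function(object, cluster) {
  if (missing(cluster)) return(object@leafOrders)
  object@leafOrders[[as.character(cluster)]]
})

## ---- show methods ----

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix [%s]: %d genes x %d samples\n",
              object@assayType, nrow(object), ncol(object)))
  cd <- colData(object)
  cat(sprintf("  genotypes: %s; timepoints (ZT): %s\n",
              paste(unique(cd$genotype), collapse = ", "),
              paste(sort(unique(cd$zt)), collapse = ", ")))
})

setMethod("show", "NormalizedCounts", function(object) {
  cat(sprintf(
    "NormalizedCounts [%s]: %d genes x %d samples (UQ factors %.3f-%.3f)\n",
    object@assayType, nrow(object), ncol(object),
    min(object@normFactors), max(object@normFactors)))
})

setMethod("show", "CosinorFit", function(object) {
  cat(sprintf("CosinorFit%s: period %g h, n = %d\n",
              if (is.na(object@gene)) "" else paste0(" [", object@gene, "]"),
              object@period, object@n))
  cat(sprintf(
    "  mesor %.3f, amplitude %.3f (log2), peak ZT%.2f, fold %.2f\n",
    object@mesor, object@amplitude, object@phase, object@foldChange))
  cat(sprintf("  p = %.3g, q = %.3g\n", object@pvalue, object@qvalue))
})

setMethod("show", "FeedingRegime", function(object) {
  cat(sprintf("FeedingRegime '%s': %.0f%% of food intake in the dark phase\n",
              object@name, 100 * object@darkFraction))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d classes x %d genes, ZT {%s} x %d replicate(s)\n",
    length(object@geneClasses), object@nGenesPerClass,
    paste(object@timepoints, collapse = ","), object@nReplicates))
  cat(sprintf("  genotypes: %s; feeding: %s; noise: %s (dispersion %g)\n",
              paste(object@genotypes, collapse = ", "),
              object@feeding@name, object@noise, object@dispersion))
  cat(sprintf("  library size %g, seed %d\n",
              object@librarySize, object@seed))
})

setMethod("show", "ProteinSeries", function(object) {
  cat(sprintf("ProteinSeries [%s]: %d lanes at ZT {%s}\n", object@protein,
              length(object@timepoints),
              paste(sort(unique(object@timepoints)), collapse = ",")))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d genes in %d clusters (WSS %.2f, seed %d)\n",
              length(object@assignments), object@k, object@wss,
              object@seed))
  print(table(factor(object@assignments, levels = seq_len(object@k))))
})
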