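#' Per-gene feature length
#'
#' Length in base pairs of the feature the counts of an assay were summarized
#' over: CDS for ribosome footprints, exonic length for mRNA, intronic length
#' for pre-mRNA.
#'
#' @param object A [CountMatrix] or [NormalizedCounts] object.
#' @return Numeric vector, one length per gene.
#' @export
setGeneric("featureLength", function(object) standardGeneric("featureLength"))

#' Assay type of a count matrix
#'
#' @param object A [CountMatrix] or [NormalizedCounts] object.
#' @return One of `"rpf"`, `"rna_exon"`, `"rna_intron"`.
#' @export
setGeneric("assayType", function(object) standardGeneric("assayType"))

#' Per-sample library sizes (total mapped reads)
#'
#' @param object A [CountMatrix] or [NormalizedCounts] object.
#' @return Numeric vector, one value per sample.
#' @export
setGeneric("librarySize", function(object) standardGeneric("librarySize"))

#' Per-sample normalization factors
#'
#' @param object A [NormalizedCounts] object.
#' @return Numeric vector of factors with geometric mean 1.
#' @export
setGeneric("normFactors", function(object) standardGeneric("normFactors"))

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = 1e9 * count / (library_size * length_bp)`, using the raw library
#' size (total mapped reads) and the assay-appropriate feature length.
#'
#' @param object A [CountMatrix].
#' @return Numeric matrix, genes by samples.
#' @export
setGeneric("rpkm", function(object) standardGeneric("rpkm"))

#' @rdname CosinorFit-class
#' @param object A [CosinorFit].
#' @export
setGeneric("mesor", function(object) standardGeneric("mesor"))

#' @rdname CosinorFit-class
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))

#' @rdname CosinorFit-class
#' @export
setGeneric("peakPhase", function(object) standardGeneric("peakPhase"))

#' @rdname CosinorFit-class
#' @export
setGeneric("foldChange", function(object) standardGeneric("foldChange"))

#' @rdname CosinorFit-class
#' @export
setGeneric("pvalue", function(object) standardGeneric("pvalue"))

#' @rdname CosinorFit-class
#' @export
setGeneric("qvalue", function(object) standardGeneric("qvalue"))

#' @rdname CosinorFit-class
#' @param value Numeric in `[0, 1]`.
#' @export
setGeneric("qvalue<-", function(object, value) standardGeneric("qvalue<-"))

#' @rdname ClusterResult-class
#' @param object A [ClusterResult].
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterCentroids",
           function(object) standardGeneric("clusterCentroids"))

#' @rdname ClusterResult-class
#' @export
setGeneric("wssCurve", function(object) standardGeneric("wssCurve"))

#' @rdname ClusterResult-class
#' @param cluster Integer cluster id; if missing, a list over all clusters.
#' @export
setGeneric("leafOrder",
           function(object, cluster) standardGeneric("leafOrder"))
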