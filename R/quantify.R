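## Normalization, RPKM and translation efficiency.

#' Read-length filter masks
#'
#' Inclusive read-length windows applied before counting: 24-35 nt for
#' ribosome footprints (the monosome-protected size range), 21-60 nt for
#' total RNA.
#'
#' @param lengths Integer read lengths in nt.
#' @param assay `"footprint"` or `"total_rna"`.
#' @return Logical mask, `TRUE` for reads to keep.
#' @examples
#' filterReadLengths(c(23, 24, 35, 36), "footprint")
#' @export
filterReadLengths <- function(lengths, assay = c("footprint", "total_rna")) {
  assay <- match.arg(assay)
  if (length(lengths) == 0) return(logical(0))
  stopifnot(lengths > 0, lengths == round(lengths))
  rng <- switch(assay, footprint = c(24L, 35L), total_rna = c(21L, 60L))
  lengths >= rng[1] & lengths <= rng[2]
}

#' Upper-quartile normalization factors
#'
#' Genes with zero counts in every sample are dropped; for each sample
#' the 75th percentile of the remaining counts is taken (type-7, linear
#' interpolation between order statistics) and factors are centred to a
#' geometric mean of 1.
#'
#' @param m A [CountMatrix] (or a bare counts matrix).
#' @return Named numeric vector of per-sample factors.
#' @examples
#' cm <- countMatrix(
#'   matrix(c(1:10, 2L * 1:10), 10,
#'          dimnames = list(paste0("g", 1:10), c("a", "b"))),
#'   data.frame(genotype = "WT", zt = 0, replicate = 1:2,
#'              library_size = 1e7),
#'   lengthBp = rep(1000, 10), assayType = "rna_exon")
#' upperQuartileFactors(cm)  # c(1, 2) / sqrt(2)
#' @export
upperQuartileFactors <- function(m) {
  cts <- if (is(m, "SummarizedExperiment")) assay(m, "counts") else
    as.matrix(m)
  if (ncol(cts) < 1) stop("at least one sample required")
  keep <- rowSums(cts) > 0
  if (!any(keep)) stop("all counts are zero")
  uq <- apply(cts[keep, , drop = FALSE], 2, stats::quantile,
              probs = 0.75, type = 7, names = FALSE)
  if (any(uq == 0))
    stop("upper quartile is zero for sample(s): ",
         paste(colnames(cts)[uq == 0], collapse = ", "))
  stats::setNames(uq / exp(mean(log(uq))), colnames(cts))
}

#' Apply normalization factors to a count matrix
#'
#' @param m A [CountMatrix].
#' @param factors Per-sample factors, typically from
#'   [upperQuartileFactors()]; computed from `m` if omitted.
#' @return A [NormalizedCounts] whose `"normalized"` assay is
#'   `count / factor`.
#' @export
normalizeCounts <- function(m, factors = upperQuartileFactors(m)) {
  stopifnot(is(m, "CountMatrix"))
  if (length(factors) != ncol(m))
    stop("need one factor per sample (got ", length(factors), " for ",
         ncol(m), " samples)")
  norm <- sweep(assay(m, "counts"), 2, factors, "/")
  se <- SummarizedExperiment(
    assays = list(normalized = norm, counts = assay(m, "counts")),
    colData = colData(m), rowData = rowData(m))
  new("NormalizedCounts", se, assayType = m@assayType,
      normFactors = unname(factors))
}

#' @rdname rpkm
#' @export
setMethod("rpkm", "CountMatrix", function(object) {
  len <- featureLength(object)
  lib <- librarySize(object)
  if (any(len <= 0)) stop("feature lengths must be > 0")
  if (any(lib <= 0)) stop("library sizes must be > 0")
  1e9 * sweep(assay(object, "counts"), 2, lib, "/") / len
})

#' Per-animal log2 translation efficiency
#'
#' Pairs footprint and mRNA libraries from the same animal on
#' `(genotype, zt, replicate)` and computes
#' `log2((rpf_norm + pseudocount) / (rna_norm + pseudocount))` per gene.
#' TE is a relative quantity: feature lengths (CDS vs exon) do not
#' cancel, so values are comparable across samples for one gene, and
#' across genes only qualitatively.
#'
#' @param rpf,rna [NormalizedCounts] for the footprint and exonic mRNA
#'   layers, same genes.
#' @param pseudocount Added to both numerator and denominator (default
#'   0.5 normalized counts; keeps knockout-zeroed genes finite).
#' @return A `data.frame` (TE table) with columns `gene`, `genotype`,
#'   `zt`, `replicate`, `log2TE`.
#' @export
translationEfficiency <- function(rpf, rna, pseudocount = 0.5) {
  stopifnot(is(rpf, "NormalizedCounts"), is(rna, "NormalizedCounts"))
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (!identical(rownames(rpf), rownames(rna)))
    stop("rpf and rna matrices must cover the same genes")
  keyOf <- function(x) {
    cd <- colData(x)
    paste(cd$genotype, cd$zt, cd$replicate, sep = "|")
  }
  krpf <- keyOf(rpf); krna <- keyOf(rna)
  if (anyDuplicated(krpf) || anyDuplicated(krna))
    stop("duplicate (genotype, zt, replicate) within a layer")
  unmatched <- c(setdiff(krpf, krna), setdiff(krna, krpf))
  if (length(unmatched))
    stop("unmatched animal(s) between rpf and rna: ",
         paste(unmatched, collapse = ", "))
  ord <- match(krpf, krna)
  te <- log2((assay(rpf, "normalized") + pseudocount) /
             (assay(rna, "normalized")[, ord, drop = FALSE] + pseudocount))
  cd <- colData(rpf)
  data.frame(
    gene = rep(rownames(rpf), times = ncol(rpf)),
    genotype = rep(cd$genotype, each = nrow(rpf)),
    zt = rep(cd$zt, each = nrow(rpf)),
    replicate = rep(cd$replicate, each = nrow(rpf)),
    log2TE = as.vector(te),
    stringsAsFactors = FALSE)
}

#' Replicate-mean TE per condition
#'
#' @param te TE table from [translationEfficiency()].
#' @param conditions `data.frame` with columns `genotype` and `zt` giving
#'   the condition order; defaults to all combinations present, genotype
#'   varying slowest.
#' @return Numeric matrix, genes x conditions, of mean log2 TE; columns
#'   named `<genotype>_ZT<zt>` in the given order.
#' @export
conditionMeans <- function(te, conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- unique(te[, c("genotype", "zt")])
    conditions <- conditions[order(match(conditions$genotype,
                                         unique(te$genotype)),
                                   conditions$zt), , drop = FALSE]
  }
  genes <- unique(te$gene)
  out <- matrix(NA_real_, length(genes), nrow(conditions),
                dimnames = list(genes,
                                sprintf("%s_ZT%g", conditions$genotype,
                                        conditions$zt)))
  for (i in seq_len(nrow(conditions))) {
    sel <- te$genotype == conditions$genotype[i] &
      te$zt == conditions$zt[i]
    if (!any(sel))
      stop("no replicates for condition ", conditions$genotype[i],
           " ZT", conditions$zt[i])
    out[, i] <- tapply(te$log2TE[sel], factor(te$gene[sel], levels = genes),
                       mean)
  }
  out
}
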