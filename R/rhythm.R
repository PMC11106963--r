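## 24-h harmonic (cosinor) fitting and classification of the
## rhythm-generating layer per gene.

## Core least-squares machinery shared by the single-series and
## matrix-of-genes entry points. Y: genes x samples.
.cosinorCore <- function(times, Y, period) {
  n <- length(times)
  if (length(unique(times)) < 4)
    stop("cosinor fitting needs >= 4 distinct timepoints")
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  coef <- t(solve(crossprod(X), crossprod(X, t(Y))))  # genes x 3
  fitted <- coef %*% t(X)
  rss1 <- rowSums((Y - fitted)^2)
  rss0 <- rowSums((Y - rowMeans(Y))^2)
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  p <- stats::pf(fstat, 2, n - 3, lower.tail = FALSE)
  p[rss0 < 1e-12] <- 1           # constant series: nothing to explain
  p[rss1 < 1e-12 & rss0 >= 1e-12] <- 0
  amp <- sqrt(coef[, 2]^2 + coef[, 3]^2)
  phase <- (period * atan2(coef[, 3], coef[, 2]) / (2 * pi)) %% period
  phase[phase >= period] <- 0     # guard the x %% period == period case
  data.frame(mesor = coef[, 1], a = coef[, 2], b = coef[, 3],
             amplitude = amp, phase = phase, pvalue = p,
             foldChange = 2^(2 * amp), n = n, row.names = rownames(Y))
}

#' Fit a 24-h cosinor to one series
#'
#' Least squares of `y = m + a*cos(2*pi*t/P) + b*sin(2*pi*t/P)`.
#' Amplitude is `sqrt(a^2 + b^2)`, peak phase
#' `(P/(2*pi)) * atan2(b, a) mod P`, and the p-value comes from the
#' F-test of the harmonic pair against the intercept-only model with
#' df `(2, n - 3)`. Replicate observations at a timepoint enter as
#' independent points. Values are expected on the log2 scale (e.g.
#' `log2(RPKM + 0.5)`), making `2^(2*amplitude)` the linear
#' peak-to-trough fold-change.
#'
#' @param times ZT hours (>= 4 distinct values).
#' @param values Numeric response, same length.
#' @param period Period in hours (default 24).
#' @param gene Optional gene id carried into the result.
#' @return A [CosinorFit].
#' @examples
#' t <- seq(0, 22, by = 2)
#' fit <- cosinorFit(t, 3 + 2 * cos(2 * pi * (t - 6) / 24))
#' peakPhase(fit)   # 6
#' foldChange(fit)  # 16
#' @export
cosinorFit <- function(times, values, period = 24, gene = NA_character_) {
  stopifnot(length(times) == length(values))
  if (length(unique(times)) < 2) stop("all timepoints are identical")
  f <- .cosinorCore(times, matrix(values, nrow = 1), period)
  new("CosinorFit", gene = gene, mesor = f$mesor, coefA = f$a,
      coefB = f$b, amplitude = f$amplitude, phase = f$phase,
      period = period, pvalue = f$pvalue, qvalue = NA_real_,
      foldChange = f$foldChange, n = as.integer(f$n))
}

#' Fit cosinors to every gene of a matrix
#'
#' Vectorized across genes: one shared design matrix, closed-form
#' coefficients, per-gene F-tests, then multiplicity adjustment across
#' the genes of the layer.
#'
#' @param values Numeric matrix, genes x samples, on the log2 scale.
#' @param times ZT hours, one per column.
#' @param period Period in hours (default 24).
#' @param adjust Adjustment across genes: `"bh"` (default), `"sidak"`,
#'   or `"none"`.
#' @return A [S4Vectors::DataFrame] with one row per gene: `mesor`, `a`,
#'   `b`, `amplitude`, `phase`, `pvalue`, `qvalue`, `foldChange`, `n`.
#' @export
fitRhythms <- function(values, times, period = 24,
                       adjust = c("bh", "sidak", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(is.matrix(values), length(times) == ncol(values))
  f <- .cosinorCore(times, values, period)
  f$qvalue <- if (adjust == "none") f$pvalue else
    adjustPvalues(f$pvalue, adjust)
  DataFrame(f[c("mesor", "a", "b", "amplitude", "phase", "pvalue",
                "qvalue", "foldChange", "n")])
}

#' Multiplicity adjustment of p-values
#'
#' `"bh"` is the Benjamini-Hochberg step-up (FDR); `"sidak"` is the
#' Sidak family-wise correction `1 - (1 - p)^m` with `m = length(p)`.
#'
#' @param pvalues Numeric in `[0, 1]`.
#' @param method `"bh"` or `"sidak"`.
#' @return Adjusted p-values, same length.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh")  # all 0.04
#' adjustPvalues(0.05, "sidak")                    # unchanged, m = 1
#' @export
adjustPvalues <- function(pvalues, method = c("bh", "sidak")) {
  method <- match.arg(method)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  switch(method,
         bh = stats::p.adjust(pvalues, method = "BH"),
         sidak = 1 - (1 - pvalues)^length(pvalues))
}

#' Call a fit rhythmic
#'
#' A gene is rhythmic when its adjusted p-value passes `alpha` and its
#' linear peak-to-trough fold-change reaches `minFold`; the fold floor
#' excludes the "modest rhythmicity" regime (< 1.5-fold) that the
#' pipeline deliberately does not call.
#'
#' @param fit A [CosinorFit] with `qvalue` set, or a fit table from
#'   [fitRhythms()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param minFold Minimum peak-to-trough fold-change (default 1.5).
#' @return Logical (vector for a fit table).
#' @export
callRhythmic <- function(fit, alpha = 0.05, minFold = 1.5) {
  if (is(fit, "CosinorFit")) {
    if (is.na(fit@qvalue))
      stop("qvalue not set; run adjustPvalues over the relevant family")
    return(fit@qvalue <= alpha && fit@foldChange >= minFold)
  }
  if (any(is.na(fit$qvalue))) stop("qvalue column not set")
  fit$qvalue <= alpha & fit$foldChange >= minFold
}

.asFitTable <- function(x) {
  if (is(x, "CosinorFit"))
    return(DataFrame(amplitude = x@amplitude, phase = x@phase,
                     pvalue = x@pvalue, qvalue = x@qvalue,
                     foldChange = x@foldChange,
                     row.names = if (is.na(x@gene)) "gene" else x@gene))
  x
}

#' Classify the rhythm-generating layer of each gene
#'
#' Exon-intron decomposition of where a diurnal rhythm arises:
#' a rhythmic pre-mRNA (intron) signal implies transcriptional control;
#' a rhythmic mRNA (exon) with flat pre-mRNA implies a
#' post-transcriptionally generated rhythm (mRNA stability); a rhythmic
#' translation efficiency implies translational control. Genes passing
#' several tests are `MIXED`, genes passing none are `NONE`.
#'
#' @param fits Named list with elements `intron`, `exon`, `rpf`, `te`:
#'   each a fit table from [fitRhythms()] (rows aligned across layers)
#'   or a single-gene [CosinorFit]. The footprint fit is carried through
#'   as supporting evidence but does not enter the flags.
#' @param alpha,minFold Thresholds passed to [callRhythmic()].
#' @return A [S4Vectors::DataFrame] with logical columns
#'   `transcriptional`, `postTranscriptional`, `translational` and a
#'   `mode` factor (`TRANSCRIPTIONAL`, `POST_TRANSCRIPTIONAL`,
#'   `TRANSLATIONAL`, `MIXED`, `NONE`).
#' @export
classifyRegulatoryMode <- function(fits, alpha = 0.05, minFold = 1.5) {
  need <- c("intron", "exon", "rpf", "te")
  miss <- setdiff(need, names(fits))
  if (length(miss))
    stop("missing layer(s): ", paste(miss, collapse = ", "))
  fits <- lapply(fits[need], .asFitTable)
  ns <- vapply(fits, nrow, 0L)
  if (length(unique(ns)) != 1)
    stop("layer fit tables must have the same genes")
  rhythmic <- lapply(fits, callRhythmic, alpha = alpha, minFold = minFold)
  transcriptional <- rhythmic$intron
  postTranscriptional <- rhythmic$exon & !rhythmic$intron
  translational <- rhythmic$te
  nflags <- transcriptional + postTranscriptional + translational
  mode <- ifelse(nflags == 0, "NONE",
          ifelse(nflags > 1, "MIXED",
          ifelse(transcriptional, "TRANSCRIPTIONAL",
          ifelse(postTranscriptional, "POST_TRANSCRIPTIONAL",
                 "TRANSLATIONAL"))))
  DataFrame(transcriptional = transcriptional,
            postTranscriptional = postTranscriptional,
            translational = translational,
            mode = factor(mode, levels = c("TRANSCRIPTIONAL",
                                           "POST_TRANSCRIPTIONAL",
                                           "TRANSLATIONAL", "MIXED",
                                           "NONE")),
            row.names = rownames(fits$exon))
}

#' Signed circular phase difference
#'
#' Shortest signed arc from `phi1` to `phi2` on the 24-h circle, mapped
#' to `(-12, 12]`; a 12-h result is the phase inversion seen when
#' feeding-driven rhythms flip under day-feeding.
#'
#' @param phi1,phi2 Phases in ZT hours, in `[0, 24)`.
#' @return Signed difference in hours, in `(-12, 12]`.
#' @examples
#' comparePhases(22, 2)  # 4: shortest arc across midnight
#' comparePhases(12, 0)  # 12: inversion
#' @export
comparePhases <- function(phi1, phi2) {
  stopifnot(phi1 >= 0, phi1 < 24, phi2 >= 0, phi2 < 24)
  d <- (phi2 - phi1) %% 24
  ifelse(d > 12, d - 24, d)
}
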