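suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

## Minimal CountMatrix around a bare matrix, defaulting metadata.
tinyCountMatrix <- function(counts, zt = rep(0, ncol(counts)),
                            genotype = rep("WT", ncol(counts)),
                            replicate = seq_len(ncol(counts)),
                            librarySize = rep(1e7, ncol(counts)),
                            lengthBp = rep(1000, nrow(counts)),
                            assayType = "rna_exon") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  countMatrix(counts,
              data.frame(genotype = genotype, zt = zt,
                         replicate = replicate,
                         library_size = librarySize),
              lengthBp = lengthBp, assayType = assayType)
}

## One-class config for focused simulations.
oneClassConfig <- function(class, ...) {
  simConfig(geneClasses = defaultGenePanel()[class], ...)
}

## Independent phase-grid cosinor oracle: amplitude by closed-form 1-D
## least squares at each candidate peak phase (0.001-h grid).
gridCosinor <- function(times, values, period = 24, step = 0.001) {
  phases <- seq(0, period - step, by = step)
  w <- 2 * pi / period
  y <- values - mean(values)
  ## regressor c(t) = cos(w (t - phi)); centred slope = best amplitude
  C <- outer(phases, times, function(p, t) cos(w * (t - p)))
  Cc <- C - rowMeans(C)
  num <- as.vector(Cc %*% y)
  den <- rowSums(Cc^2)
  amp <- num / den
  rss <- sum(y^2) - amp * num
  i <- which.min(rss)
  list(amplitude = abs(amp[i]),
       phase = if (amp[i] >= 0) phases[i] else
         (phases[i] + period / 2) %% period)
}
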