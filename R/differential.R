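## Timepoint x genotype contrasts, derepression-pattern calls, and
## western-blot quantification.

#' Two-sample Student's t-test (pooled variance, two-tailed)
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = TRUE`, with
#' the degenerate cases pinned down: identical constant groups give
#' `t = 0, p = 1`; zero pooled variance with different means gives an
#' infinite statistic and `p = 0`.
#'
#' @param groupA,groupB Numeric vectors, each of length >= 2.
#' @return `list(t=, df=, p=)`.
#' @examples
#' ttestUnpaired(c(0, 1, 2), c(3, 4, 5))  # t = -3.674, p ~ 0.021
#' @export
ttestUnpaired <- function(groupA, groupB) {
  na <- length(groupA); nb <- length(groupB)
  if (na < 2 || nb < 2) stop("each group needs at least 2 observations")
  df <- na + nb - 2
  pooled <- (sum((groupA - mean(groupA))^2) +
             sum((groupB - mean(groupB))^2)) / df
  if (pooled < .Machine$double.eps^0.9) {
    if (isTRUE(all.equal(mean(groupA), mean(groupB))))
      return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf, df = df,
                p = 0))
  }
  ht <- stats::t.test(groupA, groupB, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' One-way ANOVA with Sidak-adjusted pairwise comparisons
#'
#' Fits a one-way ANOVA over all groups, then tests each requested pair
#' with the pooled mean squared error and residual degrees of freedom;
#' p-values are Sidak-adjusted with `m` = number of comparisons:
#' `p_adj = 1 - (1 - p)^m`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @param comparisons List of index pairs, e.g. `list(c(1, 2), c(1, 3))`.
#' @return `data.frame` with one row per comparison: `i`, `j`,
#'   `estimate` (mean i - mean j), `t`, `p`, `p_adj`, plus the ANOVA
#'   `F` and residual df as attributes `"F"` and `"df"`.
#' @export
anovaSidak <- function(groups, comparisons) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  if (!length(comparisons)) stop("empty comparisons list")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) < .Machine$double.eps) {
    out <- do.call(rbind, lapply(comparisons, function(cmp)
      data.frame(i = cmp[1], j = cmp[2], estimate = 0, t = 0, p = 1,
                 p_adj = 1)))
    attr(out, "F") <- 0
    attr(out, "df") <- c(length(groups) - 1L,
                         length(y) - length(groups))
    return(out)
  }
  at <- stats::anova(stats::aov(y ~ g))
  mse <- at["Residuals", "Mean Sq"]
  dfres <- at["Residuals", "Df"]
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    i <- cmp[1]; j <- cmp[2]
    est <- mean(groups[[i]]) - mean(groups[[j]])
    se <- sqrt(mse * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
    tt <- if (se == 0) {
      if (est == 0) 0 else sign(est) * Inf
    } else est / se
    p <- if (is.infinite(tt)) 0 else
      2 * stats::pt(-abs(tt), dfres)
    data.frame(i = i, j = j, estimate = est, t = tt, p = p,
               p_adj = 1 - (1 - p)^m)
  })
  out <- do.call(rbind, rows)
  attr(out, "F") <- at["g", "F value"]
  attr(out, "df") <- c(at["g", "Df"], dfres)
  out
}

.teArm <- function(te, gene, zt, genotype) {
  v <- te$log2TE[te$gene == gene & te$zt == zt & te$genotype == genotype]
  if (length(v) < 2)
    stop(sprintf("fewer than 2 replicates for %s at ZT%g in %s",
                 gene, zt, genotype))
  v
}

#' Knockout vs wild-type TE contrast at one timepoint
#'
#' @param te TE table from [translationEfficiency()] (or any long table
#'   with columns `gene`, `genotype`, `zt`, `replicate`, `log2TE`).
#' @param gene Gene id.
#' @param zt ZT timepoint.
#' @param koGenotype,wtGenotype The two arms; `delta` is KO minus WT.
#' @return One-row `data.frame`: `gene`, `zt`, `ko`, `wt`, `delta`, `t`,
#'   `p`, `p_adj` (= `p`: no multiplicity within a single contrast),
#'   `n_ko`, `n_wt`.
#' @seealso [teContrasts()] for a batch with BH adjustment across
#'   contrasts, [derepressionProfile()] for the two-timepoint pattern.
#' @export
teContrast <- function(te, gene, zt, koGenotype, wtGenotype = "WT") {
  ko <- .teArm(te, gene, zt, koGenotype)
  wt <- .teArm(te, gene, zt, wtGenotype)
  ht <- ttestUnpaired(ko, wt)
  data.frame(gene = gene, zt = zt, ko = koGenotype, wt = wtGenotype,
             delta = mean(ko) - mean(wt), t = ht$t, p = ht$p,
             p_adj = ht$p, n_ko = length(ko), n_wt = length(wt),
             stringsAsFactors = FALSE)
}

#' Batch TE contrasts with FDR across the run
#'
#' Runs [teContrast()] for every requested gene x timepoint pair and
#' applies Benjamini-Hochberg (default) across all contrasts of the run.
#'
#' @inheritParams teContrast
#' @param genes Gene ids (default: all genes in `te`).
#' @param zts Timepoints (default: all in `te`).
#' @param adjust `"bh"` or `"sidak"` across the contrast set.
#' @return `data.frame` with one row per contrast, `p_adj` filled.
#' @export
teContrasts <- function(te, koGenotype, wtGenotype = "WT",
                        genes = unique(te$gene),
                        zts = sort(unique(te$zt)),
                        adjust = c("bh", "sidak")) {
  adjust <- match.arg(adjust)
  grid <- expand.grid(gene = genes, zt = zts, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    teContrast(te, grid$gene[i], grid$zt[i], koGenotype, wtGenotype)
  }))
  out$p_adj <- adjustPvalues(out$p, adjust)
  out
}

#' Derepression pattern across the light and dark timepoints
#'
#' Classifies a gene's knockout response from its contrasts at the two
#' cohort timepoints (light phase, ZT < 12, vs dark onset, ZT >= 12):
#' a timepoint counts as significant when `p_adj <= alpha` and the
#' effect reaches `minDelta` log2 units (positive delta = derepression
#' for TE contrasts; set `useAbs = TRUE` for abundance contrasts of
#' 3'-IRE genes, where the sign is reported raw).
#'
#' @param contrasts `data.frame` of two rows (one per timepoint) as
#'   produced by [teContrast()]/[teContrasts()], all for one gene.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param minDelta Magnitude floor in log2 units (default 0.5).
#' @param useAbs Use `|delta|` against the floor (abundance contrasts).
#' @return One-row `data.frame`: `gene`, `pattern` (`NONE`,
#'   `LIGHT_PHASE_ONLY`, `DARK_PHASE_ONLY`, `CONSTITUTIVE`), and the
#'   per-timepoint `delta`/`significant` pairs.
#' @export
derepressionProfile <- function(contrasts, alpha = 0.05, minDelta = 0.5,
                                useAbs = FALSE) {
  if (nrow(contrasts) != 2)
    stop("need exactly one contrast per timepoint (2 rows)")
  if (length(unique(contrasts$gene)) != 1)
    stop("contrasts must concern a single gene")
  light <- contrasts$zt < 12
  if (sum(light) != 1)
    stop("need one light-phase (ZT < 12) and one dark-onset timepoint")
  eff <- if (useAbs) abs(contrasts$delta) else contrasts$delta
  sig <- contrasts$p_adj <= alpha & eff >= minDelta
  pattern <- if (sig[light] && sig[!light]) "CONSTITUTIVE"
             else if (sig[light]) "LIGHT_PHASE_ONLY"
             else if (sig[!light]) "DARK_PHASE_ONLY"
             else "NONE"
  data.frame(gene = contrasts$gene[1], pattern = pattern,
             zt_light = contrasts$zt[light],
             delta_light = contrasts$delta[light],
             sig_light = sig[light],
             zt_dark = contrasts$zt[!light],
             delta_dark = contrasts$delta[!light],
             sig_dark = sig[!light],
             stringsAsFactors = FALSE)
}

#' Quantify a western-blot series
#'
#' Divides each target band by its loading-control band (e.g. VINCULIN),
#' rescales to a reference (the first lane, or the mean of all lanes),
#' and reports the peak/trough ratio of the per-timepoint means. The
#' ratio is invariant to the reference choice.
#'
#' @param series A [ProteinSeries].
#' @param reference `"control_mean"` (default) or `"first"`.
#' @return `list(normalized=, timepointMeans=, ratio=)`.
#' @examples
#' s <- simulateProteinSeries("IRP1", ratio = 1, cv = 0)
#' normalizeBlot(s)$ratio  # 1: flat protein
#' @export
normalizeBlot <- function(series, reference = c("control_mean", "first")) {
  stopifnot(is(series, "ProteinSeries"))
  reference <- match.arg(reference)
  if (any(series@loading <= 0)) stop("loading intensities must be > 0")
  v <- series@intensity / series@loading
  v <- v / switch(reference, first = v[1], control_mean = mean(v))
  tm <- tapply(v, series@timepoints, mean)
  list(normalized = v, timepointMeans = tm,
       ratio = max(tm) / min(tm))
}
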