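test_that("constant series fit flat with p = 1", {
  t <- seq(0, 22, by = 2)
  fit <- cosinorFit(t, rep(3, length(t)))
  expect_equal(amplitude(fit), 0, tolerance = 1e-12)
  expect_equal(foldChange(fit), 1, tolerance = 1e-12)
  expect_equal(pvalue(fit), 1)
})

test_that("a noise-free harmonic is recovered in closed form", {
  t <- seq(0, 22, by = 2)
  y <- 3 + 2 * cos(2 * pi * (t - 6) / 24)
  fit <- cosinorFit(t, y)
  expect_equal(mesor(fit), 3, tolerance = 1e-9)
  expect_equal(amplitude(fit), 2, tolerance = 1e-9)
  expect_equal(peakPhase(fit), 6, tolerance = 1e-9)
  expect_equal(foldChange(fit), 16, tolerance = 1e-9)
  expect_lt(pvalue(fit), 1e-12)
})

test_that("cosinor matches the phase-grid brute-force oracle on random
           series", {
  set.seed(101)
  t <- rep(seq(0, 22, by = 2), 2)
  for (i in 1:5) {
    y <- rnorm(length(t), sd = 1) +
      runif(1, 0, 2) * cos(2 * pi * (t - runif(1, 0, 24)) / 24)
    fit <- cosinorFit(t, y)
    oracle <- gridCosinor(t, y)
    expect_equal(amplitude(fit), oracle$amplitude, tolerance = 1e-3)
    dphi <- abs(comparePhases(peakPhase(fit), oracle$phase))
    expect_lt(dphi, 1e-3 * 24)
  }
})

test_that("shifting all timestamps shifts the phase and nothing else", {
  set.seed(5)
  t <- seq(0, 22, by = 2)
  y <- 1 + 0.8 * cos(2 * pi * (t - 17) / 24) + rnorm(12, sd = 0.2)
  f0 <- cosinorFit(t, y)
  for (delta in c(3, 11.5, 20)) {
    fs <- cosinorFit((t + delta) %% 24, y)
    expect_equal(peakPhase(fs), (peakPhase(f0) + delta) %% 24,
                 tolerance = 1e-9)
    expect_equal(amplitude(fs), amplitude(f0), tolerance = 1e-9)
    expect_equal(pvalue(fs), pvalue(f0), tolerance = 1e-9)
    expect_equal(mesor(fs), mesor(f0), tolerance = 1e-9)
  }
})

test_that("fitRhythms matches per-gene cosinorFit and needs 4 distinct
           timepoints", {
  set.seed(8)
  t <- rep(c(0, 6, 12, 18), each = 2)
  Y <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("g", 1:5), NULL))
  tab <- fitRhythms(Y, t, adjust = "none")
  for (g in 1:5) {
    f <- cosinorFit(t, Y[g, ])
    expect_equal(tab$amplitude[g], amplitude(f), tolerance = 1e-12)
    expect_equal(tab$pvalue[g], pvalue(f), tolerance = 1e-12)
  }
  expect_error(cosinorFit(rep(c(0, 8, 16), 2), rnorm(6)), "4 distinct")
  expect_error(cosinorFit(rep(3, 6), rnorm(6)), "identical")
})

test_that("p-value adjustment follows BH and Sidak by hand", {
  expect_equal(adjustPvalues(0.03, "bh"), 0.03)
  expect_equal(adjustPvalues(0.03, "sidak"), 0.03)
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjustPvalues(c(0.05, 0.5), "sidak")[1], 0.0975,
               tolerance = 1e-12)
  expect_error(adjustPvalues(c(0.1, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("rhythm calls need both significance and the 1.5-fold floor", {
  mk <- function(q, fold) {
    f <- cosinorFit(seq(0, 22, 2),
                    1 + (log2(fold) / 2) *
                      cos(2 * pi * seq(0, 22, 2) / 24))
    qvalue(f) <- q
    f
  }
  expect_true(callRhythmic(mk(0.01, 4)))
  expect_false(callRhythmic(mk(0.01, 1.4)))  # the sub-1.5-fold regime
  expect_false(callRhythmic(mk(0.2, 4)))
  f <- cosinorFit(seq(0, 22, 2), rnorm(12))
  expect_error(callRhythmic(f), "qvalue")
})

test_that("regulatory-mode classification reproduces the canonical
           layer patterns", {
  t <- rep(seq(0, 22, by = 2), 2)
  rhythmic <- function() {
    f <- cosinorFit(t, 2 * cos(2 * pi * (t - 18) / 24))
    qvalue(f) <- 1e-6
    f
  }
  flat <- function() {
    f <- cosinorFit(t, rnorm(length(t), sd = 1e-3))
    qvalue(f) <- 1
    f
  }
  mode1 <- classifyRegulatoryMode(list(intron = flat(), exon = rhythmic(),
                                       rpf = rhythmic(), te = flat()))
  expect_equal(as.character(mode1$mode), "POST_TRANSCRIPTIONAL")
  mode2 <- classifyRegulatoryMode(list(intron = flat(), exon = flat(),
                                       rpf = rhythmic(), te = rhythmic()))
  expect_equal(as.character(mode2$mode), "TRANSLATIONAL")
  mode3 <- classifyRegulatoryMode(list(intron = rhythmic(),
                                       exon = rhythmic(),
                                       rpf = rhythmic(), te = flat()))
  expect_equal(as.character(mode3$mode), "TRANSCRIPTIONAL")
  mode4 <- classifyRegulatoryMode(list(intron = flat(), exon = flat(),
                                       rpf = flat(), te = flat()))
  expect_equal(as.character(mode4$mode), "NONE")
  mode5 <- classifyRegulatoryMode(list(intron = rhythmic(),
                                       exon = rhythmic(),
                                       rpf = rhythmic(),
                                       te = rhythmic()))
  expect_equal(as.character(mode5$mode), "MIXED")
  expect_error(classifyRegulatoryMode(list(intron = flat())), "missing")
})

test_that("circular phase differences take the shortest signed arc", {
  expect_equal(comparePhases(12, 12), 0)
  expect_equal(comparePhases(22, 2), 4)
  expect_equal(comparePhases(2, 22), -4)
  expect_equal(comparePhases(12, 0), 12)  # inversion maps to +12
  expect_equal(comparePhases(0, 12), 12)
  expect_error(comparePhases(25, 0))
})

test_that("estimated fold of a noise-free simulated series equals the
           configured fold to 1e-6", {
  cfg <- oneClassConfig("Alas2_like", nGenesPerClass = 1, seed = 1)
  exp <- expectedRpkm(cfg)
  sh <- exp$samples[exp$samples$assay == "rpf", ]
  fit <- cosinorFit(sh$zt, log2(exp$rpkm$rpf["Alas2_like_g01", ]))
  expect_equal(foldChange(fit), 2^(2 * 0.5), tolerance = 1e-6)
})

test_that("trough-phase recovery: median error below 1 h across 200
           noisy simulations", {
  troughs <- vapply(1:200, function(s) {
    cfg <- oneClassConfig("Ftl1_like", nGenesPerClass = 1, seed = s)
    sim <- simulateExperiment(cfg)
    zt <- colData(sim$counts$rpf)$zt
    y <- log2(rpkm(sim$counts$rpf)["Ftl1_like_g01", ] + 0.5)
    (peakPhase(cosinorFit(zt, y)) + 12) %% 24
  }, 0)
  expect_lte(median(abs(comparePhases(rep(12, 200), troughs))), 1)
})
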