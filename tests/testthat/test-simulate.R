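test_that("identical configs give bit-identical simulations", {
  cfg <- simConfig(nGenesPerClass = 2, seed = 11)
  s1 <- simulateExperiment(cfg)
  s2 <- simulateExperiment(cfg)
  for (layer in names(s1$counts))
    expect_identical(assay(s1$counts[[layer]], "counts"),
                     assay(s2$counts[[layer]], "counts"))
  expect_identical(s1$truth, s2$truth)
  sOther <- simulateExperiment(simConfig(nGenesPerClass = 2, seed = 12))
  expect_false(identical(assay(s1$counts$rpf, "counts"),
                         assay(sOther$counts$rpf, "counts")))
})

test_that("noise-free counts equal the rounded analytic means", {
  cfg <- koCohortConfig(nGenesPerClass = 2, seed = 3, noise = "off")
  sim <- simulateExperiment(cfg)
  exp <- expectedRpkm(cfg)
  lens <- list(rpf = exp$genes$cds_len, rna_exon = exp$genes$exon_len,
               rna_intron = exp$genes$intron_len)
  for (layer in names(sim$counts)) {
    mu <- exp$rpkm[[layer]] * lens[[layer]] / 1e3 * (1e7 / 1e6)
    expect_equal(assay(sim$counts[[layer]], "counts"),
                 round(mu), tolerance = 0)
  }
})

test_that("a flat class at RPKM 50, 1 kb, 1e7 reads gives count 500", {
  cls <- geneClassSpec("flat", intronRpkm = 50, exonRpkm = 50,
                       baselineLog2TE = 0,
                       lengths = c(cds = 1000, exon = 1000,
                                   intron = 1000))
  cfg <- simConfig(nGenesPerClass = 1, noise = "off", seed = 1,
                   geneClasses = list(cls))
  sim <- simulateExperiment(cfg)
  for (layer in names(sim$counts))
    expect_true(all(assay(sim$counts[[layer]], "counts") == 500))
})

test_that("cosinor on the noise-free RPKM surface recovers the configured
           rhythm to 1e-6", {
  cfg <- simConfig(nGenesPerClass = 1, seed = 1)
  exp <- expectedRpkm(cfg)
  sh <- exp$samples[exp$samples$assay == "rpf", ]
  fit <- cosinorFit(sh$zt, log2(exp$rpkm$rpf["Ftl1_like_g01", ]))
  expect_equal(amplitude(fit), 1.0, tolerance = 1e-6)
  expect_equal(peakPhase(fit), 0, tolerance = 1e-6)
  expect_equal(foldChange(fit), 4, tolerance = 1e-6)
  fitD <- cosinorFit(sh$zt, log2(exp$rpkm$rpf["Dbp_like_g01", ]))
  expect_equal(amplitude(fitD), 2.0, tolerance = 1e-6)
  expect_equal(peakPhase(fitD), 10, tolerance = 1e-6)
})

test_that("feeding regimes rescale and invert feeding-driven rhythms", {
  nr <- applyFeedingRegime(1, 12, feedingRegime("night_restricted"),
                           "feeding")
  expect_equal(nr, list(amplitude = 1, phase = 12))
  ar <- applyFeedingRegime(1, 12, feedingRegime("arrhythmic"), "feeding")
  expect_equal(ar$amplitude, 0.02, tolerance = 1e-12)
  expect_equal(ar$phase, 12)
  df <- applyFeedingRegime(1, 12, feedingRegime("day_fed"), "feeding")
  expect_equal(df, list(amplitude = 1, phase = 0))
  # clock- and non-driven rhythms are untouched by the regime
  for (drv in c("clock", "none"))
    expect_equal(applyFeedingRegime(1, 12, feedingRegime("day_fed"), drv),
                 list(amplitude = 1, phase = 12))
})

test_that("realized amplitude is non-decreasing in feeding rhythmicity", {
  fractions <- c(0.5, 0.51, 0.56, 0.6, 0.76, 0.9, 1.0, 0.4, 0.2, 0.0)
  strength <- abs(2 * fractions - 1)
  amps <- vapply(fractions, function(d) {
    applyFeedingRegime(0.75, 18, feedingRegime("x", d),
                       "feeding")$amplitude
  }, 0)
  ord <- order(strength)
  expect_true(all(diff(amps[ord]) >= 0))
})

test_that("clock knockouts flatten clock-driven but not feeding-driven
           classes", {
  cfg <- simConfig(nGenesPerClass = 1, genotypes = c("WT", "Bmal1KO"),
                   seed = 2)
  exp <- expectedRpkm(cfg)
  sh <- exp$samples[exp$samples$assay == "rna_exon", ]
  ko <- sh$genotype == "Bmal1KO"
  dbp <- exp$rpkm$rna_exon["Dbp_like_g01", ]
  tfrc <- exp$rpkm$rna_exon["Tfrc_like_g01", ]
  expect_true(sd(log2(dbp[ko])) < 1e-12)       # clock target flattened
  expect_gt(sd(log2(dbp[!ko])), 0.5)
  expect_equal(sd(log2(tfrc[ko])), sd(log2(tfrc[!ko])),
               tolerance = 1e-12)              # feeding target unchanged
})

test_that("knocking out the encoding gene ablates footprints but only
           dents its mRNA", {
  cfg <- koCohortConfig(nGenesPerClass = 1, seed = 4, noise = "off")
  exp <- expectedRpkm(cfg)
  sh <- exp$samples[exp$samples$assay == "rpf", ]
  pick <- function(layer, genotype) {
    s <- exp$samples[exp$samples$assay == layer, ]
    mean(exp$rpkm[[layer]]["Aco1_marker_g01", s$genotype == genotype] /
         exp$rpkm[[layer]]["Aco1_marker_g01", s$genotype == "WT"])
  }
  expect_equal(pick("rpf", "Aco1KO"), 0.05, tolerance = 1e-9)
  expect_equal(pick("rna_exon", "Aco1KO"), 0.7, tolerance = 1e-9)
  expect_equal(pick("rpf", "Ireb2KO"), 1, tolerance = 1e-9)
})

test_that("knockout TE effects land at the right timepoint and layer", {
  cfg <- koCohortConfig(nGenesPerClass = 1, seed = 4, noise = "off")
  exp <- expectedRpkm(cfg)
  lr <- function(layer, genotype, zt) {
    s <- exp$samples[exp$samples$assay == layer, ]
    sel <- s$genotype == genotype & s$zt == zt
    unname(log2(exp$rpkm[[layer]]["Ftl1_like_g01", sel][1]))
  }
  # Ireb2 knockout derepresses Ftl1-like TE by +2 log2 at ZT5 only,
  # through the footprint layer, leaving its mRNA untouched
  expect_equal(lr("rpf", "Ireb2KO", 5) - lr("rpf", "WT", 5), 2,
               tolerance = 1e-9)
  expect_equal(lr("rpf", "Ireb2KO", 12) - lr("rpf", "WT", 12), 0,
               tolerance = 1e-9)
  expect_equal(lr("rna_exon", "Ireb2KO", 5) - lr("rna_exon", "WT", 5), 0,
               tolerance = 1e-9)
})

test_that("the truth ledger encodes one record per gene with the
           expected modes", {
  cfg <- simConfig(nGenesPerClass = 3, seed = 1)
  truth <- simTruth(cfg)
  expected <- sum(vapply(defaultGenePanel(),
                         function(cls) 3 * cls@sizeFactor, 0))
  expect_equal(nrow(truth), expected)
  expect_false(anyDuplicated(truth$gene_id) > 0)
  modeOf <- function(cl) unique(truth$mode[truth$class == cl])
  expect_equal(modeOf("Ftl1_like"), "TRANSLATIONAL")
  expect_equal(modeOf("Tfrc_like"), "POST_TRANSCRIPTIONAL")
  expect_equal(modeOf("Dbp_like"), "TRANSCRIPTIONAL")
  expect_equal(modeOf("Flat_filler"), "NONE")
  # sub-threshold rhythm (1.41-fold) deliberately stays NONE
  expect_equal(modeOf("Slc40a1_like"), "NONE")
})

test_that("simulated protein series honour ratio and noise settings", {
  flat <- simulateProteinSeries("IRP1", ratio = 1, cv = 0, seed = 1)
  expect_true(all(flat@intensity == flat@intensity[1]))
  expect_equal(normalizeBlot(flat)$ratio, 1)
  clean <- simulateProteinSeries(ratio = 10, cv = 0, seed = 1)
  expect_equal(normalizeBlot(clean)$ratio, 10, tolerance = 1e-9)
  expect_error(simulateProteinSeries(ratio = 0.5), "ratio")
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(genotypes = "Nrf2KO"), "genotype")
  expect_error(simConfig(librarySize = -1), "librarySize")
  expect_error(simConfig(dispersion = 0), "dispersion")
  expect_error(simConfig(timepoints = c(0, 25)), "timepoints")
  expect_error(feedingRegime("x", darkFraction = 1.2), "darkFraction")
  expect_error(geneClassSpec("x", intronRpkm = 1, exonRpkm = 10,
                             rpfRhythm = rhythmSpec(1, 25, "clock")),
               "phase")
})
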