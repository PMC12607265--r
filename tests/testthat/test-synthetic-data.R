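test_that("genotype simulation is deterministic and respects dosage domain", {
  cfg <- simConfig(nLines = 40, nSnps = 120, seed = 42)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosage(g1), dosage(g2))
  expect_true(all(dosage(g1) %in% 0:2))
  # positions strictly increasing per chromosome (validity enforces it too)
  expect_true(validObject(g1))
  # seeds differ -> different matrices
  g3 <- simulateGenotypes(simConfig(nLines = 40, nSnps = 120, seed = 43))
  expect_false(identical(dosage(g1), dosage(g3)))
})

test_that("empirical allele frequencies follow the binomial sampling model", {
  # at f = 0.5 with n lines, each SNP's alt frequency should fall within 3
  # binomial SEs of 0.5 (2n allele draws per SNP)
  n <- 10000L
  cfg <- simConfig(nLines = n, nSnps = 40, mafRange = c(0.5, 0.5), seed = 7)
  gd <- simulateGenotypes(cfg)
  f <- colMeans(dosage(gd)) / 2
  se <- sqrt(0.5 * 0.5 / (2 * n))
  expect_true(all(abs(f - 0.5) <= 3 * se))
})

test_that("degenerate forced frequencies give fixed dosages", {
  cfg <- simConfig(nLines = 2, nSnps = 1, nChromosomes = 1, seed = 1)
  gd <- simulateGenotypes(cfg, freqOverride = 1)
  expect_true(all(dosage(gd) == 2))
  gd0 <- simulateGenotypes(cfg, freqOverride = 0)
  expect_true(all(dosage(gd0) == 0))
})

test_that("too many SNPs for the genome is an error naming the limit", {
  cfg <- simConfig(nSnps = 100, nChromosomes = 1, chromLengthBp = 50, seed = 1)
  expect_error(simulateGenotypes(cfg), "available positions")
})

test_that("gene panel respects TSS strand convention and branch cycling", {
  cfg <- simConfig(nPanelGenes = 12, seed = 3)
  panel <- simulateGenePanel(cfg)
  m <- S4Vectors::mcols(panel)
  plus <- as.character(GenomicRanges::strand(panel)) == "+"
  expect_identical(m$tss[plus], GenomicRanges::start(panel)[plus])
  expect_identical(m$tss[!plus], GenomicRanges::end(panel)[!plus])
  expect_identical(unique(m$branch),
                   c("porphyrin", "chlorophyll", "heme", "siroheme",
                     "bilin", "catabolism"))
  one <- simulateGenePanel(simConfig(nPanelGenes = 1, seed = 1))
  expect_identical(S4Vectors::mcols(one)$tss, GenomicRanges::start(one))
})

test_that("70 genes on 10 chromosomes have disjoint bodies per chromosome", {
  panel <- simulateGenePanel(simConfig(nPanelGenes = 70, seed = 5))
  # interval-overlap scan, independent of the generator's placement logic
  byChrom <- split(panel, as.character(GenomicRanges::seqnames(panel)))
  for (gr in byChrom) {
    if (length(gr) < 2) next
    o <- order(GenomicRanges::start(gr))
    expect_true(all(GenomicRanges::start(gr)[o][-1] >
                    GenomicRanges::end(gr)[o][-length(gr)]))
  }
  expect_error(simulateGenePanel(simConfig(nPanelGenes = 70,
                                           nChromosomes = 1,
                                           chromLengthBp = 1e4, seed = 1)),
               "too small")
})

test_that("noiseless expression is an exact linear function of dosages", {
  cfg <- simConfig(nLines = 30, nSnps = 100, nPanelGenes = 10,
                   noiseSd = 0, cisEffectSd = 0, seed = 2)
  gd <- simulateGenotypes(cfg)
  panel <- simulateGenePanel(cfg)
  expr <- simulateExpression(gd, panel, cfg, "L3Base", baseline = 5)
  expect_true(all(expr == 5))

  cfg2 <- simConfig(nLines = 30, nSnps = 100, nPanelGenes = 10,
                    noiseSd = 0, cisEffectSd = 0, seed = 2,
                    regulators = list(plantedRegulator(7L, "gene003", 1)))
  e2 <- simulateExpression(gd, panel, cfg2, "L3Base", baseline = 0)
  expect_equal(e2["gene003", ], dosage(gd)[, 7], ignore_attr = TRUE)
  expect_true(all(e2[rownames(e2) != "gene003", ] == 0))
})

test_that("sign flip applies only in the designated tissue", {
  cfg <- simConfig(nLines = 20, nSnps = 50, nPanelGenes = 10, noiseSd = 0,
                   cisEffectSd = 0, seed = 9,
                   regulators = list(plantedRegulator(
                     5L, c("gene001", "gene002"), 2,
                     signFlipGenes = "gene001", flipTissue = "LMAD")))
  gd <- simulateGenotypes(cfg)
  panel <- simulateGenePanel(cfg)
  base <- simulateExpression(gd, panel, cfg, "L3Base")
  flip <- simulateExpression(gd, panel, cfg, "LMAD")
  expect_equal(flip["gene001", ], -base["gene001", ])
  expect_equal(flip["gene002", ], base["gene002", ])
})

test_that("missing regulator SNPs and targets are errors", {
  cfg <- simConfig(nLines = 10, nSnps = 20, nPanelGenes = 5, seed = 1,
                   regulators = list(plantedRegulator(999L, "gene001", 1)))
  gd <- simulateGenotypes(cfg)
  panel <- simulateGenePanel(cfg)
  expect_error(simulateExpression(gd, panel, cfg), "out of range")
  cfg2 <- simConfig(nLines = 10, nSnps = 20, nPanelGenes = 5, seed = 1,
                    regulators = list(plantedRegulator(1L, "nope", 1)))
  expect_error(simulateExpression(gd, panel, cfg2), "not in panel")
})

test_that("phenotype simulation encodes mutant-only (epistatic) effects", {
  cfg <- simConfig(nLines = 50, nSnps = 20, seed = 4)
  gd <- simulateGenotypes(cfg)
  # noiseless: MT strictly increasing in dosage, WT flat
  ph <- simulatePhenotypes(gd, 1, mutantEffect = 5, wtEffect = 0,
                           traitMean = 30, traitSd = 0, seed = 4)
  g <- unname(dosage(gd)[, 1])
  expect_equal(ph$MT_CCMI, 30 + 5 * g)
  expect_true(all(ph$WT_CCMI == 30))
  # no effects, no noise -> constant at the mean
  ph0 <- simulatePhenotypes(gd, 1, mutantEffect = 0, traitSd = 0, seed = 1)
  expect_true(all(ph0$MT_CCMII == 30) && all(ph0$WT_CCMII == 30))
  expect_error(simulatePhenotypes(gd, 1, 1, traitSd = -1), "traitSd")
})

test_that("GWAS power separates mutant and wild-type traits at the focal SNP", {
  # Monte-Carlo power check: with a strong mutant-only effect the focal SNP
  # reaches p <= 1e-4 on the MT trait but not on the WT trait
  reps <- 25
  hitMT <- hitWT <- logical(reps)
  for (i in seq_len(reps)) {
    cfg <- simConfig(nLines = 500, nSnps = 20, seed = 100 + i)
    gd <- simulateGenotypes(cfg)
    ph <- simulatePhenotypes(gd, 1, mutantEffect = 2, traitSd = 1,
                             seed = 100 + i)
    pmt <- scanGene(gd, ph$MT_CCMI)$p_value[1]
    pwt <- scanGene(gd, ph$WT_CCMI)$p_value[1]
    hitMT[i] <- pmt <= 1e-4
    hitWT[i] <- pwt <= 1e-4
  }
  expect_true(all(hitMT))
  expect_true(mean(hitWT) <= 0.2)
})

test_that("genotype, panel, expression and phenotype writers round-trip", {
  cfg <- simConfig(nLines = 12, nSnps = 30, nPanelGenes = 6, seed = 6)
  gd <- simulateGenotypes(cfg)
  panel <- simulateGenePanel(cfg)
  td <- withr::local_tempdir()

  p <- writeDosageTsv(gd, file.path(td, "d.tsv"))
  back <- readDosageTsv(p)
  expect_equal(dosage(back), dosage(gd))

  writeGenotypeVcf(gd, file.path(td, "g.vcf"))
  skip_if_not_installed("VariantAnnotation")
  vback <- readGenotypeVcf(file.path(td, "g.vcf"))
  expect_equal(unname(dosage(vback)[lineIds(gd), colnames(dosage(gd))]),
               unname(dosage(gd)))

  writePanelBed(panel, file.path(td, "p.bed"))
  writePanelGff3(panel, file.path(td, "p.gff3"))
  bback <- readPanel(file.path(td, "p.bed"))
  gback <- readPanel(file.path(td, "p.gff3"))
  for (pb in list(bback, gback)) {
    expect_equal(S4Vectors::mcols(pb)$gene_id, S4Vectors::mcols(panel)$gene_id)
    expect_equal(GenomicRanges::start(pb), GenomicRanges::start(panel))
    expect_equal(S4Vectors::mcols(pb)$tss, S4Vectors::mcols(panel)$tss)
  }
  expect_equal(S4Vectors::mcols(bback)$branch, S4Vectors::mcols(panel)$branch)

  expr <- simulateExpression(gd, panel, cfg, "L3Base")
  writeExpressionTsv(expr, file.path(td, "e.tsv"))
  eback <- readExpressionTsv(file.path(td, "e.tsv"))
  expect_equal(eback, expr[, , drop = FALSE], ignore_attr = TRUE)
})
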