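# Shared fixtures, built in code.

# Small study with one planted coordinate regulator: 300 lines, 500 SNPs,
# 70 genes. The regulator is a common variant (chromosome-10 SNP with MAF
# nearest 0.3) while its targets are the first panel genes (chromosomes
# 1-2), so every planted effect is unambiguously trans-acting and the
# regulator allele segregates widely enough to be mappable.
regulatorStudy <- function(seed = 1L, nLines = 300L, effect = 0.5,
                           noiseSd = 0.5, targets = sprintf("gene%03d", 1:10),
                           flipGene = character(0), flipTissue = NA) {
  base <- simConfig(nLines = nLines, nSnps = 500L, nPanelGenes = 70L,
                    noiseSd = noiseSd, cisEffectSd = 0.5, seed = seed)
  gd <- suppressMessages(recodeAndFilter(simulateGenotypes(base)))
  s <- snpMap(gd)
  on10 <- which(as.character(GenomicRanges::seqnames(s)) == "10")
  regSnp <- names(s)[on10[which.min(abs(S4Vectors::mcols(s)$maf[on10] -
                                        0.3))]]
  cfg <- simConfig(nLines = nLines, nSnps = 500L, nPanelGenes = 70L,
                   noiseSd = noiseSd, cisEffectSd = 0.5, seed = seed,
                   regulators = list(plantedRegulator(regSnp, targets,
                                                      effect,
                                                      signFlipGenes = flipGene,
                                                      flipTissue = flipTissue)))
  list(cfg = cfg, genotypes = gd, panel = simulateGenePanel(cfg),
       regSnp = regSnp, targets = targets, effect = effect)
}

# A tiny association table for hotspot-logic unit tests.
assocRow <- function(chrom, pos, gene, beta = 1, p = 1e-5,
                     tissue = "L3Base") {
  data.frame(snp = paste0(chrom, "-", pos), chrom = as.character(chrom),
             pos = pos, gene = gene, tissue = tissue, beta = beta,
             p_value = p, n = 100L)
}

assocTable <- function(...) do.call(rbind, list(...))

# Independent closed-form simple-regression oracle: r-to-t conversion.
olsOracle <- function(x, y) {
  n <- length(x)
  r <- suppressWarnings(stats::cor(x, y))
  beta <- r * stats::sd(y) / stats::sd(x)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(beta = beta, p = 2 * stats::pt(-abs(t), n - 2))
}
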