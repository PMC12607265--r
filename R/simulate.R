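#' Simulate a biallelic genotype matrix for inbred lines
#'
#' Draws per-SNP alternate-allele frequencies uniformly from
#' `mafRange(config)` and samples each line's dosage as two independent allele
#' draws (Binomial(2, f)), mimicking inbred-panel genotypes after imputation.
#' SNP positions are placed uniformly without replacement along each
#' chromosome; SNPs are spread as evenly as possible over chromosomes.
#' Frequencies below 0.05 may be generated (the downstream MAF filter is
#' expected to remove them).
#'
#' All draws are taken from a stream seeded by `config@seed`, so identical
#' configurations give bit-identical output.
#'
#' @param config a [SimConfig-class] object.
#' @param freqOverride optional numeric vector (length 1 or `nSnps`) of
#'   alternate-allele frequencies in \[0, 1\] that replaces the uniform draw;
#'   intended for degenerate-case testing.
#' @return A [GenotypeData-class] object with lines `line001`, ... and SNP ids
#'   `chrom-pos`.
#' @examples
#' gd <- simulateGenotypes(simConfig(nLines = 20, nSnps = 50, seed = 7))
#' table(dosage(gd)[, 1])
#' @export
simulateGenotypes <- function(config, freqOverride = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nchr <- config@nChromosomes
  perChrom <- diff(round(seq(0, config@nSnps, length.out = nchr + 1)))
  if (any(perChrom > config@chromLengthBp))
    stop("nSnps exceeds available positions: up to ",
         floor(config@chromLengthBp), " per chromosome, requested ",
         max(perChrom))
  chrom <- rep(as.character(seq_len(nchr)), perChrom)
  pos <- unlist(lapply(perChrom, function(k)
    sort(sample.int(config@chromLengthBp, k))), use.names = FALSE)
  f <- if (is.null(freqOverride))
    stats::runif(config@nSnps, config@mafRange[1], config@mafRange[2])
  else rep_len(freqOverride, config@nSnps)
  d <- vapply(f, function(fi) stats::rbinom(config@nLines, 2L, fi),
              integer(config@nLines))
  rownames(d) <- sprintf("line%03d", seq_len(config@nLines))
  gr <- GRanges(chrom, IRanges(pos, width = 1), ref = "A", alt = "T")
  gr <- .withToyGenome(gr, nchr, config@chromLengthBp)
  genotypeData(d, gr)
}

.BRANCHES <- c("porphyrin", "chlorophyll", "heme", "siroheme", "bilin",
               "catabolism")

#' Simulate the gene panel annotation
#'
#' Lays `nPanelGenes` non-overlapping gene bodies of fixed length (4 kb) on
#' the toy genome, spread evenly across chromosomes and evenly spaced within
#' each chromosome. Strands alternate + / - and a pathway-branch label is
#' cycled over porphyrin, chlorophyll, heme, siroheme, bilin and catabolism,
#' mirroring a branched biosynthetic pathway panel. The transcription start
#' site (TSS) is the start coordinate on + genes and the end coordinate on -
#' genes.
#'
#' @param config a [SimConfig-class] object.
#' @param geneLength gene-body length in bp.
#' @return A `GRanges` with mcols `gene_id`, `branch`, `tss`.
#' @examples
#' panel <- simulateGenePanel(simConfig(nPanelGenes = 12, seed = 1))
#' table(S4Vectors::mcols(panel)$branch)
#' @export
simulateGenePanel <- function(config, geneLength = 4000) {
  stopifnot(is(config, "SimConfig"))
  ng <- config@nPanelGenes
  nchr <- config@nChromosomes
  perChrom <- diff(round(seq(0, ng, length.out = nchr + 1)))
  chrom <- character(0); start <- numeric(0)
  for (ci in seq_len(nchr)) {
    k <- perChrom[ci]
    if (k == 0) next
    # even spacing; require a gap between consecutive bodies
    step <- floor(config@chromLengthBp / (k + 1))
    if (step <= geneLength)
      stop("genome too small for requested panel: need >", geneLength,
           " bp spacing on chromosome ", ci)
    chrom <- c(chrom, rep(as.character(ci), k))
    start <- c(start, step * seq_len(k))
  }
  end <- start + geneLength - 1
  strand <- rep_len(c("+", "-"), ng)
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$gene_id <- sprintf("gene%03d", seq_len(ng))
  mcols(gr)$branch <- rep_len(.BRANCHES, ng)
  mcols(gr)$tss <- as.integer(ifelse(strand == "+", start, end))
  names(gr) <- mcols(gr)$gene_id
  gr <- .withToyGenome(gr, nchr, config@chromLengthBp)
  gr
}

# register all toy chromosomes (even empty ones) with their lengths
.withToyGenome <- function(gr, nchr, chromLengthBp) {
  lv <- as.character(seq_len(nchr))
  seqlevels(gr) <- lv
  seqlengths(gr) <- stats::setNames(rep(chromLengthBp, nchr), lv)
  gr
}

#' Map each panel gene to its nearest SNP (the gene's cis SNP)
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param panel gene panel `GRanges` from [simulateGenePanel()].
#' @return integer vector of SNP column indices, NA where a gene's chromosome
#'   carries no SNP; named by gene id.
#' @keywords internal
.cisSnpIndex <- function(genotypes, panel) {
  s <- snpMap(genotypes)
  schrom <- as.character(GenomicRanges::seqnames(s))
  spos <- GenomicRanges::start(s)
  vapply(seq_along(panel), function(i) {
    onchrom <- which(schrom == as.character(GenomicRanges::seqnames(panel[i])))
    if (!length(onchrom)) return(NA_integer_)
    tss <- mcols(panel)$tss[i]
    onchrom[which.min(abs(spos[onchrom] - tss))]
  }, integer(1))
}

#' Simulate panel expression with planted cis and trans architecture
#'
#' Builds expression(gene, line) = baseline + cis * dosage(cis SNP of gene) +
#' sum over planted regulators of effect * dosage(regulator SNP) + Gaussian
#' noise. Per-gene cis effects are drawn N(0, `cisEffectSd`) once (seed +1
#' substream) so they are shared across tissues; noise is drawn from a
#' tissue-specific substream so tissues are independent replicates. Regulator
#' targets listed in `signFlipGenes` have their trans effect negated when
#' `tissue` equals the regulator's `flipTissue`.
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param panel gene panel `GRanges`.
#' @param config a [SimConfig-class] object carrying `regulators`, `noiseSd`,
#'   `cisEffectSd` and the seed.
#' @param tissue tissue label (enters the noise substream and sign-flip rule).
#' @param baseline baseline expression level added to every entry.
#' @return genes x lines numeric matrix (rownames gene ids, colnames line
#'   ids) with attribute `"cis_snp"` giving each gene's cis SNP column index.
#' @examples
#' cfg <- simConfig(nLines = 30, nSnps = 100, nPanelGenes = 10,
#'                  noiseSd = 0, cisEffectSd = 0, seed = 3)
#' expr <- simulateExpression(simulateGenotypes(cfg),
#'                            simulateGenePanel(cfg), cfg, "L3Base")
#' stopifnot(all(expr == expr[1, 1]))
#' @export
simulateExpression <- function(genotypes, panel, config, tissue = "L3Base",
                               baseline = 0) {
  stopifnot(is(genotypes, "GenotypeData"), is(config, "SimConfig"))
  d <- dosage(genotypes)
  ng <- length(panel)
  genes <- mcols(panel)$gene_id
  cisIdx <- .cisSnpIndex(genotypes, panel)
  set.seed(config@seed + 1L)
  cisEff <- stats::rnorm(ng, 0, config@cisEffectSd)
  expr <- matrix(baseline, nrow = ng, ncol = nrow(d),
                 dimnames = list(genes, rownames(d)))
  for (i in seq_len(ng)) if (!is.na(cisIdx[i]) && cisEff[i] != 0)
    expr[i, ] <- expr[i, ] + cisEff[i] * d[, cisIdx[i]]
  for (r in config@regulators) {
    j <- .resolveSnp(genotypes, r$snp)
    miss <- setdiff(r$targets, genes)
    if (length(miss))
      stop("regulator target genes not in panel: ",
           paste(miss, collapse = ", "))
    for (k in seq_along(r$targets)) {
      eff <- r$effects[k]
      if (r$targets[k] %in% r$signFlipGenes &&
          identical(tissue, r$flipTissue)) eff <- -eff
      expr[r$targets[k], ] <- expr[r$targets[k], ] + eff * d[, j]
    }
  }
  if (config@noiseSd > 0) {
    set.seed(config@seed + 1000L +
             sum(utf8ToInt(tissue)) %% 997L)
    expr <- expr + matrix(stats::rnorm(length(expr), 0, config@noiseSd),
                          nrow = ng)
  }
  attr(expr, "cis_snp") <- stats::setNames(cisIdx, genes)
  expr
}

.resolveSnp <- function(genotypes, snp) {
  if (is.numeric(snp)) {
    if (snp < 1 || snp > nSnps(genotypes))
      stop("regulator SNP index out of range: ", snp)
    return(as.integer(snp))
  }
  j <- match(snp, colnames(dosage(genotypes)))
  if (is.na(j)) stop("regulator SNP not found: ", snp)
  j
}

#' Simulate mutant/wild-type phenotypes with an epistatic focal SNP
#'
#' Emulates paired chlorophyll-meter readings from mutant (MT) and wild-type
#' (WT) F1 siblings at two timepoints (CCMI, CCMII). The focal SNP shifts the
#' mutant trait by `mutantEffect` per alternate allele but the wild-type
#' trait only by `wtEffect` (default 0), so the phenotypic consequence of the
#' focal variant requires the mutant background (epistasis). Noise draws are
#' independent across MT/WT and timepoints.
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param focalSnp SNP column index or `chrom-pos` id.
#' @param mutantEffect,wtEffect trait units per alternate allele.
#' @param traitMean,traitSd trait baseline and residual SD (`traitSd` > 0
#'   unless exactly 0 for noiseless checks).
#' @param seed integer seed.
#' @return data.frame with columns `line`, `MT_CCMI`, `WT_CCMI`, `MT_CCMII`,
#'   `WT_CCMII`.
#' @examples
#' gd <- simulateGenotypes(simConfig(nLines = 20, nSnps = 10, seed = 2))
#' ph <- simulatePhenotypes(gd, focalSnp = 1, mutantEffect = 5, traitSd = 1,
#'                          seed = 2)
#' head(ph)
#' @export
simulatePhenotypes <- function(genotypes, focalSnp, mutantEffect,
                               wtEffect = 0, traitMean = 30, traitSd = 2,
                               seed = 1L) {
  if (traitSd < 0) stop("traitSd must be > 0 (or 0 for noiseless checks)")
  j <- .resolveSnp(genotypes, focalSnp)
  g <- unname(dosage(genotypes)[, j])
  n <- length(g)
  set.seed(seed + 2000L)
  noise <- function() if (traitSd > 0) stats::rnorm(n, 0, traitSd) else 0
  data.frame(line = rownames(dosage(genotypes)),
             MT_CCMI = traitMean + mutantEffect * g + noise(),
             WT_CCMI = traitMean + wtEffect * g + noise(),
             MT_CCMII = traitMean + mutantEffect * g + noise(),
             WT_CCMII = traitMean + wtEffect * g + noise(),
             row.names = NULL)
}
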