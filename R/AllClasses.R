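#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<- seqnames<-
NULL

#' GenotypeData: dosage matrix plus SNP map
#'
#' Container for a complete (no missing calls) biallelic genotype matrix of
#' inbred lines. Rows are lines, columns are SNPs; entries count copies of the
#' alternate allele (0, 1 or 2). The SNP map is a [GenomicRanges::GRanges] of
#' width-1 positions carrying `ref`, `alt` and `maf` metadata columns. SNP
#' identifiers follow the `chrom-pos` convention (e.g. `"5-144452049"`).
#'
#' Validity enforces: column count equal to SNP map length, dosages confined
#' to \{0, 1, 2\}, strictly increasing positions within each chromosome, and
#' stored minor allele frequencies that agree with the dosage matrix.
#'
#' @slot dosage numeric matrix, lines x SNPs, values in \{0, 1, 2\}.
#' @slot snps `GRanges` with mcols `ref`, `alt`, `maf`.
#'
#' @seealso [genotypeData()], [dosage()], [snpMap()], [recodeAndFilter()]
#' @exportClass GenotypeData
setClass("GenotypeData",
  representation(dosage = "matrix", snps = "GRanges"))

setValidity("GenotypeData", function(object) {
  msg <- character(0)
  d <- object@dosage
  s <- object@snps
  if (ncol(d) != length(s))
    msg <- c(msg, "ncol(dosage) must equal length(snps)")
  if (length(d) && !all(d %in% c(0, 1, 2)))
    msg <- c(msg, "dosage values must be 0, 1 or 2")
  if (is.null(rownames(d)))
    msg <- c(msg, "dosage must have line identifiers as rownames")
  need <- c("ref", "alt", "maf")
  if (!all(need %in% colnames(mcols(s))))
    msg <- c(msg, "snp map must carry mcols ref, alt, maf")
  if (ncol(d) == length(s) && length(s)) {
    bychrom <- split(GenomicRanges::start(s),
                     as.character(GenomicRanges::seqnames(s)))
    if (!all(vapply(bychrom, function(p) !is.unsorted(p, strictly = TRUE),
                    logical(1))))
      msg <- c(msg, "SNP positions must be strictly increasing per chromosome")
    if (nrow(d) > 0 && "maf" %in% colnames(mcols(s))) {
      f <- colMeans(d) / 2
      maf <- pmin(f, 1 - f)
      if (max(abs(maf - mcols(s)$maf)) > 1e-8)
        msg <- c(msg, "stored maf disagrees with dosage-derived maf")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage lines x SNPs matrix of alternate-allele counts with line ids
#'   as rownames. Column names are replaced by `chrom-pos` SNP identifiers.
#' @param snps `GRanges` of SNP positions with mcols `ref` and `alt`; `maf` is
#'   (re)computed from the dosage matrix.
#' @return A [GenotypeData-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200), width = 1),
#'                              ref = "A", alt = "T")
#' d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'             dimnames = list(paste0("L", 1:3), NULL))
#' gd <- genotypeData(d, gr)
#' nSnps(gd)
#' @export
genotypeData <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  f <- if (nrow(dosage)) colMeans(dosage) / 2 else numeric(ncol(dosage))
  mcols(snps)$maf <- pmin(f, 1 - f)
  ids <- paste0(as.character(GenomicRanges::seqnames(snps)), "-",
                GenomicRanges::start(snps))
  colnames(dosage) <- ids
  names(snps) <- ids
  new("GenotypeData", dosage = dosage, snps = snps)
}

#' SimConfig: parameters of the synthetic study
#'
#' Describes the toy genome, genotype sampling, the gene panel and the planted
#' regulatory architecture used by the synthetic-data generator. Defaults give
#' a desk-scale stand-in for a diversity-panel eGWAS: 300 lines genotyped at
#' biallelic SNPs on a 10-chromosome x 20 Mb genome, a 70-gene panel with
#' cis-acting variants at each gene, and optional planted trans regulators.
#'
#' @slot nLines number of inbred lines.
#' @slot nChromosomes,chromLengthBp toy genome shape.
#' @slot nSnps total SNP count (spread evenly over chromosomes).
#' @slot mafRange range of per-SNP alternate-allele frequencies, in (0, 0.5].
#' @slot nPanelGenes size of the gene panel.
#' @slot cisEffectSd SD of per-gene cis effects (expression units per allele).
#' @slot regulators list of planted regulators, see [plantedRegulator()].
#' @slot noiseSd SD of Gaussian expression noise.
#' @slot seed integer seed; fully determines all generator output.
#' @seealso [simConfig()], [simulateGenotypes()], [simulateExpression()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nLines = "integer", nChromosomes = "integer",
    chromLengthBp = "numeric", nSnps = "integer", mafRange = "numeric",
    nPanelGenes = "integer", cisEffectSd = "numeric", regulators = "list",
    noiseSd = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nLines < 2) msg <- c(msg, "nLines must be >= 2")
  counts <- c(object@nChromosomes, object@nSnps, object@nPanelGenes)
  if (any(counts < 1)) msg <- c(msg, "all counts must be positive")
  if (object@chromLengthBp < 1) msg <- c(msg, "chromLengthBp must be positive")
  mr <- object@mafRange
  if (length(mr) != 2 || mr[1] > mr[2] || mr[1] <= 0 || mr[2] > 0.5)
    msg <- c(msg, "mafRange must lie within (0, 0.5]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@cisEffectSd < 0) msg <- c(msg, "cisEffectSd must be >= 0")
  for (r in object@regulators) {
    if (!all(c("snp", "targets", "effects") %in% names(r)))
      msg <- c(msg, "each regulator needs snp, targets, effects")
    else if (length(r$targets) != length(r$effects) || any(r$effects == 0))
      msg <- c(msg, "regulator effects must be nonzero, one per target gene")
  }
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' @param nLines,nChromosomes,chromLengthBp,nSnps,mafRange,nPanelGenes
#'   genome and sampling parameters; see [SimConfig-class].
#' @param cisEffectSd SD of per-gene cis effect sizes; 0 disables cis effects.
#' @param regulators list of [plantedRegulator()] specifications.
#' @param noiseSd residual expression SD (expression units).
#' @param seed integer; determines every downstream draw.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nLines = 50, nSnps = 200, nPanelGenes = 10, seed = 1)
#' @export
simConfig <- function(nLines = 300L, nChromosomes = 10L,
                      chromLengthBp = 2e7, nSnps = 1000L,
                      mafRange = c(0.05, 0.5), nPanelGenes = 70L,
                      cisEffectSd = 0.5, regulators = list(),
                      noiseSd = 0.5, seed = 1L) {
  new("SimConfig", nLines = as.integer(nLines),
      nChromosomes = as.integer(nChromosomes),
      chromLengthBp = as.numeric(chromLengthBp), nSnps = as.integer(nSnps),
      mafRange = as.numeric(mafRange), nPanelGenes = as.integer(nPanelGenes),
      cisEffectSd = as.numeric(cisEffectSd), regulators = regulators,
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Specify a planted trans regulator
#'
#' A planted regulator is a SNP whose alternate allele shifts the expression
#' of a set of panel genes (>= 8 by default in downstream hotspot calling),
#' with one shared effect direction except for an optional subset whose sign
#' is inverted in a designated tissue. This emulates a coordinately acting
#' trans-regulatory hotspot with a single divergently regulated gene.
#'
#' @param snp SNP index (column of the genotype matrix) or `chrom-pos` id.
#' @param targets character vector of target gene ids (panel members).
#' @param effects numeric effect sizes (expression units per alternate
#'   allele), one per target, all nonzero. A scalar is recycled.
#' @param signFlipGenes subset of `targets` whose effect is negated in
#'   `flipTissue`.
#' @param flipTissue tissue label in which the sign flip applies.
#' @return A named list understood by [simConfig()].
#' @examples
#' reg <- plantedRegulator(25, paste0("gene", 1:10), 0.8,
#'                         signFlipGenes = "gene1", flipTissue = "LMAD")
#' @export
plantedRegulator <- function(snp, targets, effects,
                             signFlipGenes = character(0),
                             flipTissue = NA_character_) {
  stopifnot(length(targets) >= 1, all(signFlipGenes %in% targets))
  effects <- rep_len(as.numeric(effects), length(targets))
  list(snp = snp, targets = as.character(targets), effects = effects,
       signFlipGenes = as.character(signFlipGenes),
       flipTissue = as.character(flipTissue))
}
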