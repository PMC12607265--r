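#' Association-scan configuration
#'
#' @param mafMin minimum minor allele frequency retained (default 0.05).
#' @param pReportMax only associations with p <= this are kept in scan
#'   output tables (default 1e-4, the preliminary eGWAS cutoff).
#' @param covariates optional lines x k numeric matrix of covariates added to
#'   every per-SNP model.
#' @return list of class `ScanConfig`.
#' @export
scanConfig <- function(mafMin = 0.05, pReportMax = 1e-4, covariates = NULL) {
  stopifnot(mafMin >= 0, mafMin < 0.5, pReportMax > 0, pReportMax <= 1)
  structure(list(mafMin = mafMin, pReportMax = pReportMax,
                 covariates = covariates), class = "ScanConfig")
}

#' Recode to alternate-allele dosage and apply the MAF filter
#'
#' Dosage already counts the alternate ("T"-recoded) allele in
#' [GenotypeData-class]; this step removes SNPs whose minor allele frequency
#' `min(f, 1 - f)` falls below `mafMin` (monomorphic SNPs always go: zero
#' variance is untestable). In/out counts are logged via `message()`.
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param mafMin frequency threshold (default 0.05).
#' @return A filtered [GenotypeData-class] object.
#' @examples
#' gd <- simulateGenotypes(simConfig(nLines = 50, nSnps = 100,
#'                                   mafRange = c(0.01, 0.5), seed = 1))
#' nSnps(recodeAndFilter(gd))
#' @export
recodeAndFilter <- function(genotypes, mafMin = 0.05) {
  f <- colMeans(dosage(genotypes)) / 2
  maf <- pmin(f, 1 - f)
  keep <- if (mafMin > 0) maf >= mafMin else maf > 0
  message("MAF filter: ", sum(keep), " of ", length(keep), " SNPs retained")
  if (!any(keep)) stop("no SNPs left after MAF filtering at ", mafMin)
  genotypes[, which(keep)]
}

# Vectorised simple OLS of each column of Y on each column of X, after
# optionally partialling out covariates from both (Frisch-Waugh). Returns
# beta, t and p matrices (SNPs x traits) and the residual dfs.
.olsScan <- function(X, Y, covariates = NULL) {
  n <- nrow(X)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    k <- ncol(covariates)
    q <- qr(cbind(1, covariates))
    X <- qr.resid(q, X)
    Y <- qr.resid(q, Y)
  } else {
    X <- sweep(X, 2, colMeans(X))
    Y <- sweep(Y, 2, colMeans(Y))
  }
  df <- n - 2L - k
  if (df < 1) stop("too few samples: n must exceed number of covariates + 2")
  sxx <- colSums(X^2)
  if (any(sxx == 0)) stop("zero-variance SNP in scan input (filter first)")
  syy <- colSums(Y^2)
  sxy <- crossprod(X, Y)                       # SNPs x traits
  beta <- sxy / sxx
  r2 <- sxy^2 / outer(sxx, syy)
  # constant trait: define beta 0, p 1
  const <- syy == 0
  r2[, const] <- 0
  beta[, const] <- 0
  r2 <- pmin(r2, 1)
  tstat <- sign(beta) * sqrt(r2 * df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[1 - r2 < 1e-12 & !matrix(const, nrow(beta), ncol(beta), byrow = TRUE)] <- 0
  p[, const] <- 1
  list(beta = beta, t = tstat, p = p, df = df, n = n)
}

#' Single-marker linear scan of one trait
#'
#' Ordinary least squares of `y` on each SNP's alternate-allele dosage (plus
#' covariates if supplied); the reported effect is the dosage coefficient
#' with a two-sided t-test p-value. A perfect fit is reported as p = 0
#' (downstream logic only thresholds); a constant `y` gives beta = 0, p = 1.
#'
#' @param genotypes a [GenotypeData-class] object with no zero-variance SNPs
#'   (run [recodeAndFilter()] first).
#' @param y per-line trait values, aligned with `lineIds(genotypes)`.
#' @param covariates optional lines x k matrix.
#' @param trait label stored in the `gene_or_trait` column.
#' @return data.frame with columns `snp`, `chrom`, `pos`, `gene_or_trait`,
#'   `beta`, `p_value`, `n`.
#' @examples
#' gd <- simulateGenotypes(simConfig(nLines = 40, nSnps = 20, seed = 5))
#' y <- dosage(gd)[, 3] * 0.8 + rnorm(40)
#' head(scanGene(gd, y))
#' @export
scanGene <- function(genotypes, y, covariates = NULL, trait = "trait") {
  stopifnot(length(y) == nLines(genotypes))
  fit <- .olsScan(dosage(genotypes), matrix(as.numeric(y)), covariates)
  s <- snpMap(genotypes)
  data.frame(snp = names(s),
             chrom = as.character(GenomicRanges::seqnames(s)),
             pos = GenomicRanges::start(s),
             gene_or_trait = trait,
             beta = fit$beta[, 1], p_value = fit$p[, 1], n = fit$n,
             row.names = NULL)
}

#' Expression GWAS over a gene panel
#'
#' Runs [scanGene()] for every panel gene against every SNP and concatenates
#' the results, retaining associations with p <= `pReportMax`. Lines are
#' intersected (and order-aligned) between the genotype and expression
#' matrices. Full-scan p-value histograms (20 bins per gene) are kept in the
#' `"p_histogram"` attribute for diagnostics.
#'
#' @param genotypes a filtered [GenotypeData-class] object.
#' @param expression genes x lines matrix.
#' @param tissue tissue label recorded on every row.
#' @param config a [scanConfig()]; `mafMin` is not re-applied here.
#' @return data.frame with columns `snp`, `chrom`, `pos`, `gene`, `tissue`,
#'   `beta`, `p_value`, `n`, ordered by gene then p-value.
#' @examples
#' cfg <- simConfig(nLines = 60, nSnps = 50, nPanelGenes = 5, seed = 9)
#' gd <- recodeAndFilter(simulateGenotypes(cfg))
#' expr <- simulateExpression(gd, simulateGenePanel(cfg), cfg, "L3Base")
#' assoc <- scanPanel(gd, expr, "L3Base", scanConfig(pReportMax = 1))
#' @export
scanPanel <- function(genotypes, expression, tissue = "L3Base",
                      config = scanConfig()) {
  shared <- intersect(lineIds(genotypes), colnames(expression))
  if (!length(shared)) stop("no shared lines between genotypes and expression")
  genotypes <- genotypes[match(shared, lineIds(genotypes)), ]
  Y <- t(expression[, shared, drop = FALSE])
  if (ncol(Y) == 0) {
    out <- data.frame(snp = character(0), chrom = character(0),
                      pos = numeric(0), gene = character(0),
                      tissue = character(0), beta = numeric(0),
                      p_value = numeric(0), n = integer(0))
    attr(out, "p_histogram") <- list()
    return(out)
  }
  fit <- .olsScan(dosage(genotypes), Y, config$covariates)
  s <- snpMap(genotypes)
  genes <- colnames(Y)
  hist <- lapply(seq_along(genes), function(g)
    tabulate(pmin(floor(fit$p[, g] * 20) + 1, 20), 20))
  names(hist) <- genes
  keep <- which(fit$p <= config$pReportMax, arr.ind = TRUE)
  keep <- keep[order(keep[, 2], fit$p[keep]), , drop = FALSE]
  out <- data.frame(snp = names(s)[keep[, 1]],
                    chrom = as.character(GenomicRanges::seqnames(s))[keep[, 1]],
                    pos = GenomicRanges::start(s)[keep[, 1]],
                    gene = genes[keep[, 2]],
                    tissue = tissue,
                    beta = fit$beta[keep], p_value = fit$p[keep],
                    n = fit$n, row.names = NULL)
  attr(out, "p_histogram") <- hist
  out
}

#' Write an association table as TSV
#'
#' @param assoc association data.frame from [scanPanel()].
#' @param path output path; `.gz` suffix writes gzip.
#' @param normalizeByTraitMean optional named vector of trait means; when
#'   given, an extra `beta_normalized` column (beta / trait mean) is added to
#'   the exported table only (stored betas are never rescaled).
#' @return `path`, invisibly.
#' @export
writeAssociationTsv <- function(assoc, path, normalizeByTraitMean = NULL) {
  out <- assoc
  if (!is.null(normalizeByTraitMean)) {
    key <- if ("gene" %in% names(out)) out$gene else out$gene_or_trait
    out$beta_normalized <- out$beta / normalizeByTraitMean[key]
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAssociationTsv
#' @export
readAssociationTsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}
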