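#' Per-gene Z-score standardization of an expression matrix
#'
#' Each gene (row) is centred on its mean over samples and scaled by its
#' sample standard deviation (n - 1 denominator). Zero-variance genes become
#' all-zero rows with a warning, so they contribute 0 to downstream indices
#' rather than shrinking gene sets.
#'
#' @param expression genes x samples numeric matrix (>= 2 samples).
#' @return matrix of the same shape; per gene, mean 0 and SD 1 (or all 0).
#' @examples
#' z <- zscoreMatrix(matrix(c(1, 3, 2, 2), 2, byrow = TRUE,
#'                          dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' z["g1", ]  # -0.707, +0.707
#' @export
zscoreMatrix <- function(expression) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 2) stop("Z-scores need at least 2 samples")
  mu <- rowMeans(expression)
  sd <- apply(expression, 1, stats::sd)
  zero <- sd == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) set to all-zero Z rows")
    sd[zero] <- 1
  }
  z <- (expression - mu) / sd
  z[zero, ] <- 0
  z
}

#' Gene-set expression index
#'
#' The index of a sample is the unweighted mean of its per-gene Z-scores over
#' a named gene set; used as an aggregate GWAS trait for coordinated pathway
#' expression (e.g. a 22-gene chlorophyll-biosynthesis index), or to compare
#' direction-grouped differentially expressed gene sets across samples.
#'
#' @param z Z-score matrix from [zscoreMatrix()].
#' @param geneSet non-empty character vector of row names of `z`.
#' @param name gene-set label.
#' @param direction optional tag: `"induced"`, `"repressed"` or `"none"`.
#' @return data.frame with columns `sample`, `index`, `set`, `direction`;
#'   the `index` column is directly usable as a trait in [scanGene()].
#' @examples
#' z <- rbind(g1 = c(1, -1), g2 = c(3, -3))
#' colnames(z) <- c("s1", "s2")
#' expressionIndex(z, c("g1", "g2"), "demo")$index  # 2, -2
#' @export
expressionIndex <- function(z, geneSet, name = "index",
                            direction = c("none", "induced", "repressed")) {
  direction <- match.arg(direction)
  if (!length(geneSet)) stop("empty gene set")
  miss <- setdiff(geneSet, rownames(z))
  if (length(miss))
    stop("gene(s) missing from Z-score matrix: ",
         paste(miss, collapse = ", "))
  idx <- colMeans(z[geneSet, , drop = FALSE])
  data.frame(sample = colnames(z), index = unname(idx), set = name,
             direction = direction, row.names = NULL)
}

#' Derive ratio and difference chlorophyll traits
#'
#' Adds, per timepoint, `Ratio_CCM* = MT / WT` and `Diff_CCM* = WT - MT` to a
#' phenotype table of paired mutant (MT) and wild-type (WT) chlorophyll meter
#' readings. Families with a zero WT reading get an NA ratio and a message.
#'
#' @param phenotypes data.frame with columns `MT_CCMI`, `WT_CCMI`,
#'   `MT_CCMII`, `WT_CCMII` (any subset of the two timepoints is accepted).
#' @return the input with added `Ratio_CCMI`/`Diff_CCMI` and/or
#'   `Ratio_CCMII`/`Diff_CCMII` columns.
#' @examples
#' deriveCcmTraits(data.frame(MT_CCMI = 20, WT_CCMI = 40))
#' @export
deriveCcmTraits <- function(phenotypes) {
  for (tp in c("CCMI", "CCMII")) {
    mt <- paste0("MT_", tp); wt <- paste0("WT_", tp)
    if (!all(c(mt, wt) %in% names(phenotypes))) next
    zero <- phenotypes[[wt]] == 0
    if (any(zero))
      message(sum(zero), " famil(ies) with WT_", tp,
              " = 0: ratio set to NA")
    ratio <- phenotypes[[mt]] / phenotypes[[wt]]
    ratio[zero] <- NA_real_
    phenotypes[[paste0("Ratio_", tp)]] <- ratio
    phenotypes[[paste0("Diff_", tp)]] <- phenotypes[[wt]] - phenotypes[[mt]]
  }
  phenotypes
}

#' Write/read index and phenotype tables as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path` invisibly, or the data.frame read.
#' @export
writeTableTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTableTsv
#' @export
readTableTsv <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
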