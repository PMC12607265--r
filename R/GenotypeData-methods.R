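#' @rdname GenotypeData-class
#' @param object,x a `GenotypeData` object
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname GenotypeData-class
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nLines", function(x) standardGeneric("nLines"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @describeIn GenotypeData-class lines x SNPs alternate-allele dosage matrix
#' @export
setMethod("dosage", "GenotypeData", function(x) x@dosage)

#' @describeIn GenotypeData-class SNP map as a `GRanges` (ref, alt, maf)
#' @export
setMethod("snpMap", "GenotypeData", function(x) x@snps)

#' @describeIn GenotypeData-class line identifiers
#' @export
setMethod("lineIds", "GenotypeData", function(x) rownames(x@dosage))

#' @describeIn GenotypeData-class number of lines
#' @export
setMethod("nLines", "GenotypeData", function(x) nrow(x@dosage))

#' @describeIn GenotypeData-class number of SNPs
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosage))

#' @describeIn GenotypeData-class subset by lines (i) and/or SNPs (j)
#' @param i,j,drop line and SNP indices; `drop` is ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  # genomic order is preserved regardless of the order of j, and maf is
  # recomputed because a line subset changes allele frequencies
  if (!is.logical(j) && !is.character(j)) j <- sort(unique(j))
  if (is.character(j)) j <- sort(match(j, colnames(x@dosage)))
  genotypeData(x@dosage[i, j, drop = FALSE], x@snps[j])
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosage), "lines x",
      ncol(object@dosage), "SNPs\n")
  sl <- unique(as.character(GenomicRanges::seqnames(object@snps)))
  cat("  chromosomes:", paste(utils::head(sl, 6), collapse = ", "),
      if (length(sl) > 6) "..." else "", "\n")
  if (length(object@snps))
    cat("  MAF range:",
        paste(signif(range(mcols(object@snps)$maf), 3), collapse = " - "),
        "\n")
})
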