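#' Write genotypes as a minimal biallelic VCF
#'
#' Emits a VCFv4.2 file with a single `GT` FORMAT field; dosages 0/1/2 map to
#' `0/0`, `0/1`, `1/1`. One sample column per line.
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param path output file path (`.vcf`).
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(genotypes, path) {
  s <- snpMap(genotypes)
  d <- dosage(genotypes)
  gt <- c("0/0", "0/1", "1/1")[t(d) + 1]
  gtm <- matrix(gt, nrow = ncol(d))
  body <- paste(as.character(GenomicRanges::seqnames(s)),
                GenomicRanges::start(s), names(s),
                mcols(s)$ref, mcols(s)$alt, ".", "PASS", ".", "GT",
                apply(gtm, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##contig=<ID=", seqlevels(s), ",length=",
           ifelse(is.na(seqlengths(s)), max(GenomicRanges::start(s)),
                  seqlengths(s)), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write/read a TSV dosage matrix (lines x SNPs, header = chrom-pos ids)
#'
#' @param genotypes a [GenotypeData-class] object.
#' @param path file path.
#' @return `writeDosageTsv`: `path` invisibly; `readDosageTsv`: a
#'   [GenotypeData-class] object (ref/alt recorded as A/T, the recoded
#'   convention in which dosage counts the alternate "T" allele).
#' @export
writeDosageTsv <- function(genotypes, path) {
  d <- dosage(genotypes)
  utils::write.table(data.frame(line = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDosageTsv
#' @export
readDosageTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df[[1]]
  parts <- strsplit(colnames(d), "-", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1)
  pos <- as.numeric(vapply(parts, `[`, "", 2))
  gr <- GRanges(chrom, IRanges(pos, width = 1), ref = "A", alt = "T")
  genotypeData(d, gr)
}

#' Read genotypes from a VCF file
#'
#' Uses `VariantAnnotation::readVcf`; multi-allelic records are dropped with
#' a logged count, and dosage is the count of the alternate allele per the
#' "reference = A, alternate = T" recoding convention.
#'
#' @param path a VCF file.
#' @return A [GenotypeData-class] object.
#' @export
readGenotypeVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF input")
  v <- VariantAnnotation::readVcf(path)
  nalt <- lengths(VariantAnnotation::alt(v))
  if (any(nalt != 1)) {
    message("dropped ", sum(nalt != 1), " multi-allelic record(s)")
    v <- v[nalt == 1]
  }
  gt <- VariantAnnotation::geno(v)$GT
  d <- matrix(vapply(strsplit(gt, "[/|]"),
                     function(a) sum(a != "0"), integer(1)),
              nrow = nrow(gt), dimnames = dimnames(gt))
  rr <- SummarizedExperiment::rowRanges(v)
  gr <- granges(rr)
  mcols(gr)$ref <- as.character(rr$REF)
  mcols(gr)$alt <- vapply(rr$ALT, function(a) as.character(a)[1], "")
  genotypeData(t(d), gr)
}

#' Write the gene panel as BED6 or GFF3
#'
#' BED6 carries the branch label in the name field (`gene_id|branch`); GFF3
#' writes gene features with `ID` and `branch` attributes. Both go through
#' rtracklayer.
#'
#' @param panel gene panel `GRanges` (mcols `gene_id`, `branch`, `tss`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePanelBed <- function(panel, path) {
  out <- granges(panel)
  mcols(out)$name <- paste0(mcols(panel)$gene_id, "|", mcols(panel)$branch)
  mcols(out)$score <- 0L
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' @rdname writePanelBed
#' @export
writePanelGff3 <- function(panel, path) {
  out <- granges(panel)
  mcols(out)$type <- "gene"
  mcols(out)$ID <- mcols(panel)$gene_id
  mcols(out)$branch <- mcols(panel)$branch
  rtracklayer::export(out, path, format = "GFF3")
  invisible(path)
}

#' Read a gene panel from BED6 or GFF3
#'
#' @param path annotation file ending in `.bed`, `.gff3` or `.gff`.
#' @return `GRanges` with mcols `gene_id`, `branch`, `tss`.
#' @export
readPanel <- function(path) {
  gr <- rtracklayer::import(path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    parts <- strsplit(mcols(gr)$name, "|", fixed = TRUE)
    mcols(gr)$gene_id <- vapply(parts, `[`, "", 1)
    mcols(gr)$branch <- vapply(parts, `[`, "", 2)
  } else {
    mcols(gr)$gene_id <- mcols(gr)$ID
  }
  mcols(gr)$tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                          GenomicRanges::end(gr), GenomicRanges::start(gr))
  names(gr) <- mcols(gr)$gene_id
  gr
}

#' Write/read an expression matrix as TSV (genes x lines)
#'
#' @param expr genes x lines matrix.
#' @param path file path.
#' @return `writeExpressionTsv`: `path` invisibly; `readExpressionTsv`: a
#'   numeric matrix.
#' @export
writeExpressionTsv <- function(expr, path) {
  utils::write.table(data.frame(gene = rownames(expr), expr,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
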