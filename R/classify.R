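#' Classify associations as cis, trans, or proximal-excluded
#'
#' Distance is measured from the SNP position to the nearest gene-body edge
#' (0 if the SNP lies inside the gene; 1-based coordinates). A SNP within
#' `cisKb` of the gene is cis-acting; a SNP on another chromosome or at
#' `transMb` or more is trans-acting; everything in between is
#' "proximal-excluded" - a deliberate gap class, since only the two extremes
#' have a defined regulatory interpretation.
#'
#' @param associations association data.frame (columns `snp`, `chrom`, `pos`,
#'   `gene`, `tissue`, `beta`, `p_value`).
#' @param panel gene panel `GRanges` with mcols `gene_id`.
#' @param cisKb cis distance threshold in kb (default 50).
#' @param transMb trans distance threshold in Mb (default 1).
#' @return the input data.frame with added columns `distance` (bp; NA for
#'   different-chromosome pairs) and `class` (factor: cis, trans,
#'   proximal-excluded).
#' @examples
#' panel <- GenomicRanges::GRanges("1", IRanges::IRanges(100000, 105000),
#'                                 gene_id = "g1")
#' names(panel) <- "g1"
#' a <- data.frame(snp = "1-60000", chrom = "1", pos = 60000, gene = "g1",
#'                 tissue = "L3Base", beta = 1, p_value = 1e-6)
#' classifyCisTrans(a, panel)$class
#' @export
classifyCisTrans <- function(associations, panel, cisKb = 50, transMb = 1) {
  gi <- match(associations$gene, mcols(panel)$gene_id)
  if (anyNA(gi))
    stop("gene(s) absent from annotation: ",
         paste(unique(associations$gene[is.na(gi)]), collapse = ", "))
  gchrom <- as.character(GenomicRanges::seqnames(panel))[gi]
  gstart <- GenomicRanges::start(panel)[gi]
  gend <- GenomicRanges::end(panel)[gi]
  pos <- associations$pos
  inside <- pos >= gstart & pos <= gend
  dist <- pmin(abs(pos - gstart), abs(pos - gend))
  dist[inside] <- 0
  same <- associations$chrom == gchrom
  dist[!same] <- NA_real_
  cls <- rep("proximal-excluded", nrow(associations))
  cls[same & dist <= cisKb * 1000] <- "cis"
  cls[!same | dist >= transMb * 1e6] <- "trans"
  associations$distance <- dist
  associations$class <- factor(cls, c("cis", "trans", "proximal-excluded"))
  associations
}

#' Exclusive genomic window index
#'
#' Half-open tiles `[i*W, (i+1)*W)` anchored at coordinate 0.
#'
#' @param pos 1-based positions.
#' @param windowKb window size in kb.
#' @return integer (0-based) window indices.
#' @export
windowIndex <- function(pos, windowKb) as.integer(floor(pos / (windowKb * 1000)))

#' Number of exclusive windows tiling a genome
#'
#' Each chromosome contributes `floor(length / window)` full windows plus one
#' for any remainder; e.g. a 2.5 Gb genome in 40 kb windows has 62,500.
#'
#' @param chromLengths numeric vector of chromosome lengths in bp.
#' @param windowKb window size in kb.
#' @return total window count.
#' @examples
#' genomeWindowCount(2.5e9, 40)  # 62500
#' @export
genomeWindowCount <- function(chromLengths, windowKb) {
  w <- windowKb * 1000
  sum(floor(chromLengths / w) + (chromLengths %% w > 0))
}

#' Retain the top (lowest-p) trans SNP per gene per 250 kb window
#'
#' Within each exclusive window, for each (gene, tissue), only the record
#' with the smallest p-value survives; ties break to the smaller position and
#' then the lexicographically smaller SNP id, so the result is fully
#' deterministic.
#'
#' @param transAssoc classified association table restricted to trans records.
#' @param windowKb exclusive window size in kb (default 250).
#' @return the surviving records with an added `window_index` column.
#' @export
selectTopSnps <- function(transAssoc, windowKb = 250) {
  if (!nrow(transAssoc)) {
    transAssoc$window_index <- integer(0)
    return(transAssoc)
  }
  transAssoc$window_index <- windowIndex(transAssoc$pos, windowKb)
  o <- order(transAssoc$gene, transAssoc$tissue, transAssoc$chrom,
             transAssoc$window_index, transAssoc$p_value, transAssoc$pos,
             transAssoc$snp)
  t2 <- transAssoc[o, ]
  key <- paste(t2$gene, t2$tissue, t2$chrom, t2$window_index, sep = "\r")
  out <- t2[!duplicated(key), ]
  rownames(out) <- NULL
  out
}
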