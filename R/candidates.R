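#' Candidate genes around a hot SNP, ranked by TSS distance
#'
#' Genes whose transcription start site lies within `windowKb` of the SNP
#' (boundary inclusive) are split by genomic side of the SNP (upstream =
#' smaller coordinate, downstream = larger; genome + orientation, not gene
#' strand) and the nearest `maxPerSide` per side are kept, ranked 1 (closest)
#' upward by TSS distance. A gene whose body overlaps the SNP is reported
#' once as `inside` with distance 0 and rank 1. Distance ties break to the
#' smaller gene start, then the lexicographically smaller id.
#'
#' @param chrom,pos SNP coordinate.
#' @param panel gene annotation `GRanges` with mcols `gene_id`, `tss`.
#' @param maxPerSide flanking genes retained per side (default 3).
#' @param windowKb search window in kb (default 125).
#' @return data.frame with columns `locus`, `gene`, `side`, `tss_distance`,
#'   `rank`; empty when no gene qualifies.
#' @export
annotateHotSnp <- function(chrom, pos, panel, maxPerSide = 3,
                           windowKb = 125) {
  locus <- paste0(chrom, "-", pos)
  onchrom <- panel[as.character(GenomicRanges::seqnames(panel)) == chrom]
  empty <- data.frame(locus = character(0), gene = character(0),
                      side = character(0), tss_distance = numeric(0),
                      rank = integer(0))
  if (!length(onchrom)) return(empty)
  tss <- mcols(onchrom)$tss
  gstart <- GenomicRanges::start(onchrom)
  gid <- mcols(onchrom)$gene_id
  inside <- gstart <= pos & GenomicRanges::end(onchrom) >= pos
  dist <- abs(tss - pos)
  rows <- list()
  if (any(inside))
    rows$inside <- data.frame(locus = locus, gene = gid[inside],
                              side = "inside", tss_distance = 0,
                              rank = 1L)
  for (sd in c("upstream", "downstream")) {
    sel <- !inside & dist <= windowKb * 1000 &
      (if (sd == "upstream") tss < pos else tss >= pos)
    if (!any(sel)) next
    o <- order(dist[sel], gstart[sel], gid[sel])
    keep <- utils::head(which(sel)[o], maxPerSide)
    rows[[sd]] <- data.frame(locus = locus, gene = gid[keep], side = sd,
                             tss_distance = dist[keep],
                             rank = seq_along(keep))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate genes for a windowed hotspot
#'
#' Hotspot boundaries are the minimum and maximum positions of the member
#' SNPs. Genes whose bodies overlap the boundary interval are retained as
#' `inside` candidates (no rank); in addition the nearest gene on each side
#' is retained as a flanking candidate if its TSS lies within `windowKb` of
#' the boundary edge (inclusive).
#'
#' @param chrom hotspot chromosome.
#' @param memberSnps positions of the SNPs comprising the hotspot
#'   (non-empty).
#' @param panel gene annotation `GRanges` with mcols `gene_id`, `tss`.
#' @param windowKb flank search distance in kb (default 125).
#' @return data.frame with columns `locus`, `gene`, `side`, `tss_distance`
#'   (0 for inside genes), `rank` (NA for inside genes, 1 for flanks).
#' @export
annotateHotspot <- function(chrom, memberSnps, panel, windowKb = 125) {
  if (!length(memberSnps)) stop("empty hotspot member SNP set")
  lo <- min(memberSnps); hi <- max(memberSnps)
  locus <- paste0(chrom, ":", lo, "-", hi)
  onchrom <- panel[as.character(GenomicRanges::seqnames(panel)) == chrom]
  tss <- mcols(onchrom)$tss
  gstart <- GenomicRanges::start(onchrom)
  gend <- GenomicRanges::end(onchrom)
  gid <- mcols(onchrom)$gene_id
  inside <- gstart <= hi & gend >= lo
  rows <- list()
  if (any(inside))
    rows$inside <- data.frame(locus = locus, gene = gid[inside],
                              side = "inside", tss_distance = 0,
                              rank = NA_integer_)
  left <- !inside & tss < lo
  if (any(left)) {
    d <- lo - tss
    j <- which(left)[order(d[left], gstart[left], gid[left])][1]
    if (d[j] <= windowKb * 1000)
      rows$up <- data.frame(locus = locus, gene = gid[j], side = "upstream",
                            tss_distance = d[j], rank = 1L)
  }
  right <- !inside & tss > hi
  if (any(right)) {
    d <- tss - hi
    j <- which(right)[order(d[right], gstart[right], gid[right])][1]
    if (d[j] <= windowKb * 1000)
      rows$down <- data.frame(locus = locus, gene = gid[j],
                              side = "downstream", tss_distance = d[j],
                              rank = 1L)
  }
  if (!length(rows))
    return(data.frame(locus = character(0), gene = character(0),
                      side = character(0), tss_distance = numeric(0),
                      rank = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate annotation for a table of hotspot calls
#'
#' Dispatches [annotateHotSnp()] for single-position tiers (hot SNPs and hot
#' top SNPs) and [annotateHotspot()] for windowed hotspots, using the top-SNP
#' positions inside each window as the member SNPs.
#'
#' @param calls hotspot call data.frame from the detectors.
#' @param panel gene annotation `GRanges`.
#' @param topSnps top-SNP table (needed for windowed hotspots).
#' @param maxPerSide,windowKb see [annotateHotSnp()].
#' @return combined candidate data.frame.
#' @export
annotateCalls <- function(calls, panel, topSnps = NULL, maxPerSide = 3,
                          windowKb = 125) {
  out <- lapply(seq_len(nrow(calls)), function(i) {
    if (calls$tier[i] == "window_hotspot") {
      if (is.null(topSnps)) stop("topSnps required for window hotspots")
      member <- topSnps$pos[topSnps$chrom == calls$chrom[i] &
                            topSnps$tissue == calls$tissue[i] &
                            topSnps$pos >= calls$start[i] &
                            topSnps$pos < calls$end[i]]
      annotateHotspot(calls$chrom[i], member, panel, windowKb)
    } else {
      annotateHotSnp(calls$chrom[i], calls$start[i], panel, maxPerSide,
                     windowKb)
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(locus = character(0), gene = character(0),
                      side = character(0), tss_distance = numeric(0),
                      rank = integer(0))
  out
}
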