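.emptyCalls <- function(tier) {
  data.frame(tier = character(0), snp = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), tissue = character(0),
             n_genes = integer(0), genes = character(0))
}

.makeCalls <- function(tier, split, chrom, start, end, snp = NA_character_) {
  genes <- vapply(split, function(df)
    paste(sort(unique(df$gene)), collapse = ";"), "")
  data.frame(tier = tier, snp = snp, chrom = chrom, start = start, end = end,
             tissue = vapply(split, function(df) df$tissue[1], ""),
             n_genes = vapply(split, function(df)
               length(unique(df$gene)), integer(1)),
             genes = genes, row.names = NULL)
}

#' Detect hot SNPs
#'
#' A hot SNP is a single trans-acting SNP associated (p <= `pMax`) with the
#' expression of at least `minGenes` distinct panel genes in one tissue.
#'
#' @param transAssoc classified trans association table.
#' @param pMax association p-value cutoff (default 1e-4).
#' @param minGenes minimum number of distinct affected genes (default 8).
#' @return data.frame of calls: `tier`, `snp`, `chrom`, `start`, `end`
#'   (start = end = SNP position), `tissue`, `n_genes`, `genes`
#'   (semicolon-delimited, sorted).
#' @export
detectHotSnps <- function(transAssoc, pMax = 1e-4, minGenes = 8) {
  a <- transAssoc[transAssoc$p_value <= pMax, , drop = FALSE]
  if (!nrow(a)) return(.emptyCalls("hot_snp"))
  sp <- split(a, paste(a$snp, a$tissue, sep = "\r"), drop = TRUE)
  ng <- vapply(sp, function(df) length(unique(df$gene)), integer(1))
  sp <- sp[ng >= minGenes]
  if (!length(sp)) return(.emptyCalls("hot_snp"))
  out <- .makeCalls("hot_snp", sp,
                    chrom = vapply(sp, function(df) df$chrom[1], ""),
                    start = vapply(sp, function(df) df$pos[1], 0),
                    end = vapply(sp, function(df) df$pos[1], 0),
                    snp = vapply(sp, function(df) df$snp[1], ""))
  out <- out[order(out$tissue, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Detect hot top SNPs
#'
#' A hot top SNP is a single position that is the per-window top SNP (see
#' [selectTopSnps()]) for at least `minGenes` distinct genes in one tissue.
#' Counting is per tissue: being the top SNP of 5 genes in one tissue and 3
#' in another makes no call in either.
#'
#' @param topSnps table from [selectTopSnps()].
#' @param minGenes minimum distinct-gene count (default 8).
#' @return data.frame of calls as in [detectHotSnps()], tier `hot_top_snp`.
#' @export
detectHotTopSnps <- function(topSnps, minGenes = 8) {
  if (!nrow(topSnps)) return(.emptyCalls("hot_top_snp"))
  sp <- split(topSnps, paste(topSnps$snp, topSnps$tissue, sep = "\r"),
              drop = TRUE)
  ng <- vapply(sp, function(df) length(unique(df$gene)), integer(1))
  sp <- sp[ng >= minGenes]
  if (!length(sp)) return(.emptyCalls("hot_top_snp"))
  out <- .makeCalls("hot_top_snp", sp,
                    chrom = vapply(sp, function(df) df$chrom[1], ""),
                    start = vapply(sp, function(df) df$pos[1], 0),
                    end = vapply(sp, function(df) df$pos[1], 0),
                    snp = vapply(sp, function(df) df$snp[1], ""))
  out <- out[order(out$tissue, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Detect windowed trans-eQTL hotspots
#'
#' The genome is tiled into exclusive half-open windows (default 40 kb)
#' anchored at coordinate 0; a window is a hotspot if it contains top SNPs
#' for at least `minGenes` distinct genes in one tissue.
#'
#' @param topSnps table from [selectTopSnps()].
#' @param windowKb hotspot window size in kb (default 40).
#' @param minGenes minimum distinct-gene count (default 8).
#' @param chromLengths optional chromosome lengths; when given, the total
#'   genome window count is attached as attribute `"n_windows"`.
#' @return data.frame of calls, tier `window_hotspot`, with `start`/`end`
#'   the half-open window bounds.
#' @export
detectHotspotWindows <- function(topSnps, windowKb = 40, minGenes = 8,
                                 chromLengths = NULL) {
  if (!nrow(topSnps)) {
    out <- .emptyCalls("window_hotspot")
  } else {
    w <- windowIndex(topSnps$pos, windowKb)
    sp <- split(topSnps, paste(topSnps$chrom, w, topSnps$tissue, sep = "\r"),
                drop = TRUE)
    ng <- vapply(sp, function(df) length(unique(df$gene)), integer(1))
    sp <- sp[ng >= minGenes]
    if (!length(sp)) {
      out <- .emptyCalls("window_hotspot")
    } else {
      ws <- vapply(sp, function(df)
        windowIndex(df$pos[1], windowKb) * windowKb * 1000, 0)
      out <- .makeCalls("window_hotspot", sp,
                        chrom = vapply(sp, function(df) df$chrom[1], ""),
                        start = ws, end = ws + windowKb * 1000)
      out <- out[order(out$tissue, out$chrom, out$start), ]
      rownames(out) <- NULL
    }
  }
  if (!is.null(chromLengths))
    attr(out, "n_windows") <- genomeWindowCount(chromLengths, windowKb)
  out
}

#' Signed effect matrix and concordance for hotspot calls
#'
#' Builds a calls x genes matrix of association effects (beta where p <=
#' `pMax`, else 0), flags each call as concordant when all its nonzero
#' entries share one sign, and orders rows by agglomerative hierarchical
#' clustering (Ward linkage, `hclust` method `ward.D2`) on Euclidean
#' distances between effect profiles.
#'
#' @param calls hotspot calls (any tier) from the detectors.
#' @param associations association table the calls were derived from.
#' @param pMax significance cutoff for including an effect (default 1e-4).
#' @return list with `effects` (matrix), `concordant` (logical per call),
#'   `divergent_genes` (list of gene ids opposing the majority sign per
#'   call), and `order` (dendrogram row order).
#' @export
effectDirectionMatrix <- function(calls, associations, pMax = 1e-4) {
  if (!nrow(calls)) stop("no hotspot calls supplied")
  genes <- sort(unique(unlist(strsplit(calls$genes, ";", fixed = TRUE))))
  eff <- matrix(0, nrow(calls), length(genes),
                dimnames = list(.callId(calls), genes))
  a <- associations[associations$p_value <= pMax, , drop = FALSE]
  for (i in seq_len(nrow(calls))) {
    sel <- a$tissue == calls$tissue[i] & a$chrom == calls$chrom[i] &
      (if (!is.na(calls$snp[i])) a$snp == calls$snp[i]
       else a$pos >= calls$start[i] & a$pos < calls$end[i])
    ai <- a[sel & a$gene %in% strsplit(calls$genes[i], ";")[[1]], ]
    if (nrow(ai)) {
      # per gene keep the strongest (smallest-p) effect in the locus
      ai <- ai[order(ai$p_value), ]
      ai <- ai[!duplicated(ai$gene), ]
      eff[i, ai$gene] <- ai$beta
    }
  }
  signs <- sign(eff)
  concordant <- apply(signs, 1, function(s) {
    s <- s[s != 0]
    length(s) == 0 || all(s == s[1])
  })
  divergent <- lapply(seq_len(nrow(eff)), function(i) {
    s <- signs[i, ]
    nz <- s[s != 0]
    if (!length(nz)) return(character(0))
    maj <- sign(sum(nz))
    if (maj == 0) return(names(nz))
    names(nz)[nz != maj]
  })
  ord <- if (nrow(eff) > 1)
    stats::hclust(stats::dist(eff), method = "ward.D2")$order
  else 1L
  list(effects = eff, concordant = concordant,
       divergent_genes = divergent, order = ord)
}

.callId <- function(calls)
  ifelse(!is.na(calls$snp), paste(calls$snp, calls$tissue, sep = "|"),
         paste0(calls$chrom, ":", calls$start, "-", calls$end, "|",
                calls$tissue))

#' Tabulate divergent regulation of a focal gene within hotspots
#'
#' For every SNP residing in a hotspot window that affects the focal gene and
#' at least `minOther` other genes at p <= `pMax` (in the same tissue),
#' reports whether the focal-gene effect sign opposes the majority sign of
#' the other affected genes. SNPs whose other-gene signs tie are reported
#' with `divergent = NA` and excluded from the summary fraction.
#'
#' @param hotspots window-hotspot calls from [detectHotspotWindows()].
#' @param associations trans association table.
#' @param focalGene focal gene id (must occur in `associations`).
#' @param minOther minimum number of other affected genes (default 2).
#' @param pMax association cutoff (default 1e-4).
#' @return list with `table` (per-SNP rows: snp, tissue, focal_beta,
#'   n_other, majority_sign, divergent) and `summary` (per-tissue divergent
#'   count, total and fraction).
#' @export
divergenceTabulation <- function(hotspots, associations, focalGene,
                                 minOther = 2, pMax = 1e-4) {
  if (!focalGene %in% associations$gene)
    stop("focal gene absent from associations: ", focalGene)
  a <- associations[associations$p_value <= pMax, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(hotspots))) {
    sel <- a$tissue == hotspots$tissue[i] & a$chrom == hotspots$chrom[i] &
      a$pos >= hotspots$start[i] & a$pos < hotspots$end[i]
    ai <- a[sel, , drop = FALSE]
    for (s in unique(ai$snp[ai$gene == focalGene])) {
      asnp <- ai[ai$snp == s, ]
      others <- asnp[asnp$gene != focalGene, ]
      if (length(unique(others$gene)) < minOther) next
      focalBeta <- asnp$beta[asnp$gene == focalGene][1]
      osign <- sign(others$beta[!duplicated(others$gene)])
      maj <- sign(sum(osign))
      rows[[length(rows) + 1]] <- data.frame(
        snp = s, tissue = hotspots$tissue[i], focal_beta = focalBeta,
        n_other = length(unique(others$gene)), majority_sign = maj,
        divergent = if (maj == 0) NA else sign(focalBeta) != maj)
    }
  }
  tab <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(snp = character(0), tissue = character(0),
               focal_beta = numeric(0), n_other = integer(0),
               majority_sign = numeric(0), divergent = logical(0))
  sm <- if (nrow(tab)) {
    sp <- split(tab, tab$tissue)
    do.call(rbind, lapply(sp, function(df) {
      ok <- !is.na(df$divergent)
      data.frame(tissue = df$tissue[1], n_divergent = sum(df$divergent[ok]),
                 n_total = sum(ok),
                 fraction = if (sum(ok)) sum(df$divergent[ok]) / sum(ok)
                            else NA_real_)
    }))
  } else data.frame(tissue = character(0), n_divergent = integer(0),
                    n_total = integer(0), fraction = numeric(0))
  rownames(sm) <- NULL
  list(table = tab, summary = sm)
}

#' Export hotspot calls as TSV or BED
#'
#' @param calls hotspot call data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHotspotTsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeHotspotTsv
#' @export
writeHotspotBed <- function(calls, path) {
  if (!nrow(calls)) { writeLines(character(0), path); return(invisible(path)) }
  gr <- GRanges(calls$chrom,
                IRanges(pmax(calls$start, 1), pmax(calls$end, calls$start)))
  mcols(gr)$name <- paste0(calls$tier, "|", calls$tissue, "|", calls$n_genes)
  mcols(gr)$score <- calls$n_genes
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
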