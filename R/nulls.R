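# Log-space upper tail P(X >= m) for X ~ Binomial(n, p), accumulated with
# logsumexp so tail probabilities near 1e-23 do not underflow.
.binomTail <- function(m, n, p) {
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  if (m <= 0) return(1)
  if (m > n) return(0)
  k <- m:n
  lg <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  mx <- max(lg)
  exp(mx + log(sum(exp(lg - mx))))
}

#' Analytic binomial expectation for hotspot-containing windows
#'
#' Under the null that each gene's top SNPs land in genomic windows
#' independently and uniformly, the chance a given window holds a top SNP of
#' a given gene is `p = (nTopSnps / nGenes) / nWindows` (the per-gene top-SNP
#' rate spread over the windows). The chance a window holds top SNPs for at
#' least `minGenes` of the `nGenes` genes is the Binomial(`nGenes`, p) upper
#' tail, and the expected number of hotspot-containing windows is `nWindows`
#' times that tail. The tail is accumulated in log space.
#'
#' @param nTopSnps total top-SNP count over all genes (e.g. 48,734 for one
#'   tissue of the motivating study).
#' @param nGenes panel size (default 70).
#' @param nWindows number of exclusive windows (default 62,500, a 2.5 Gb
#'   genome in 40 kb tiles).
#' @param minGenes hotspot gene threshold (default 8).
#' @param perWindowProb optional explicit per-window probability; overrides
#'   the value derived from `nTopSnps` (useful to reproduce reported
#'   arithmetic carried out on a rounded rate).
#' @return list with `per_window_prob`, `tail_prob`, `expected_windows`,
#'   and `top_snps_per_gene`.
#' @examples
#' binomialHotspotExpectation(48734)$per_window_prob  # ~0.0111
#' @export
binomialHotspotExpectation <- function(nTopSnps, nGenes = 70,
                                       nWindows = 62500, minGenes = 8,
                                       perWindowProb = NULL) {
  stopifnot(nGenes >= 1, nWindows >= 1, minGenes <= nGenes)
  perGene <- nTopSnps / nGenes
  p <- if (is.null(perWindowProb)) perGene / nWindows else perWindowProb
  if (p > 1) stop("per-window probability exceeds 1")
  tail <- .binomTail(minGenes, nGenes, p)
  list(per_window_prob = p, tail_prob = tail,
       expected_windows = nWindows * tail, top_snps_per_gene = perGene)
}

#' Permutation null for windowed hotspot counts
#'
#' Re-creates the permutation scheme used to attach an FDR to observed
#' hotspot counts: per permutation, every tallied association is assigned
#' independently and uniformly to one of `nWindows` bins, and a bin is a
#' null hotspot if it collects at least `minGenes` associations
#' (`countMode = "associations"`, the literal tally criterion) or
#' associations from at least `minGenes` distinct genes
#' (`countMode = "genes"`, the stricter criterion matching the real hotspot
#' definition). The FDR is the mean null hotspot count per permutation
#' divided by the observed count.
#'
#' @param tallies per-gene association (top SNP) counts, length = panel size.
#' @param observed observed hotspot count; 0 gives `fdr = NA`.
#' @param nWindows number of bins (default 62,500).
#' @param minGenes hotspot threshold (default 8).
#' @param nPermutations number of permuted data sets (default 1000).
#' @param seed integer seed.
#' @param countMode `"associations"` or `"genes"`.
#' @return list with `null_mean_per_perm`, `null_counts` (per permutation),
#'   and `fdr`.
#' @examples
#' permutationFdr(rep(3, 70), observed = 10, nWindows = 500,
#'                nPermutations = 20, seed = 1)$null_mean_per_perm
#' @export
permutationFdr <- function(tallies, observed, nWindows = 62500,
                           minGenes = 8, nPermutations = 1000, seed = 1L,
                           countMode = c("associations", "genes")) {
  countMode <- match.arg(countMode)
  if (any(tallies < 0)) stop("negative tallies")
  stopifnot(observed >= 0, nPermutations >= 1)
  set.seed(seed)
  total <- sum(tallies)
  counts <- numeric(nPermutations)
  if (total > 0) {
    geneOf <- rep.int(seq_along(tallies), tallies)
    for (i in seq_len(nPermutations)) {
      bins <- sample.int(nWindows, total, replace = TRUE)
      if (countMode == "associations") {
        counts[i] <- sum(tabulate(bins, nWindows) >= minGenes)
      } else {
        key <- !duplicated(bins * (length(tallies) + 1) + geneOf)
        counts[i] <- sum(tabulate(bins[key], nWindows) >= minGenes)
      }
    }
  }
  nullMean <- mean(counts)
  list(null_mean_per_perm = nullMean, null_counts = counts,
       fdr = hotspotFdr(nullMean, observed))
}

#' FDR from a permutation null mean and an observed count
#'
#' @param nullMean mean null hotspot count per permutation.
#' @param observed observed hotspot count.
#' @return `nullMean / observed`, or `NA` when `observed` is 0.
#' @examples
#' hotspotFdr(0.092, 195)  # ~4.7e-4
#' @export
hotspotFdr <- function(nullMean, observed) {
  if (observed == 0) return(NA_real_)
  nullMean / observed
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (0 < alpha <= 1).
#' @param nTests number of tests (>= 1).
#' @return `alpha / nTests`.
#' @examples
#' bonferroniThreshold(0.05, 2.4e7)  # ~2.1e-9
#' @export
bonferroniThreshold <- function(alpha, nTests) {
  if (nTests < 1) stop("nTests must be >= 1")
  stopifnot(alpha > 0, alpha <= 1)
  alpha / nTests
}

#' Expected-hit FDR for hotspot-phenotype overlap
#'
#' Expected chance overlaps between hotspot-resident SNPs and phenotype
#' associations are `nHotspotSnps * nTraits * pThreshold`; the FDR is this
#' expectation over the observed hit count.
#'
#' @param nHotspotSnps number of SNPs residing in hotspots.
#' @param nTraits number of phenotypic traits tested (e.g. 8 CCM traits).
#' @param pThreshold per-test significance cutoff.
#' @param observedHits observed number of SNP-trait associations at the
#'   cutoff; 0 gives `fdr = NA`.
#' @return list with `expected_hits` and `fdr`.
#' @examples
#' overlapFdr(1000, 8, 1e-4, observedHits = 2)$fdr  # 0.4
#' @export
overlapFdr <- function(nHotspotSnps, nTraits, pThreshold, observedHits) {
  stopifnot(nHotspotSnps >= 0, nTraits >= 0, observedHits >= 0)
  expected <- nHotspotSnps * nTraits * pThreshold
  list(expected_hits = expected,
       fdr = if (observedHits == 0) NA_real_ else expected / observedHits)
}
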