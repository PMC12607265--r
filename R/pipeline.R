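#' Assemble a pipeline configuration
#'
#' One object holds every tunable of the full analysis. Exactly one of
#' `sim` (a [SimConfig-class], simulate-mode) or `inputs` (named list of file
#' paths: `genotypes`, `expression` [named by tissue], `annotation`,
#' `phenotypes`) must be supplied. Every analysis constant appears here once,
#' with the field-standard defaults: 50 kb cis, 1 Mb trans, 250 kb top-SNP
#' windows, 40 kb hotspot windows, 125 kb candidate windows, p <= 1e-4,
#' 8 genes, MAF 0.05, 1000 permutations.
#'
#' @param sim optional [SimConfig-class] for simulate mode.
#' @param inputs optional named list of input file paths.
#' @param tissues tissue labels to analyse.
#' @param scan a [scanConfig()].
#' @param cisKb,transMb,topsnpWindowKb,hotspotWindowKb,minGenes
#'   classification and hotspot thresholds.
#' @param candidateWindowKb,maxPerSide candidate annotation parameters.
#' @param nPermutations,countMode permutation-null parameters.
#' @param indexGeneSet optional character vector of gene ids for the pathway
#'   expression index; default: panel genes labelled `chlorophyll`.
#' @param nPhenotypeTraits number of phenotype traits for the overlap FDR.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sim = NULL, inputs = NULL,
                           tissues = c("L3Base", "LMAD"),
                           scan = scanConfig(),
                           cisKb = 50, transMb = 1, topsnpWindowKb = 250,
                           hotspotWindowKb = 40, minGenes = 8,
                           candidateWindowKb = 125, maxPerSide = 3,
                           nPermutations = 1000,
                           countMode = "associations",
                           indexGeneSet = NULL, nPhenotypeTraits = 8) {
  if (is.null(sim) == is.null(inputs))
    stop("exactly one of 'sim' or 'inputs' must be given")
  stopifnot(cisKb > 0, transMb > 0, topsnpWindowKb > 0, hotspotWindowKb > 0,
            minGenes > 0, candidateWindowKb > 0)
  structure(list(sim = sim, inputs = inputs, tissues = tissues, scan = scan,
                 cisKb = cisKb, transMb = transMb,
                 topsnpWindowKb = topsnpWindowKb,
                 hotspotWindowKb = hotspotWindowKb, minGenes = minGenes,
                 candidateWindowKb = candidateWindowKb,
                 maxPerSide = maxPerSide, nPermutations = nPermutations,
                 countMode = countMode, indexGeneSet = indexGeneSet,
                 nPhenotypeTraits = nPhenotypeTraits),
            class = "PipelineConfig")
}

#' Run the full hotspot analysis
#'
#' Orchestrates: simulate (or load) -> MAF filter -> per-tissue eGWAS scan ->
#' cis/trans classification -> top SNPs -> three hotspot tiers -> analytic
#' and permutation nulls -> pathway index GWAS -> candidate annotation ->
#' hotspot-phenotype overlap. Stage outputs are written as TSV under
#' `outDir` with a manifest (stage, file, md5) and a JSON summary of counts
#' per tier, null expectations, FDRs and index GWAS hits. Identical
#' configurations give byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if absent).
#' @return invisibly, a list with the summary and the in-memory stage
#'   results.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(sim = simConfig(nLines = 60, nSnps = 120,
#'                                       nPanelGenes = 12, seed = 4),
#'                       tissues = "L3Base", nPermutations = 50)
#' res <- runPipeline(cfg, file.path(tempdir(), "teqhot-demo"))
#' res$summary$n_hot_snps
#' }
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(writer, x, name) {
    p <- file.path(outDir, name)
    writer(x, p)
    files <<- c(files, p)
    p
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$sim)) {
    genotypes <- simulateGenotypes(config$sim)
    panel <- simulateGenePanel(config$sim)
    expression <- lapply(stats::setNames(config$tissues, config$tissues),
                         function(tt) simulateExpression(genotypes, panel,
                                                         config$sim, tt))
    phenotypes <- if (length(config$sim@regulators))
      simulatePhenotypes(genotypes,
                         focalSnp = config$sim@regulators[[1]]$snp,
                         mutantEffect = 2, seed = config$sim@seed)
    else NULL
    put(writeDosageTsv, genotypes, "genotypes.tsv")
    put(writePanelGff3, panel, "panel.gff3")
    for (tt in config$tissues)
      put(writeExpressionTsv, expression[[tt]],
          paste0("expression_", tt, ".tsv"))
    if (!is.null(phenotypes))
      put(writeTableTsv, phenotypes, "phenotypes.tsv")
  } else {
    inp <- config$inputs
    genotypes <- if (grepl("\\.vcf$", inp$genotypes))
      readGenotypeVcf(inp$genotypes) else readDosageTsv(inp$genotypes)
    panel <- readPanel(inp$annotation)
    expression <- lapply(stats::setNames(config$tissues, config$tissues),
                         function(tt) readExpressionTsv(inp$expression[[tt]]))
    phenotypes <- if (!is.null(inp$phenotypes))
      readTableTsv(inp$phenotypes) else NULL
  }

  # --- scan + classify ------------------------------------------------
  genotypes <- recodeAndFilter(genotypes, config$scan$mafMin)
  summary <- list(n_lines = nLines(genotypes), n_snps = nSnps(genotypes),
                  n_genes = length(panel))
  chromLengths <- seqlengths(snpMap(genotypes))
  if (anyNA(chromLengths))
    chromLengths <- tapply(GenomicRanges::start(snpMap(genotypes)),
                           as.character(GenomicRanges::seqnames(
                             snpMap(genotypes))), max)
  nWindows <- genomeWindowCount(chromLengths, config$hotspotWindowKb)
  summary$n_windows <- nWindows

  assoc <- do.call(rbind, lapply(config$tissues, function(tt)
    scanPanel(genotypes, expression[[tt]], tt, config$scan)))
  assoc <- classifyCisTrans(assoc, panel, config$cisKb, config$transMb)
  put(function(x, p) writeAssociationTsv(x, p), assoc, "associations.tsv")
  summary$n_associations <- nrow(assoc)
  summary$n_cis <- sum(assoc$class == "cis")
  summary$n_trans <- sum(assoc$class == "trans")

  trans <- assoc[assoc$class == "trans", ]
  topSnps <- selectTopSnps(trans, config$topsnpWindowKb)
  put(writeTableTsv, topSnps, "top_snps.tsv")

  hotSnps <- detectHotSnps(trans, config$scan$pReportMax, config$minGenes)
  hotTop <- detectHotTopSnps(topSnps, config$minGenes)
  hotWin <- detectHotspotWindows(topSnps, config$hotspotWindowKb,
                                 config$minGenes, chromLengths)
  calls <- rbind(hotSnps, hotTop, hotWin)
  put(writeHotspotTsv, calls, "hotspot_calls.tsv")
  put(writeHotspotBed, calls, "hotspot_calls.bed")
  summary$n_hot_snps <- nrow(hotSnps)
  summary$n_hot_top_snps <- nrow(hotTop)
  summary$n_window_hotspots <- nrow(hotWin)

  # --- nulls ----------------------------------------------------------
  seed <- if (!is.null(config$sim)) config$sim@seed else 1L
  summary$null <- lapply(stats::setNames(config$tissues, config$tissues),
                         function(tt) {
    tsT <- topSnps[topSnps$tissue == tt, ]
    expct <- binomialHotspotExpectation(nrow(tsT), length(panel), nWindows,
                                        config$minGenes)
    tallies <- table(factor(tsT$gene, mcols(panel)$gene_id))
    obs <- sum(hotWin$tissue == tt)
    perm <- permutationFdr(as.numeric(tallies), obs, nWindows,
                           config$minGenes, config$nPermutations,
                           seed = seed, countMode = config$countMode)
    list(n_top_snps = nrow(tsT),
         per_window_prob = expct$per_window_prob,
         tail_prob = expct$tail_prob,
         expected_windows = expct$expected_windows,
         null_mean_per_perm = perm$null_mean_per_perm,
         permutation_fdr = perm$fdr)
  })

  # --- pathway index GWAS --------------------------------------------
  idxSet <- config$indexGeneSet
  if (is.null(idxSet))
    idxSet <- mcols(panel)$gene_id[mcols(panel)$branch == "chlorophyll"]
  summary$index_gwas <- lapply(stats::setNames(config$tissues,
                                               config$tissues),
                               function(tt) {
    z <- suppressWarnings(zscoreMatrix(expression[[tt]]))
    idx <- expressionIndex(z, idxSet, "pathway_index")
    sc <- scanGene(genotypes, idx$index[match(lineIds(genotypes),
                                              idx$sample)],
                   config$scan$covariates, trait = "pathway_index")
    hits <- sc[sc$p_value <= config$scan$pReportMax, ]
    put(writeTableTsv, hits,
        paste0("index_gwas_hits_", tt, ".tsv"))
    list(n_hits = nrow(hits),
         min_p = if (nrow(sc)) min(sc$p_value) else NA_real_,
         top_snp = if (nrow(sc)) sc$snp[which.min(sc$p_value)]
                   else NA_character_)
  })

  # --- candidates -----------------------------------------------------
  cand <- annotateCalls(calls, panel, topSnps, config$maxPerSide,
                        config$candidateWindowKb)
  put(writeTableTsv, cand, "candidates.tsv")
  summary$n_candidates <- nrow(cand)

  # --- phenotype overlap ---------------------------------------------
  if (!is.null(phenotypes)) {
    ph <- deriveCcmTraits(phenotypes)
    traits <- intersect(c("MT_CCMI", "WT_CCMI", "MT_CCMII", "WT_CCMII",
                          "Ratio_CCMI", "Diff_CCMI", "Ratio_CCMII",
                          "Diff_CCMII"), names(ph))
    hotspotSnps <- unique(trans$snp[vapply(seq_len(nrow(trans)), function(i)
      any(trans$chrom[i] == hotWin$chrom & trans$pos[i] >= hotWin$start &
          trans$pos[i] < hotWin$end), logical(1))])
    if (length(hotspotSnps)) {
      sub <- genotypes[, match(hotspotSnps, colnames(dosage(genotypes)))]
      hits <- 0
      for (tr in traits) {
        y <- ph[[tr]][match(lineIds(sub), ph$line)]
        ok <- !is.na(y)
        sc <- scanGene(sub[which(ok), ], y[ok], trait = tr)
        hits <- hits + sum(sc$p_value <= config$scan$pReportMax)
      }
      ov <- overlapFdr(length(hotspotSnps), length(traits),
                       config$scan$pReportMax, hits)
      summary$overlap <- list(n_hotspot_snps = length(hotspotSnps),
                              n_traits = length(traits),
                              observed_hits = hits,
                              expected_hits = ov$expected_hits,
                              fdr = ov$fdr)
    }
  }

  # --- manifest + summary --------------------------------------------
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- data.frame(file = basename(c(files,
                                           file.path(outDir, "summary.json"))),
                         md5 = unname(tools::md5sum(
                           c(files, file.path(outDir, "summary.json")))))
  writeTableTsv(manifest, file.path(outDir, "manifest.tsv"))
  invisible(list(summary = summary, genotypes = genotypes, panel = panel,
                 associations = assoc, topSnps = topSnps, calls = calls,
                 candidates = cand))
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipelineConfig()]'s arguments; a `sim:` block is passed
#' to [simConfig()] and a `scan:` block to [scanConfig()].
#'
#' @param path YAML file path.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(simConfig, y$sim)
  if (!is.null(y$scan)) y$scan <- do.call(scanConfig, y$scan)
  do.call(pipelineConfig, y)
}
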