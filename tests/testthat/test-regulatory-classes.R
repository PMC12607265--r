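panel1 <- local({
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(100000, 105000),
                               strand = "+", gene_id = "g1",
                               branch = "porphyrin", tss = 100000)
  names(gr) <- "g1"
  gr
})

test_that("cis/trans/proximal classification follows the distance rules", {
  a <- rbind(assocRow("1", 60000, "g1"),      # 40 kb -> cis
             assocRow("1", 1200000, "g1"),    # 1.095 Mb -> trans
             assocRow("1", 500000, "g1"),     # 395 kb -> proximal-excluded
             assocRow("2", 500, "g1"))        # other chromosome -> trans
  cl <- classifyCisTrans(a, panel1)
  expect_equal(as.character(cl$class),
               c("cis", "trans", "proximal-excluded", "trans"))
  expect_equal(cl$distance, c(40000, 1095000, 395000, NA))
  # inside the gene body -> distance 0, cis
  ins <- classifyCisTrans(assocRow("1", 102000, "g1"), panel1)
  expect_equal(ins$distance, 0)
  expect_equal(as.character(ins$class), "cis")
  expect_error(classifyCisTrans(assocRow("1", 1, "unknown"), panel1),
               "unknown")
})

test_that("the three classes partition every record", {
  set.seed(8)
  pos <- sample.int(5e6, 200)
  a <- do.call(rbind, lapply(pos, function(p)
    assocRow(sample(c("1", "2"), 1), p, "g1")))
  cl <- classifyCisTrans(a, panel1)
  expect_false(anyNA(cl$class))
  expect_identical(nrow(cl), 200L)
  tab <- table(cl$class)
  expect_identical(sum(tab), 200L)
})

test_that("top-SNP selection keeps the per-window minimum with stable ties", {
  a <- rbind(assocRow("1", 10000, "gA", p = 1e-5),
             assocRow("1", 20000, "gA", p = 1e-6))
  expect_identical(selectTopSnps(a)$pos, 20000)
  tie <- rbind(assocRow("1", 10000, "gA", p = 1e-6),
               assocRow("1", 20000, "gA", p = 1e-6))
  expect_identical(selectTopSnps(tie)$pos, 10000)
  # 240 kb and 260 kb fall in different 250 kb tiles: both kept
  twoTiles <- rbind(assocRow("1", 240000, "gA", p = 1e-5),
                    assocRow("1", 260000, "gA", p = 1e-6))
  expect_identical(sort(selectTopSnps(twoTiles)$pos), c(240000, 260000))
  # per (gene, tissue): different genes in one window each keep a record
  two <- rbind(assocRow("1", 10000, "gA"), assocRow("1", 20000, "gB"))
  expect_identical(nrow(selectTopSnps(two)), 2L)
  # exhaustive small-instance check: each survivor has the window minimum p
  set.seed(5)
  rnd <- do.call(rbind, lapply(1:100, function(i)
    assocRow("1", sample.int(1e6, 1), sample(c("gA", "gB"), 1),
             p = runif(1))))
  ts <- selectTopSnps(rnd)
  w <- windowIndex(rnd$pos, 250)
  for (i in seq_len(nrow(ts))) {
    grp <- rnd[rnd$gene == ts$gene[i] & w == ts$window_index[i], ]
    expect_equal(ts$p_value[i], min(grp$p_value))
  }
})

test_that("hot SNP calls require >= minGenes distinct genes at the cutoff", {
  eight <- do.call(rbind, lapply(sprintf("g%02d", 1:8), function(g)
    assocRow("1", 5000, g, p = 5e-5)))
  expect_identical(nrow(detectHotSnps(eight)), 1L)
  expect_identical(detectHotSnps(eight)$n_genes, 8L)
  seven <- rbind(eight[1:7, ], assocRow("1", 5000, "g08", p = 2e-4))
  expect_identical(nrow(detectHotSnps(seven)), 0L)
  # duplicate associations to one gene do not inflate the count
  dup <- rbind(eight[1:7, ], eight[7, ])
  expect_identical(nrow(detectHotSnps(dup)), 0L)
})

test_that("hot top SNP counting is per tissue", {
  ts <- rbind(do.call(rbind, lapply(sprintf("g%02d", 1:5), function(g)
                assocRow("1", 5000, g, tissue = "L3Base"))),
              do.call(rbind, lapply(sprintf("g%02d", 6:8), function(g)
                assocRow("1", 5000, g, tissue = "LMAD"))))
  ts$window_index <- windowIndex(ts$pos, 250)
  expect_identical(nrow(detectHotTopSnps(ts)), 0L)
  same <- do.call(rbind, lapply(sprintf("g%02d", 1:8), function(g)
    assocRow("1", 5000, g)))
  same$window_index <- 0L
  expect_identical(nrow(detectHotTopSnps(same)), 1L)
})

test_that("hot top SNPs are a subset of hot SNPs on the same data", {
  set.seed(13)
  for (rep in 1:5) {
    a <- do.call(rbind, lapply(1:300, function(i)
      assocRow("1", sample.int(2e6, 1), sprintf("g%02d", sample.int(12, 1)),
               p = 10^runif(1, -8, -4))))
    hot <- detectHotSnps(a, minGenes = 3)
    ts <- selectTopSnps(a)
    htop <- detectHotTopSnps(ts, minGenes = 3)
    expect_true(all(htop$snp %in% hot$snp))
  }
})

test_that("window hotspots respect tiling and report the genome window count", {
  inWin <- do.call(rbind, lapply(1:8, function(i)
    assocRow("1", 5000 + (i - 1) * 4000, sprintf("g%02d", i))))
  inWin$window_index <- windowIndex(inWin$pos, 250)
  calls <- detectHotspotWindows(inWin, chromLengths = 2.5e9)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$start, 0)
  expect_identical(calls$end, 40000)
  expect_identical(attr(calls, "n_windows"), 62500)
  # 4 genes in [0,40k) and 4 in [40k,80k): no call
  split44 <- do.call(rbind, lapply(1:8, function(i)
    assocRow("1", if (i <= 4) 10000 + i else 50000 + i, sprintf("g%02d", i))))
  split44$window_index <- windowIndex(split44$pos, 250)
  expect_identical(nrow(detectHotspotWindows(split44)), 0L)
})

test_that("hotspot calls are invariant to row order and window-aligned shifts", {
  set.seed(17)
  a <- do.call(rbind, lapply(1:200, function(i)
    assocRow("1", sample.int(4e5, 1), sprintf("g%02d", sample.int(10, 1)),
             p = 10^runif(1, -7, -4))))
  ts <- selectTopSnps(a)
  ref <- detectHotspotWindows(ts, minGenes = 4)
  perm <- detectHotspotWindows(ts[sample.int(nrow(ts)), ], minGenes = 4)
  expect_equal(ref, perm)
  shifted <- ts
  shifted$pos <- shifted$pos + 3 * 40000
  shifted$snp <- paste0(shifted$chrom, "-", shifted$pos)
  sh <- detectHotspotWindows(shifted, minGenes = 4)
  expect_equal(sh$start, ref$start + 3 * 40000)
  expect_equal(sh$n_genes, ref$n_genes)
  expect_equal(sh$genes, ref$genes)
})

test_that("effect-direction matrix flags concordance and orders by clustering", {
  a <- rbind(assocRow("1", 5000, "g1", beta = 1),
             assocRow("1", 5000, "g2", beta = 2),
             assocRow("1", 5000, "g3", beta = 0.5),
             assocRow("1", 9000, "g1", beta = 1),
             assocRow("1", 9000, "g2", beta = 2),
             assocRow("1", 9000, "g3", beta = -0.5))
  calls <- detectHotSnps(a, minGenes = 3)
  em <- effectDirectionMatrix(calls, a)
  expect_identical(dim(em$effects), c(2L, 3L))
  expect_identical(unname(em$concordant), c(TRUE, FALSE))
  expect_identical(em$divergent_genes[[2]], "g3")
  # identical rows sit adjacent in the dendrogram order
  a2 <- rbind(a[1:3, ],
              within(a[1:3, ], { pos <- 7000; snp <- "1-7000" }),
              a[4:6, ])
  calls2 <- detectHotSnps(a2, minGenes = 3)
  em2 <- effectDirectionMatrix(calls2, a2)
  ids <- rownames(em2$effects)[em2$order]
  i1 <- which(ids == "1-5000|L3Base"); i2 <- which(ids == "1-7000|L3Base")
  expect_equal(abs(i1 - i2), 1L)
})

test_that("divergence tabulation isolates the focal gene's opposing sign", {
  mk <- function(focalBeta, tissue) rbind(
    assocRow("1", 5000, "cf1", beta = focalBeta, tissue = tissue),
    assocRow("1", 5000, "g2", beta = 1, tissue = tissue),
    assocRow("1", 5000, "g3", beta = 1, tissue = tissue))
  hs <- data.frame(tier = "window_hotspot", snp = NA, chrom = "1",
                   start = 0, end = 40000, tissue = c("LMAD", "L3Base"),
                   n_genes = 3L, genes = "cf1;g2;g3")
  a <- rbind(mk(-2, "LMAD"), mk(2, "L3Base"))
  dv <- divergenceTabulation(hs, a, "cf1")
  sm <- dv$summary[order(dv$summary$tissue), ]
  expect_equal(sm$fraction, c(0, 1))
  # a SNP affecting the focal gene and only one other is excluded
  small <- rbind(assocRow("1", 5000, "cf1", beta = -1),
                 assocRow("1", 5000, "g2", beta = 1))
  dv2 <- divergenceTabulation(hs[hs$tissue == "L3Base", ], small, "cf1")
  expect_identical(nrow(dv2$table), 0L)
  expect_error(divergenceTabulation(hs, a, "absent"), "absent")
})
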