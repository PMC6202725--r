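test_that("threshold curve matches hand-computed proportions on a toy track", {
  cov <- toyTrack(c(0, 0, 5, 5, 5, 12, 12, 12, 12, 12))
  region <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 10))
  curve <- thresholdCurve(cov, region, thresholds = c(1, 10, 100))
  expect_equal(curve$proportion, c(0.8, 0.5, 0.0))

  # uniform depth 8: step function at t = 8
  cov8 <- toyTrack(rep(8, 50))
  region <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 50))
  curve <- thresholdCurve(cov8, region)
  expect_equal(curve$proportion, ifelse(curve$threshold <= 8, 1, 0))

  expect_error(thresholdCurve(cov8, GenomicRanges::GRanges()), "empty")
})

test_that("threshold curve equals the per-base histogram complement on random tracks", {
  set.seed(11)
  for (rep in 1:3) {
    depths <- rnbinom(400, mu = 12, size = 3)
    cov <- toyTrack(depths)
    region <- GenomicRanges::GRanges("s1", IRanges::IRanges(21, 350))
    curve <- thresholdCurve(cov, region, thresholds = 1:100)
    d <- depths[21:350]
    oracle <- vapply(1:100, function(t) mean(d >= t), numeric(1))
    expect_equal(curve$proportion, oracle)
    # 1 - ECDF identity at t - 1
    expect_equal(curve$proportion, 1 - ecdf(d)(0:99))
    # monotone non-increasing
    expect_true(all(diff(curve$proportion) <= 0))
  }
})

test_that("gene mean coverage averages per-bp depth with missing bases as zero", {
  cov <- toyTrack(c(rep(0, 50), rep(20, 50)))
  gene <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 100),
                                 ID = "g1")
  expect_equal(unname(geneMeanCoverage(cov, gene)), 10)
  # fully uncovered gene
  gene0 <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 50), ID = "g0")
  expect_equal(unname(geneMeanCoverage(cov, gene0)), 0)
  # gene on a scaffold absent from the track
  geneX <- GenomicRanges::GRanges("s9", IRanges::IRanges(1, 50), ID = "gx")
  expect_equal(unname(geneMeanCoverage(cov, geneX)), 0)
  # three-step toy track against a per-base brute force
  depths <- c(rep(3, 10), rep(7, 25), rep(40, 15))
  covS <- toyTrack(depths)
  gene <- GenomicRanges::GRanges("s1", IRanges::IRanges(5, 45), ID = "g")
  expect_equal(unname(geneMeanCoverage(covS, gene)), mean(depths[5:45]))
})

test_that("library overlap intersects gene sets against the reference list", {
  sets <- rep(list(paste0("g", 1:100)), 8)
  ov <- libraryOverlap(sets, paste0("g", 1:100))
  expect_equal(ov$count, 100L)
  expect_equal(ov$percentage, 100)

  ov <- libraryOverlap(list(c("A", "B"), c("B", "C")), letters[1:4])
  expect_equal(ov$count, 1L)
  expect_equal(ov$percentage, 25)
})

test_that("flank coverage counts covered bp strand-aware with clipping", {
  # 100 bp scaffold, gene at 41-60 on +; upstream flank 21-40, downstream 61-80
  depths <- rep(0, 100)
  depths[21:40] <- 15       # upstream fully covered
  depths[61:70] <- 15       # downstream half covered
  cov <- toyTrack(depths)
  gene <- GenomicRanges::GRanges("s1", IRanges::IRanges(41, 60),
                                 strand = "+", ID = "g1")
  GenomeInfoDb::seqlengths(gene) <- c(s1 = 100)
  fc <- flankCoverage(cov, gene, flank = 20, minDepth = 10)
  expect_equal(fc$perGene$upstream_bp, 20L)
  expect_equal(fc$perGene$downstream_bp, 10L)

  # minus strand flips the orientation
  geneM <- gene
  GenomicRanges::strand(geneM) <- "-"
  fcM <- flankCoverage(cov, geneM, flank = 20, minDepth = 10)
  expect_equal(fcM$perGene$upstream_bp, 10L)
  expect_equal(fcM$perGene$downstream_bp, 20L)

  # fully uncovered flank
  geneFar <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 10),
                                    strand = "+", ID = "g2")
  GenomeInfoDb::seqlengths(geneFar) <- c(s1 = 100)
  fc0 <- flankCoverage(cov, geneFar, flank = 5, minDepth = 10)
  expect_equal(fc0$perGene$downstream_bp, 0L)

  # per-base brute force on a random step track
  set.seed(12)
  depths <- rnbinom(100, mu = 12, size = 2)
  covR <- toyTrack(depths)
  fcR <- flankCoverage(covR, gene, flank = 20, minDepth = 10)
  expect_equal(fcR$perGene$upstream_bp, sum(depths[21:40] >= 10))
  expect_equal(fcR$perGene$downstream_bp, sum(depths[61:80] >= 10))
})

test_that("the capture report ties the QC metrics together on simulated data", {
  sim <- simulateTbs(tinyConfig(nGenes = 4, scaffoldLength = 20000,
                                nGenets = 2))
  rep <- captureReport(sim$coverage, sim$genes, sim$probes,
                       thresholds = c(1, 5, 10, 50, 100))
  expect_equal(nrow(rep$curves), 4 * 2 * 5)  # libraries x feature types x t
  expect_true(all(rep$curves$proportion >= 0 & rep$curves$proportion <= 1))
  expect_true(all(rep$coveredFraction$genes > 0.9))  # capture targets genes
  expect_equal(dim(rep$geneMeanCoverage), c(4L, 4L))
  expect_lte(rep$overlap$count, min(lengths(rep$geneSets)))
  # coverage round-trips through bedGraph
  d <- tempfile(); dir.create(d)
  id <- colnames(sim$experiment)[1]
  writeBedGraph(sim$coverage[[id]], file.path(d, "c.bedGraph"))
  back <- readBedGraph(file.path(d, "c.bedGraph"),
                       seqlengths = GenomeInfoDb::seqlengths(sim$genes))
  expect_equal(as.integer(back[["scaffold01"]]),
               as.integer(sim$coverage[[id]][["scaffold01"]]))
})
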