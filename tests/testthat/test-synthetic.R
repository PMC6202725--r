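test_that("reference counts follow the configuration by construction", {
  cfg <- tinyConfig(nGenes = 10, exonsPerGene = 3, probeRegionsPerGene = 3,
                    scaffoldLength = 50000)
  ref <- simulateReference(cfg)
  expect_equal(length(ref$genes), 10L)
  expect_equal(length(ref$exons), 30L)
  expect_equal(length(ref$probes), 30L)
  # genes non-overlapping, probes within gene span +/- 1 kbp
  expect_equal(length(GenomicRanges::reduce(ref$genes, ignore.strand = TRUE)),
               10L)
  flanked <- suppressWarnings(GenomicRanges::resize(
    ref$genes, GenomicRanges::width(ref$genes) + 2000, fix = "center"))
  within <- IRanges::overlapsAny(ref$probes, flanked, type = "within",
                                 ignore.strand = TRUE)
  expect_true(all(within))
  # lambda carries enough cytosines on each strand for conversion estimation
  lam <- as.character(ref$genome[["lambda"]])
  expect_gte(lengths(regmatches(lam, gregexpr("C", lam))), 100)
  expect_gte(lengths(regmatches(lam, gregexpr("G", lam))), 100)
})

test_that("a scaffold too short for the requested genes raises a sizing error", {
  expect_error(simulateReference(tinyConfig(nGenes = 30,
                                            scaffoldLength = 5000)),
               "too short to host")
})

test_that("the same seed reproduces byte-identical output files", {
  cfg <- tinyConfig(nGenes = 4, scaffoldLength = 20000, nGenets = 2)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(simulateTbs(cfg), d1)
  writeSimulation(simulateTbs(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) >= 8)
  expect_equal(f1, list.files(d2, recursive = TRUE))
  sum1 <- tools::md5sum(file.path(d1, f1))
  sum2 <- tools::md5sum(file.path(d2, f1))
  expect_equal(unname(sum1), unname(sum2))
})

test_that("methylation truth honours degenerate and boundary settings", {
  cfg <- tinyConfig(betaDispersion = Inf)
  ref <- simulateReference(cfg)
  sites <- enumerateCytosines(ref$genome)
  truth <- simulateMethylationTruth(sites, ref$genes, cfg)
  ctx <- S4Vectors::mcols(sites)$context
  lam <- as.character(GenomicRanges::seqnames(sites)) == "lambda"
  # concentration -> Inf collapses the Beta to the context mean exactly
  expect_true(all(truth$m_ortet[ctx == "CHH" & !lam] == 0.013))
  expect_true(all(truth$m_ortet[ctx == "CG" & !lam] == 0.213))
  expect_true(all(truth$m_ortet[lam] == 0))

  # no planted DMPs: ortet truth equals ramet truth everywhere
  cfg0 <- tinyConfig(dmpFraction = 0)
  truth0 <- simulateMethylationTruth(sites, ref$genes, cfg0)
  expect_identical(truth0$m_ortet, truth0$m_ramet)
  expect_false(any(truth0$is_dmp))
})

test_that("planted-DMP count follows the rounding rule and flags round-trip", {
  cfg <- tinyConfig(dmpFraction = 0.01, nGenes = 8, scaffoldLength = 40000)
  ref <- simulateReference(cfg)
  sites <- enumerateCytosines(ref$genome)
  truth <- simulateMethylationTruth(sites, ref$genes, cfg)
  ctx <- S4Vectors::mcols(sites)$context
  lam <- as.character(GenomicRanges::seqnames(sites)) == "lambda"
  genic <- IRanges::overlapsAny(sites, ref$genes, ignore.strand = TRUE)
  eligible <- sum(genic & ctx != "unknown" & !lam)
  expect_equal(sum(truth$is_dmp), round(0.01 * eligible))
  # flagged sites are exactly those whose ortet/ramet truths differ
  expect_equal(truth$is_dmp, truth$m_ortet != truth$m_ramet)
  # shifts keep the ramet truth inside [0, 1]
  expect_true(all(truth$m_ramet >= 0 & truth$m_ramet <= 1))
})

test_that("count generation respects saturation and error-free boundaries", {
  cfg <- tinyConfig(conversionRate = 1, nGenes = 3, scaffoldLength = 15000)
  ref <- simulateReference(cfg)
  sites <- enumerateCytosines(ref$genome)
  truth <- simulateMethylationTruth(sites, ref$genes, cfg)
  lam <- as.character(GenomicRanges::seqnames(sites)) == "lambda"

  # m = 0 and perfect conversion: no methylated read at any lambda site
  cnt <- simulateCounts(sites, truth, ref, cfg)
  expect_true(all(methCounts(cnt$experiment)[lam, ] == 0))

  # m = 1 everywhere: methylated count equals coverage
  truth1 <- truth
  truth1$m_ortet <- truth1$m_ramet <- rep(1, nrow(truth))
  cnt1 <- simulateCounts(sites, truth1, ref, cfg)
  expect_equal(methCounts(cnt1$experiment),
               totalCoverage(cnt1$experiment))

  # site coverage equals the bedGraph track depth at the site
  x <- cnt$experiment
  id <- colnames(x)[1]
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(x))
  sel <- which(as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(x))) == "scaffold01")[1:50]
  expect_equal(totalCoverage(x)[sel, id],
               as.integer(cnt$coverage[[id]][["scaffold01"]][pos[sel]]))
})

test_that("observed methylation at half-methylated truth matches binomial error", {
  # m = 0.5 at perfect conversion: observed fraction within 3 binomial SE
  cfg <- tinyConfig(conversionRate = 1, betaDispersion = Inf,
                    muContext = c(CG = 0.5, CHG = 0.5, CHH = 0.5),
                    dmpFraction = 0, nGenes = 6, coverageMean = 30)
  sim <- simulateTbs(cfg)
  ctx <- siteContext(sim$experiment)
  lam <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(sim$experiment))) == "lambda"
  sel <- !lam & ctx != "unknown"
  M <- sum(methCounts(sim$experiment)[sel, ])
  tot <- sum(totalCoverage(sim$experiment)[sel, ])
  expect_gte(tot, 10000)
  se <- sqrt(0.25 / tot)
  expect_lt(abs(M / tot - 0.5), 3 * se)
})

test_that("aggregate observed methylation converges to mu + (1-mu)(1-c)", {
  cfg <- tinyConfig(conversionRate = 0.99, betaDispersion = Inf,
                    dmpFraction = 0, nGenes = 6, coverageMean = 40)
  sim <- simulateTbs(cfg)
  ctx <- siteContext(sim$experiment)
  lam <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(sim$experiment))) == "lambda"
  M <- methCounts(sim$experiment); tot <- totalCoverage(sim$experiment)
  for (cc in c("CG", "CHG", "CHH")) {
    sel <- !lam & ctx == cc
    n <- sum(tot[sel, ])
    expect_gte(n, 1e5)
    mu <- cfg@muContext[[cc]]
    expected <- mu + (1 - mu) * 0.01
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(sum(M[sel, ]) / n - expected), 3 * se)
  }
})
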