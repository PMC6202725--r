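## independent Fisher oracle: exhaustive enumeration via explicit binomial
## coefficient ratios, no dhyper
fisherOracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  supp <- max(0, k - m2):min(k, m1)
  prob <- vapply(supp, function(x)
    choose(m1, x) * choose(m2, k - x) / choose(n, k), numeric(1))
  pObs <- choose(m1, a) * choose(m2, k - a) / choose(n, k)
  sum(prob[prob <= pObs * (1 + 1e-7)])
}

test_that("Fisher p equals 1 for identical proportions and is label-symmetric", {
  expect_equal(fisherTestPooled(10, 10, 10, 10), 1)
  p1 <- fisherTestPooled(2, 18, 12, 8)
  expect_equal(p1, fisherTestPooled(12, 8, 2, 18))
  expect_equal(p1, fisherOracle(2, 18, 12, 8), tolerance = 1e-12)
  expect_equal(p1, fisher.test(matrix(c(2, 18, 12, 8), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
})

test_that("Fisher p matches exhaustive enumeration on all tables with margins <= 30", {
  tab <- expand.grid(m1 = 0:30, m2 = 0:30)
  tab <- tab[tab$m1 + tab$m2 > 0, ]
  set.seed(99)
  ## all (a, c) for a stratified sample of margin pairs, plus small full grids
  sel <- rbind(tab[tab$m1 <= 6 & tab$m2 <= 6, ],
               tab[sample(nrow(tab), 120), ])
  cases <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
    m1 <- sel$m1[i]; m2 <- sel$m2[i]
    expand.grid(a = 0:m1, c = 0:m2, m1 = m1, m2 = m2)
  }))
  p <- fisherTestPooled(cases$a, cases$m1 - cases$a,
                        cases$c, cases$m2 - cases$c)
  pOracle <- mapply(fisherOracle, cases$a, cases$m1 - cases$a,
                    cases$c, cases$m2 - cases$c)
  expect_lt(max(abs(p - pOracle)), 1e-12)
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(adjustQ(0.01), 0.01)
  expect_equal(adjustQ(c(0.001, 0.01, 0.02, 0.03)),
               c(0.004, 0.02, 0.8 / 30, 0.03))
  expect_equal(adjustQ(rep(0.04, 5)), rep(0.04, 5))
  set.seed(5)
  p <- runif(200)^2
  q <- adjustQ(p)
  # direct formula: sort, p(i) * m / i, cumulative min from the top
  o <- order(p)
  direct <- rev(cummin(rev(p[o] * length(p) / seq_along(p))))
  expect_equal(q[o], pmin(direct, 1))
  expect_true(all(q >= p))
  expect_error(adjustQ(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pair differences are signed ortet-minus-ramet percentages", {
  M <- cbind(o1 = c(5L, 4L), r1 = c(3L, 4L), o2 = c(9L, 0L), r2 = c(5L, 0L))
  U <- cbind(o1 = c(5L, 6L), r1 = c(7L, 6L), o2 = c(1L, 10L), r2 = c(5L, 10L))
  cd <- S4Vectors::DataFrame(library_id = colnames(M),
                             genet = c(1, 1, 2, 2),
                             environment = c("ortet", "ramet",
                                             "ortet", "ramet"))
  x <- toyExperiment(M, U, colData = cd)
  pd <- pairDifferences(x)
  expect_equal(pd[1, ], c(genet1 = 20, genet2 = 40))
  expect_equal(pd[2, ], c(genet1 = 0, genet2 = 0))
})

test_that("the DMP cascade applies stat, effect and consistency thresholds", {
  mkx <- function(pairDiffVec, base = 0.5, cov = 60L) {
    # one site per row; 4 genets; ortet level base+diff+delta_g, ramet base
    nG <- length(pairDiffVec)
    M <- U <- matrix(0L, 1, 2 * nG)
    cd <- S4Vectors::DataFrame(
      library_id = paste0("l", 1:(2 * nG)),
      genet = rep(seq_len(nG), each = 2),
      environment = rep(c("ortet", "ramet"), nG))
    for (g in seq_len(nG)) {
      mo <- round(cov * (base + pairDiffVec[g] / 100))
      mr <- round(cov * base)
      M[1, 2 * g - 1] <- as.integer(mo); U[1, 2 * g - 1] <- cov - as.integer(mo)
      M[1, 2 * g] <- as.integer(mr); U[1, 2 * g] <- cov - as.integer(mr)
    }
    toyExperiment(M, U, colData = cd)
  }
  # all pairs strongly shifted in one direction: a DMP
  x <- mkx(c(30, 32, 40, 28))
  res <- dmpCascade(x)
  expect_true(res$passed_stat[1])
  expect_true(res$passed_effect[1])
  expect_true(res$passed_consistency[1])
  expect_true(res$is_dmp[1])
  # one pair in the opposite direction: consistency fails
  x2 <- mkx(c(30, -32, 40, 42))
  res2 <- dmpCascade(x2)
  expect_false(res2$passed_consistency[1])
  expect_false(res2$is_dmp[1])
  # one pair below the 10% magnitude: consistency fails
  x3 <- mkx(c(30, 8, 40, 42))
  expect_false(dmpCascade(x3)$passed_consistency[1])
})

test_that("DMP sets shrink monotonically as thresholds tighten", {
  sim <- simulateTbs(tinyConfig(nGenes = 6, dmpFraction = 0.02,
                                coverageMean = 50, seed = 77))
  loose <- dmpCascade(sim$experiment,
                      dmpConfig(minGroupDiff = 15, qThreshold = 0.05,
                                minPairDiff = 5))
  tight <- dmpCascade(sim$experiment, dmpConfig())
  key <- function(r) paste(r$scaffold, r$position, r$strand)[which(r$is_dmp)]
  expect_true(all(key(tight) %in% key(loose)))
  expect_lte(sum(tight$is_dmp), sum(loose$is_dmp))
})

test_that("planted DMPs are recovered with high recall at high coverage", {
  sim <- simulateTbs(tinyConfig(nGenes = 8, scaffoldLength = 40000,
                                dmpFraction = 0.02, dmpShift = 0.35,
                                coverageMean = 60, conversionRate = 1,
                                seed = 21))
  res <- dmpCascade(sim$experiment)
  truthKey <- with(as.data.frame(sim$sites)[sim$truth$is_dmp, ],
                   paste(seqnames, start, strand))
  resKey <- paste(res$scaffold, res$position, res$strand)
  analyzedPlanted <- intersect(truthKey, resKey)
  called <- resKey[res$is_dmp]
  recall <- mean(analyzedPlanted %in% called)
  expect_gte(recall, 0.8)
  # false DMPs among unplanted analysed sites stay near the nominal q level
  falsePos <- setdiff(called, truthKey)
  expect_lte(length(falsePos), max(3, 3 * 0.01 * length(resKey)))
})

test_that("the logistic alternative broadly agrees with Fisher on strong sites", {
  sim <- simulateTbs(tinyConfig(nGenes = 4, scaffoldLength = 20000,
                                dmpFraction = 0.05, dmpShift = 0.4,
                                coverageMean = 60, seed = 13))
  # restrict to a small subset for speed
  x <- filterSites(sim$experiment, filterConfig(), mode = "all")
  x <- x[seq_len(min(200, nrow(x))), ]
  rF <- dmpCascade(x, dmpConfig(test = "fisher_pooled"))
  rL <- dmpCascade(x, dmpConfig(test = "logistic"))
  strong <- which(rF$q < 1e-4 & abs(rF$group_diff) > 30)
  if (length(strong))
    expect_true(mean(rL$p[strong] < 0.05, na.rm = TRUE) > 0.7)
  expect_equal(nrow(rF), nrow(rL))
})
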