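#' @include methcalls.R
NULL

#' Two-sided Fisher's exact p for 2x2 count tables, vectorised
#'
#' For each site, the table [[#C ortet, #T ortet], [#C ramet, #T ramet]] is
#' tested conditionally on its margins: p is the sum of hypergeometric
#' probabilities of all tables at most as probable as the observed one (the
#' usual two-sided convention, with a 1 + 1e-7 relative tolerance on the
#' probability comparison).
#'
#' @param a,b,c,d integer vectors: a = #C group 1, b = #T group 1,
#'   c = #C group 2, d = #T group 2.
#' @return Numeric vector of p-values.
#' @examples
#' fisherTestPooled(10, 10, 10, 10)  # 1: identical proportions
#' @export
fisherTestPooled <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  p <- numeric(n)
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- pmax(0L, k - m2); hi <- pmin(k, m1)
  sup <- hi - lo + 1L
  chunk <- 5000L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    reps <- sup[idx]
    site <- rep(idx, reps)
    kk <- unlist(lapply(idx, function(i) lo[i]:hi[i]), use.names = FALSE)
    dens <- stats::dhyper(kk, m1[site], m2[site], k[site])
    dObs <- stats::dhyper(a[idx], m1[idx], m2[idx], k[idx])
    keep <- dens <= dObs[match(site, idx)] * (1 + 1e-7)
    ps <- rowsum(dens * keep, site)
    p[as.integer(rownames(ps))] <- pmin(ps[, 1], 1)
  }
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (monotone, q >= p), via
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values of the same length.
#' @export
adjustQ <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' DMP calling configuration
#'
#' Thresholds of the three-stage cascade: q-value significance, group
#' effect-size, and the per-clone-pair consistency filter (every ortet/ramet
#' pair must differ by more than \code{minPairDiff} percentage points in the
#' direction of the group difference).
#'
#' @param minGroupDiff minimum absolute ortet-ramet difference, percentage
#'   points (default 25).
#' @param qThreshold q-value cutoff (default 0.01).
#' @param minPairDiff minimum per-pair same-direction difference, percentage
#'   points (default 10); must not exceed \code{minGroupDiff}.
#' @param test \code{"fisher_pooled"} (counts pooled within environment,
#'   deterministic and oracle-checkable) or \code{"logistic"} (per-library
#'   binomial GLM with environment as covariate).
#' @param correction multiple-testing correction; only \code{"BH"}.
#' @return A list of class \code{DmpConfig}.
#' @export
dmpConfig <- function(minGroupDiff = 25, qThreshold = 0.01, minPairDiff = 10,
                      test = c("fisher_pooled", "logistic"),
                      correction = "BH") {
  test <- match.arg(test)
  correction <- match.arg(correction)
  if (minGroupDiff <= 0 || qThreshold <= 0 || minPairDiff <= 0)
    stop("thresholds must be positive")
  if (minPairDiff > minGroupDiff)
    stop("minPairDiff must not exceed minGroupDiff")
  structure(list(minGroupDiff = minGroupDiff, qThreshold = qThreshold,
                 minPairDiff = minPairDiff, test = test,
                 correction = correction),
            class = "DmpConfig")
}

.pairCols <- function(x) {
  cd <- colData(x)
  if (!all(c("genet", "environment") %in% colnames(cd)))
    stop("colData must carry 'genet' and 'environment' for DMP analysis")
  genets <- sort(unique(cd$genet))
  ort <- vapply(genets, function(g)
    which(cd$genet == g & cd$environment == "ortet")[1], integer(1))
  ram <- vapply(genets, function(g)
    which(cd$genet == g & cd$environment == "ramet")[1], integer(1))
  if (any(is.na(ort)) || any(is.na(ram)))
    stop("every genet needs one ortet and one ramet library")
  list(genets = genets, ortet = ort, ramet = ram)
}

#' Signed per-clone-pair methylation differences
#'
#' For each genet g, 100 * (weighted methylation of ortet_g - ramet_g) at
#' every site; positive values mean higher methylation in the ortet
#' (high-elevation) member. Sites where a pair member has zero coverage get
#' NA for that pair (such sites are ineligible for the consistency filter and
#' should be removed by the all-libraries coverage filter first).
#'
#' @param x A \linkS4class{MethylationExperiment} with genet/environment
#'   colData.
#' @return Numeric matrix, sites x genets, in percentage points.
#' @export
pairDifferences <- function(x) {
  pc <- .pairCols(x)
  ml <- methLevel(x)
  out <- 100 * (ml[, pc$ortet, drop = FALSE] - ml[, pc$ramet, drop = FALSE])
  colnames(out) <- paste0("genet", pc$genets)
  out
}

.logisticP <- function(M, U, isOrtet) {
  env <- factor(ifelse(isOrtet, "ortet", "ramet"))
  vapply(seq_len(nrow(M)), function(i) {
    y <- cbind(M[i, ], U[i, ])
    fit <- try(suppressWarnings(stats::glm(y ~ env, family = stats::binomial)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    cf <- summary(fit)$coefficients
    if (nrow(cf) < 2) return(NA_real_)
    cf[2, 4]
  }, numeric(1))
}

#' The DMP cascade: test, correct, effect-size and consistency filters
#'
#' Sites are restricted to those with coverage inside the filter bounds in
#' ALL libraries, then each context is analysed separately: counts are pooled
#' within environment and tested per site (Fisher's exact by default), BH
#' q-values are computed within context, and three flags are set --
#' \code{passed_stat} (q < qThreshold), \code{passed_effect} (|group
#' difference| > minGroupDiff percentage points, ortet minus ramet), and
#' \code{passed_consistency} (all per-pair differences share the group
#' difference's sign and each exceeds minPairDiff in magnitude). A DMP passes
#' all three.
#'
#' @param x A \linkS4class{MethylationExperiment}.
#' @param config A \code{\link{dmpConfig}}.
#' @param filter A \code{\link{filterConfig}} (8-100x by default).
#' @return A \link[S4Vectors]{DataFrame}, one row per analysed site:
#'   scaffold, position, strand, context, group_diff (pct points), p, q,
#'   pair_diffs (matrix column), the three flags and \code{is_dmp}. Summarise
#'   with \code{\link{dmpSummary}}.
#' @export
dmpCascade <- function(x, config = dmpConfig(), filter = filterConfig()) {
  keep <- siteContext(x) %in% .CONTEXTS &
    as.character(GenomicRanges::seqnames(rowRanges(x))) != "lambda"
  xx <- filterSites(x[keep, ], filter, mode = "all")
  pc <- .pairCols(xx)
  M <- assay(xx, "M"); U <- assay(xx, "U")
  Mo <- rowSums(M[, pc$ortet, drop = FALSE])
  Uo <- rowSums(U[, pc$ortet, drop = FALSE])
  Mr <- rowSums(M[, pc$ramet, drop = FALSE])
  Ur <- rowSums(U[, pc$ramet, drop = FALSE])
  groupDiff <- 100 * (Mo / (Mo + Uo) - Mr / (Mr + Ur))
  pd <- pairDifferences(xx)
  ctx <- siteContext(xx)
  p <- q <- rep(NA_real_, nrow(M))
  for (cc in .CONTEXTS) {
    sel <- ctx == cc
    if (!any(sel)) next
    p[sel] <- if (config$test == "fisher_pooled")
      fisherTestPooled(Mo[sel], Uo[sel], Mr[sel], Ur[sel])
    else
      .logisticP(M[sel, , drop = FALSE], U[sel, , drop = FALSE],
                 colData(xx)$environment == "ortet")
    q[sel] <- adjustQ(p[sel])   # corrected within context
  }
  sgn <- sign(groupDiff)
  consistent <- rowSums(sign(pd) == sgn & abs(pd) > config$minPairDiff) ==
    ncol(pd) & sgn != 0
  rr <- rowRanges(xx)
  res <- DataFrame(
    scaffold = as.character(GenomicRanges::seqnames(rr)),
    position = GenomicRanges::start(rr),
    strand = as.character(GenomicRanges::strand(rr)),
    context = ctx,
    group_diff = groupDiff,
    p = p, q = q,
    pair_diffs = I(pd),
    passed_stat = q < config$qThreshold,
    passed_effect = abs(groupDiff) > config$minGroupDiff,
    passed_consistency = consistent)
  res$is_dmp <- res$passed_stat & res$passed_effect & res$passed_consistency
  S4Vectors::metadata(res) <- list(config = config, filter = filter)
  res
}

#' Per-context DMP summary table
#'
#' Counts, per context and in total: analysed positions (coverage-filtered in
#' all libraries), DMPs passing the statistical and effect-size thresholds,
#' and DMPs additionally passing the per-pair consistency filter, with the
#' latter also as a percentage of analysed positions.
#'
#' @param records result of \code{\link{dmpCascade}}.
#' @return data.frame with one row per context plus a total row.
#' @export
dmpSummary <- function(records) {
  rows <- lapply(.CONTEXTS, function(cc) {
    sel <- records$context == cc
    n <- sum(sel)
    stat <- sum(records$passed_stat[sel] & records$passed_effect[sel],
                na.rm = TRUE)
    cons <- sum(records$is_dmp[sel], na.rm = TRUE)
    data.frame(context = cc, analyzed_positions = n,
               dmps = stat, dmps_consistent = cons,
               pct_consistent = if (n > 0) 100 * cons / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(context = "total",
                        analyzed_positions = sum(out$analyzed_positions),
                        dmps = sum(out$dmps),
                        dmps_consistent = sum(out$dmps_consistent),
                        pct_consistent = NA_real_))
}
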