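#' @include utils.R methcalls.R
NULL

#' Split gene bodies into n positionally ordered bins
#'
#' Each gene span (introns included) is tiled by exactly \code{nBins}
#' contiguous bins ordered 5'->3' in transcription direction: bin 1 holds the
#' transcriptional start, so for minus-strand genes it sits at the highest
#' forward coordinate. Bin lengths differ by at most 1 bp, the first
#' \code{length \%\% nBins} bins (in transcription order) being one bp longer.
#' Genes shorter than \code{nBins} bp are excluded with a warning.
#'
#' @param genes GRanges with strand and (optionally) an \code{ID} column.
#' @param nBins number of bins (default 20).
#' @return GRanges of bins with metadata columns \code{gene} and \code{bin}
#'   (1..nBins).
#' @export
geneBins <- function(genes, nBins = 20) {
  short <- GenomicRanges::width(genes) < nBins
  if (any(short)) {
    warning("excluding ", sum(short), " gene(s) shorter than ", nBins, " bp")
    genes <- genes[!short]
  }
  n <- length(genes)
  if (n == 0)
    return(GenomicRanges::GRanges(gene = character(), bin = integer()))
  ids <- S4Vectors::mcols(genes)$ID
  if (is.null(ids)) ids <- as.character(seq_len(n))
  w <- GenomicRanges::width(genes)
  base <- w %/% nBins
  rem <- w %% nBins
  binIdx <- rep(seq_len(nBins), n)
  wbin <- rep(base, each = nBins) + as.integer(binIdx <= rep(rem, each = nBins))
  cum <- unlist(lapply(seq_len(n), function(i)
    cumsum(wbin[(i - 1) * nBins + seq_len(nBins)])))
  gStart <- rep(GenomicRanges::start(genes), each = nBins)
  gEnd <- rep(GenomicRanges::end(genes), each = nBins)
  minus <- rep(as.character(GenomicRanges::strand(genes)) == "-", each = nBins)
  bStart <- ifelse(minus, gEnd - cum + 1L, gStart + cum - wbin)
  bEnd <- ifelse(minus, gEnd - cum + wbin, gStart + cum - 1L)
  out <- GenomicRanges::GRanges(
    rep(as.character(GenomicRanges::seqnames(genes)), each = nBins),
    IRanges::IRanges(bStart, bEnd),
    strand = rep(as.character(GenomicRanges::strand(genes)), each = nBins),
    gene = rep(ids, each = nBins), bin = binIdx)
  sl <- GenomeInfoDb::seqlengths(genes)
  if (!is.null(sl) && !any(is.na(sl))) {
    GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(genes)
    GenomeInfoDb::seqlengths(out) <- sl
  }
  out
}

#' Bin retention rule
#'
#' A bin is retained iff its mean per-bp read depth lies in
#' [\code{minCoverage}, \code{maxCoverage}] AND at least one cytosine call of
#' the target context falls inside it. A call at 0\% methylation counts: any
#' site whose coverage passed the per-library filter is a call.
#'
#' @param bins GRanges from \code{\link{geneBins}}.
#' @param cov \code{RleList} of depths for the library.
#' @param calls GRanges of the library's filtered call sites for the target
#'   context.
#' @param minCoverage,maxCoverage closed bounds on mean bin depth.
#' @return Logical vector, one per bin.
#' @export
binRetention <- function(bins, cov, calls, minCoverage = 8,
                         maxCoverage = 100) {
  meanDepth <- .binMeanDepth(bins, cov)
  nCalls <- GenomicRanges::countOverlaps(bins, calls, ignore.strand = TRUE)
  meanDepth >= minCoverage & meanDepth <= maxCoverage & nCalls >= 1
}

.binMeanDepth <- function(bins, cov) {
  out <- numeric(length(bins))
  chrs <- as.character(GenomicRanges::seqnames(bins))
  for (chr in unique(chrs)) {
    sel <- which(chrs == chr)
    rr <- IRanges::ranges(bins[sel])
    if (chr %in% names(cov)) {
      r <- cov[[chr]]
      mx <- max(BiocGenerics::end(rr))
      if (length(r) < mx) r <- c(r, S4Vectors::Rle(0L, mx - length(r)))
      out[sel] <- IRanges::viewMeans(IRanges::Views(r, rr))
    }
  }
  out
}

#' Metagene gene-body methylation profile
#'
#' The 20-bin profile of gene-body methylation per cytosine context. Per
#' library, sites are coverage-filtered (8-100x by default), each gene body is
#' split into \code{nBins} bins ordered 5'->3', bins failing the retention
#' rule (\code{\link{binRetention}}) are dropped, the retained bins' values
#' are the mean of their sites' weighted methylation percentages (unweighted
#' by coverage by default; \code{weightByCoverage} pools reads instead), and
#' bins at the same position index are averaged across genes. Library
#' profiles are then averaged position-wise (\code{pooled = TRUE} instead
#' pools all retained gene-bins across libraries). The grand mean over the
#' \code{nBins} positions and all libraries is the reported context-level
#' methylation.
#'
#' @param x A \linkS4class{MethylationExperiment}.
#' @param genes GRanges of gene bodies.
#' @param context contexts to profile (default all three).
#' @param nBins number of bins (default 20).
#' @param filter A \code{\link{filterConfig}} applied per library.
#' @param coverage optional named list of per-library \code{RleList} tracks
#'   used for the mean-bin-depth clause; if missing, the mean of site
#'   coverages inside the bin is used instead.
#' @param weightByCoverage average site percentages (default) or pool reads.
#' @param pooled average per-library profiles (default) or pool gene-bins.
#' @return data.frame with \code{context}, \code{bin}, \code{mean_pct},
#'   \code{n_sites}, \code{n_genes}; the per-context grand means are attached
#'   as \code{attr(, "grand_mean")} and the per-library bin profiles as
#'   \code{attr(, "per_library")}.
#' @export
metageneProfile <- function(x, genes, context = c("CG", "CHG", "CHH"),
                            nBins = 20, filter = filterConfig(),
                            coverage = NULL, weightByCoverage = FALSE,
                            pooled = FALSE) {
  bins <- geneBins(genes, nBins)
  if (length(bins) == 0) {
    warning("no genes long enough to bin; empty profile")
    return(data.frame(context = character(), bin = integer(),
                      mean_pct = numeric(), n_sites = integer(),
                      n_genes = integer()))
  }
  rr <- rowRanges(x)
  ctxAll <- siteContext(x)
  M <- assay(x, "M"); U <- assay(x, "U")
  cov <- M + U
  pass <- cov >= filter$minCoverage & cov <= filter$maxCoverage
  hits <- GenomicRanges::findOverlaps(rr, bins, ignore.strand = TRUE)
  sHit <- S4Vectors::queryHits(hits)
  bHit <- S4Vectors::subjectHits(hits)
  ids <- colnames(x)
  nbin <- length(bins)

  binDepth <- lapply(ids, function(id) {
    if (!is.null(coverage)) .binMeanDepth(bins, coverage[[id]]) else NULL
  })
  names(binDepth) <- ids

  res <- list()
  grand <- perLib <- list()
  for (cc in context) {
    values <- matrix(NA_real_, nBins, length(ids),
                     dimnames = list(NULL, ids))
    nSites <- nGenes <- matrix(0L, nBins, length(ids))
    pooledVals <- pooledIdx <- list()
    for (j in seq_along(ids)) {
      sel <- ctxAll[sHit] == cc & pass[cbind(sHit, j)]
      hs <- sHit[sel]; hb <- bHit[sel]
      if (!length(hs)) next
      pct <- 100 * M[cbind(hs, j)] / cov[cbind(hs, j)]
      nPerBin <- tabulate(hb, nbin)
      if (weightByCoverage) {
        mSum <- rowsum(as.numeric(M[cbind(hs, j)]), hb)
        cSum <- rowsum(as.numeric(cov[cbind(hs, j)]), hb)
        binVal <- rep(NA_real_, nbin)
        binVal[as.integer(rownames(mSum))] <- 100 * mSum[, 1] / cSum[, 1]
      } else {
        sums <- rep(0, nbin)
        agg <- rowsum(pct, hb)
        sums[as.integer(rownames(agg))] <- agg[, 1]
        binVal <- ifelse(nPerBin > 0, sums / nPerBin, NA_real_)
      }
      meanDepth <- if (!is.null(binDepth[[j]])) binDepth[[j]] else {
        covSums <- rep(0, nbin)
        aggAll <- rowsum(as.numeric(cov[cbind(sHit, j)]), bHit)
        nAll <- tabulate(bHit, nbin)
        covSums[as.integer(rownames(aggAll))] <- aggAll[, 1]
        ifelse(nAll > 0, covSums / nAll, 0)
      }
      keep <- meanDepth >= filter$minCoverage &
        meanDepth <= filter$maxCoverage & nPerBin >= 1
      idx <- S4Vectors::mcols(bins)$bin
      kept <- keep & !is.na(binVal)
      if (!any(kept)) next
      values[, j] <- vapply(seq_len(nBins), function(b)
        mean(binVal[kept & idx == b]), numeric(1))
      nSites[, j] <- vapply(seq_len(nBins), function(b)
        sum(nPerBin[kept & idx == b]), numeric(1))
      nGenes[, j] <- vapply(seq_len(nBins), function(b)
        sum(kept & idx == b), numeric(1))
      pooledVals[[j]] <- binVal[kept]
      pooledIdx[[j]] <- idx[kept]
    }
    if (pooled) {
      pv <- unlist(pooledVals); pi <- unlist(pooledIdx)
      prof <- vapply(seq_len(nBins), function(b) {
        v <- pv[pi == b]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
    } else {
      prof <- rowMeans(values, na.rm = TRUE)
      prof[is.nan(prof)] <- NA_real_
    }
    res[[cc]] <- data.frame(context = cc, bin = seq_len(nBins),
                            mean_pct = prof,
                            n_sites = rowSums(nSites),
                            n_genes = rowSums(nGenes))
    grand[[cc]] <- mean(values, na.rm = TRUE)
    perLib[[cc]] <- values
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "grand_mean") <- unlist(grand)
  attr(out, "per_library") <- perLib
  out
}

#' Grand mean methylation per context from a metagene profile
#'
#' Mean over all bins and libraries, as attached by
#' \code{\link{metageneProfile}}.
#'
#' @param profile result of \code{\link{metageneProfile}}.
#' @return Named numeric vector of percentages.
#' @export
metageneGrandMean <- function(profile) {
  gm <- attr(profile, "grand_mean")
  if (is.null(gm)) stop("profile carries no grand_mean attribute")
  gm
}
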