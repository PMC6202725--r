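#' @include utils.R
NULL

#' Read / write bedGraph coverage tracks
#'
#' bedGraph intervals are 0-based half-open on disk (the conversion happens
#' inside rtracklayer); in memory coverage is a per-scaffold
#' \link[S4Vectors]{RleList} step function.
#'
#' @param path bedGraph file.
#' @param seqlengths optional named scaffold lengths used to pad the track
#'   with zeros (bedGraph written with -bga style zero runs does not need it).
#' @return An \code{RleList} of integer depths.
#' @export
readBedGraph <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- GenomicRanges::coverage(gr, weight = "score")
  if (!is.null(seqlengths)) cov <- .padCoverage(cov, seqlengths)
  cov
}

#' @param cov an \code{RleList} of depths.
#' @rdname readBedGraph
#' @export
writeBedGraph <- function(cov, path) {
  gr <- methods::as(cov, "GRanges")
  names(S4Vectors::mcols(gr)) <- "score"
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Coverage threshold curve over a region set
#'
#' For each threshold t, the proportion of region base pairs covered by at
#' least t reads -- the capture-efficiency curve. Regions are merged before
#' counting so overlapping records are not double-counted; scaffolds missing
#' from the track count as depth 0.
#'
#' @param cov \code{RleList} of depths (see \code{\link{readBedGraph}}).
#' @param regions GRanges of probe regions or gene bodies (non-empty).
#' @param thresholds integer thresholds (default 1..100).
#' @return data.frame with \code{threshold} and \code{proportion};
#'   proportions are monotonically non-increasing in t.
#' @export
thresholdCurve <- function(cov, regions, thresholds = 1:100) {
  if (length(regions) == 0)
    stop("empty region set: no base pairs to profile")
  regions <- GenomicRanges::reduce(regions, ignore.strand = TRUE)
  d <- .regionDepths(cov, regions)
  tmax <- max(thresholds)
  ## counts[k] = #bp with depth == k-1 (depths above tmax capped: they pass all)
  counts <- tabulate(pmin(d, tmax) + 1L, nbins = tmax + 1L)
  atLeast <- rev(cumsum(rev(counts)))  # atLeast[k] = #bp with depth >= k-1
  prop <- atLeast[pmin(thresholds, tmax) + 1L] / length(d)
  data.frame(threshold = thresholds, proportion = prop)
}

#' Fraction of features covered at all
#'
#' The complementary "covered with at least one read" summary: the fraction
#' of features (genes or probe regions) with at least one base pair at depth
#' >= \code{minDepth}.
#'
#' @param cov \code{RleList} of depths.
#' @param regions GRanges of features.
#' @param minDepth minimum depth (default 1).
#' @return Single proportion in [0, 1].
#' @export
featureCoveredFraction <- function(cov, regions, minDepth = 1) {
  if (length(regions) == 0) stop("empty region set")
  hit <- vapply(seq_along(regions), function(i) {
    any(.regionDepths(cov, regions[i]) >= minDepth)
  }, logical(1))
  mean(hit)
}

#' Mean read depth over each gene span
#'
#' Mean over every base pair of the gene body (introns included); base pairs
#' outside the track's extent count as depth 0.
#'
#' @param cov \code{RleList} of depths.
#' @param genes GRanges with an \code{ID} metadata column (or unnamed).
#' @return Named numeric vector of mean depths.
#' @export
geneMeanCoverage <- function(cov, genes) {
  out <- numeric(length(genes))
  chrs <- as.character(GenomicRanges::seqnames(genes))
  for (chr in unique(chrs)) {
    sel <- which(chrs == chr)
    rr <- IRanges::ranges(genes[sel])
    if (chr %in% names(cov)) {
      r <- cov[[chr]]
      mx <- max(BiocGenerics::end(rr))
      if (length(r) < mx) r <- c(r, S4Vectors::Rle(0L, mx - length(r)))
      out[sel] <- IRanges::viewMeans(IRanges::Views(r, rr))
    } else out[sel] <- 0
  }
  ids <- S4Vectors::mcols(genes)$ID
  if (!is.null(ids)) names(out) <- ids
  out
}

#' Cross-library gene overlap
#'
#' Intersection of the per-library gene sets (typically genes with mean
#' coverage >= 10x) and its size as a percentage of the reference gene list.
#'
#' @param geneSets list of character vectors, one per library.
#' @param referenceGenes character vector: the full reference gene list.
#' @return list with \code{genes} (the intersection), \code{count} and
#'   \code{percentage}.
#' @examples
#' libraryOverlap(list(c("a", "b"), c("b", "c")), letters[1:4])  # 1 gene, 25%
#' @export
libraryOverlap <- function(geneSets, referenceGenes) {
  stopifnot(length(geneSets) >= 1)
  inter <- Reduce(intersect, geneSets)
  list(genes = inter, count = length(inter),
       percentage = 100 * length(inter) / length(referenceGenes))
}

#' Covered flank lengths up- and downstream of gene bodies
#'
#' For each gene, the number of base pairs in its 5' (upstream) and 3'
#' (downstream) flank -- strand-aware, clipped at scaffold edges -- with depth
#' >= \code{minDepth}. A capture design targeting gene bodies covers only a
#' thin rim of flank, which this summarises.
#'
#' @param cov \code{RleList} of depths.
#' @param genes GRanges (strand used for up/down orientation).
#' @param flank flank width in bp (default 1000).
#' @param minDepth minimum depth (default 10).
#' @return list with \code{perGene} (data.frame gene, upstream_bp,
#'   downstream_bp) and \code{summary} (mean and SEM over genes whose flank
#'   has nonzero width).
#' @export
flankCoverage <- function(cov, genes, flank = 1000, minDepth = 10) {
  seqlens <- GenomeInfoDb::seqlengths(genes)
  st <- as.character(GenomicRanges::strand(genes))
  countCovered <- function(gr) {
    vapply(seq_along(gr), function(i) {
      if (GenomicRanges::width(gr)[i] == 0) return(NA_integer_)
      sum(.regionDepths(cov, gr[i]) >= minDepth)
    }, integer(1))
  }
  up <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(genes, flank, start = TRUE)))
  dn <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(genes, flank, start = FALSE)))
  upBp <- countCovered(up)
  dnBp <- countCovered(dn)
  ids <- S4Vectors::mcols(genes)$ID
  if (is.null(ids)) ids <- as.character(seq_along(genes))
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(
    perGene = data.frame(gene = ids, upstream_bp = upBp,
                         downstream_bp = dnBp),
    summary = data.frame(
      flank = c("upstream", "downstream"),
      n_genes = c(sum(!is.na(upBp)), sum(!is.na(dnBp))),
      mean_bp = c(mean(upBp, na.rm = TRUE), mean(dnBp, na.rm = TRUE)),
      sem_bp = c(sem(upBp[!is.na(upBp)]), sem(dnBp[!is.na(dnBp)]))))
}

#' Capture-efficiency report across libraries
#'
#' Assembles, per library: the threshold curves over probe regions and gene
#' bodies (thresholds 1..100), the fraction of features covered at all, the
#' per-gene mean coverage and the set of genes with mean coverage >=
#' \code{minMeanCoverage}; plus the cross-library overlap of those gene sets
#' and the flanking-coverage summary.
#'
#' @param covs named list of per-library \code{RleList} tracks.
#' @param genes,probes GRanges (genes need an \code{ID} column).
#' @param thresholds threshold grid (default 1..100).
#' @param minMeanCoverage mean-coverage cutoff for the overlap (default 10).
#' @param flank,flankMinDepth see \code{\link{flankCoverage}}.
#' @return list with \code{curves} (long data.frame: library, feature_type,
#'   threshold, proportion), \code{coveredFraction}, \code{geneMeanCoverage}
#'   (genes x libraries matrix), \code{geneSets}, \code{overlap},
#'   \code{flanks} (per-library summaries).
#' @export
captureReport <- function(covs, genes, probes, thresholds = 1:100,
                          minMeanCoverage = 10, flank = 1000,
                          flankMinDepth = 10) {
  ids <- names(covs)
  stopifnot(!is.null(ids))
  curves <- do.call(rbind, lapply(ids, function(id) {
    rbind(cbind(library = id, feature_type = "probe",
                thresholdCurve(covs[[id]], probes, thresholds)),
          cbind(library = id, feature_type = "gene",
                thresholdCurve(covs[[id]], genes, thresholds)))
  }))
  coveredFraction <- do.call(rbind, lapply(ids, function(id) {
    data.frame(library = id,
               genes = featureCoveredFraction(covs[[id]], genes),
               probes = featureCoveredFraction(covs[[id]], probes))
  }))
  gmc <- vapply(ids, function(id) geneMeanCoverage(covs[[id]], genes),
                numeric(length(genes)))
  geneIds <- S4Vectors::mcols(genes)$ID
  if (is.null(geneIds)) geneIds <- as.character(seq_along(genes))
  rownames(gmc) <- geneIds
  geneSets <- lapply(ids, function(id) geneIds[gmc[, id] >= minMeanCoverage])
  names(geneSets) <- ids
  overlap <- libraryOverlap(geneSets, geneIds)
  flanks <- lapply(covs, flankCoverage, genes = genes, flank = flank,
                   minDepth = flankMinDepth)
  list(curves = curves, coveredFraction = coveredFraction,
       geneMeanCoverage = gmc, geneSets = geneSets, overlap = overlap,
       flanks = lapply(flanks, `[[`, "summary"))
}
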