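#' @include methcalls.R
NULL

#' Per-context methylation percentage matrix
#'
#' Libraries x sites matrix of weighted methylation percentages over the
#' sites of one context passing the coverage filter in ALL libraries
#' (complete cases by construction).
#'
#' @param x A \linkS4class{MethylationExperiment}.
#' @param context one of CG/CHG/CHH.
#' @param filter A \code{\link{filterConfig}}.
#' @return Numeric matrix, libraries x sites, columns named
#'   scaffold:position:strand.
#' @export
methylationMatrix <- function(x, context, filter = filterConfig()) {
  keep <- siteContext(x) == context &
    as.character(GenomicRanges::seqnames(rowRanges(x))) != "lambda"
  xx <- filterSites(x[keep, ], filter, mode = "all")
  ml <- t(100 * methLevel(xx))
  rr <- rowRanges(xx)
  colnames(ml) <- paste(GenomicRanges::seqnames(rr),
                        GenomicRanges::start(rr),
                        GenomicRanges::strand(rr), sep = ":")
  ml
}

#' PCA of methylation profiles
#'
#' Column-centred principal component analysis (no unit-variance scaling:
#' methylation percentages share a scale) of a libraries x sites matrix, or
#' of the matrix built from a \linkS4class{MethylationExperiment} for one
#' context. PC signs are fixed by making the largest-magnitude loading of
#' each component positive, so plots are reproducible.
#'
#' @param x matrix (libraries x sites) or a
#'   \linkS4class{MethylationExperiment}.
#' @param k number of components to report (default 3, capped at the rank).
#' @param context context (experiment input only).
#' @param filter coverage filter (experiment input only).
#' @param ... unused.
#' @return list with \code{scores} (data.frame library, PC1..PCk),
#'   \code{varianceExplained} (fractions, non-increasing, summing to <= 1
#'   over the reported k), \code{sdev} and \code{totalVariance}.
#' @rdname pcaProfiles
#' @export
setMethod("pcaProfiles", "matrix", function(x, k = 3, ...) {
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 libraries and 2 sites")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  tot <- sum(ev)
  k <- min(k, length(ev))
  for (j in seq_len(k)) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  scores <- data.frame(library = rownames(x) %||% as.character(seq_len(nrow(x))),
                       pr$x[, seq_len(k), drop = FALSE])
  rownames(scores) <- NULL
  list(scores = scores,
       varianceExplained = if (tot > 0) ev[seq_len(k)] / tot
                           else rep(0, k),
       sdev = pr$sdev, totalVariance = tot)
})

#' @rdname pcaProfiles
#' @export
setMethod("pcaProfiles", "MethylationExperiment",
          function(x, k = 3, context = "CG", filter = filterConfig(), ...) {
  mat <- methylationMatrix(x, context, filter)
  out <- pcaProfiles(mat, k = k)
  cd <- colData(x)
  if ("genet" %in% colnames(cd)) out$scores$genet <- cd$genet
  if ("environment" %in% colnames(cd))
    out$scores$environment <- cd$environment
  out
})

`%||%` <- function(a, b) if (is.null(a)) b else a
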