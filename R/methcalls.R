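#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for MethylationExperiment
#'
#' \code{methCounts}/\code{unmethCounts} return the #C / #T count matrices,
#' \code{totalCoverage} their sum, \code{methLevel} the per-site weighted
#' methylation fraction #C/(#C+#T) (NA where coverage is 0), and
#' \code{siteContext} the per-site context labels.
#'
#' @param x A \linkS4class{MethylationExperiment}.
#' @param ... unused.
#' @return Matrices (sites x libraries) or a character vector of contexts.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("methCounts", "MethylationExperiment", function(x)
  assay(x, "M"))

#' @rdname accessors
#' @export
setMethod("unmethCounts", "MethylationExperiment", function(x)
  assay(x, "U"))

#' @rdname accessors
#' @export
setMethod("totalCoverage", "MethylationExperiment", function(x)
  assay(x, "M") + assay(x, "U"))

#' @rdname accessors
#' @export
setMethod("methLevel", "MethylationExperiment", function(x, ...) {
  M <- assay(x, "M"); cov <- M + assay(x, "U")
  out <- M / cov
  out[cov == 0] <- NA_real_
  out
})

#' @rdname accessors
#' @export
setMethod("siteContext", "MethylationExperiment", function(x)
  as.character(S4Vectors::mcols(rowRanges(x))$context))

#' Weighted methylation level
#'
#' The read-count-weighted methylation estimate #C/(#C+#T). Zero-coverage
#' sites have no defined level and must be filtered before calling this; use
#' \code{\link{methLevel}} for the NA-propagating matrix variant.
#'
#' @param countMethylated,countUnmethylated non-negative counts (vectorised).
#' @return Numeric vector of fractions in [0, 1].
#' @examples
#' weightedMethylation(5, 15)   # 0.25
#' @export
weightedMethylation <- function(countMethylated, countUnmethylated) {
  if (any(countMethylated < 0) || any(countUnmethylated < 0))
    stop("counts must be non-negative")
  cov <- countMethylated + countUnmethylated
  if (any(cov == 0))
    stop("weighted methylation is undefined at zero coverage; ",
         "filter such sites first")
  countMethylated / cov
}

#' Bisulfite conversion rate from an unmethylated spike-in
#'
#' Read-pooled estimate: the proportion of all reads over unmethylated control
#' cytosines that were successfully converted to T, i.e.
#' sum(#T) / sum(#C + #T). The alternative per-site average (mean of per-site
#' #T/(#C+#T)) is available via \code{pool = FALSE}.
#'
#' @param x A \linkS4class{MethylationExperiment} (the control scaffold is
#'   selected with \code{control}) or a numeric vector of methylated counts.
#' @param u numeric vector of unmethylated counts (vector interface).
#' @param control scaffold name of the spike-in (default \code{"lambda"}).
#' @param pool pool reads across sites (default) or average per-site rates.
#' @param ... unused.
#' @return Conversion rate as a fraction in [0, 1]; for an experiment, a named
#'   vector with one estimate per library.
#' @examples
#' conversionRate(c(4, 6), c(396, 594))  # 0.99
#' @rdname conversionRate
#' @export
setMethod("conversionRate", "numeric", function(x, u, pool = TRUE, ...) {
  if (length(x) == 0) stop("no control calls supplied")
  if (pool) {
    tot <- sum(x) + sum(u)
    if (tot == 0) stop("conversion rate undefined: zero total coverage")
    sum(u) / tot
  } else {
    cov <- x + u
    if (all(cov == 0)) stop("conversion rate undefined: zero total coverage")
    mean((u / cov)[cov > 0])
  }
})

#' @rdname conversionRate
#' @export
setMethod("conversionRate", "MethylationExperiment",
          function(x, control = "lambda", pool = TRUE, ...) {
  sel <- as.character(GenomicRanges::seqnames(rowRanges(x))) == control
  if (!any(sel))
    stop("no sites on control scaffold '", control, "'")
  M <- assay(x, "M")[sel, , drop = FALSE]
  U <- assay(x, "U")[sel, , drop = FALSE]
  vapply(seq_len(ncol(M)), function(j)
    conversionRate(M[, j], U[, j], pool = pool), numeric(1)) |>
    stats::setNames(colnames(M))
})

#' Coverage filter configuration
#'
#' Positions are retained when their read coverage lies in the closed interval
#' [\code{minCoverage}, \code{maxCoverage}]; the defaults of 8 and 100 select
#' positions with enough reads for a stable weighted methylation estimate
#' while discarding collapsed-repeat pileups.
#'
#' @param minCoverage,maxCoverage closed coverage bounds in reads.
#' @return A list of class \code{FilterConfig}.
#' @export
filterConfig <- function(minCoverage = 8, maxCoverage = 100) {
  if (minCoverage < 1 || minCoverage > maxCoverage)
    stop("need 1 <= minCoverage <= maxCoverage")
  structure(list(minCoverage = minCoverage, maxCoverage = maxCoverage),
            class = "FilterConfig")
}

#' Logical matrix of sites passing the coverage filter per library
#'
#' @param x A \linkS4class{MethylationExperiment}.
#' @param config A \code{\link{filterConfig}}.
#' @return Logical sites x libraries matrix.
#' @export
coveragePass <- function(x, config = filterConfig()) {
  cov <- totalCoverage(x)
  cov >= config$minCoverage & cov <= config$maxCoverage
}

#' Apply the coverage filter
#'
#' For a per-library call table (data.frame with \code{count_methylated} and
#' \code{count_unmethylated}) the rows with coverage inside the closed
#' interval are retained. For a \linkS4class{MethylationExperiment},
#' \code{mode = "all"} (the default) keeps sites passing in every library --
#' the site set used by all cross-library analyses (PCA, DMP calling) -- while
#' \code{mode = "any"} keeps sites passing in at least one.
#'
#' @param x calls (data.frame) or a \linkS4class{MethylationExperiment}.
#' @param config A \code{\link{filterConfig}}.
#' @param mode \code{"all"} or \code{"any"} (experiment method only).
#' @param ... unused.
#' @return Object of the same class, subset to passing rows.
#' @examples
#' df <- data.frame(count_methylated = c(3, 4, 50, 101),
#'                  count_unmethylated = c(4, 4, 50, 0))
#' filterSites(df)   # coverages 7,8,100,101 -> keeps 8 and 100
#' @rdname filterSites
#' @export
setMethod("filterSites", "data.frame", function(x, config = filterConfig(), ...) {
  cov <- x$count_methylated + x$count_unmethylated
  x[cov >= config$minCoverage & cov <= config$maxCoverage, , drop = FALSE]
})

#' @rdname filterSites
#' @export
setMethod("filterSites", "MethylationExperiment",
          function(x, config = filterConfig(), mode = c("all", "any"), ...) {
  mode <- match.arg(mode)
  pass <- coveragePass(x, config)
  keep <- if (mode == "all") rowSums(pass) == ncol(pass) else rowSums(pass) > 0
  x[keep, ]
})

.REPORT_COLS <- c("scaffold", "position", "strand", "count_methylated",
                  "count_unmethylated", "context", "trinucleotide")

#' Read / write Bismark-style cytosine reports
#'
#' The dialect is a 7-column TSV: scaffold, 1-based position, strand (+/-),
#' count of methylated reads (#C), count of unmethylated reads (#T), context
#' (CG/CHG/CHH/unknown) and trinucleotide. No header by default. Rows with
#' context \code{unknown} are preserved on read but excluded from all
#' statistics downstream. Malformed rows raise an error naming the offending
#' line.
#'
#' @param path file path.
#' @param header whether the file has / should get a header line.
#' @return \code{readCytosineReport}: a data.frame with the seven columns.
#' @export
readCytosineReport <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          col.names = .REPORT_COLS,
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer", "character",
                                         "character"),
                          quote = "", comment.char = "")
  off <- if (header) 1L else 0L
  bad <- function(i, what)
    stop("cytosine report ", path, ", line ", i + off, ": ", what)
  chk <- function(cond, what) {
    i <- which(cond)
    if (length(i)) bad(i[1], what)
  }
  chk(is.na(df$position) | df$position < 1,
      "position must be a positive 1-based integer")
  chk(!df$strand %in% c("+", "-"), "strand must be '+' or '-'")
  chk(is.na(df$count_methylated) | is.na(df$count_unmethylated) |
        df$count_methylated < 0 | df$count_unmethylated < 0,
      "counts must be non-negative integers")
  chk(!df$context %in% .CONTEXT_LEVELS,
      "context must be CG, CHG, CHH or unknown")
  df
}

#' @param calls data.frame as returned by \code{readCytosineReport}, or a
#'   \linkS4class{MethylationExperiment} plus \code{library} selecting one
#'   column.
#' @param library library id (experiment input only).
#' @rdname readCytosineReport
#' @export
writeCytosineReport <- function(calls, path, library = NULL, header = FALSE) {
  if (is(calls, "MethylationExperiment")) {
    stopifnot(!is.null(library))
    rr <- rowRanges(calls)
    calls <- data.frame(
      scaffold = as.character(GenomicRanges::seqnames(rr)),
      position = GenomicRanges::start(rr),
      strand = as.character(GenomicRanges::strand(rr)),
      count_methylated = assay(calls, "M")[, library],
      count_unmethylated = assay(calls, "U")[, library],
      context = S4Vectors::mcols(rr)$context,
      trinucleotide = S4Vectors::mcols(rr)$trinucleotide)
  }
  utils::write.table(calls[, .REPORT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Assemble per-library cytosine reports into a MethylationExperiment
#'
#' All reports must describe the identical site set (same scaffolds,
#' positions, strands, in any order); sites are aligned to the first report.
#'
#' @param paths named character vector of report paths (names become library
#'   ids unless \code{colData} is given).
#' @param colData optional per-library metadata (one row per path).
#' @param header passed to \code{\link{readCytosineReport}}.
#' @return A \linkS4class{MethylationExperiment}.
#' @export
readCytosineReports <- function(paths, colData = NULL, header = FALSE) {
  dfs <- lapply(paths, readCytosineReport, header = header)
  key <- function(d) paste(d$scaffold, d$position, d$strand)
  k1 <- key(dfs[[1]])
  M <- U <- matrix(0L, nrow(dfs[[1]]), length(dfs))
  for (j in seq_along(dfs)) {
    idx <- match(k1, key(dfs[[j]]))
    if (any(is.na(idx)))
      stop("report ", paths[j], " does not cover the same site set")
    M[, j] <- dfs[[j]]$count_methylated[idx]
    U[, j] <- dfs[[j]]$count_unmethylated[idx]
  }
  sites <- GenomicRanges::GRanges(
    dfs[[1]]$scaffold, IRanges::IRanges(dfs[[1]]$position, width = 1L),
    strand = dfs[[1]]$strand, context = dfs[[1]]$context,
    trinucleotide = dfs[[1]]$trinucleotide)
  ids <- names(paths)
  if (is.null(ids)) ids <- paste0("lib", seq_along(paths))
  if (is.null(colData)) colData <- DataFrame(library_id = ids)
  MethylationExperiment(M, U, sites, colData)
}
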