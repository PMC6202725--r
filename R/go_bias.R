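#' @include diffmeth.R
NULL

#' Map DMPs to their host genes
#'
#' A DMP is assigned to a gene when it falls inside the gene span extended by
#' \code{flank} bp on each side (the capture/mapping reference includes 1 kbp
#' of flank). DMPs outside every gene region are counted in an intergenic
#' bucket and reported via a message.
#'
#' @param records result of \code{\link{dmpCascade}} (rows with
#'   \code{is_dmp} are used).
#' @param genes GRanges with an \code{ID} metadata column.
#' @param flank bp added to each side of the gene span (default 1000).
#' @return list with \code{all} (character vector of genes containing >= 1
#'   DMP of any context), \code{byContext} (per-context gene sets) and
#'   \code{intergenic} (count of unassigned DMPs).
#' @export
genesWithDmp <- function(records, genes, flank = 1000) {
  dm <- records[!is.na(records$is_dmp) & records$is_dmp, , drop = FALSE]
  if (nrow(dm) == 0)
    return(list(all = character(),
                byContext = stats::setNames(
                  rep(list(character()), length(.CONTEXTS)), .CONTEXTS),
                intergenic = 0L))
  sites <- GenomicRanges::GRanges(dm$scaffold,
                                  IRanges::IRanges(dm$position, width = 1L))
  regions <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(genes, GenomicRanges::width(genes) + 2L * flank,
                          fix = "center")))
  hits <- GenomicRanges::findOverlaps(sites, regions, ignore.strand = TRUE)
  ids <- S4Vectors::mcols(genes)$ID
  assigned <- ids[S4Vectors::subjectHits(hits)]
  siteGene <- split(assigned, S4Vectors::queryHits(hits))
  nInter <- nrow(dm) - length(unique(S4Vectors::queryHits(hits)))
  if (nInter > 0)
    message(nInter, " DMP(s) outside all gene regions (intergenic)")
  byContext <- lapply(.CONTEXTS, function(cc) {
    qs <- which(dm$context == cc)
    sort(unique(unlist(siteGene[as.character(qs)])))
  })
  names(byContext) <- .CONTEXTS
  list(all = sort(unique(assigned)), byContext = byContext,
       intergenic = nInter)
}

#' GO term over/under-representation among a gene set
#'
#' Hypergeometric bias test of each GO term's frequency in a sample of genes
#' (e.g. DMP-containing genes) against the annotated universe: the upper tail
#' gives the enrichment p, the lower tail the depletion p, the reported
#' direction is the smaller tail, and BH correction is applied within each
#' namespace. The universe is the set of reference genes with at least one
#' annotation (unannotated genes carry no information on term bias); sample
#' genes without annotation are dropped with a message. Terms with fewer than
#' \code{minCount} universe genes are skipped. No ancestor propagation is
#' performed: annotation is taken as provided.
#'
#' @param sampleGenes character vector of genes of interest.
#' @param annotation data.frame with \code{gene_id}, \code{term_id},
#'   \code{namespace} (BP/MF/CC).
#' @param minCount minimum universe genes per term (default 3).
#' @return data.frame: term, namespace, sample_count, universe_count,
#'   expected, direction (enriched/depleted), p_enrich, p_deplete, p
#'   (smaller tail), q (BH within namespace), sorted by q.
#' @export
goBiasTest <- function(sampleGenes, annotation, minCount = 3) {
  stopifnot(all(c("gene_id", "term_id", "namespace") %in% names(annotation)))
  universe <- unique(annotation$gene_id)
  dropped <- setdiff(sampleGenes, universe)
  if (length(dropped))
    message(length(dropped), " sample gene(s) without annotation dropped")
  sample <- intersect(unique(sampleGenes), universe)
  if (length(sample) == 0)
    return(data.frame(term = character(), namespace = character(),
                      sample_count = integer(), universe_count = integer(),
                      expected = numeric(), direction = character(),
                      p_enrich = numeric(), p_deplete = numeric(),
                      p = numeric(), q = numeric()))
  N <- length(universe)
  n <- length(sample)
  byTerm <- split(annotation$gene_id, annotation$term_id)
  ns <- annotation$namespace[match(names(byTerm), annotation$term_id)]
  K <- vapply(byTerm, function(g) length(unique(g)), integer(1))
  keep <- K >= minCount
  byTerm <- byTerm[keep]; ns <- ns[keep]; K <- K[keep]
  k <- vapply(byTerm, function(g) length(intersect(g, sample)), integer(1))
  pEnr <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pDep <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  expected <- n * K / N
  out <- data.frame(term = names(byTerm), namespace = ns,
                    sample_count = k, universe_count = K,
                    expected = expected,
                    direction = ifelse(pEnr <= pDep, "enriched", "depleted"),
                    p_enrich = pEnr, p_deplete = pDep,
                    p = pmin(pEnr, pDep))
  out$q <- NA_real_
  for (nsp in unique(out$namespace))
    out$q[out$namespace == nsp] <- adjustQ(out$p[out$namespace == nsp])
  rownames(out) <- NULL
  out[order(out$q, out$p), ]
}
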