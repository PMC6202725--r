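#' @include AllClasses.R utils.R contexts.R
NULL

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy reference: genome, annotation, probe design, spike-in
#'
#' Generates random scaffolds hosting non-overlapping genes (fixed length,
#' evenly spaced, random strand), each with \code{exonsPerGene} exons evenly
#' spread over the gene body and \code{probeRegionsPerGene} capture probe
#' regions inside the gene span, plus a dedicated unmethylated
#' \code{"lambda"} spike-in sequence. Gene spacing leaves at least 1 kbp
#' between a gene's 1 kbp flank and its neighbour, mirroring a capture design
#' that targets gene bodies plus 1 kbp of flank.
#'
#' @param config A \code{\link{simConfig}}.
#' @return A list with \code{genome} (DNAStringSet incl. \code{lambda}),
#'   \code{genes}, \code{exons} and \code{probes} (GRanges; exon records carry
#'   \code{Parent} gene ids).
#' @export
simulateReference <- function(config) {
  validObject(config)
  set.seed(stageSeed(config@seed, "reference"))
  nS <- as.integer(config@nScaffolds)
  sLen <- as.integer(config@scaffoldLength)
  nG <- as.integer(config@nGenes)
  gLen <- as.integer(config@geneLength)
  perScaf <- diff(round(seq(0, nG, length.out = nS + 1)))
  gap <- 2200L  # >= 2 x 1 kbp flank + margin between adjacent genes
  need <- max(perScaf) * (gLen + gap)
  if (need > sLen)
    stop("scaffoldLength (", sLen, ") too short to host ", max(perScaf),
         " genes of ", gLen, " bp with ", gap,
         " bp spacing; need at least ", need, " bp")
  seqs <- vapply(seq_len(nS), function(i) .randomDNA(sLen), character(1))
  names(seqs) <- sprintf("scaffold%02d", seq_len(nS))
  lambda <- .randomDNA(as.integer(config@lambdaLength))
  genome <- Biostrings::DNAStringSet(c(seqs, lambda = lambda))

  geneChr <- rep(names(seqs), perScaf)
  slot <- unlist(lapply(perScaf, seq_len))
  slotW <- sLen %/% ifelse(perScaf[match(geneChr, names(seqs))] > 0,
                           perScaf[match(geneChr, names(seqs))], 1L)
  gStart <- (slot - 1L) * slotW + gap %/% 2L + 1L
  gStrand <- sample(c("+", "-"), nG, replace = TRUE)
  geneIds <- sprintf("gene%04d", seq_len(nG))
  genes <- GenomicRanges::GRanges(
    geneChr, IRanges::IRanges(gStart, width = gLen), strand = gStrand,
    type = "gene", ID = geneIds)
  GenomeInfoDb::seqlevels(genes) <- names(genome)
  GenomeInfoDb::seqlengths(genes) <- nchar(as.character(genome))

  k <- as.integer(config@exonsPerGene)
  eW <- max(1L, as.integer(round(gLen * 0.6 / k)))
  ## exon starts evenly spread so the first starts at the gene start and the
  ## last ends at the gene end
  rel <- if (k == 1) 0L else round(seq(0L, gLen - eW, length.out = k))
  exons <- GenomicRanges::GRanges(
    rep(geneChr, each = k),
    IRanges::IRanges(rep(gStart, each = k) + rep(rel, nG), width = eW),
    strand = rep(gStrand, each = k),
    type = "exon",
    ID = sprintf("%s.exon%d", rep(geneIds, each = k), rep(seq_len(k), nG)),
    Parent = rep(geneIds, each = k))
  GenomeInfoDb::seqlevels(exons) <- names(genome)
  GenomeInfoDb::seqlengths(exons) <- nchar(as.character(genome))

  np <- as.integer(config@probeRegionsPerGene)
  pW <- max(50L, as.integer(round(gLen / (np + 1))))
  pRel <- round(seq(0L, gLen - pW, length.out = max(np, 1)))
  probes <- GenomicRanges::GRanges(
    rep(geneChr, each = np),
    IRanges::IRanges(rep(gStart, each = np) + rep(pRel, nG), width = pW),
    strand = "*",
    name = sprintf("%s.probe%d", rep(geneIds, each = np), rep(seq_len(np), nG)))
  GenomeInfoDb::seqlevels(probes) <- names(genome)
  GenomeInfoDb::seqlengths(probes) <- nchar(as.character(genome))

  list(genome = genome, genes = genes, exons = exons, probes = probes)
}

#' Simulate per-site true methylation and plant DMPs
#'
#' Each known-context site receives a true methylation fraction drawn from a
#' Beta distribution with the context's mean and concentration
#' \code{betaDispersion} (\code{Inf} gives the mean exactly). Lambda sites are
#' truly unmethylated. A fraction \code{dmpFraction} of eligible sites (known
#' context, inside a gene body) is planted as DMPs: the ramet truth is shifted
#' by \code{dmpShift}, clipped to [0, 1]. Shift signs are balanced among sites
#' where both directions stay inside [0, 1]; a site where one direction would
#' be clipped to nothing receives the feasible sign, so every planted site
#' carries a real effect.
#'
#' @param sites GRanges from \code{\link{enumerateCytosines}}.
#' @param genes gene GRanges (eligibility mask for DMP planting).
#' @param config A \code{\link{simConfig}}.
#' @return A \link[S4Vectors]{DataFrame} (one row per site): \code{m_ortet},
#'   \code{m_ramet}, \code{is_dmp}, \code{shift} (signed, 0 where unplanted).
#' @export
simulateMethylationTruth <- function(sites, genes, config) {
  validObject(config)
  set.seed(stageSeed(config@seed, "truth"))
  ctx <- S4Vectors::mcols(sites)$context
  lambda <- as.character(GenomicRanges::seqnames(sites)) == "lambda"
  m <- numeric(length(sites))
  for (cc in .CONTEXTS) {
    sel <- ctx == cc & !lambda
    if (!any(sel)) next
    mu <- config@muContext[[cc]]
    if (is.infinite(config@betaDispersion)) {
      m[sel] <- mu
    } else {
      m[sel] <- stats::rbeta(sum(sel), mu * config@betaDispersion,
                             (1 - mu) * config@betaDispersion)
    }
  }
  m[ctx == "unknown" | lambda] <- 0

  genic <- IRanges::overlapsAny(sites, genes, ignore.strand = TRUE)
  eligible <- which(genic & ctx != "unknown" & !lambda)
  nFlag <- round(config@dmpFraction * length(eligible))
  flagged <- if (nFlag > 0) sort(sample(eligible, nFlag)) else integer()
  shift <- numeric(length(sites))
  if (length(flagged)) {
    d <- config@dmpShift
    canUp <- m[flagged] + d <= 1
    canDown <- m[flagged] - d >= 0
    sgn <- numeric(length(flagged))
    both <- canUp & canDown
    if (any(both)) {
      nb <- sum(both)
      s <- rep(c(1, -1), length.out = nb)
      sgn[both] <- sample(s)  # balanced among feasible-both sites
    }
    sgn[!both & canUp] <- 1
    sgn[!both & canDown] <- -1
    ## neither direction fully feasible (d > 0.5): take the larger change
    rest <- sgn == 0
    sgn[rest] <- ifelse(m[flagged][rest] < 0.5, 1, -1)
    shift[flagged] <- sgn * d
  }
  mRamet <- clip01(m + shift)
  DataFrame(m_ortet = m, m_ramet = mRamet,
            is_dmp = shift != 0, shift = shift)
}

#' Simulate per-library counts and coverage tracks
#'
#' Coverage is drawn independently per base and library as negative binomial
#' (\code{coverageMean}, size \code{coverageDispersion}) over the captured
#' space (gene bodies +/- 1 kbp, clipped at scaffold edges, plus the whole
#' lambda sequence) and is zero elsewhere; a site's coverage is the track
#' depth at its base. The methylated read count is Binomial(coverage,
#' m + (1 - m)(1 - conversionRate)): methylated Cs never convert, unmethylated
#' Cs fail to convert with probability 1 - conversionRate and then read as
#' methylated. Ortet libraries use \code{m_ortet}, ramets \code{m_ramet}; an
#' optional per-genet random effect (\code{genetNoiseSd}) jitters the shared
#' baseline of both members of a genet.
#'
#' @param sites GRanges from \code{\link{enumerateCytosines}}.
#' @param truth DataFrame from \code{\link{simulateMethylationTruth}}.
#' @param reference list from \code{\link{simulateReference}}.
#' @param config A \code{\link{simConfig}}.
#' @return A list: \code{experiment} (\linkS4class{MethylationExperiment},
#'   2 x nGenets libraries) and \code{coverage} (named list of per-library
#'   RleList tracks).
#' @export
simulateCounts <- function(sites, truth, reference, config) {
  validObject(config)
  set.seed(stageSeed(config@seed, "counts"))
  seqlens <- GenomeInfoDb::seqlengths(reference$genome)
  if (is.null(seqlens) || any(is.na(seqlens)))
    seqlens <- stats::setNames(nchar(as.character(reference$genome)),
                               names(reference$genome))
  flanked <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::resize(reference$genes,
                          GenomicRanges::width(reference$genes) + 2000L,
                          fix = "center")))
  captured <- GenomicRanges::reduce(flanked, ignore.strand = TRUE)
  lam <- GenomicRanges::GRanges("lambda",
                                IRanges::IRanges(1L, seqlens[["lambda"]]))
  GenomeInfoDb::seqlevels(lam) <- GenomeInfoDb::seqlevels(captured)
  captured <- sort(c(captured, lam))

  nGenets <- as.integer(config@nGenets)
  envs <- c("ortet", "ramet")
  ids <- as.vector(t(outer(seq_len(nGenets), envs,
                           function(g, e) sprintf("genet%d_%s", g, e))))
  genets <- rep(seq_len(nGenets), each = 2L)
  environment <- rep(envs, nGenets)

  chrs <- as.character(GenomicRanges::seqnames(sites))
  pos <- GenomicRanges::start(sites)
  capChr <- as.character(GenomicRanges::seqnames(captured))
  nbp <- GenomicRanges::width(captured)
  err <- 1 - config@conversionRate

  M <- U <- matrix(0L, length(sites), length(ids))
  covList <- vector("list", length(ids))
  names(covList) <- ids
  genetNoise <- if (config@genetNoiseSd > 0)
    matrix(stats::rnorm(length(sites) * nGenets, 0, config@genetNoiseSd),
           ncol = nGenets)
  else NULL

  capStart <- GenomicRanges::start(captured)
  capEnd <- GenomicRanges::end(captured)
  for (j in seq_along(ids)) {
    depths <- stats::rnbinom(sum(nbp), mu = config@coverageMean,
                             size = config@coverageDispersion)
    depthByInt <- split(depths, rep(seq_along(capChr), nbp))
    covL <- lapply(names(seqlens), function(chr) {
      v <- integer(seqlens[[chr]])
      for (i in which(capChr == chr))
        v[capStart[i]:capEnd[i]] <- depthByInt[[i]]
      S4Vectors::Rle(v)
    })
    names(covL) <- names(seqlens)
    covList[[j]] <- methods::as(covL, "SimpleRleList")
    siteCov <- integer(length(sites))
    for (chr in unique(chrs)) {
      sel <- chrs == chr
      siteCov[sel] <- as.integer(covList[[j]][[chr]][pos[sel]])
    }
    m <- if (environment[j] == "ortet") truth$m_ortet else truth$m_ramet
    if (!is.null(genetNoise)) m <- clip01(m + genetNoise[, genets[j]])
    pApp <- m + (1 - m) * err
    M[, j] <- stats::rbinom(length(sites), siteCov, pApp)
    U[, j] <- siteCov - M[, j]
  }
  cd <- DataFrame(library_id = ids, genet = genets, environment = environment)
  list(experiment = MethylationExperiment(M, U, sites, cd),
       coverage = covList)
}

#' Run the whole simulator
#'
#' Convenience wrapper: reference, cytosine enumeration, methylation truth,
#' counts. Deterministic given \code{config@seed}; the three stochastic stages
#' use derived sub-seeds so later stages never perturb earlier draws.
#'
#' @param config A \code{\link{simConfig}}.
#' @return A list: \code{config}, \code{genome}, \code{genes}, \code{exons},
#'   \code{probes}, \code{sites}, \code{truth}, \code{experiment},
#'   \code{coverage}.
#' @examples
#' sim <- simulateTbs(simConfig(nScaffolds = 1, scaffoldLength = 20000,
#'                              nGenes = 4, seed = 3))
#' sim$experiment
#' @export
simulateTbs <- function(config) {
  ref <- simulateReference(config)
  sites <- enumerateCytosines(ref$genome)
  truth <- simulateMethylationTruth(sites, ref$genes, config)
  cnt <- simulateCounts(sites, truth, ref, config)
  c(list(config = config), ref,
    list(sites = sites, truth = truth,
         experiment = cnt$experiment, coverage = cnt$coverage))
}

#' Write a simulation to disk in standard formats
#'
#' FASTA (reference incl. lambda), GFF3 (gene/mRNA/exon; 1-based closed),
#' BED (probes; 0-based half-open), per-library cytosine report TSVs,
#' per-library bedGraph coverage tracks, and the truth table TSV.
#'
#' @param sim list from \code{\link{simulateTbs}}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  p$fasta <- file.path(outdir, "reference.fa")
  Biostrings::writeXStringSet(sim$genome, p$fasta)

  gn <- sim$genes
  S4Vectors::mcols(gn)$Parent <- NA_character_
  mrna <- gn
  S4Vectors::mcols(mrna)$type <- "mRNA"
  S4Vectors::mcols(mrna)$Parent <- S4Vectors::mcols(sim$genes)$ID
  S4Vectors::mcols(mrna)$ID <- paste0(S4Vectors::mcols(sim$genes)$ID, ".mRNA")
  ex <- sim$exons
  S4Vectors::mcols(ex)$Parent <- paste0(S4Vectors::mcols(ex)$Parent, ".mRNA")
  ann <- c(gn, mrna, ex)
  ann <- ann[order(as.character(GenomicRanges::seqnames(ann)),
                   GenomicRanges::start(ann),
                   match(S4Vectors::mcols(ann)$type,
                         c("gene", "mRNA", "exon")))]
  p$gff3 <- file.path(outdir, "annotation.gff3")
  rtracklayer::export(ann, p$gff3, format = "gff3")

  p$bed <- file.path(outdir, "probes.bed")
  rtracklayer::export(sim$probes, p$bed, format = "bed")

  p$truth <- file.path(outdir, "truth.tsv")
  tt <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(sim$sites)),
    position = GenomicRanges::start(sim$sites),
    strand = as.character(GenomicRanges::strand(sim$sites)),
    context = S4Vectors::mcols(sim$sites)$context,
    m_ortet = sim$truth$m_ortet, m_ramet = sim$truth$m_ramet,
    is_dmp = sim$truth$is_dmp, shift = sim$truth$shift)
  utils::write.table(tt, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ids <- colnames(sim$experiment)
  p$reports <- file.path(outdir, paste0(ids, ".CX_report.txt"))
  names(p$reports) <- ids
  for (id in ids)
    writeCytosineReport(sim$experiment, p$reports[[id]], library = id)
  p$bedgraph <- file.path(outdir, paste0(ids, ".coverage.bedGraph"))
  names(p$bedgraph) <- ids
  for (id in ids)
    writeBedGraph(sim$coverage[[id]], p$bedgraph[[id]])
  invisible(p)
}

#' Simulate a synthetic gene-to-GO annotation
#'
#' Artifact plumbing for end-to-end runs: assigns each gene a Poisson number
#' of GO terms drawn from a size-skewed term pool across the BP/MF/CC
#' namespaces. Purely synthetic labels (GO:SIM...), not real ontology terms.
#'
#' @param geneIds character vector of gene ids.
#' @param nTerms size of the term pool.
#' @param termsPerGene mean number of terms per gene.
#' @param seed integer seed.
#' @return data.frame with \code{gene_id}, \code{term_id}, \code{namespace}.
#' @export
simulateGoAnnotation <- function(geneIds, nTerms = 40, termsPerGene = 3,
                                 seed = 1) {
  set.seed(stageSeed(seed, "go"))
  terms <- sprintf("GO:SIM%04d", seq_len(nTerms))
  ns <- sample(c("BP", "MF", "CC"), nTerms, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
  wt <- stats::rexp(nTerms) + 0.1   # size-skewed term usage
  n <- pmax(1L, stats::rpois(length(geneIds), termsPerGene))
  rows <- lapply(seq_along(geneIds), function(i) {
    t <- sample(terms, min(n[i], nTerms), prob = wt)
    data.frame(gene_id = geneIds[i], term_id = t,
               namespace = ns[match(t, terms)])
  })
  do.call(rbind, rows)
}
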