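#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")
.CONTEXT_LEVELS <- c(.CONTEXTS, "unknown")

#' SimulationConfig: parameters of the synthetic TBS experiment
#'
#' Describes a toy targeted-bisulfite-sequencing study: a small multi-scaffold
#' genome carrying non-overlapping genes (each with a fixed number of exons and
#' capture probe regions), an unmethylated lambda-like spike-in, per-context
#' true methylation levels, negative-binomial site coverage, a bisulfite
#' non-conversion error, and a configurable fraction of planted differentially
#' methylated positions (DMPs) separating the two environments of a paired
#' ortet/ramet clone design.
#'
#' Per-site true methylation is drawn from a Beta distribution parameterised by
#' its mean (\code{muContext}, one value per cytosine context) and a
#' concentration \code{betaDispersion}; larger concentration means truths
#' tighter around the context mean, \code{Inf} collapses the distribution to
#' the mean exactly. Unmethylated cytosines fail to convert with probability
#' \code{1 - conversionRate} and then read as methylated; methylated cytosines
#' never convert. Planted DMPs shift the ramet truth by \code{dmpShift}
#' (sign recorded per site, balanced where both directions are feasible within
#' [0, 1]).
#'
#' @slot nScaffolds number of genomic scaffolds (lambda excluded).
#' @slot scaffoldLength length of each scaffold in bp.
#' @slot nGenes total number of genes across scaffolds.
#' @slot geneLength gene body length in bp.
#' @slot exonsPerGene exons per gene.
#' @slot probeRegionsPerGene capture probe regions per gene.
#' @slot nGenets number of clone pairs; libraries = nGenets x {ortet, ramet}.
#' @slot muContext named numeric, mean true methylation per context (CG/CHG/CHH).
#' @slot betaDispersion Beta concentration around the context mean.
#' @slot coverageMean,coverageDispersion negative-binomial coverage mean and
#'   size (dispersion) per base and library.
#' @slot conversionRate fraction of unmethylated Cs successfully converted.
#' @slot dmpFraction fraction of eligible (genic, known-context) sites planted
#'   as DMPs.
#' @slot dmpShift methylation-fraction shift applied to the ramet truth at
#'   planted sites.
#' @slot lambdaLength length of the unmethylated spike-in sequence in bp.
#' @slot genetNoiseSd optional per-genet random effect (sd on the methylation
#'   fraction scale); 0 disables it.
#' @slot seed integer seed that fully determines all outputs.
#' @export
setClass("SimulationConfig",
  representation(
    nScaffolds = "numeric",
    scaffoldLength = "numeric",
    nGenes = "numeric",
    geneLength = "numeric",
    exonsPerGene = "numeric",
    probeRegionsPerGene = "numeric",
    nGenets = "numeric",
    muContext = "numeric",
    betaDispersion = "numeric",
    coverageMean = "numeric",
    coverageDispersion = "numeric",
    conversionRate = "numeric",
    dmpFraction = "numeric",
    dmpShift = "numeric",
    lambdaLength = "numeric",
    genetNoiseSd = "numeric",
    seed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos1 <- function(x, nm) {
    if (length(x) != 1 || !is.finite(x) || x < 1)
      msg <<- c(msg, sprintf("'%s' must be a single value >= 1", nm))
  }
  pos1(object@nScaffolds, "nScaffolds")
  pos1(object@scaffoldLength, "scaffoldLength")
  pos1(object@nGenes, "nGenes")
  pos1(object@geneLength, "geneLength")
  pos1(object@exonsPerGene, "exonsPerGene")
  pos1(object@probeRegionsPerGene, "probeRegionsPerGene")
  pos1(object@nGenets, "nGenets")
  pos1(object@lambdaLength, "lambdaLength")
  if (!all(.CONTEXTS %in% names(object@muContext)))
    msg <- c(msg, "'muContext' must be named with CG, CHG and CHH")
  frac <- c(object@muContext, object@conversionRate, object@dmpFraction)
  if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1))
    msg <- c(msg, "muContext, conversionRate and dmpFraction must lie in [0, 1]")
  if (length(object@dmpShift) != 1 || object@dmpShift < 0 || object@dmpShift > 1)
    msg <- c(msg, "'dmpShift' must lie in [0, 1]")
  if (object@betaDispersion <= 0)
    msg <- c(msg, "'betaDispersion' must be > 0 (Inf allowed)")
  if (object@coverageMean <= 0 || object@coverageDispersion <= 0)
    msg <- c(msg, "coverage parameters must be > 0")
  if (object@genetNoiseSd < 0)
    msg <- c(msg, "'genetNoiseSd' must be >= 0")
  if (length(object@seed) != 1 || !is.finite(object@seed) ||
      object@seed != round(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults describe the study archetype the simulator emulates: 4 clone pairs
#' (8 libraries), genes with three exons and three probe regions each,
#' per-context mean gene-body methylation of 21.3\% (CG), 11.0\% (CHG) and
#' 1.3\% (CHH), negative-binomial site coverage around 30x, and a bisulfite
#' conversion rate of 99.5\%.
#'
#' @param nScaffolds,scaffoldLength,nGenes,geneLength,exonsPerGene,probeRegionsPerGene
#'   genome architecture; see \linkS4class{SimulationConfig}.
#' @param nGenets,muContext,betaDispersion,coverageMean,coverageDispersion,conversionRate,dmpFraction,dmpShift,lambdaLength,genetNoiseSd,seed
#'   see \linkS4class{SimulationConfig}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 10, seed = 7)
#' cfg
#' @export
simConfig <- function(nScaffolds = 4, scaffoldLength = 100000, nGenes = 80,
                      geneLength = 1500, exonsPerGene = 3,
                      probeRegionsPerGene = 3, nGenets = 4,
                      muContext = c(CG = 0.213, CHG = 0.110, CHH = 0.013),
                      betaDispersion = 20, coverageMean = 30,
                      coverageDispersion = 5, conversionRate = 0.995,
                      dmpFraction = 0.01, dmpShift = 0.35,
                      lambdaLength = 3000, genetNoiseSd = 0, seed = 1) {
  new("SimulationConfig",
      nScaffolds = nScaffolds, scaffoldLength = scaffoldLength,
      nGenes = nGenes, geneLength = geneLength, exonsPerGene = exonsPerGene,
      probeRegionsPerGene = probeRegionsPerGene, nGenets = nGenets,
      muContext = muContext[.CONTEXTS], betaDispersion = betaDispersion,
      coverageMean = coverageMean, coverageDispersion = coverageDispersion,
      conversionRate = conversionRate, dmpFraction = dmpFraction,
      dmpShift = dmpShift, lambdaLength = lambdaLength,
      genetNoiseSd = genetNoiseSd, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  genome: %d scaffold(s) x %d bp, %d genes (%d bp, %d exons, %d probe regions each)\n",
              object@nScaffolds, as.integer(object@scaffoldLength),
              object@nGenes, as.integer(object@geneLength),
              object@exonsPerGene, object@probeRegionsPerGene))
  cat(sprintf("  design: %d genets (%d libraries), lambda spike-in %d bp\n",
              object@nGenets, 2L * object@nGenets,
              as.integer(object@lambdaLength)))
  cat(sprintf("  truth:  mu = %s, concentration %s\n",
              paste(sprintf("%s %.3f", names(object@muContext),
                            object@muContext), collapse = ", "),
              format(object@betaDispersion)))
  cat(sprintf("  counts: coverage NB(mean %.1f, size %.1f), conversion %.4f\n",
              object@coverageMean, object@coverageDispersion,
              object@conversionRate))
  cat(sprintf("  DMPs:   fraction %.4f, shift %.2f; seed %d\n",
              object@dmpFraction, object@dmpShift, as.integer(object@seed)))
})

#' MethylationExperiment: per-cytosine counts for a set of libraries
#'
#' A \link[SummarizedExperiment]{RangedSummarizedExperiment} whose rows are
#' strand-resolved cytosine sites (with \code{context} and
#' \code{trinucleotide} metadata columns) and whose columns are sequencing
#' libraries. Two integer assays hold the Bismark-style counts: \code{M}
#' (reads supporting an unconverted, methylated C) and \code{U} (reads
#' supporting a converted T). \code{colData} carries \code{library_id} and,
#' for paired clone designs, \code{genet} and \code{environment}
#' ("ortet"/"ramet").
#'
#' @export
setClass("MethylationExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  msg <- character()
  if (!all(c("M", "U") %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'M' and 'U' are required")
  else {
    M <- assay(object, "M"); U <- assay(object, "U")
    if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
  }
  if (!"library_id" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'library_id'")
  if ("context" %in% colnames(S4Vectors::mcols(rowRanges(object)))) {
    ctx <- as.character(S4Vectors::mcols(rowRanges(object))$context)
    if (!all(ctx %in% .CONTEXT_LEVELS))
      msg <- c(msg, "site contexts must be CG, CHG, CHH or unknown")
  } else {
    msg <- c(msg, "rowRanges must carry a 'context' column")
  }
  if ("environment" %in% colnames(colData(object))) {
    env <- colData(object)$environment
    if (!all(env %in% c("ortet", "ramet") | is.na(env)))
      msg <- c(msg, "environment labels must be 'ortet' or 'ramet'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationExperiment
#'
#' @param M,U integer matrices (sites x libraries) of methylated (#C) and
#'   unmethylated (#T) read counts.
#' @param sites \link[GenomicRanges]{GRanges} of width-1 cytosine positions
#'   with metadata columns \code{context} and \code{trinucleotide}, e.g. from
#'   \code{\link{enumerateCytosines}}.
#' @param colData \code{DataFrame}/\code{data.frame} with one row per library;
#'   must contain \code{library_id}; \code{genet} and \code{environment} are
#'   used by the differential-methylation machinery.
#' @return A \linkS4class{MethylationExperiment}.
#' @export
MethylationExperiment <- function(M, U, sites, colData) {
  M <- as.matrix(M); U <- as.matrix(U)
  storage.mode(M) <- "integer"; storage.mode(U) <- "integer"
  colData <- DataFrame(colData)
  if (!is.null(colData$library_id)) {
    rownames(colData) <- colData$library_id
    colnames(M) <- colnames(U) <- colData$library_id
  }
  se <- SummarizedExperiment(assays = list(M = M, U = U),
                             rowRanges = sites, colData = colData)
  new("MethylationExperiment", se)
}

setMethod("show", "MethylationExperiment", function(object) {
  callNextMethod()
  ctx <- table(factor(siteContext(object), levels = .CONTEXT_LEVELS))
  cat("site contexts:", paste(sprintf("%s %d", names(ctx), ctx),
                              collapse = ", "), "\n")
})
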