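## small simulation configs used across test files

tinyConfig <- function(...) {
  args <- list(nScaffolds = 1, scaffoldLength = 30000, nGenes = 6,
               geneLength = 1200, lambdaLength = 1500, seed = 42)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

## brute-force context classifier: rebuilds each trinucleotide by string
## slicing and applies the CG/CHG/CHH rules independently of the package
bruteForceSites <- function(seqchar, name = "s") {
  n <- nchar(seqchar)
  out <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (i in seq_len(n)) {
    b <- substr(seqchar, i, i)
    if (b == "C") {
      d1 <- if (i + 1 <= n) substr(seqchar, i + 1, i + 1) else ""
      d2 <- if (i + 2 <= n) substr(seqchar, i + 2, i + 2) else ""
      ctx <- if (nchar(d1) == 0 || nchar(d2) == 0) "unknown"
      else if (d1 == "G") "CG"
      else if (d1 %in% c("A", "C", "T") && d2 == "G") "CHG"
      else if (d1 %in% c("A", "C", "T") && d2 %in% c("A", "C", "T")) "CHH"
      else "unknown"
      out[[length(out) + 1]] <- data.frame(pos = i, strand = "+",
                                           context = ctx)
    } else if (b == "G") {
      d1 <- if (i - 1 >= 1) comp[[substr(seqchar, i - 1, i - 1)]] else ""
      d2 <- if (i - 2 >= 1) comp[[substr(seqchar, i - 2, i - 2)]] else ""
      ctx <- if (nchar(d1) == 0 || nchar(d2) == 0) "unknown"
      else if (d1 == "G") "CG"
      else if (d1 %in% c("A", "C", "T") && d2 == "G") "CHG"
      else if (d1 %in% c("A", "C", "T") && d2 %in% c("A", "C", "T")) "CHH"
      else "unknown"
      out[[length(out) + 1]] <- data.frame(pos = i, strand = "-",
                                           context = ctx)
    }
  }
  do.call(rbind, out)
}

## a hand-built two-library experiment with fully controlled counts
toyExperiment <- function(M, U, contexts = NULL, positions = NULL,
                          colData = NULL) {
  M <- as.matrix(M); U <- as.matrix(U)
  n <- nrow(M)
  if (is.null(contexts)) contexts <- rep("CG", n)
  if (is.null(positions)) positions <- seq(10, by = 10, length.out = n)
  sites <- GenomicRanges::GRanges("s1",
    IRanges::IRanges(positions, width = 1), strand = "+",
    context = contexts, trinucleotide = rep("CGA", n))
  if (is.null(colData))
    colData <- S4Vectors::DataFrame(
      library_id = paste0("lib", seq_len(ncol(M))))
  MethylationExperiment(M, U, sites, colData)
}

## step coverage track on one scaffold from a vector of per-base depths
toyTrack <- function(depths, chr = "s1") {
  out <- list(S4Vectors::Rle(as.integer(depths)))
  names(out) <- chr
  methods::as(out, "SimpleRleList")
}
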