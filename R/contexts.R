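#' Classify a cytosine trinucleotide into CG/CHG/CHH
#'
#' Plant methylation contexts are defined by the two bases downstream of a
#' cytosine on its own strand (5'->3'): \code{CG} if the next base is G,
#' \code{CHG} if the next base is H (A/C/T) and the one after is G, \code{CHH}
#' if both are H. A context-determining base that is ambiguous (N) or missing
#' (\code{.} padding at a scaffold edge) yields \code{unknown}; note the third
#' base is irrelevant for CG, so e.g. \code{"CGN"} is still CG.
#'
#' @param trinucleotide character vector of 3-mers read 5'->3' on the
#'   cytosine's strand; the first base must be C.
#' @return Character vector of \code{"CG"}, \code{"CHG"}, \code{"CHH"} or
#'   \code{"unknown"}.
#' @examples
#' classifyContext(c("CGA", "CAG", "CTT", "CNG"))
#' @export
classifyContext <- function(trinucleotide) {
  tri <- toupper(as.character(trinucleotide))
  if (any(substr(tri, 1, 1) != "C"))
    stop("trinucleotides must start with C (got e.g. '",
         tri[substr(tri, 1, 1) != "C"][1], "')")
  bad <- grepl("[^ACGTN.]", substr(tri, 2, 3))
  if (any(bad))
    stop("trinucleotide bases must be A/C/G/T/N (got e.g. '", tri[bad][1], "')")
  b2 <- substr(tri, 2, 2)
  b3 <- substr(tri, 3, 3)
  h <- c("A", "C", "T")
  ctx <- rep("unknown", length(tri))
  ctx[b2 == "G"] <- "CG"
  ctx[b2 %in% h & b3 == "G"] <- "CHG"
  ctx[b2 %in% h & b3 %in% h] <- "CHH"
  ctx
}

#' Enumerate every cytosine of a genome on both strands
#'
#' Emits one record per forward-strand C and per forward-strand G (a
#' reverse-strand C), with the trinucleotide read 5'->3' on the site's strand
#' (for minus-strand sites, the reverse complement of the three forward bases
#' ending at the G). Sites with fewer than two downstream bases on their
#' strand get '.'-padded trinucleotides and context \code{unknown}; they are
#' excluded from all downstream statistics but kept in reports.
#'
#' @param genome A \link[Biostrings]{DNAStringSet} or path to a FASTA file.
#' @return A \link[GenomicRanges]{GRanges} of width-1 sites, sorted by
#'   scaffold and position, with metadata columns \code{context} and
#'   \code{trinucleotide} and seqlengths set from the genome.
#' @examples
#' gn <- Biostrings::DNAStringSet(c(s1 = "ACGT"))
#' enumerateCytosines(gn)
#' @export
enumerateCytosines <- function(genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(genome)))
    stop("genome sequences must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))
  res <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    s <- as.character(genome[[i]])
    n <- nchar(s)
    posC <- as.integer(gregexpr("C", s, fixed = TRUE)[[1]])
    posG <- as.integer(gregexpr("G", s, fixed = TRUE)[[1]])
    if (length(posC) == 1 && posC == -1L) posC <- integer()
    if (length(posG) == 1 && posG == -1L) posG <- integer()
    triC <- if (length(posC)) substring(s, posC, pmin(posC + 2L, n))
            else character()
    if (length(posG)) {
      fwd <- substring(s, pmax(posG - 2L, 1L), posG)
      triG <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fwd)))
    } else triG <- character()
    pad <- function(x) paste0(x, strrep(".", 3L - nchar(x)))
    triC <- pad(triC); triG <- pad(triG)
    ctxC <- if (length(posC)) classifyContext(triC) else character()
    ctxG <- if (length(posG)) classifyContext(triG) else character()
    ## edge rule: fewer than 2 downstream bases on the site's strand
    ctxC[posC > n - 2L] <- "unknown"
    ctxG[posG < 3L] <- "unknown"
    pos <- c(posC, posG)
    if (!length(pos)) { res[[i]] <- NULL; next }
    o <- order(pos)
    res[[i]] <- data.frame(
      chr = names(genome)[i], pos = pos[o],
      strand = rep(c("+", "-"), c(length(posC), length(posG)))[o],
      context = c(ctxC, ctxG)[o],
      trinucleotide = c(triC, triG)[o])
  }
  tab <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(tab))
    tab <- data.frame(chr = character(), pos = integer(),
                      strand = character(), context = character(),
                      trinucleotide = character())
  out <- GenomicRanges::GRanges(
    seqnames = factor(tab$chr, levels = names(genome)),
    ranges = IRanges::IRanges(tab$pos, width = 1L),
    strand = tab$strand,
    context = tab$context, trinucleotide = tab$trinucleotide)
  GenomeInfoDb::seqlengths(out) <- nchar(as.character(genome))
  out
}
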