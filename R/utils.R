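## internal helpers

clip01 <- function(x) pmin(1, pmax(0, x))

## derived per-stage seeds: adding a stage never perturbs earlier stages' draws
.STAGE_OFFSETS <- c(reference = 101L, truth = 211L, counts = 307L,
                    go = 401L, pipeline = 503L)

stageSeed <- function(seed, stage) {
  off <- .STAGE_OFFSETS[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

## ensure an RleList has a run for every requested scaffold, padded to seqlength
.padCoverage <- function(cov, seqlens) {
  out <- lapply(names(seqlens), function(chr) {
    len <- seqlens[[chr]]
    if (!is.null(cov) && chr %in% names(cov)) {
      r <- cov[[chr]]
      if (length(r) < len) r <- c(r, S4Vectors::Rle(0L, len - length(r)))
      r[seq_len(len)]
    } else {
      S4Vectors::Rle(0L, len)
    }
  })
  names(out) <- names(seqlens)
  methods::as(out, "SimpleRleList")
}

## per-base depths of a coverage RleList over (assumed disjoint) ranges
.regionDepths <- function(cov, regions) {
  if (length(regions) == 0) return(integer())
  chrs <- as.character(GenomicRanges::seqnames(regions))
  out <- vector("list", length(unique(chrs)))
  i <- 0L
  for (chr in unique(chrs)) {
    i <- i + 1L
    rr <- IRanges::ranges(regions[chrs == chr])
    if (chr %in% names(cov)) {
      r <- cov[[chr]]
      mx <- max(BiocGenerics::end(rr))
      if (length(r) < mx) r <- c(r, S4Vectors::Rle(0L, mx - length(r)))
      out[[i]] <- as.integer(unlist(IRanges::Views(r, rr), use.names = FALSE))
    } else {
      out[[i]] <- integer(sum(BiocGenerics::width(rr)))
    }
  }
  unlist(out, use.names = FALSE)
}
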