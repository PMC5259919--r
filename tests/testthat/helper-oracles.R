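## Shared fixtures and independent brute-force oracles used across the
## suite. Oracles are deliberately written as slow per-basepair /
## per-case loops, independent of the package's vectorised code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## GRanges from 0-based half-open coordinates (the convention most of
## the worked examples are written in)
gr0 <- function(chrom, start0, end0, chromSizes, strand = "*", ...) {
  GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand,
          seqlengths = chromSizes, ...)
}

## a tiny BinnedMethylation with explicit rms rows
tinyMeth <- function(rmsRows, subtype, chromLen = NULL, binSize = 100L) {
  m <- as.matrix(rmsRows)
  if (is.null(chromLen)) chromLen <- nrow(m) * binSize
  bins <- makeBinIndex(c(chr1 = as.integer(chromLen)), binSize)
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  BinnedMethylation(m, bins, subtype, binSize = binSize)
}

## per-basepair membership oracle: which bases (1-based) of a chromosome
## are covered by any interval of a GRanges
bpCoverage <- function(gr, chrom, chromLen) {
  v <- logical(chromLen)
  sel <- as.character(seqnames(gr)) == chrom
  for (i in which(sel)) {
    s <- max(1L, start(gr)[i]); e <- min(chromLen, end(gr)[i])
    if (e >= s) v[s:e] <- TRUE
  }
  v
}

## run-length DMR oracle: scan a significance/direction vector and build
## regions allowing gaps of non-significant bins
dmrOracle <- function(sig, dir, maxGap = 0L) {
  runs <- list()
  cur <- NULL
  gap <- 0L
  for (i in seq_along(sig)) {
    if (sig[i] && dir[i] != "tie") {
      if (is.null(cur)) {
        cur <- list(from = i, to = i, dir = dir[i])
      } else if (dir[i] == cur$dir && gap <= maxGap) {
        cur$to <- i
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- list(from = i, to = i, dir = dir[i])
      }
      gap <- 0L
    } else if (!is.null(cur)) {
      gap <- gap + 1L
      if (gap > maxGap) {
        runs[[length(runs) + 1L]] <- cur
        cur <- NULL
        gap <- 0L
      }
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}

## exact-summation binomial upper tail, independent of pbinom
binomTailOracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

## brute-force subtype-specific rule on carrier fractions
specificOracle <- function(frac, minIn = 0.30, maxOut = 0.10) {
  hit <- names(frac)[vapply(names(frac), function(s)
    frac[[s]] >= minIn && all(frac[setdiff(names(frac), s)] < maxOut),
    logical(1))]
  if (length(hit)) hit else NA_character_
}

## build a calls-like table from per-site carrier counts per subtype
callsFromCarriers <- function(counts, nPer = c(luminal = 10L, basalA = 10L,
                                               basalB = 10L)) {
  subtype <- factor(rep(names(nPer), nPer), levels = names(nPer))
  names(subtype) <- sprintf("%s_%02d", rep(names(nPer), nPer),
                            unlist(lapply(nPer, seq_len)))
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (st in names(nPer)) {
      k <- counts[i, st]
      if (k > 0) {
        carriers <- names(subtype)[subtype == st][seq_len(k)]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "chr1", pos = i, sample = carriers,
          coverage = 30L, mismatches = 15L, rms = 0.5,
          eligible = TRUE, isMutated = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  list(calls = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       subtype = subtype)
}
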