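## Differential methylation between subtype pairs: per-bin Welch t-tests
## with Bonferroni control, merging of significant bins into DMRs,
## per-region significant-bin counts, and hypomethylation ratios.

.SUBTYPE_PAIRS <- list(c("luminal", "basalA"), c("luminal", "basalB"),
                       c("basalA", "basalB"))

#' Per-bin differential methylation test between two subtypes
#'
#' Runs a Welch (unequal-variance) two-sample t-test on every bin's RMS
#' values between the two subtypes of \code{pair}, then applies
#' Bonferroni correction over the bins actually tested. Bins with an NA
#' cell or zero variance in both groups are skipped; their counts are
#' attached as attributes. The hypomethylated member of the pair
#' (\code{hypoIn}) is the one with the lower group mean (\code{"tie"} on
#' exact equality).
#'
#' @param meth a \linkS4class{BinnedMethylation}.
#' @param pair character(2), the two subtype labels to compare.
#' @param alpha significance level on the Bonferroni-adjusted p (0.05).
#' @return data.frame with one row per bin: \code{bin, chrom, start,
#'   end, meanA, meanB, t, p, pAdj, significant, hypoIn, tested};
#'   attributes \code{nSkippedNA}, \code{nSkippedZeroVar}, \code{mTested}
#'   record the multiplicity bookkeeping. Coordinates are 0-based
#'   half-open.
#' @export
pairwiseBinTest <- function(meth, pair, alpha = 0.05) {
  stopifnot(is(meth, "BinnedMethylation"), length(pair) == 2L)
  subtype <- as.character(subtypes(meth))
  if (!all(pair %in% subtype))
    stop("pair members not found among sample subtypes: ",
         paste(setdiff(pair, subtype), collapse = ", "))
  X <- rms(meth)[, subtype == pair[1], drop = FALSE]
  Y <- rms(meth)[, subtype == pair[2], drop = FALSE]
  n1 <- ncol(X); n2 <- ncol(Y)
  if (n1 < 2L || n2 < 2L)
    stop("each pair member needs >= 2 samples (got ", n1, " and ", n2, ")")

  hasNA <- rowSums(is.na(X)) + rowSums(is.na(Y)) > 0
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  zeroVar <- !hasNA & (v1 + v2 == 0)
  tested <- !hasNA & !zeroVar

  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[!tested] <- NA_real_
  mTested <- sum(tested)
  pAdj <- pmin(1, p * mTested)

  hypoIn <- ifelse(m1 < m2, pair[1], ifelse(m1 > m2, pair[2], "tie"))
  bins <- SummarizedExperiment::rowRanges(meth)
  out <- data.frame(
    bin = seq_along(bins),
    chrom = as.character(GenomicRanges::seqnames(bins)),
    start = GenomicRanges::start(bins) - 1L,
    end = GenomicRanges::end(bins),
    meanA = m1, meanB = m2, t = tstat, p = p, pAdj = pAdj,
    significant = tested & !is.na(pAdj) & pAdj < alpha,
    hypoIn = hypoIn, tested = tested,
    stringsAsFactors = FALSE)
  attr(out, "pair") <- pair
  attr(out, "alpha") <- alpha
  attr(out, "mTested") <- mTested
  attr(out, "nSkippedNA") <- sum(hasNA)
  attr(out, "nSkippedZeroVar") <- sum(zeroVar)
  out
}

#' Merge significant bins into differentially methylated regions
#'
#' Consecutive significant bins with the same hypomethylation direction
#' become one DMR; up to \code{maxGapBins} intervening non-significant
#' bins are tolerated inside a region. Bins on different chromosomes, or
#' separated by a significant bin of the opposite direction, never merge.
#'
#' @param results output of \code{\link{pairwiseBinTest}} (bins in
#'   genomic order).
#' @param maxGapBins non-significant bins allowed inside a DMR (0 =
#'   strictly adjacent).
#' @return data.frame: \code{chrom, start, end, nBins, hypoIn,
#'   minPAdj, binFrom, binTo} (0-based half-open coordinates).
#' @export
mergeBinsToDmrs <- function(results, maxGapBins = 0L) {
  stopifnot(maxGapBins >= 0L)
  sig <- which(results$significant & results$hypoIn != "tie")
  if (!length(sig))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), nBins = integer(0),
                      hypoIn = character(0), minPAdj = numeric(0),
                      binFrom = integer(0), binTo = integer(0),
                      stringsAsFactors = FALSE))
  dir <- results$hypoIn[sig]
  chrom <- results$chrom[sig]
  newRun <- c(TRUE,
              diff(sig) - 1L > maxGapBins |
                dir[-1] != dir[-length(dir)] |
                chrom[-1] != chrom[-length(chrom)])
  ## a gap may not contain a significant bin of the other direction:
  ## consecutive entries of `sig` are by construction the only
  ## significant bins, so gaps are purely non-significant bins.
  run <- cumsum(newRun)
  first <- sig[!duplicated(run)]
  last <- sig[!duplicated(run, fromLast = TRUE)]
  data.frame(
    chrom = results$chrom[first],
    start = results$start[first],
    end = results$end[last],
    nBins = as.integer(tapply(sig, run, length)),
    hypoIn = results$hypoIn[first],
    minPAdj = as.numeric(tapply(results$pAdj[sig], run, min)),
    binFrom = first, binTo = last,
    stringsAsFactors = FALSE)
}

#' Count significant bins per region class
#'
#' A multi-labelled bin increments every region class it carries.
#'
#' @param results output of \code{\link{pairwiseBinTest}}.
#' @param labels \code{CharacterList} of per-bin label sets (from
#'   \code{\link{assignBins}} / \code{\link{binLabels}}).
#' @param regionClasses classes to report (default: every label seen).
#' @return named integer vector of significant-bin counts per class.
#' @export
countByRegion <- function(results, labels,
                          regionClasses = NULL) {
  stopifnot(length(labels) == nrow(results))
  if (is.null(regionClasses))
    regionClasses <- sort(unique(unlist(labels, use.names = FALSE)))
  sig <- results$significant
  vapply(regionClasses, function(l) sum(.hasLabel(labels, l) & sig),
         integer(1))
}

#' Hypomethylation ratio within a region class
#'
#' Among significant bins carrying the region label, the fraction whose
#' lower group mean belongs to each member of the pair. Bins with tied
#' means are excluded; with no eligible bins the ratios are NA.
#'
#' @param results output of \code{\link{pairwiseBinTest}}.
#' @param labels per-bin \code{CharacterList} of region labels.
#' @param region region class, e.g. \code{"shore"} or \code{"intron"}.
#' @return named numeric(2): ratio per pair member (sums to 1 when
#'   defined), with attribute \code{nBins}.
#' @export
hypomethylationRatio <- function(results, labels, region) {
  pair <- attr(results, "pair")
  sel <- results$significant & .hasLabel(labels, region) &
    results$hypoIn != "tie"
  n <- sum(sel)
  out <- if (n == 0) setNames(c(NA_real_, NA_real_), pair)
  else setNames(c(sum(results$hypoIn[sel] == pair[1]) / n,
                  sum(results$hypoIn[sel] == pair[2]) / n), pair)
  attr(out, "nBins") <- n
  out
}

#' Run all three pairwise comparisons
#'
#' Convenience wrapper running \code{\link{pairwiseBinTest}} for the
#' luminal/basal A, luminal/basal B and basal A/basal B pairs.
#'
#' @param meth a \linkS4class{BinnedMethylation}.
#' @param alpha Bonferroni-adjusted significance level.
#' @return named list of per-pair result data.frames
#'   (\code{"Lu-BaA"}, \code{"Lu-BaB"}, \code{"BaA-BaB"}).
#' @export
allPairwiseTests <- function(meth, alpha = 0.05) {
  res <- lapply(.SUBTYPE_PAIRS, pairwiseBinTest, meth = meth, alpha = alpha)
  names(res) <- c("Lu-BaA", "Lu-BaB", "BaA-BaB")
  res
}
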