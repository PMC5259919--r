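## Cross-technology concordance: per-CpG bisulfite-style beta values vs
## affinity-capture bin RMS, compared as means over 2-kb windows tiled
## across the targeted regions, with per-sample Pearson correlation.

#' Pair per-CpG betas with bin RMS over 2-kb windows
#'
#' Windows of \code{windowSize} bp are tiled from the start of each
#' (merged) target region; the last window of a region may be shorter.
#' Per window and sample, the beta side is the unweighted mean beta of
#' the CpG sites inside the window and the RMS side is the unweighted
#' mean RMS of the bins overlapping the window. Windows missing either
#' side are dropped and counted in the \code{nDropped} attribute.
#'
#' @param betas data.frame \code{chrom, pos, sample, beta} (extra
#'   columns ignored).
#' @param meth a \linkS4class{BinnedMethylation}.
#' @param targetRegions \code{GRanges} of the captured regions.
#' @param windowSize window width in bp (2000).
#' @return data.frame \code{chrom, start, end, sample, meanBeta,
#'   meanRms}; attributes \code{nWindows}, \code{nDropped} (counted as
#'   window-sample combinations among samples present in \code{betas}).
#' @export
binBetaRmsWindows <- function(betas, meth, targetRegions,
                              windowSize = 2000L) {
  stopifnot(all(c("chrom", "pos", "sample", "beta") %in% names(betas)))
  tr <- GenomicRanges::reduce(GenomicRanges::granges(targetRegions),
                              ignore.strand = TRUE)
  win <- unlist(GenomicRanges::slidingWindows(tr, width = windowSize,
                                              step = windowSize))
  bins <- SummarizedExperiment::rowRanges(meth)
  ovB <- GenomicRanges::findOverlaps(win, bins)
  R <- rms(meth)
  rmsMean <- rep(NA_real_, length(win))
  rmsBySample <- rowsum(R[S4Vectors::subjectHits(ovB), , drop = FALSE],
                        group = S4Vectors::queryHits(ovB))
  cnt <- tabulate(S4Vectors::queryHits(ovB), nbins = length(win))

  siteGr <- GenomicRanges::GRanges(betas$chrom,
                                   IRanges::IRanges(betas$pos, betas$pos))
  ovS <- GenomicRanges::findOverlaps(siteGr, win, select = "first")
  samples <- sort(unique(betas$sample))
  out <- vector("list", length(samples))
  nDropped <- 0L
  for (i in seq_along(samples)) {
    s <- samples[i]
    sel <- betas$sample == s & !is.na(ovS)
    w <- ovS[sel]
    mb <- tapply(betas$beta[sel], factor(w, levels = seq_along(win)), mean)
    haveBeta <- !is.na(mb)
    haveRms <- cnt > 0L & s %in% colnames(R)
    keep <- haveBeta & haveRms
    nDropped <- nDropped + sum(!keep)
    if (!any(keep)) next
    idx <- which(keep)
    mr <- rmsBySample[match(idx, as.integer(rownames(rmsBySample))), s] /
      cnt[idx]
    out[[i]] <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(win))[idx],
      start = GenomicRanges::start(win)[idx] - 1L,
      end = GenomicRanges::end(win)[idx],
      sample = s, meanBeta = as.vector(mb[keep]), meanRms = mr,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sample = character(0),
                      meanBeta = numeric(0), meanRms = numeric(0))
  attr(res, "nWindows") <- length(win) * length(samples)
  attr(res, "nDropped") <- nDropped
  res
}

#' Pearson concordance between paired window means
#'
#' @param pairs data.frame from \code{\link{binBetaRmsWindows}}.
#' @param minPairs minimum windows per sample (3).
#' @return data.frame with one row per sample (\code{sample, r, n}) and
#'   the cross-sample average as attribute \code{meanR}.
#' @export
pearsonConcordance <- function(pairs, minPairs = 3L) {
  sp <- split(pairs, pairs$sample)
  rows <- lapply(sp, function(d) {
    ok <- nrow(d) >= minPairs && sd(d$meanBeta) > 0 && sd(d$meanRms) > 0
    data.frame(sample = d$sample[1],
               r = if (ok) cor(d$meanBeta, d$meanRms) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "meanR") <- mean(out$r, na.rm = TRUE)
  out
}
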