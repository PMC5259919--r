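## CpG-island-relative methylation meta-profiles: absolute-coordinate
## flanks (default +/-500 bp in 100-bp steps) around islands rescaled to
## a fixed number of internal slices, per-subtype mean curves, per-island
## heatmap matrices, and position-wise one-way ANOVA across subtypes.

#' Compute an island-anchored methylation meta-profile
#'
#' The axis has \code{flankBp/step} left-flank positions (absolute bp
#' upstream of the island start), \code{kInternal} island-internal
#' slices (percent coordinates), and the mirrored right flank. A
#' position's value for one island and sample is the length-weighted
#' mean RMS of the bins overlapping that position's interval; islands
#' then contribute equally (unweighted mean over islands). Flank
#' positions that fall off the chromosome are NA for that island.
#'
#' @param meth a \linkS4class{BinnedMethylation}.
#' @param islands \code{GRanges} of CpG islands.
#' @param flankBp flank width in bp, a multiple of the bin size (500).
#' @param kInternal number of internal slices (20, i.e. 5\% steps).
#' @return object of class \code{MetaProfile}: list with
#'   \code{positions} (data.frame axis metadata), \code{sampleProfiles}
#'   (positions x samples, mean over islands), \code{subtypeCurves}
#'   (positions x subtypes), \code{islandMatrices} (per-subtype
#'   islands x positions heatmap matrices), \code{subtype}.
#' @export
computeMetaprofile <- function(meth, islands, flankBp = 500L,
                               kInternal = 20L) {
  stopifnot(is(meth, "BinnedMethylation"), length(islands) > 0,
            flankBp %% binSize(meth) == 0L, kInternal >= 1L)
  step <- binSize(meth)
  nF <- flankBp %/% step
  if (any(GenomicRanges::width(islands) < kInternal))
    warning("island(s) shorter than kInternal bp: slices will share bins")

  nI <- length(islands)
  s <- GenomicRanges::start(islands)
  e <- GenomicRanges::end(islands)
  chr <- as.character(GenomicRanges::seqnames(islands))
  L <- GenomicRanges::width(islands)
  nPos <- 2L * nF + kInternal

  ## per island, the genomic interval of every axis position
  posStart <- posEnd <- matrix(0, nI, nPos)
  for (j in seq_len(nF)) {                     # left flank
    posStart[, j] <- s - flankBp + (j - 1L) * step
    posEnd[, j] <- posStart[, j] + step - 1L
  }
  for (k in seq_len(kInternal)) {              # internal slices
    posStart[, nF + k] <- s + floor((k - 1) * L / kInternal)
    posEnd[, nF + k] <- s + ceiling(k * L / kInternal) - 1L
  }
  for (j in seq_len(nF)) {                     # right flank
    posStart[, nF + kInternal + j] <- e + 1L + (j - 1L) * step
    posEnd[, nF + kInternal + j] <- posStart[, nF + kInternal + j] + step - 1L
  }

  clampS <- pmax(as.vector(posStart), 1)
  clampE <- pmax(as.vector(posEnd), clampS - 1)  # zero width when off-chrom
  axisGr <- GenomicRanges::GRanges(
    rep(chr, nPos), IRanges::IRanges(clampS, clampE))
  sl <- GenomeInfoDb::seqlengths(meth)
  islandOf <- rep(seq_len(nI), nPos)
  posOf <- rep(seq_len(nPos), each = nI)
  valid <- as.vector(posEnd) >= 1 &
    as.vector(posStart) <= sl[rep(chr, nPos)]

  bins <- SummarizedExperiment::rowRanges(meth)
  R <- rms(meth)
  ov <- GenomicRanges::findOverlaps(axisGr[valid], bins)
  q <- S4Vectors::queryHits(ov); b <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(axisGr[valid])[q], IRanges::ranges(bins)[b]))
  num <- rowsum(w * R[b, , drop = FALSE], group = q)
  den <- rowsum(w, group = q)
  vals <- matrix(NA_real_, sum(valid), ncol(meth))
  vals[as.integer(rownames(num)), ] <- num / as.vector(den)
  values <- matrix(NA_real_, nI * nPos, ncol(meth))
  values[valid, ] <- vals

  sampleProfiles <- matrix(NA_real_, nPos, ncol(meth),
                           dimnames = list(NULL, colnames(meth)))
  for (p in seq_len(nPos)) {
    rows <- values[posOf == p, , drop = FALSE]
    sampleProfiles[p, ] <- colMeans(rows, na.rm = TRUE)
  }

  subtype <- subtypes(meth)
  lev <- levels(subtype)
  subtypeCurves <- vapply(lev, function(g)
    rowMeans(sampleProfiles[, subtype == g, drop = FALSE]),
    numeric(nPos))
  islandMatrices <- lapply(setNames(lev, lev), function(g) {
    m <- matrix(NA_real_, nI, nPos)
    sel <- subtype == g
    for (p in seq_len(nPos))
      m[, p] <- rowMeans(values[posOf == p, sel, drop = FALSE], na.rm = TRUE)
    m
  })

  positions <- data.frame(
    index = seq_len(nPos),
    type = rep(c("flank_left", "internal", "flank_right"),
               c(nF, kInternal, nF)),
    label = c(sprintf("%dbp", seq(-flankBp, -step, by = step)),
              sprintf("%.0f%%", (seq_len(kInternal) - 0.5) / kInternal * 100),
              sprintf("+%dbp", seq(step, flankBp, by = step))),
    boundaryAdjacent = c(seq_len(nF) == nF,
                         seq_len(kInternal) %in% c(1L, kInternal),
                         seq_len(nF) == 1L),
    stringsAsFactors = FALSE)
  structure(list(positions = positions, sampleProfiles = sampleProfiles,
                 subtypeCurves = subtypeCurves,
                 islandMatrices = islandMatrices, subtype = subtype),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat("MetaProfile:", nrow(x$positions), "axis positions,",
      ncol(x$sampleProfiles), "samples,",
      nrow(x$islandMatrices[[1]]), "islands\n")
  invisible(x)
}

#' Position-wise subtype ANOVA along the meta-profile axis
#'
#' At every axis position, a one-way ANOVA across subtypes on the
#' per-sample island-averaged values (one value per sample, so islands
#' are not treated as replicates), Bonferroni-corrected over axis
#' positions.
#'
#' @param profile a \code{MetaProfile} from
#'   \code{\link{computeMetaprofile}}.
#' @return data.frame: \code{index, label, p, pAdj}.
#' @export
positionwiseAnova <- function(profile) {
  stopifnot(inherits(profile, "MetaProfile"))
  subtype <- droplevels(profile$subtype)
  if (nlevels(subtype) < 2L || any(table(subtype) < 2L))
    stop("need >= 2 subtypes with >= 2 samples each")
  nPos <- nrow(profile$positions)
  p <- vapply(seq_len(nPos), function(i) {
    y <- profile$sampleProfiles[i, ]
    ok <- !is.na(y)
    if (length(unique(y[ok])) < 2L) return(NA_real_)
    oneway.test(y[ok] ~ subtype[ok], var.equal = TRUE)$p.value
  }, numeric(1))
  m <- sum(!is.na(p))
  data.frame(index = seq_len(nPos), label = profile$positions$label,
             p = p, pAdj = pmin(1, p * m), stringsAsFactors = FALSE)
}
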