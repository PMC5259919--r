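## CpG mutation analysis on pileup count tables: a binomial
## sequencing-error caller, methylation-stratified mutation rates with
## subtype ANOVA, subtype-specific mutation classification (>=30% of one
## subtype, <10% of each other), and regional counts of specific
## mutations.

#' Call CpG mutations from coverage/mismatch counts
#'
#' For every observation the one-sided binomial tail probability
#' \eqn{P[X \ge mismatches \mid coverage, seqError]} is computed; an
#' observation is called mutated when that probability is below
#' \code{callAlpha} and coverage is at least \code{minCoverage}.
#' Coverage above \code{maxReads} is capped, with mismatches subsampled
#' proportionally. This is an explicit count-based stand-in for a
#' pileup caller: users with real data can instead supply binary calls.
#'
#' @param obs data.frame with columns \code{chrom, pos, sample,
#'   coverage, mismatches, rms}.
#' @param seqError assumed per-base sequencing error rate (0.002).
#' @param callAlpha tail-probability threshold for a call (1e-3).
#' @param minCoverage minimum reads for a site to be callable (10).
#' @param maxReads coverage cap (250).
#' @return the input with added columns \code{pError}, \code{eligible}
#'   (coverage filter) and \code{isMutated}.
#' @export
callMutations <- function(obs, seqError = 0.002, callAlpha = 1e-3,
                          minCoverage = 10L, maxReads = 250L) {
  need <- c("chrom", "pos", "sample", "coverage", "mismatches")
  stopifnot(all(need %in% names(obs)), seqError > 0, seqError < 0.5)
  if (any(obs$mismatches > obs$coverage))
    stop(sum(obs$mismatches > obs$coverage),
         " record(s) with mismatches > coverage")
  if (any(obs$mismatches < 0 | obs$coverage < 0))
    stop("negative counts in observation table")
  cov <- obs$coverage
  mm <- obs$mismatches
  over <- cov > maxReads
  if (any(over)) {
    mm[over] <- round(mm[over] * maxReads / cov[over])
    cov[over] <- maxReads
  }
  pErr <- ifelse(mm == 0, 1,
                 pbinom(mm - 1L, cov, seqError, lower.tail = FALSE))
  obs$pError <- pErr
  obs$eligible <- cov >= minCoverage
  obs$isMutated <- obs$eligible & pErr < callAlpha
  attr(obs, "callAlpha") <- callAlpha
  attr(obs, "seqError") <- seqError
  obs
}

.makeStrata <- function(stratumWidth = 0.05) {
  lo <- seq(0, 1 - stratumWidth, by = stratumWidth)
  data.frame(lo = lo, hi = c(lo[-1], 1.0000001),
             label = sprintf("[%.2f,%.2f)", lo, c(lo[-1], 1)))
}

.stratumOf <- function(rms, strata) {
  findInterval(rms, c(strata$lo, strata$hi[nrow(strata)]),
               rightmost.closed = TRUE, all.inside = TRUE)
}

#' Mutation rate by methylation stratum and subtype
#'
#' The mutation rate of a subtype in a methylation stratum is the number
#' of mutated site-sample observations over the number of eligible
#' (covered) site-sample observations whose bin RMS falls in the
#' stratum. Empty strata give NA, not 0.
#'
#' @param calls output of \code{\link{callMutations}} (or a table with
#'   \code{sample, rms, eligible, isMutated}).
#' @param subtype named factor: subtype per sample name.
#' @param stratumWidth methylation stratum width over \[0,1\] (0.05).
#' @return data.frame: \code{stratum, lo, hi, subtype, nSites,
#'   nMutated, rate}.
#' @export
mutationRateByMethylation <- function(calls, subtype, stratumWidth = 0.05) {
  stopifnot(all(c("sample", "rms", "eligible", "isMutated") %in%
                  names(calls)))
  strata <- .makeStrata(stratumWidth)
  el <- calls[calls$eligible, , drop = FALSE]
  st <- as.character(subtype[el$sample])
  k <- .stratumOf(el$rms, strata)
  lev <- levels(factor(subtype))
  grid <- expand.grid(stratum = seq_len(nrow(strata)), subtype = lev,
                      stringsAsFactors = FALSE)
  keyAll <- paste(k, st)
  keyGrid <- paste(grid$stratum, grid$subtype)
  nSites <- as.vector(table(factor(keyAll, levels = keyGrid)))
  nMut <- as.vector(tapply(el$isMutated,
                           factor(keyAll, levels = keyGrid), sum))
  nMut[is.na(nMut)] <- 0L
  data.frame(stratum = grid$stratum,
             lo = strata$lo[grid$stratum], hi = pmin(strata$hi, 1)[grid$stratum],
             subtype = grid$subtype,
             nSites = nSites, nMutated = as.integer(nMut),
             rate = ifelse(nSites > 0, nMut / nSites, NA_real_),
             stringsAsFactors = FALSE)
}

#' Per-sample mutation rates per methylation stratum
#'
#' The unit of analysis for \code{\link{stratumAnova}}: one rate per
#' sample per stratum (NA when the sample has no eligible observation in
#' the stratum).
#'
#' @inheritParams mutationRateByMethylation
#' @return matrix strata x samples of rates.
#' @export
perSampleStratumRates <- function(calls, subtype, stratumWidth = 0.05) {
  strata <- .makeStrata(stratumWidth)
  samples <- names(subtype)
  el <- calls[calls$eligible, , drop = FALSE]
  k <- .stratumOf(el$rms, strata)
  sIdx <- match(el$sample, samples)
  key <- factor(paste(k, sIdx),
                levels = paste(rep(seq_len(nrow(strata)), length(samples)),
                               rep(seq_along(samples),
                                   each = nrow(strata))))
  n <- as.vector(table(key))
  mut <- as.vector(tapply(el$isMutated, key, sum))
  r <- ifelse(n > 0, mut / n, NA_real_)
  matrix(r, nrow = nrow(strata), ncol = length(samples),
         dimnames = list(strata$label, samples))
}

#' One-way ANOVA of per-sample mutation rates across subtypes
#'
#' Per stratum, the per-sample rates are compared across subtypes by
#' one-way ANOVA; p-values are Bonferroni-corrected over the strata
#' actually tested (those with at least 2 samples per subtype carrying
#' a rate).
#'
#' @param rates strata x samples matrix from
#'   \code{\link{perSampleStratumRates}}.
#' @param subtype named factor: subtype per sample.
#' @param alpha Bonferroni-adjusted significance level (0.05).
#' @return data.frame: \code{stratum, label, p, pAdj, significant}
#'   (significance at Bonferroni-adjusted 0.05).
#' @export
stratumAnova <- function(rates, subtype, alpha = 0.05) {
  subtype <- droplevels(factor(subtype[colnames(rates)]))
  p <- vapply(seq_len(nrow(rates)), function(i) {
    y <- rates[i, ]
    ok <- !is.na(y)
    if (any(table(subtype[ok]) < 2L) || length(unique(y[ok])) < 2L)
      return(NA_real_)
    oneway.test(y[ok] ~ subtype[ok], var.equal = TRUE)$p.value
  }, numeric(1))
  m <- sum(!is.na(p))
  pAdj <- pmin(1, p * m)
  data.frame(stratum = seq_len(nrow(rates)), label = rownames(rates),
             p = p, pAdj = pAdj,
             significant = !is.na(pAdj) & pAdj < alpha,
             stringsAsFactors = FALSE)
}

#' Classify subtype-specific mutations
#'
#' A site is specific to a subtype iff the fraction of that subtype's
#' samples carrying a mutation call is at least \code{minIn} while the
#' carrier fraction in each other subtype is below \code{maxOut}. With
#' \code{minIn > maxOut} a site can match at most one subtype.
#'
#' @param calls output of \code{\link{callMutations}}.
#' @param subtype named factor: subtype per sample (denominators are the
#'   full per-subtype sample counts).
#' @param minIn minimum carrier fraction in the assigned subtype (0.30).
#' @param maxOut maximum carrier fraction in each other subtype (0.10).
#' @return data.frame: \code{chrom, pos, assigned} plus one
#'   \code{freq_<subtype>} column per subtype; only assigned sites are
#'   returned.
#' @export
classifySubtypeSpecific <- function(calls, subtype, minIn = 0.30,
                                    maxOut = 0.10) {
  if (minIn <= maxOut)
    stop("minIn must exceed maxOut, otherwise assignment is ambiguous")
  lev <- levels(factor(subtype))
  nPer <- table(factor(subtype, levels = lev))
  mut <- calls[calls$isMutated, , drop = FALSE]
  if (!nrow(mut))
    return(.emptySpecific(lev))
  st <- as.character(subtype[mut$sample])
  site <- paste(mut$chrom, mut$pos)
  tab <- table(factor(site), factor(st, levels = lev))
  freq <- sweep(unclass(tab), 2L, as.numeric(nPer), "/")
  qual <- freq >= minIn
  othersOk <- vapply(seq_along(lev), function(j)
    apply(freq[, -j, drop = FALSE] < maxOut, 1L, all), logical(nrow(freq)))
  if (is.null(dim(othersOk)))
    othersOk <- matrix(othersOk, nrow = 1)
  assignable <- qual & othersOk
  hit <- which(rowSums(assignable) > 0L)
  if (!length(hit))
    return(.emptySpecific(lev))
  assigned <- lev[apply(assignable[hit, , drop = FALSE], 1L, which.max)]
  key <- rownames(freq)[hit]
  parts <- do.call(rbind, strsplit(key, " "))
  out <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                    assigned = assigned, stringsAsFactors = FALSE)
  fr <- as.data.frame(freq[hit, , drop = FALSE])
  names(fr) <- paste0("freq_", lev)
  out <- cbind(out, fr, row.names = NULL)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

.emptySpecific <- function(lev) {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    assigned = character(0), stringsAsFactors = FALSE)
  for (l in lev) out[[paste0("freq_", l)]] <- numeric(0)
  out
}

#' Regional counts of subtype-specific mutations with subtype ANOVA
#'
#' Counts assigned sites per region class per assigned subtype, and per
#' region runs a one-way ANOVA across subtypes on per-sample carrier
#' counts (for each sample, the number of specific sites in the region
#' at which it carries a mutation call), Bonferroni-corrected over
#' regions.
#'
#' @param specific output of \code{\link{classifySubtypeSpecific}}.
#' @param calls output of \code{\link{callMutations}}.
#' @param meth a \linkS4class{BinnedMethylation} with labels assigned
#'   (provides the bin tiling and region labels for the sites).
#' @param regionClasses region classes to report.
#' @param alpha Bonferroni-adjusted significance level (0.05).
#' @return list with \code{counts} (region x subtype matrix) and
#'   \code{anova} (data.frame region, p, pAdj, significant).
#' @export
regionalMutationCounts <- function(specific, calls, meth,
                                   regionClasses = c("CpGI", "shore",
                                                     "shelf", "promoter",
                                                     "exon", "intron",
                                                     "intergenic"),
                                   alpha = 0.05) {
  labels <- binLabels(meth)
  stopifnot(!is.null(labels))
  subtype <- subtypes(meth)
  lev <- levels(subtype)
  samples <- colnames(meth)
  bins <- SummarizedExperiment::rowRanges(meth)
  counts <- matrix(0L, length(regionClasses), length(lev),
                   dimnames = list(regionClasses, lev))
  anovaP <- rep(NA_real_, length(regionClasses))
  if (nrow(specific)) {
    siteGr <- GenomicRanges::GRanges(specific$chrom,
                                     IRanges::IRanges(specific$pos,
                                                      specific$pos))
    binOf <- GenomicRanges::findOverlaps(siteGr, bins, select = "first")
    siteKey <- paste(specific$chrom, specific$pos)
    mut <- calls[calls$isMutated, , drop = FALSE]
    mutKey <- paste(mut$chrom, mut$pos)
    for (ri in seq_along(regionClasses)) {
      inRegion <- !is.na(binOf) &
        .hasLabel(labels[ifelse(is.na(binOf), 1L, binOf)],
                  regionClasses[ri]) & !is.na(binOf)
      if (!any(inRegion)) next
      counts[ri, ] <- as.vector(table(
        factor(specific$assigned[inRegion], levels = lev)))
      ## per-sample carrier counts over this region's specific sites
      sel <- mutKey %in% siteKey[inRegion]
      perSample <- as.vector(table(factor(mut$sample[sel],
                                          levels = samples)))
      if (length(unique(perSample)) >= 2L &&
          all(table(subtype) >= 2L))
        anovaP[ri] <- oneway.test(perSample ~ subtype,
                                  var.equal = TRUE)$p.value
    }
  }
  m <- sum(!is.na(anovaP))
  pAdj <- pmin(1, anovaP * max(m, 1L))
  list(counts = counts,
       anova = data.frame(region = regionClasses, p = anovaP,
                          pAdj = pAdj,
                          significant = !is.na(pAdj) & pAdj < alpha,
                          stringsAsFactors = FALSE))
}
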