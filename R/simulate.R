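## Synthetic study generator. Emulates a three-subtype breast cancer cell
## line panel profiled by affinity-capture methylation sequencing:
## a toy annotated genome (islands, genes, TFBS), subtype-structured bin
## methylation with basal-B shore hypomethylation and island-boundary
## methylation peaks in luminal/basal A, expression inversely coupled to
## promoter-TFBS methylation for a planted gene set, and CpG pileup
## observations whose mutation probability is a step function of the
## methylation level with subtype-specific rates and planted
## subtype-specific sites. Every stage is deterministic given the seed.

#' Simulation configuration
#'
#' Builds and validates the parameter list consumed by
#' \code{\link{simulateStudy}} and the individual \code{simulate*}
#' stages. Defaults define the reference desk-scale study: 10 cell lines
#' per subtype (luminal, basal A, basal B), 50 CpG islands whose 2 kb
#' shores tile into exactly 2,000 100-bp shore bins, 200 of which carry a
#' basal-B hypomethylation effect of -0.3 RMS, truncated-normal bin noise
#' of sd 0.1, and 20 genes whose expression is inversely coupled to the
#' methylation of TFBS planted in their promoter-shore overlap.
#'
#' @param seed integer RNG seed; every stage derives its stream from it.
#' @param nChroms,chromLen toy genome geometry (chromosomes of equal
#'   length, bp).
#' @param nIslands number of CpG islands, spread evenly over chromosomes.
#' @param islandLenRange island length range in bp (snapped to the bin
#'   grid).
#' @param nGenes number of genes (each anchored at an island TSS;
#'   alternating strand).
#' @param nCoupledGenes genes with expression inversely coupled to
#'   promoter-TFBS methylation (first \code{nCoupledGenes} genes).
#' @param nTfbsPerPromoter TFBS planted per promoter.
#' @param nTfs number of transcription factors (round-robin assignment);
#'   TF expression is subtype-invariant by construction.
#' @param samplesPerSubtype named vector of sample counts.
#' @param regionMeanRms baseline mean RMS per region class.
#' @param shoreHypoEffect RMS shift applied to basal B samples on the
#'   planted shore bins (default -0.3).
#' @param nPlantedShoreBins total planted shore bins (split evenly over
#'   the coupled genes' promoter-side shores).
#' @param boundaryPeakEffect,boundaryPeakBins island-boundary methylation
#'   peak (+RMS on the \code{boundaryPeakBins} shore bins adjacent to
#'   each island end) applied to luminal and basal A samples only.
#' @param noiseSd per-cell RMS noise sd (values clamped to \[0,1\]).
#' @param geneLen,tfbsLen lengths in bp.
#' @param shoreWidth,shelfWidth,promoterLen annotation widths in bp.
#' @param binSize methylation bin width in bp.
#' @param exprBaseline,couplingStrength,exprNoiseSd expression model:
#'   coupled gene expression = baseline - coupling * promoter TFBS RMS +
#'   Normal(0, exprNoiseSd) noise (log-intensity scale).
#' @param nSites background CpG sites for the mutation table.
#' @param meanCoverage,maxReads coverage model: Poisson(meanCoverage)
#'   capped at maxReads.
#' @param seqError per-base sequencing error rate for non-mutated sites.
#' @param mutationRateLow,mutationRateHigh named per-subtype mutation
#'   probabilities below / at-or-above \code{rateStepRms}.
#' @param rateStepRms methylation level at which the rate steps.
#' @param specificFraction planted subtype-specific sites as a fraction
#'   of \code{nSites}; basal A specific sites are placed in
#'   CpGI/shore/shelf bins and basal B specific sites in intron bins.
#' @param homFraction fraction of mutation events that are homozygous
#'   (mismatch fraction near 1 instead of 0.5).
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nChroms = 2L, chromLen = 1e6,
                      nIslands = 50L, islandLenRange = c(500L, 1500L),
                      nGenes = 40L, nCoupledGenes = 20L,
                      nTfbsPerPromoter = 2L, nTfs = 5L,
                      samplesPerSubtype = c(luminal = 10L, basalA = 10L,
                                            basalB = 10L),
                      regionMeanRms = c(CpGI = 0.15, shore = 0.45,
                                        shelf = 0.6, gene = 0.7,
                                        intergenic = 0.65),
                      shoreHypoEffect = -0.3, nPlantedShoreBins = 200L,
                      boundaryPeakEffect = 0.2, boundaryPeakBins = 2L,
                      noiseSd = 0.1,
                      geneLen = 3000L, tfbsLen = 20L,
                      shoreWidth = 2000L, shelfWidth = 2000L,
                      promoterLen = 2000L, binSize = 100L,
                      exprBaseline = 8, couplingStrength = 3,
                      exprNoiseSd = 0.3,
                      nSites = 2000L, meanCoverage = 30, maxReads = 250L,
                      seqError = 0.002,
                      mutationRateLow = c(luminal = 0.01, basalA = 0.03,
                                          basalB = 0.01),
                      mutationRateHigh = c(luminal = 0.05, basalA = 0.05,
                                           basalB = 0.15),
                      rateStepRms = 0.5,
                      specificFraction = 0.05, homFraction = 0.2) {
  cfg <- as.list(environment())
  st <- c("luminal", "basalA", "basalB")
  stopifnot(
    cfg$seed == as.integer(cfg$seed),
    cfg$nChroms >= 1, cfg$chromLen > 0, cfg$nIslands >= 0,
    cfg$nGenes <= cfg$nIslands, cfg$nCoupledGenes <= cfg$nGenes,
    all(st %in% names(cfg$samplesPerSubtype)),
    all(cfg$samplesPerSubtype > 0),
    all(cfg$regionMeanRms >= 0 & cfg$regionMeanRms <= 1),
    all(c("CpGI", "shore", "shelf", "gene", "intergenic") %in%
          names(cfg$regionMeanRms)),
    cfg$noiseSd >= 0, cfg$binSize > 0,
    cfg$nPlantedShoreBins %% max(cfg$nCoupledGenes, 1L) == 0,
    all(st %in% names(cfg$mutationRateLow)),
    all(st %in% names(cfg$mutationRateHigh)),
    all(unlist(cfg[c("mutationRateLow", "mutationRateHigh")]) >= 0),
    all(unlist(cfg[c("mutationRateLow", "mutationRateHigh")]) <= 1),
    cfg$seqError > 0, cfg$seqError < 0.5,
    cfg$specificFraction >= 0, cfg$specificFraction <= 1)
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig: seed", x$seed, "|", x$nChroms, "chrom x",
      format(x$chromLen, big.mark = ","), "bp |", x$nIslands, "islands |",
      x$nGenes, "genes (", x$nCoupledGenes, "coupled ) |",
      sum(x$samplesPerSubtype), "samples\n")
  invisible(x)
}

.subtypeVector <- function(cfg) {
  st <- c("luminal", "basalA", "basalB")
  n <- cfg$samplesPerSubtype[st]
  pref <- c(luminal = "Lu", basalA = "BaA", basalB = "BaB")
  samples <- unlist(lapply(st, function(s)
    sprintf("%s%02d", pref[[s]], seq_len(n[[s]]))))
  setNames(factor(rep(st, n), levels = st), samples)
}

#' Generate the toy annotated genome
#'
#' Islands are placed on the bin grid, evenly spaced so that islands,
#' 2 kb shores and 2 kb shelves never collide. Each gene is anchored at
#' an island: odd genes on the + strand with the TSS at the island start
#' (promoter = the left shore), even genes on the - strand with the TSS
#' at the island end (promoter = the right shore). TFBS are planted
#' inside the promoter-shore overlap, in the island-adjacent half for
#' coupled genes so they sit on the planted differentially methylated
#' bins.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return list with elements \code{chromSizes}, \code{islands},
#'   \code{genes}, \code{exons}, \code{tfbs} (GRanges with tfbs_id),
#'   \code{tfbsLinks} (data.frame tfbs_id, tf_id, target_gene,
#'   validated), \code{regions} (the labelled region set), and
#'   \code{truth} (planted shore-bin GRanges and coupled gene ids).
#' @export
simulateGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  chromSizes <- setNames(rep(as.integer(cfg$chromLen), cfg$nChroms),
                         paste0("chr", seq_len(cfg$nChroms)))
  perChrom <- ceiling(cfg$nIslands / cfg$nChroms)
  spacing <- floor(cfg$chromLen / perChrom)
  margin <- cfg$shoreWidth + cfg$shelfWidth + cfg$geneLen
  if (cfg$nIslands > 0 &&
      spacing < max(cfg$islandLenRange) + 2 * margin)
    stop("infeasible geometry: islands too dense for shores/shelves/genes")
  lens <- if (cfg$nIslands)
    sample(seq(cfg$islandLenRange[1], cfg$islandLenRange[2],
               by = cfg$binSize), cfg$nIslands, replace = TRUE) else integer(0)
  idx <- seq_len(cfg$nIslands) - 1L
  chrom <- if (cfg$nIslands) paste0("chr", (idx %/% perChrom) + 1L)
           else character(0)
  within <- idx %% perChrom
  start0 <- within * spacing + margin          # 0-based, on the bin grid
  start0 <- (start0 %/% cfg$binSize) * cfg$binSize
  islands <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start0 + 1L, start0 + lens),
    seqlengths = chromSizes)

  ## genes anchored at islands, alternating strand
  gi <- seq_len(cfg$nGenes)
  strand <- if (length(gi)) ifelse(gi %% 2L == 1L, "+", "-") else character(0)
  gStart <- ifelse(strand == "+", GenomicRanges::start(islands)[gi],
                   GenomicRanges::end(islands)[gi] - cfg$geneLen + 1L)
  genes <- GenomicRanges::GRanges(
    chrom[gi], IRanges::IRanges(gStart, gStart + cfg$geneLen - 1L),
    strand = strand, gene_id = sprintf("gene%03d", gi),
    seqlengths = chromSizes)
  ## three exons at fixed offsets within the gene body (strand-agnostic)
  exOff <- rbind(c(0L, 299L), c(1199L, 1499L), c(2699L, 2999L))
  exons <- GenomicRanges::GRanges(
    rep(chrom[gi], each = 3L),
    IRanges::IRanges(rep(gStart, each = 3L) + exOff[, 1],
                     rep(gStart, each = 3L) + exOff[, 2]),
    strand = rep(strand, each = 3L),
    gene_id = rep(sprintf("gene%03d", gi), each = 3L),
    seqlengths = chromSizes)

  ## TFBS inside promoter-shore overlap; island-adjacent 1 kb for coupled
  tfbsList <- vector("list", cfg$nGenes)
  for (g in gi) {
    coupled <- g <= cfg$nCoupledGenes
    isl <- islands[g]
    if (strand[g] == "+") {
      hi <- GenomicRanges::start(isl) - 1L
      lo <- hi - (if (coupled) 1000L else cfg$promoterLen) + 1L
    } else {
      lo <- GenomicRanges::end(isl) + 1L
      hi <- lo + (if (coupled) 1000L else cfg$promoterLen) - 1L
    }
    pos <- sort(sample(lo:(hi - cfg$tfbsLen), cfg$nTfbsPerPromoter))
    tfbsList[[g]] <- GenomicRanges::GRanges(
      chrom[g], IRanges::IRanges(pos, pos + cfg$tfbsLen - 1L),
      seqlengths = chromSizes)
  }
  tfbs <- if (length(tfbsList)) do.call(c, tfbsList)
  else GenomicRanges::GRanges(seqlengths = chromSizes)
  nT <- length(tfbs)
  S4Vectors::mcols(tfbs)$tfbs_id <- sprintf("tfbs%04d", seq_len(nT))
  geneOfTfbs <- rep(sprintf("gene%03d", gi), each = cfg$nTfbsPerPromoter)
  tfbsLinks <- data.frame(
    tfbs_id = S4Vectors::mcols(tfbs)$tfbs_id,
    tf_id = sprintf("TF%02d", (seq_len(nT) - 1L) %% cfg$nTfs + 1L),
    target_gene = geneOfTfbs,
    validated = rep(TRUE, nT),
    stringsAsFactors = FALSE)

  regions <- buildRegionSet(islands, genes, exons, tfbs,
                            shoreWidth = cfg$shoreWidth,
                            shelfWidth = cfg$shelfWidth,
                            promoterLen = cfg$promoterLen)

  ## planted shore bins: island-adjacent promoter-side bins of coupled genes
  binsPerGene <- if (cfg$nCoupledGenes)
    cfg$nPlantedShoreBins %/% cfg$nCoupledGenes else 0L
  planted <- GenomicRanges::GRanges(seqlengths = chromSizes)
  if (binsPerGene > 0L && cfg$nCoupledGenes > 0L) {
    cg <- seq_len(cfg$nCoupledGenes)
    isl <- islands[cg]
    left <- strand[cg] == "+"
    s0 <- ifelse(left,
                 GenomicRanges::start(isl) - binsPerGene * cfg$binSize,
                 GenomicRanges::end(isl) + 1L)
    planted <- GenomicRanges::GRanges(
      chrom[cg],
      IRanges::IRanges(s0, s0 + binsPerGene * cfg$binSize - 1L),
      seqlengths = chromSizes)
  }
  list(chromSizes = chromSizes, islands = islands, genes = genes,
       exons = exons, tfbs = tfbs, tfbsLinks = tfbsLinks,
       regions = regions,
       truth = list(plantedShoreRegions = planted,
                    coupledGenes = sprintf("gene%03d",
                                           seq_len(cfg$nCoupledGenes))))
}

#' Simulate the subtype-structured bin methylation matrix
#'
#' Each bin gets a baseline mean from its region class (island < shelf <
#' shore, by default), plus subtype effects: an island-boundary peak
#' (+\code{boundaryPeakEffect}) on the shore bins adjacent to each island
#' end in luminal and basal A, and the planted shore hypomethylation
#' (\code{shoreHypoEffect}) in basal B, plus Normal(0, noiseSd) noise,
#' clamped to \[0,1\].
#'
#' @param genome output of \code{\link{simulateGenome}}.
#' @param cfg the \code{\link{simConfig}}.
#' @return a \linkS4class{BinnedMethylation} with region labels assigned
#'   and the planted-bin truth in \code{metadata()$truth}.
#' @export
simulateMethylation <- function(genome, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  bins <- makeBinIndex(genome$chromSizes, cfg$binSize)
  labels <- assignBins(bins, genome$regions)
  base <- .binBaseline(labels, cfg$regionMeanRms)

  subtype <- .subtypeVector(cfg)
  nS <- length(subtype)
  effect <- matrix(0, nrow = length(bins), ncol = 3,
                   dimnames = list(NULL, c("luminal", "basalA", "basalB")))
  if (length(genome$islands) && cfg$boundaryPeakBins > 0 &&
      cfg$boundaryPeakEffect != 0) {
    w <- cfg$boundaryPeakBins * cfg$binSize
    leftFlank <- GenomicRanges::trim(suppressWarnings(
      GenomicRanges::flank(genome$islands, width = w, start = TRUE)))
    rightFlank <- GenomicRanges::trim(suppressWarnings(
      GenomicRanges::flank(genome$islands, width = w, start = FALSE)))
    bb <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      bins, c(leftFlank, rightFlank))))
    effect[bb, c("luminal", "basalA")] <-
      effect[bb, c("luminal", "basalA")] + cfg$boundaryPeakEffect
  }
  plantedBins <- integer(0)
  if (length(genome$truth$plantedShoreRegions)) {
    plantedBins <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
      bins, genome$truth$plantedShoreRegions, type = "within")))
    effect[plantedBins, "basalB"] <-
      effect[plantedBins, "basalB"] + cfg$shoreHypoEffect
  }
  mu <- base + effect[, as.character(subtype), drop = FALSE]
  m <- mu + matrix(rnorm(length(bins) * nS, sd = cfg$noiseSd),
                   nrow = length(bins))
  m <- pmin(pmax(m, 0), 1)
  colnames(m) <- names(subtype)
  bm <- BinnedMethylation(m, bins, subtype, binSize = cfg$binSize)
  SummarizedExperiment::rowData(bm)$labels <- labels
  S4Vectors::metadata(bm)$truth <- list(
    plantedBins = sort(plantedBins),
    plantedShoreRegions = genome$truth$plantedShoreRegions)
  bm
}

## baseline mean per bin from its label set (priority island > shore >
## shelf > genic > intergenic)
.binBaseline <- function(labels, regionMeanRms) {
  genic <- c("gene", "exon", "intron", "promoter", "TFBS", "UTR5", "UTR3")
  base <- rep(regionMeanRms[["intergenic"]], length(labels))
  base[.hasLabel(labels, genic)] <- regionMeanRms[["gene"]]
  for (l in c("shelf", "shore", "CpGI"))
    base[.hasLabel(labels, l)] <- regionMeanRms[[l]]
  base
}

#' Simulate gene expression coupled to promoter-TFBS methylation
#'
#' Coupled genes follow \code{baseline - coupling * (mean TFBS RMS) +
#' noise}; uncoupled genes and TF genes are subtype-invariant noise
#' around the baseline, so the TF-similarity filter is satisfiable by
#' construction.
#'
#' @param meth \linkS4class{BinnedMethylation} from
#'   \code{\link{simulateMethylation}}.
#' @param genome output of \code{\link{simulateGenome}}.
#' @param cfg the \code{\link{simConfig}}.
#' @return \code{SummarizedExperiment} (assay \code{exprs}, genes +
#'   TF genes in rows) with coupled-gene truth in \code{metadata()$truth}.
#' @export
simulateExpression <- function(meth, genome, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 2L)
  subtype <- subtypes(meth)
  nS <- ncol(meth)
  tm <- tfbsMethylation(meth, genome$tfbs)
  geneIds <- unique(genome$tfbsLinks$target_gene)
  promMeth <- do.call(rbind, lapply(geneIds, function(g) {
    ids <- genome$tfbsLinks$tfbs_id[genome$tfbsLinks$target_gene == g]
    colMeans(tm[rownames(tm) %in% ids, , drop = FALSE])
  }))
  rownames(promMeth) <- geneIds
  coupled <- genome$truth$coupledGenes
  expr <- matrix(cfg$exprBaseline, nrow = length(geneIds), ncol = nS,
                 dimnames = list(geneIds, colnames(meth)))
  expr[coupled, ] <- cfg$exprBaseline -
    cfg$couplingStrength * promMeth[coupled, , drop = FALSE]
  expr <- expr + matrix(rnorm(length(expr), sd = cfg$exprNoiseSd),
                        nrow = nrow(expr))
  unc <- setdiff(geneIds, coupled)
  expr[unc, ] <- expr[unc, ] +
    matrix(rnorm(length(unc) * nS, sd = 0.6), nrow = length(unc))
  tfIds <- sort(unique(genome$tfbsLinks$tf_id))
  tfExpr <- cfg$exprBaseline +
    matrix(rnorm(length(tfIds) * nS, sd = 0.5), nrow = length(tfIds),
           dimnames = list(tfIds, colnames(meth)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = rbind(expr, tfExpr)),
    colData = S4Vectors::DataFrame(subtype = subtype,
                                   row.names = colnames(meth)))
  S4Vectors::metadata(se)$truth <- list(coupledGenes = coupled)
  se
}

#' Simulate per-CpG-site pileup observations
#'
#' Background sites are scattered uniformly over bins; per site and
#' sample the mutation probability is a step function of that sample's
#' bin RMS (\code{mutationRateLow} below \code{rateStepRms},
#' \code{mutationRateHigh} at or above it, per subtype). A configured
#' fraction of extra sites is planted as subtype-specific (carried by
#' 35-60\% of one subtype's samples, absent elsewhere), with basal A
#' specific sites restricted to CpGI/shore/shelf bins and basal B
#' specific sites to intron bins. Coverage is Poisson(meanCoverage)
#' capped at maxReads; mutated observations draw mismatches at fraction
#' 0.5 (het) or ~1 (hom), others at the sequencing error rate.
#'
#' @param meth \linkS4class{BinnedMethylation} with labels assigned.
#' @param cfg the \code{\link{simConfig}}.
#' @return list with \code{sites} (data.frame chrom, pos, sample,
#'   coverage, mismatches, rms), \code{events} (logical site x sample
#'   truth matrix), and \code{truth} (planted subtype-specific sites).
#' @export
simulateMutations <- function(meth, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 3L)
  bins <- SummarizedExperiment::rowRanges(meth)
  labels <- binLabels(meth)
  stopifnot(!is.null(labels))
  subtype <- subtypes(meth)
  nS <- ncol(meth)
  R <- rms(meth)

  bgBin <- sample.int(length(bins), cfg$nSites, replace = TRUE)
  nSpec <- round(cfg$specificFraction * cfg$nSites)
  specSub <- rep(c("basalA", "basalB", "luminal"), length.out = nSpec)
  pickBins <- function(pool, n) {
    if (n == 0L) return(integer(0))
    if (!length(pool)) pool <- seq_along(bins)   # degenerate genome
    pool[sample.int(length(pool), n, replace = TRUE)]
  }
  cpgRelated <- .hasLabel(labels, c("CpGI", "shore", "shelf"))
  specBin <- integer(nSpec)
  specBin[specSub == "basalA"] <-
    pickBins(which(cpgRelated), sum(specSub == "basalA"))
  ## intron-only bins, so the intron enrichment is not confounded with
  ## islands/shores that gene bodies overlap
  specBin[specSub == "basalB"] <-
    pickBins(which(.hasLabel(labels, "intron") & !cpgRelated),
             sum(specSub == "basalB"))
  specBin[specSub == "luminal"] <-
    sample.int(length(bins), sum(specSub == "luminal"), replace = TRUE)

  allBin <- c(bgBin, specBin)
  off <- floor(runif(length(allBin)) * GenomicRanges::width(bins)[allBin])
  pos <- GenomicRanges::start(bins)[allBin] + as.integer(off)
  chrom <- as.character(GenomicRanges::seqnames(bins))[allBin]
  ## de-duplicate colliding positions by nudging within the bin
  key <- paste(chrom, pos)
  while (anyDuplicated(key)) {
    d <- which(duplicated(key))
    pos[d] <- GenomicRanges::start(bins)[allBin[d]] +
      as.integer(floor(runif(length(d)) * GenomicRanges::width(bins)[allBin[d]]))
    key <- paste(chrom, pos)
  }
  nSite <- length(allBin)

  siteRms <- R[allBin, , drop = FALSE]          # site x sample
  pLow <- cfg$mutationRateLow[as.character(subtype)]
  pHigh <- cfg$mutationRateHigh[as.character(subtype)]
  pMat <- ifelse(siteRms < cfg$rateStepRms,
                 matrix(pLow, nSite, nS, byrow = TRUE),
                 matrix(pHigh, nSite, nS, byrow = TRUE))
  events <- matrix(runif(nSite * nS) < pMat, nSite, nS)
  ## planted subtype-specific sites override the background process
  if (nSpec > 0) {
    for (i in seq_len(nSpec)) {
      row <- cfg$nSites + i
      events[row, ] <- FALSE
      mem <- which(subtype == specSub[i])
      k <- sample(seq(ceiling(0.35 * length(mem)),
                      floor(0.60 * length(mem))), 1L)
      events[row, sample(mem, k)] <- TRUE
    }
  }

  cov <- matrix(pmin(rpois(nSite * nS, cfg$meanCoverage), cfg$maxReads),
                nSite, nS)
  hom <- matrix(runif(nSite * nS) < cfg$homFraction, nSite, nS)
  mm <- matrix(rbinom(nSite * nS, as.vector(cov), cfg$seqError), nSite, nS)
  het <- events & !hom
  mm[het] <- rbinom(sum(het), cov[het], 0.5)
  hm <- events & hom
  mm[hm] <- rbinom(sum(hm), cov[hm], 0.98)

  sites <- data.frame(
    chrom = rep(chrom, nS),
    pos = rep(pos, nS),
    sample = rep(colnames(meth), each = nSite),
    coverage = as.vector(cov),
    mismatches = as.vector(mm),
    rms = as.vector(siteRms),
    stringsAsFactors = FALSE)
  truthSpec <- if (nSpec > 0)
    data.frame(chrom = chrom[cfg$nSites + seq_len(nSpec)],
               pos = pos[cfg$nSites + seq_len(nSpec)],
               subtype = specSub, stringsAsFactors = FALSE)
  else data.frame(chrom = character(0), pos = integer(0),
                  subtype = character(0))
  list(sites = sites,
       events = events,
       siteBin = allBin,
       truth = list(specificSites = truthSpec))
}

#' Simulate per-CpG bisulfite-style beta values over target regions
#'
#' Emulates targeted bisulfite sequencing of a sample subset: CpG sites
#' every \code{siteSpacing} bp inside the target regions, with beta =
#' bin RMS + Normal(0, betaNoiseSd), clamped to \[0,1\].
#'
#' @param meth \linkS4class{BinnedMethylation}.
#' @param targetRegions \code{GRanges} of captured regions.
#' @param samples character vector of sample names to emit (default: the
#'   first two per subtype, mirroring a six-sample validation panel).
#' @param cfg the \code{\link{simConfig}}.
#' @param siteSpacing,betaNoiseSd site density and beta noise.
#' @return data.frame(chrom, pos, sample, beta, coverage).
#' @export
simulateBetas <- function(meth, targetRegions, cfg, samples = NULL,
                          siteSpacing = 50L, betaNoiseSd = 0.05) {
  set.seed(cfg$seed + 4L)
  subtype <- subtypes(meth)
  if (is.null(samples))
    samples <- unlist(lapply(split(colnames(meth), subtype), head, 2L))
  bins <- SummarizedExperiment::rowRanges(meth)
  tr <- GenomicRanges::reduce(targetRegions, ignore.strand = TRUE)
  posL <- lapply(seq_along(tr), function(i)
    seq(GenomicRanges::start(tr)[i], GenomicRanges::end(tr)[i],
        by = siteSpacing))
  chrom <- rep(as.character(GenomicRanges::seqnames(tr)), lengths(posL))
  pos <- unlist(posL)
  siteGr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::findOverlaps(siteGr, bins, select = "first")
  keep <- !is.na(hit)
  chrom <- chrom[keep]; pos <- pos[keep]; hit <- hit[keep]
  R <- rms(meth)[, samples, drop = FALSE]
  beta <- R[hit, , drop = FALSE] +
    matrix(rnorm(length(hit) * length(samples), sd = betaNoiseSd),
           ncol = length(samples))
  beta <- pmin(pmax(beta, 0), 1)
  data.frame(
    chrom = rep(chrom, length(samples)),
    pos = rep(pos, length(samples)),
    sample = rep(samples, each = length(hit)),
    beta = as.vector(beta),
    coverage = rpois(length(hit) * length(samples), cfg$meanCoverage),
    stringsAsFactors = FALSE)
}

#' Run the whole generator
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{genome}, \code{meth}, \code{expr},
#'   \code{mut}, \code{betas}, \code{subtype}, \code{truth}, \code{cfg}.
#' @export
simulateStudy <- function(cfg = simConfig()) {
  genome <- simulateGenome(cfg)
  meth <- simulateMethylation(genome, cfg)
  expr <- simulateExpression(meth, genome, cfg)
  mut <- simulateMutations(meth, cfg)
  target <- if (length(genome$genes))
    GenomicRanges::reduce(GenomicRanges::trim(suppressWarnings(
      GenomicRanges::granges(genome$genes) + cfg$promoterLen)))
  else GenomicRanges::GRanges()
  betas <- simulateBetas(meth, target, cfg)
  list(genome = genome, meth = meth, expr = expr, mut = mut,
       betas = betas, targetRegions = target,
       subtype = .subtypeVector(cfg),
       truth = list(
         plantedBins = S4Vectors::metadata(meth)$truth$plantedBins,
         coupledGenes = genome$truth$coupledGenes,
         specificSites = mut$truth$specificSites),
       cfg = cfg)
}
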