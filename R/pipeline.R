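## End-to-end orchestration: simulate (or read) a study, derive regions,
## run the DMR, metaprofile, TFBS, mutation and concordance stages,
## write every result table plus a manifest, and render a plain-text
## report.

#' Run the full analysis pipeline
#'
#' Runs every stage on a simulated study (or on tables previously
#' written with \code{\link{writeSimulation}} and re-read with the
#' package readers) and writes all result tables, a run manifest and a
#' markdown report into \code{outdir}. Deterministic given the
#' configuration seed.
#'
#' @param cfg a \code{\link{simConfig}}; ignored when \code{inputDir}
#'   is given.
#' @param outdir output directory.
#' @param inputDir optional directory of study files (as written by
#'   \code{\link{writeSimulation}}) to analyse instead of simulating.
#' @param alpha Bonferroni-adjusted significance level for bin tests and
#'   ANOVAs (0.05).
#' @param fdrThreshold TFBS Kruskal-Wallis FDR threshold (0.1).
#' @param rhoThreshold Spearman rho threshold (-0.5).
#' @param minIn,maxOut subtype-specific mutation carrier thresholds
#'   (0.30 / 0.10).
#' @param stratumWidth methylation stratum width (0.05).
#' @param flankBp,kInternal meta-profile axis parameters.
#' @return invisibly, a list with every stage's results and the
#'   manifest.
#' @export
runPipeline <- function(cfg = simConfig(), outdir, inputDir = NULL,
                        alpha = 0.05, fdrThreshold = 0.1,
                        rhoThreshold = -0.5, minIn = 0.30, maxOut = 0.10,
                        stratumWidth = 0.05, flankBp = 500L,
                        kInternal = 20L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)

  if (is.null(inputDir)) {
    sim <- simulateStudy(cfg)
    writeSimulation(sim, file.path(outdir, "inputs"))
    meth <- sim$meth; expr <- sim$expr; sites <- sim$mut$sites
    betas <- sim$betas; tfbs <- sim$genome$tfbs
    links <- sim$genome$tfbsLinks
    islands <- sim$genome$islands
    target <- sim$targetRegions
    seed <- cfg$seed
  } else {
    chromSizes <- readChromSizes(file.path(inputDir, "chrom_sizes.tsv"))
    sheet <- readSampleSheet(file.path(inputDir, "sample_sheet.tsv"))
    meth <- readMethylationMatrix(file.path(inputDir, "methylation.tsv"),
                                  sheet, chromSizes)
    expr <- readExpressionMatrix(file.path(inputDir, "expression.tsv"),
                                 sheet)
    sites <- readCpGSiteTable(file.path(inputDir, "cpg_sites.tsv"))
    betas <- read.delim(file.path(inputDir, "betas.tsv"))
    islands <- readRegionsBed(file.path(inputDir, "cpg_islands.bed"),
                              chromSizes)
    tf <- readTfbs(file.path(inputDir, "tfbs.bed"),
                   file.path(inputDir, "tfbs_links.tsv"), chromSizes)
    tfbs <- tf$tfbs; links <- tf$links
    gm <- readGeneModels(file.path(inputDir, "gene_models.tsv"),
                         chromSizes)
    regions <- buildRegionSet(islands, gm$genes, gm$exons, tfbs)
    meth <- assignBins(meth, regions)
    target <- GenomicRanges::reduce(GenomicRanges::trim(suppressWarnings(
      GenomicRanges::granges(gm$genes) + 2000L)))
    seed <- NA_integer_
  }
  stages <- c(stages, "inputs")
  labels <- binLabels(meth)
  subtype <- subtypes(meth)
  writeRegionsBed(
    if (is.null(inputDir)) sim$genome$regions else regions,
    file.path(outdir, "regions.bed"))
  stages <- c(stages, "regions")

  ## DMR stage
  dmrRes <- allPairwiseTests(meth, alpha = alpha)
  regionCounts <- sapply(dmrRes, countByRegion, labels = labels)
  ratios <- lapply(dmrRes, function(r) list(
    shore = hypomethylationRatio(r, labels, "shore"),
    intron = hypomethylationRatio(r, labels, "intron")))
  dmrs <- lapply(dmrRes, mergeBinsToDmrs)
  for (pn in names(dmrRes))
    .writeTsv(dmrRes[[pn]],
              file.path(outdir, sprintf("bins_%s.tsv", gsub("-", "_", pn))))
  .writeTsv(do.call(rbind, lapply(names(dmrs), function(pn)
    if (nrow(dmrs[[pn]])) cbind(pair = pn, dmrs[[pn]]) else NULL)),
    file.path(outdir, "dmrs.tsv"))
  .writeTsv(data.frame(region = rownames(regionCounts), regionCounts,
                       check.names = FALSE),
            file.path(outdir, "region_counts.tsv"))
  stages <- c(stages, "dmr")

  ## metaprofile stage
  profile <- computeMetaprofile(meth, islands, flankBp = flankBp,
                                kInternal = kInternal)
  profAnova <- positionwiseAnova(profile)
  profTab <- data.frame(profile$positions,
                        profile$subtypeCurves,
                        pAdj = profAnova$pAdj, check.names = FALSE)
  .writeTsv(profTab, file.path(outdir, "metaprofile.tsv"))
  stages <- c(stages, "metaprofile")

  ## TFBS stage
  promShore <- .promoterShore(labels, meth)
  hits <- tfbsScreen(meth, expr, tfbs, links, promoterShore = promShore,
                     fdrThreshold = fdrThreshold,
                     rhoThreshold = rhoThreshold)
  geneTable <- integrateTfbs(hits)
  .writeTsv(hits, file.path(outdir, "tfbs_hits.tsv"))
  .writeTsv(geneTable, file.path(outdir, "tfbs_genes.tsv"))
  stages <- c(stages, "tfbs")

  ## mutation stage
  calls <- callMutations(sites)
  rateTab <- mutationRateByMethylation(calls, subtype, stratumWidth)
  psr <- perSampleStratumRates(calls, subtype, stratumWidth)
  rateAnova <- stratumAnova(psr, subtype, alpha = alpha)
  specific <- classifySubtypeSpecific(calls, subtype, minIn, maxOut)
  regional <- regionalMutationCounts(specific, calls, meth, alpha = alpha)
  .writeTsv(rateTab, file.path(outdir, "mutation_rates.tsv"))
  .writeTsv(rateAnova, file.path(outdir, "mutation_rate_anova.tsv"))
  .writeTsv(specific, file.path(outdir, "specific_mutations.tsv"))
  .writeTsv(data.frame(region = rownames(regional$counts),
                       regional$counts, check.names = FALSE),
            file.path(outdir, "specific_mutation_regions.tsv"))
  stages <- c(stages, "mutation")

  ## concordance stage
  pairs <- binBetaRmsWindows(betas, meth, target)
  conc <- pearsonConcordance(pairs)
  .writeTsv(pairs, file.path(outdir, "concordance_windows.tsv"))
  .writeTsv(conc, file.path(outdir, "concordance.tsv"))
  stages <- c(stages, "concordance")

  results <- list(meth = meth, dmr = dmrRes, regionCounts = regionCounts,
                  ratios = ratios, dmrs = dmrs, profile = profile,
                  profAnova = profAnova, tfbsHits = hits,
                  geneTable = geneTable, calls = calls,
                  rateTable = rateTab, rateAnova = rateAnova,
                  specific = specific, regional = regional,
                  concordance = conc)
  writeReport(results, file.path(outdir, "report.md"))
  stages <- c(stages, "report")

  manifest <- list(
    package = "shoreMeth",
    version = as.character(packageVersion("shoreMeth")),
    seed = seed,
    stages = stages,
    rows = list(bins = nrow(meth), samples = ncol(meth),
                significantBins = sapply(dmrRes,
                                         function(r) sum(r$significant)),
                dmrs = sapply(dmrs, nrow),
                tfbsHits = if (nrow(hits)) sum(hits$passes) else 0L,
                genes = nrow(geneTable),
                mutationCalls = sum(calls$isMutated),
                specificSites = nrow(specific)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

.promoterShore <- function(labels, meth) {
  bins <- SummarizedExperiment::rowRanges(meth)
  GenomicRanges::reduce(bins[.hasLabel(labels, "promoter_shore")])
}

#' Write a human-readable result summary
#'
#' Markdown summary of the main result surfaces: significant bin and
#' DMR counts per pairwise comparison, shore/intron hypomethylation
#' ratios, the gene-level TFBS table, the mutation-rate strata with
#' significant subtype differences, regional specific-mutation counts,
#' and per-sample concordance.
#'
#' @param results list as assembled by \code{\link{runPipeline}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# shoreMeth run report\n")
  w("## Differential methylation (pairwise)\n")
  for (pn in names(results$dmr)) {
    r <- results$dmr[[pn]]
    w("- %s: %d significant bins, %d DMRs", pn, sum(r$significant),
      nrow(results$dmrs[[pn]]))
  }
  w("\n## Hypomethylation ratios (shore / intron)\n")
  for (pn in names(results$ratios)) {
    sh <- results$ratios[[pn]]$shore
    w("- %s shore: %s", pn,
      paste(sprintf("%s=%.2f", names(sh), sh), collapse = ", "))
  }
  w("\n## TFBS/expression integration\n")
  gt <- results$geneTable
  w("- %d genes with a passing TFBS (fraction hypomethylated in basal B: %s)",
    nrow(gt),
    ifelse(is.na(attr(gt, "fracHypoBasalB")), "NA",
           sprintf("%.2f", attr(gt, "fracHypoBasalB"))))
  w("\n## Mutation analysis\n")
  w("- %d mutation calls; %d subtype-specific sites",
    sum(results$calls$isMutated), nrow(results$specific))
  sig <- results$rateAnova[results$rateAnova$significant, , drop = FALSE]
  w("- strata with significant subtype rate differences: %s",
    ifelse(nrow(sig), paste(sig$label, collapse = ", "), "none"))
  w("\n## Concordance\n")
  w("- mean Pearson r over samples: %.3f",
    attr(results$concordance, "meanR"))
  invisible(path)
}
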