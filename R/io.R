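## Plain-text emit/read of every study table, so a simulated study
## round-trips through the same readers a real study would use. All BED
## files are 0-based half-open; TSV interval columns follow the same
## convention.

.writeTsv <- function(d, path)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write a simulated study to a directory of plain-text files
#'
#' Emits chrom sizes, islands and full labelled regions (BED), gene
#' models and TFBS links (TSV), the methylation and expression matrices,
#' the CpG site table, per-CpG betas, the sample sheet, the truth
#' tables, and a JSON echo of the configuration (including the seed).
#'
#' @param sim output of \code{\link{simulateStudy}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- sim$genome
  f <- character(0)
  p <- function(x) file.path(dir, x)

  write.table(data.frame(names(g$chromSizes), unname(g$chromSizes)),
              p("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  isl <- g$islands
  S4Vectors::mcols(isl)$label <- "CpGI"
  writeRegionsBed(isl, p("cpg_islands.bed"))
  writeRegionsBed(g$regions, p("regions.bed"))

  ex <- split(g$exons, S4Vectors::mcols(g$exons)$gene_id)
  gid <- S4Vectors::mcols(g$genes)$gene_id
  .writeTsv(data.frame(
    chrom = as.character(GenomicRanges::seqnames(g$genes)),
    start = GenomicRanges::start(g$genes) - 1L,
    end = GenomicRanges::end(g$genes),
    strand = as.character(GenomicRanges::strand(g$genes)),
    gene_id = gid,
    exon_starts = vapply(gid, function(i)
      paste(GenomicRanges::start(ex[[i]]) - 1L, collapse = ","),
      character(1)),
    exon_ends = vapply(gid, function(i)
      paste(GenomicRanges::end(ex[[i]]), collapse = ","), character(1))),
    p("gene_models.tsv"))

  tf <- g$tfbs
  S4Vectors::mcols(tf)$label <- S4Vectors::mcols(tf)$tfbs_id
  writeRegionsBed(tf, p("tfbs.bed"))
  .writeTsv(g$tfbsLinks, p("tfbs_links.tsv"))

  bins <- SummarizedExperiment::rowRanges(sim$meth)
  .writeTsv(cbind(data.frame(
    chrom = as.character(GenomicRanges::seqnames(bins)),
    start = GenomicRanges::start(bins) - 1L,
    end = GenomicRanges::end(bins)), as.data.frame(rms(sim$meth))),
    p("methylation.tsv"))
  E <- SummarizedExperiment::assay(sim$expr, "exprs")
  .writeTsv(cbind(data.frame(gene_id = rownames(E)), as.data.frame(E)),
            p("expression.tsv"))
  .writeTsv(sim$mut$sites, p("cpg_sites.tsv"))
  .writeTsv(sim$betas, p("betas.tsv"))
  .writeTsv(data.frame(sample = names(sim$subtype),
                       subtype = as.character(sim$subtype)),
            p("sample_sheet.tsv"))

  .writeTsv(data.frame(bin = sim$truth$plantedBins),
            p("truth_planted_bins.tsv"))
  .writeTsv(data.frame(gene_id = sim$truth$coupledGenes),
            p("truth_coupled_genes.tsv"))
  .writeTsv(sim$truth$specificSites, p("truth_specific_sites.tsv"))
  cfg <- sim$cfg
  class(cfg) <- NULL
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}

#' Read a sample sheet
#' @param path TSV with columns sample, subtype.
#' @param subtypeLevels allowed subtype labels.
#' @return named factor (names = samples).
#' @export
readSampleSheet <- function(path, subtypeLevels = c("luminal", "basalA",
                                                    "basalB")) {
  d <- read.delim(path, colClasses = "character")
  bad <- !d$subtype %in% subtypeLevels
  if (any(bad))
    stop("unknown subtype for sample(s): ",
         paste(d$sample[bad], collapse = ", "))
  setNames(factor(d$subtype, levels = subtypeLevels), d$sample)
}

#' Read a binned methylation matrix
#' @param path TSV: chrom, start (0-based), end, then one RMS column per
#'   sample.
#' @param sampleSheet named subtype factor from
#'   \code{\link{readSampleSheet}}.
#' @param chromSizes named integer vector.
#' @param binSize bin width in bp.
#' @return a \linkS4class{BinnedMethylation}.
#' @export
readMethylationMatrix <- function(path, sampleSheet, chromSizes,
                                  binSize = 100L) {
  d <- read.delim(path, check.names = FALSE)
  samples <- setdiff(names(d), c("chrom", "start", "end"))
  missing <- setdiff(samples, names(sampleSheet))
  if (length(missing))
    stop("samples absent from sample sheet: ",
         paste(missing, collapse = ", "))
  bins <- GenomicRanges::GRanges(
    d$chrom, IRanges::IRanges(d$start + 1L, d$end),
    seqlengths = chromSizes)
  m <- as.matrix(d[samples])
  BinnedMethylation(m, bins, sampleSheet[samples], binSize = binSize)
}

#' Read an expression matrix
#' @param path TSV: gene_id then one column per sample.
#' @param sampleSheet named subtype factor.
#' @return \code{SummarizedExperiment} with assay \code{exprs}.
#' @export
readExpressionMatrix <- function(path, sampleSheet) {
  d <- read.delim(path, check.names = FALSE)
  samples <- setdiff(names(d), "gene_id")
  m <- as.matrix(d[samples])
  rownames(m) <- d$gene_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m),
    colData = S4Vectors::DataFrame(subtype = sampleSheet[samples],
                                   row.names = samples))
}

#' Read a per-CpG-site observation table
#' @param path TSV: chrom, pos, sample, coverage, mismatches, rms.
#' @return data.frame.
#' @export
readCpGSiteTable <- function(path) {
  d <- read.delim(path)
  need <- c("chrom", "pos", "sample", "coverage", "mismatches", "rms")
  if (!all(need %in% names(d)))
    stop("CpG site table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Read TFBS intervals plus their TF/target links
#' @param bedPath BED6 with tfbs_id in the name column.
#' @param linksPath TSV: tfbs_id, tf_id, target_gene, validated.
#' @param chromSizes named integer vector.
#' @return list with \code{tfbs} (GRanges) and \code{links} (data.frame).
#' @export
readTfbs <- function(bedPath, linksPath, chromSizes) {
  gr <- readRegionsBed(bedPath, chromSizes)
  S4Vectors::mcols(gr)$tfbs_id <- S4Vectors::mcols(gr)$label
  S4Vectors::mcols(gr)$label <- "TFBS"
  links <- read.delim(linksPath, colClasses = c(validated = "logical"))
  list(tfbs = gr, links = links)
}
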