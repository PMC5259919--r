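## Genomic region derivation: shores/shelves around CpG islands, promoters,
## bin tiling and bin -> region-label assignment. Coordinates inside R
## follow the GRanges convention (1-based, closed); all BED files read or
## written are 0-based half-open, with the conversion handled by
## rtracklayer.

.REGION_LABELS <- c("CpGI", "shore", "shelf", "promoter", "exon", "intron",
                    "UTR5", "UTR3", "TFBS", "gene", "intergenic")

## fast per-element "label set contains any of `set`" for a CharacterList
.hasLabel <- function(labels, set) {
  idx <- rep(seq_along(labels), lengths(labels))
  u <- unlist(labels, use.names = FALSE)
  as.logical(tabulate(idx[u %in% set], nbins = length(labels)))
}

#' Tile a genome into fixed-width bins
#'
#' @param chromSizes named integer vector of chromosome lengths (bp).
#' @param binSize bin width in bp, default 100.
#' @return \code{GRanges} tiling every chromosome left to right; the last
#'   bin of a chromosome may be shorter.
#' @examples
#' makeBinIndex(c(chr1 = 550L), binSize = 100)
#' @export
makeBinIndex <- function(chromSizes, binSize = 100L) {
  stopifnot(binSize > 0, all(chromSizes > 0), !is.null(names(chromSizes)))
  sl <- setNames(as.integer(chromSizes), names(chromSizes))
  bins <- GenomicRanges::tileGenome(sl, tilewidth = as.integer(binSize),
                                    cut.last.tile.in.chrom = TRUE)
  names(bins) <- NULL
  bins
}

.checkWithinBounds <- function(gr, what = "interval") {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl)))
    stop("seqlengths (chromosome sizes) must be set on the input GRanges")
  bad <- GenomicRanges::start(gr) < 1L |
    GenomicRanges::end(gr) > sl[as.character(GenomeInfoDb::seqnames(gr))]
  if (any(bad))
    stop(sum(bad), " ", what, "(s) extend beyond chromosome bounds")
  invisible(TRUE)
}

#' Derive CpG island shores and shelves
#'
#' Shores are the flanks of width \code{shoreWidth} on each side of every
#' island, minus any overlap with any island; shelves are the next
#' \code{shelfWidth} outward, minus islands and shores. Islands, shores
#' and shelves are pairwise disjoint by construction, and everything is
#' clipped to chromosome bounds. The 2 kb defaults follow the common
#' shore/shelf convention for island-centric annotation.
#'
#' @param cpgi \code{GRanges} of CpG islands with seqlengths set.
#' @param shoreWidth,shelfWidth flank widths in bp (default 2000 each).
#' @return \code{GRanges} with a metadata column \code{label} in
#'   \{\code{shore}, \code{shelf}\}.
#' @export
deriveShoresShelves <- function(cpgi, shoreWidth = 2000L, shelfWidth = 2000L) {
  stopifnot(shoreWidth > 0, shelfWidth > 0)
  if (length(cpgi) == 0L) {
    out <- GenomicRanges::granges(cpgi)
    S4Vectors::mcols(out)$label <- character(0)
    return(out)
  }
  .checkWithinBounds(cpgi, "island")
  islands <- GenomicRanges::reduce(GenomicRanges::granges(cpgi),
                                   ignore.strand = TRUE)
  GenomicRanges::strand(islands) <- "*"
  shoreZone <- GenomicRanges::trim(suppressWarnings(islands + shoreWidth))
  shores <- GenomicRanges::setdiff(shoreZone, islands)
  shelfZone <- GenomicRanges::trim(
    suppressWarnings(islands + (shoreWidth + shelfWidth)))
  shelves <- GenomicRanges::setdiff(shelfZone, shoreZone)
  out <- c(shores, shelves)
  S4Vectors::mcols(out)$label <- rep(c("shore", "shelf"),
                                     c(length(shores), length(shelves)))
  sort(out)
}

#' Derive promoters upstream of transcription start sites
#'
#' The promoter of a + strand gene is the \code{promoterLen} bp upstream
#' of its start; for a - strand gene, upstream of its end. Promoters are
#' clipped to chromosome bounds and carry the gene id of their gene.
#'
#' @param genes \code{GRanges} with strand in \{+,-\}, seqlengths set and
#'   a \code{gene_id} metadata column.
#' @param promoterLen promoter length in bp (default 2000).
#' @return \code{GRanges} of promoters with \code{label = "promoter"} and
#'   \code{gene_id}.
#' @export
derivePromoters <- function(genes, promoterLen = 2000L) {
  stopifnot(promoterLen > 0)
  if (length(genes) == 0L) {
    out <- GenomicRanges::granges(genes)
    S4Vectors::mcols(out)$label <- character(0)
    S4Vectors::mcols(out)$gene_id <- character(0)
    return(out)
  }
  str <- as.character(GenomicRanges::strand(genes))
  if (any(str == "*")) {
    bad <- S4Vectors::mcols(genes)$gene_id[str == "*"]
    stop("strand missing for gene(s): ", paste(bad, collapse = ", "))
  }
  prom <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(genes, upstream = promoterLen, downstream = 0)))
  prom <- prom[GenomicRanges::width(prom) > 0L]
  out <- GenomicRanges::granges(prom)
  S4Vectors::mcols(out)$label <- "promoter"
  S4Vectors::mcols(out)$gene_id <- S4Vectors::mcols(prom)$gene_id
  out
}

#' Assemble the labelled region set used downstream
#'
#' Combines islands, derived shores/shelves, gene bodies, exons, derived
#' introns (gene minus exons), derived promoters and TFBS into one
#' labelled \code{GRanges}. Optional UTR inputs are passed through.
#'
#' @param cpgi islands (\code{GRanges}); shores/shelves derived from them.
#' @param genes gene bodies with strand and \code{gene_id}.
#' @param exons exon intervals with \code{gene_id}.
#' @param tfbs TFBS intervals (optional), labelled \code{TFBS}.
#' @param utr5,utr3 optional UTR intervals.
#' @param shoreWidth,shelfWidth,promoterLen widths in bp.
#' @return labelled \code{GRanges} with columns \code{label} and
#'   \code{gene_id} (NA where not applicable).
#' @export
buildRegionSet <- function(cpgi, genes, exons, tfbs = NULL,
                           utr5 = NULL, utr3 = NULL,
                           shoreWidth = 2000L, shelfWidth = 2000L,
                           promoterLen = 2000L) {
  lab <- function(gr, label, gene_id = NA_character_) {
    out <- GenomicRanges::granges(gr)
    GenomicRanges::strand(out) <- "*"
    S4Vectors::mcols(out)$label <- rep(label, length(out))
    gid <- S4Vectors::mcols(gr)$gene_id
    S4Vectors::mcols(out)$gene_id <-
      if (is.null(gid)) rep(gene_id, length(out)) else gid
    out
  }
  ss <- deriveShoresShelves(cpgi, shoreWidth, shelfWidth)
  shores <- ss[S4Vectors::mcols(ss)$label == "shore"]
  shelves <- ss[S4Vectors::mcols(ss)$label == "shelf"]
  introns <- GenomicRanges::setdiff(
    GenomicRanges::reduce(GenomicRanges::granges(genes), ignore.strand = TRUE),
    GenomicRanges::reduce(GenomicRanges::granges(exons), ignore.strand = TRUE))
  prom <- derivePromoters(genes, promoterLen)
  pieces <- list(
    lab(cpgi, "CpGI"), lab(shores, "shore"), lab(shelves, "shelf"),
    lab(genes, "gene"), lab(exons, "exon"), lab(introns, "intron"),
    GenomicRanges::granges(prom))
  S4Vectors::mcols(pieces[[7]])$label <- rep("promoter", length(prom))
  S4Vectors::mcols(pieces[[7]])$gene_id <- S4Vectors::mcols(prom)$gene_id
  if (!is.null(tfbs) && length(tfbs)) pieces <- c(pieces, list(lab(tfbs, "TFBS")))
  if (!is.null(utr5) && length(utr5)) pieces <- c(pieces, list(lab(utr5, "UTR5")))
  if (!is.null(utr3) && length(utr3)) pieces <- c(pieces, list(lab(utr3, "UTR3")))
  out <- do.call(c, pieces)
  stopifnot(all(S4Vectors::mcols(out)$label %in% .REGION_LABELS))
  out
}

#' Assign region labels to bins
#'
#' A bin receives a label iff it overlaps at least 1 bp of an interval
#' carrying that label; multi-labelling is allowed. Two derived
#' intersection labels are added: \code{promoter_CpGI} and
#' \code{promoter_shore}, attached to bins overlapping the literal
#' intersection of the promoter intervals with the island (resp. shore)
#' intervals. Bins overlapping nothing are labelled \code{intergenic}.
#'
#' @param bins bin tiling \code{GRanges} (from \code{\link{makeBinIndex}})
#'   or a \linkS4class{BinnedMethylation} object, in which case the labels
#'   are stored in \code{rowData(x)$labels} and the object returned.
#' @param regions labelled \code{GRanges} from \code{\link{buildRegionSet}}.
#' @return a \code{CharacterList} of label sets, one element per bin (or
#'   the annotated \code{BinnedMethylation}).
#' @export
assignBins <- function(bins, regions) {
  if (is(bins, "BinnedMethylation")) {
    lab <- assignBins(SummarizedExperiment::rowRanges(bins), regions)
    SummarizedExperiment::rowData(bins)$labels <- lab
    return(bins)
  }
  regLabel <- S4Vectors::mcols(regions)$label
  pick <- function(l) GenomicRanges::reduce(
    GenomicRanges::granges(regions[regLabel == l]), ignore.strand = TRUE)
  extra <- GenomicRanges::GRangesList(
    promoter_CpGI = GenomicRanges::intersect(pick("promoter"), pick("CpGI")),
    promoter_shore = GenomicRanges::intersect(pick("promoter"), pick("shore")))
  allReg <- c(GenomicRanges::granges(regions),
              unlist(extra, use.names = FALSE))
  allLab <- c(regLabel, rep(names(extra), lengths(extra)))
  hits <- GenomicRanges::findOverlaps(bins, allReg, minoverlap = 1L,
                                      ignore.strand = TRUE)
  labs <- unname(S4Vectors::splitAsList(
    allLab[S4Vectors::subjectHits(hits)],
    factor(S4Vectors::queryHits(hits), levels = seq_along(bins))))
  labs <- unique(labs)
  labs[lengths(labs) == 0L] <- "intergenic"
  methods::as(labs, "CharacterList")
}

## ---- file interfaces -------------------------------------------------

#' Read a two-column chromosome sizes file
#' @param path TSV with columns chrom, length (no header).
#' @return named integer vector.
#' @export
readChromSizes <- function(path) {
  d <- read.delim(path, header = FALSE, col.names = c("chrom", "length"),
                  colClasses = c("character", "integer"))
  setNames(d$length, d$chrom)
}

#' Read labelled regions from BED
#'
#' BED6 name column is taken as the region label (BED3 inputs get the
#' \code{defaultLabel}).
#' @param path BED file path.
#' @param chromSizes named integer vector (sets seqlengths).
#' @param defaultLabel label used when the BED has no name column.
#' @return labelled \code{GRanges}.
#' @export
readRegionsBed <- function(path, chromSizes, defaultLabel = "CpGI") {
  gr <- rtracklayer::import(path, format = "BED")
  GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
  GenomeInfoDb::seqlengths(gr) <- chromSizes
  nm <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$label <-
    if (is.null(nm) || all(is.na(nm))) rep(defaultLabel, length(gr)) else nm
  gr
}

#' Write labelled regions as BED6 (label in the name column)
#' @param gr labelled \code{GRanges}.
#' @param path output path.
#' @export
writeRegionsBed <- function(gr, path) {
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$name <- S4Vectors::mcols(gr)$label
  S4Vectors::mcols(out)$score <- 0L
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read minimal gene models from TSV
#'
#' Expected columns (0-based half-open coordinates, as in BED):
#' chrom, start, end, strand, gene_id, exon_starts, exon_ends (the last
#' two comma-separated).
#' @param path TSV path (with header).
#' @param chromSizes named integer vector.
#' @return list with \code{genes} and \code{exons} \code{GRanges}.
#' @export
readGeneModels <- function(path, chromSizes) {
  d <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("chrom", "start", "end", "strand", "gene_id",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(d)))
    stop("gene model file must have columns: ", paste(need, collapse = ", "))
  genes <- GenomicRanges::GRanges(
    d$chrom,
    IRanges::IRanges(as.integer(d$start) + 1L, as.integer(d$end)),
    strand = d$strand,
    gene_id = d$gene_id,
    seqlengths = chromSizes)
  es <- strsplit(d$exon_starts, ","); ee <- strsplit(d$exon_ends, ",")
  n <- lengths(es)
  exons <- GenomicRanges::GRanges(
    rep(d$chrom, n),
    IRanges::IRanges(as.integer(unlist(es)) + 1L, as.integer(unlist(ee))),
    strand = rep(d$strand, n),
    gene_id = rep(d$gene_id, n),
    seqlengths = chromSizes)
  list(genes = genes, exons = exons)
}
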