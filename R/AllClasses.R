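#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData rowRanges
#' @importFrom S4Vectors DataFrame mcols metadata queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom stats rnorm rpois rbinom runif p.adjust pt pbinom kruskal.test
#'   oneway.test cor sd complete.cases setNames aggregate
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' BinnedMethylation: fixed-width bin methylation scores across samples
#'
#' An S4 container for affinity-capture (MBDCap-seq style) methylation
#' summarised as relative methylation scores (RMS, in \[0,1\]) over a
#' genome tiling of fixed-width bins (100 bp by default). It extends
#' \linkS4class{RangedSummarizedExperiment}: rows are bins (a
#' \code{GRanges} tiling), columns are samples, and \code{colData} must
#' carry a \code{subtype} factor with the molecular subtype of each cell
#' line. Per-bin region labels (CpG island, shore, shelf, ...) live in
#' \code{rowData(x)$labels} as a \code{CharacterList} once assigned with
#' \code{\link{assignBins}}.
#'
#' @slot binSize integer(1), width of the tiling bins in bp.
#'
#' @seealso \code{\link{BinnedMethylation}} (constructor),
#'   \code{\link{rms}}, \code{\link{subtypes}}, \code{\link{binLabels}}
#' @export
setClass("BinnedMethylation",
  contains = "RangedSummarizedExperiment",
  representation(binSize = "integer")
)

setValidity("BinnedMethylation", function(object) {
  msg <- NULL
  if (!"rms" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'rms' is required")
  else {
    v <- SummarizedExperiment::assay(object, "rms")
    if (!is.numeric(v))
      msg <- c(msg, "'rms' assay must be numeric")
    else if (any(v < 0 | v > 1, na.rm = TRUE))
      msg <- c(msg, "'rms' values must lie in [0, 1]")
  }
  if (!"subtype" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'subtype' column")
  if (length(object@binSize) != 1L || object@binSize <= 0L)
    msg <- c(msg, "binSize must be a single positive integer")
  w <- GenomicRanges::width(SummarizedExperiment::rowRanges(object))
  if (length(w) && any(w > object@binSize))
    msg <- c(msg, "no bin may be wider than binSize")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BinnedMethylation object
#'
#' @param rms numeric matrix of relative methylation scores in \[0,1\],
#'   bins in rows, samples in columns.
#' @param bins \code{GRanges} of the bin tiling, same length as
#'   \code{nrow(rms)}; typically from \code{\link{makeBinIndex}}.
#' @param subtype character or factor of length \code{ncol(rms)} giving
#'   the subtype of each sample.
#' @param binSize bin width in bp (default 100).
#' @return A \linkS4class{BinnedMethylation} object.
#' @examples
#' bins <- makeBinIndex(c(chr1 = 1000L), binSize = 100)
#' m <- matrix(runif(20), nrow = 10,
#'             dimnames = list(NULL, c("s1", "s2")))
#' bm <- BinnedMethylation(m, bins, subtype = c("luminal", "basalB"))
#' @export
BinnedMethylation <- function(rms, bins, subtype, binSize = 100L) {
  stopifnot(is.matrix(rms), length(bins) == nrow(rms),
            length(subtype) == ncol(rms))
  if (is.null(colnames(rms)))
    colnames(rms) <- paste0("sample", seq_len(ncol(rms)))
  cd <- S4Vectors::DataFrame(
    subtype = factor(subtype),
    row.names = colnames(rms))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rms = rms), rowRanges = bins, colData = cd)
  new("BinnedMethylation", se, binSize = as.integer(binSize))
}

#' @rdname rms
#' @export
setGeneric("rms", function(x) standardGeneric("rms"))

#' Accessors for BinnedMethylation
#'
#' \code{rms} returns the bin-by-sample RMS matrix; \code{subtypes} the
#' per-sample subtype factor; \code{binLabels} the per-bin region label
#' sets (a \code{CharacterList}, or \code{NULL} before
#' \code{\link{assignBins}} has been run); \code{binSize} the tiling
#' width in bp.
#'
#' @param x a \linkS4class{BinnedMethylation} object.
#' @return See description per accessor.
#' @rdname rms
#' @export
setMethod("rms", "BinnedMethylation", function(x)
  SummarizedExperiment::assay(x, "rms"))

#' @rdname rms
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))

#' @rdname rms
#' @export
setMethod("subtypes", "BinnedMethylation", function(x)
  setNames(SummarizedExperiment::colData(x)$subtype, colnames(x)))

#' @rdname rms
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))

#' @rdname rms
#' @export
setMethod("binLabels", "BinnedMethylation", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("labels" %in% colnames(rd)) rd$labels else NULL
})

#' @rdname rms
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname rms
#' @export
setMethod("binSize", "BinnedMethylation", function(x) x@binSize)

setMethod("show", "BinnedMethylation", function(object) {
  cat("BinnedMethylation with", nrow(object), "bins of",
      object@binSize, "bp and", ncol(object), "samples\n")
  st <- table(subtypes(object))
  cat("subtypes:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  lab <- binLabels(object)
  if (!is.null(lab))
    cat("region labels assigned (",
        length(unique(unlist(lab))), " classes )\n", sep = "")
  invisible(NULL)
})
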