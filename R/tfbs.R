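## TFBS methylation/expression coupling: TFBS-level methylation scores
## (mean over overlapping bins), Kruskal-Wallis differential methylation
## across subtypes with Benjamini-Hochberg FDR, Spearman correlation
## with downstream gene expression, a TF-expression-similarity filter,
## and gene-level integration.

#' TFBS methylation scores
#'
#' The methylation of a TFBS in a sample is the unweighted mean RMS of
#' all bins overlapping the TFBS (by at least 1 bp). TFBS overlapping no
#' bin are excluded and reported via the \code{excluded} attribute.
#'
#' @param meth a \linkS4class{BinnedMethylation}.
#' @param tfbs \code{GRanges} with a \code{tfbs_id} metadata column.
#' @return numeric matrix TFBS x samples, rownames = tfbs_id.
#' @export
tfbsMethylation <- function(meth, tfbs) {
  stopifnot(is(meth, "BinnedMethylation"),
            !is.null(S4Vectors::mcols(tfbs)$tfbs_id))
  bins <- SummarizedExperiment::rowRanges(meth)
  ov <- GenomicRanges::findOverlaps(tfbs, bins, minoverlap = 1L,
                                    ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov)
  num <- rowsum(rms(meth)[S4Vectors::subjectHits(ov), , drop = FALSE],
                group = q)
  cnt <- tabulate(q, nbins = length(tfbs))
  hit <- cnt > 0L
  out <- num / cnt[hit]
  rownames(out) <- S4Vectors::mcols(tfbs)$tfbs_id[hit]
  attr(out, "excluded") <- S4Vectors::mcols(tfbs)$tfbs_id[!hit]
  out
}

#' Kruskal-Wallis differential methylation across subtypes per TFBS
#'
#' @param tfbsMeth TFBS x sample matrix from
#'   \code{\link{tfbsMethylation}}.
#' @param subtype per-sample subtype factor.
#' @return data.frame \code{tfbs_id, kwP, kwFdr}; rows whose values are
#'   constant across all samples get NA and are excluded from the
#'   Benjamini-Hochberg adjustment.
#' @export
differentialTfbs <- function(tfbsMeth, subtype) {
  stopifnot(ncol(tfbsMeth) == length(subtype))
  subtype <- droplevels(factor(subtype))
  p <- apply(tfbsMeth, 1L, function(v) {
    if (length(unique(v)) < 2L) return(NA_real_)
    kruskal.test(v, subtype)$p.value
  })
  data.frame(tfbs_id = rownames(tfbsMeth), kwP = p,
             kwFdr = p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation of TFBS methylation with target expression
#'
#' @param tfbsMeth TFBS x sample matrix.
#' @param expr \code{SummarizedExperiment} of expression (assay
#'   \code{exprs}) or a gene x sample matrix; samples must match columns
#'   of \code{tfbsMeth}.
#' @param links data.frame with \code{tfbs_id} and \code{target_gene}.
#' @return named numeric vector: Spearman rho per tfbs_id (NA when the
#'   target gene is absent from \code{expr}).
#' @export
expressionCorrelation <- function(tfbsMeth, expr, links) {
  E <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "exprs") else expr
  E <- E[, colnames(tfbsMeth), drop = FALSE]
  ids <- rownames(tfbsMeth)
  tg <- links$target_gene[match(ids, links$tfbs_id)]
  rho <- rep(NA_real_, length(ids))
  ok <- !is.na(tg) & tg %in% rownames(E)
  rho[ok] <- vapply(which(ok), function(i)
    cor(tfbsMeth[i, ], E[tg[i], ], method = "spearman"), numeric(1))
  setNames(rho, ids)
}

#' Does a TF have subtype-similar expression?
#'
#' TRUE iff the Kruskal-Wallis p-value of the TF's own expression across
#' subtypes is at least \code{pThreshold} (i.e. no detectable
#' subtype difference), so that downstream expression changes can be
#' attributed to TFBS methylation rather than TF abundance. A TF with
#' constant expression is similar by definition.
#'
#' @param expr expression \code{SummarizedExperiment} or matrix.
#' @param tfId TF gene id (must be a row of \code{expr}).
#' @param subtype per-sample subtype factor.
#' @param pThreshold similarity cutoff on the KW p-value (default 0.05).
#' @return logical(1).
#' @export
tfExpressionFilter <- function(expr, tfId, subtype, pThreshold = 0.05) {
  E <- if (is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr, "exprs") else expr
  if (!tfId %in% rownames(E)) stop("TF not in expression matrix: ", tfId)
  v <- E[tfId, ]
  if (length(unique(v)) < 2L) return(TRUE)
  kruskal.test(v, droplevels(factor(subtype)))$p.value >= pThreshold
}

#' Full TFBS screen
#'
#' Restricts TFBS to those overlapping a promoter/CpGI-shore overlap
#' region (when \code{promoterShore} is given), scores their
#' methylation, tests subtype differences (Kruskal-Wallis, BH FDR),
#' correlates with downstream expression (Spearman), applies the
#' TF-expression-similarity filter and the ChIP-validation flag, and
#' marks TFBS passing all screens: \code{kwFdr < fdrThreshold}, \code{
#' rho < rhoThreshold}, TF similar, validated.
#'
#' @param meth a \linkS4class{BinnedMethylation}.
#' @param expr expression \code{SummarizedExperiment} or matrix.
#' @param tfbs TFBS \code{GRanges} with \code{tfbs_id}.
#' @param links data.frame \code{tfbs_id, tf_id, target_gene, validated}.
#' @param promoterShore optional \code{GRanges} of promoter/shore
#'   intersections used as an inclusion filter.
#' @param fdrThreshold Kruskal-Wallis FDR cutoff (0.1).
#' @param rhoThreshold Spearman rho cutoff (-0.5).
#' @param tfSimilarP TF-similarity KW p threshold (0.05).
#' @return data.frame of TFBS hits with per-subtype mean methylation,
#'   \code{kwP, kwFdr, rho, tfSimilar, validated, hypoSubtype, passes}.
#' @export
tfbsScreen <- function(meth, expr, tfbs, links, promoterShore = NULL,
                       fdrThreshold = 0.1, rhoThreshold = -0.5,
                       tfSimilarP = 0.05) {
  if (!is.null(promoterShore)) {
    keep <- IRanges::overlapsAny(tfbs, promoterShore, ignore.strand = TRUE)
    tfbs <- tfbs[keep]
  }
  if (!length(tfbs))
    return(data.frame())
  tm <- tfbsMethylation(meth, tfbs)
  subtype <- subtypes(meth)
  kw <- differentialTfbs(tm, subtype)
  rho <- expressionCorrelation(tm, expr, links)
  ids <- rownames(tm)
  li <- links[match(ids, links$tfbs_id), ]
  tfSim <- vapply(unique(li$tf_id), function(tf)
    tfExpressionFilter(expr, tf, subtype, tfSimilarP), logical(1))
  grpMean <- vapply(levels(subtype), function(g)
    rowMeans(tm[, subtype == g, drop = FALSE]), numeric(nrow(tm)))
  if (is.null(dim(grpMean))) grpMean <- matrix(grpMean, nrow = 1,
    dimnames = list(ids, levels(subtype)))
  hypo <- levels(subtype)[apply(grpMean, 1L, which.min)]
  out <- data.frame(
    tfbs_id = ids, tf_id = li$tf_id, target_gene = li$target_gene,
    validated = li$validated,
    kwP = kw$kwP, kwFdr = kw$kwFdr, rho = unname(rho),
    tfSimilar = tfSim[li$tf_id],
    hypoSubtype = hypo,
    stringsAsFactors = FALSE)
  out$meanMeth <- grpMean
  out$passes <- !is.na(out$kwFdr) & out$kwFdr < fdrThreshold &
    !is.na(out$rho) & out$rho < rhoThreshold &
    out$tfSimilar & out$validated
  out
}

#' Gene-level integration of TFBS hits
#'
#' Genes with at least one passing TFBS, with the gene's best (most
#' negative) rho, minimum Kruskal-Wallis FDR, and the hypomethylated
#' subtype of its best TFBS; also reports the fraction of genes
#' hypomethylated in basal B as attribute \code{fracHypoBasalB}.
#'
#' @param hits data.frame from \code{\link{tfbsScreen}}.
#' @return data.frame \code{gene, tf, bestRho, minKwFdr, hypoSubtype,
#'   nTfbs}, ordered by bestRho.
#' @export
integrateTfbs <- function(hits) {
  empty <- data.frame(gene = character(0), tf = character(0),
                      bestRho = numeric(0), minKwFdr = numeric(0),
                      hypoSubtype = character(0), nTfbs = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(hits) || !any(hits$passes)) {
    attr(empty, "fracHypoBasalB") <- NA_real_
    return(empty)
  }
  h <- hits[hits$passes, , drop = FALSE]
  sp <- split(h, h$target_gene)
  out <- do.call(rbind, lapply(sp, function(d) {
    best <- which.min(d$rho)
    data.frame(gene = d$target_gene[1], tf = d$tf_id[best],
               bestRho = d$rho[best], minKwFdr = min(d$kwFdr),
               hypoSubtype = d$hypoSubtype[best], nTfbs = nrow(d),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$bestRho), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fracHypoBasalB") <- mean(out$hypoSubtype == "basalB")
  out
}
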