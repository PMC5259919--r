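test_that("shores flank islands, subtract islands, and clip at bounds", {
  sz <- c(chr1 = 1000000L)
  one <- gr0("chr1", 10000, 10500, sz)
  ss <- deriveShoresShelves(one, shoreWidth = 2000, shelfWidth = 2000)
  shores <- ss[mcols(ss)$label == "shore"]
  expect_equal(start(shores) - 1L, c(8000L, 10500L))
  expect_equal(end(shores), c(10000L, 12500L))

  ## two close islands: the inter-island shore is island-subtracted
  two <- gr0("chr1", c(10000, 11000), c(10500, 11400), sz)
  ss2 <- deriveShoresShelves(two, 2000, 2000)
  sh2 <- ss2[mcols(ss2)$label == "shore"]
  expect_true(any(start(sh2) - 1L == 10500 & end(sh2) == 11000))
  expect_equal(min(start(sh2)) - 1L, 8000L)
  expect_equal(max(end(sh2)), 13400L)

  ## island at the chromosome start: left shore empty
  edge <- gr0("chr1", 0, 300, sz)
  sh3 <- deriveShoresShelves(edge, 2000, 2000)
  sh3 <- sh3[mcols(sh3)$label == "shore"]
  expect_equal(length(sh3), 1L)
  expect_equal(c(start(sh3) - 1L, end(sh3)), c(300L, 2300L))

  ## out-of-bounds island is rejected; empty input is not an error
  bad <- suppressWarnings(
    GRanges("chr1", IRanges(999950, 1000200), seqlengths = sz))
  expect_error(deriveShoresShelves(bad), "beyond chromosome bounds")
  expect_length(deriveShoresShelves(one[0]), 0L)
})

test_that("islands, shores and shelves are pairwise disjoint (per-bp oracle)", {
  sz <- c(chrA = 100000L)
  set.seed(11)
  for (rep in 1:5) {
    s0 <- sort(sample(0:99000, 8))
    isl <- gr0("chrA", s0, pmin(s0 + sample(200:1500, 8, TRUE), 100000), sz)
    isl <- reduce(isl)
    seqlengths(isl) <- sz
    ss <- deriveShoresShelves(isl, 2000, 2000)
    cIsl <- bpCoverage(isl, "chrA", 100000)
    cSho <- bpCoverage(ss[mcols(ss)$label == "shore"], "chrA", 100000)
    cShe <- bpCoverage(ss[mcols(ss)$label == "shelf"], "chrA", 100000)
    expect_false(any(cIsl & cSho))
    expect_false(any(cIsl & cShe))
    expect_false(any(cSho & cShe))
    ## brute-force shore definition: within shoreWidth of an island, not island
    near <- logical(100000)
    for (i in seq_along(isl)) {
      s <- max(1, start(isl)[i] - 2000); e <- min(100000, end(isl)[i] + 2000)
      near[s:e] <- TRUE
    }
    expect_equal(cSho, near & !cIsl)
  }
})

test_that("promoters obey strand, clipping and gene propagation", {
  sz <- c(chr1 = 1000000L)
  plus <- gr0("chr1", 50000, 53000, sz, strand = "+", gene_id = "gA")
  p <- derivePromoters(plus, 2000)
  expect_equal(c(start(p) - 1L, end(p)), c(48000L, 50000L))
  expect_equal(mcols(p)$gene_id, "gA")

  minus <- gr0("chr1", 47000, 50000, sz, strand = "-", gene_id = "gB")
  p <- derivePromoters(minus, 2000)
  expect_equal(c(start(p) - 1L, end(p)), c(50000L, 52000L))

  near0 <- gr0("chr1", 1500, 4000, sz, strand = "+", gene_id = "gC")
  p <- derivePromoters(near0, 2000)
  expect_equal(c(start(p) - 1L, end(p)), c(0L, 1500L))

  nostrand <- gr0("chr1", 100, 200, sz, strand = "*", gene_id = "gD")
  expect_error(derivePromoters(nostrand), "gD")
})

test_that("promoter derivation is an involution under genome reflection", {
  sz <- c(chr1 = 100000L)
  set.seed(3)
  s0 <- sort(sample(5000:90000, 10))
  genes <- gr0("chr1", s0, s0 + 3000, sz,
               strand = sample(c("+", "-"), 10, TRUE),
               gene_id = sprintf("g%02d", 1:10))
  p <- derivePromoters(genes, 2000)
  ## reflect: position x -> L - x + 1, strands flipped
  refl <- function(gr) {
    out <- GRanges("chr1",
                   IRanges(100000L - end(gr) + 1L, 100000L - start(gr) + 1L),
                   strand = chartr("+-", "-+", as.character(strand(gr))),
                   seqlengths = sz)
    mcols(out)$gene_id <- mcols(gr)$gene_id
    out
  }
  p2 <- refl(derivePromoters(refl(genes), 2000))
  o1 <- order(start(p)); o2 <- order(start(p2))
  expect_equal(ranges(p2)[o2], ranges(p)[o1])
  expect_equal(mcols(p2)$gene_id[o2], mcols(p)$gene_id[o1])
})

test_that("bin label assignment matches a per-basepair oracle", {
  sz <- c(chrA = 100000L)
  set.seed(21)
  labs <- c("CpGI", "gene", "exon", "intron", "promoter", "shore", "TFBS")
  s0 <- sample(0:99000, 60, replace = TRUE)
  regions <- gr0("chrA", s0, pmin(s0 + sample(50:3000, 60, TRUE), 100000), sz,
                 label = sample(labs, 60, TRUE))
  bins <- makeBinIndex(sz, 100)
  got <- assignBins(bins, regions)
  ## oracle: per label, per-bp coverage, bin labelled iff any covered bp
  for (l in labs) {
    cov <- bpCoverage(regions[mcols(regions)$label == l], "chrA", 100000)
    want <- vapply(seq_along(bins), function(k)
      any(cov[start(bins)[k]:end(bins)[k]]), logical(1))
    expect_equal(unname(vapply(got, function(x) l %in% x, logical(1))),
                 want, info = l)
  }
  ## intergenic: no overlap at all
  covAll <- bpCoverage(regions, "chrA", 100000)
  wantInter <- vapply(seq_along(bins), function(k)
    !any(covAll[start(bins)[k]:end(bins)[k]]), logical(1))
  expect_equal(vapply(got, function(x) identical(x, "intergenic"),
                      logical(1)), wantInter)
})

test_that("derived promoter intersection labels follow the literal overlap", {
  sz <- c(chr1 = 100000L)
  regions <- c(
    gr0("chr1", 48000, 50000, sz, label = "promoter"),
    gr0("chr1", 49000, 51000, sz, label = "shore"),
    gr0("chr1", 51000, 51500, sz, label = "CpGI"))
  bins <- makeBinIndex(sz, 100)
  got <- assignBins(bins, regions)
  binAt <- function(pos0) pos0 %/% 100 + 1
  expect_true("promoter_shore" %in% got[[binAt(49500)]])
  expect_false("promoter_shore" %in% got[[binAt(48200)]])   # promoter only
  expect_false("promoter_shore" %in% got[[binAt(50500)]])   # shore only
  expect_false("promoter_CpGI" %in% got[[binAt(51100)]])    # no overlap at all
  ## a bin straddling an island boundary inside the bin gets both classes
  regions2 <- c(gr0("chr1", 9950, 10450, sz, label = "CpGI"),
                gr0("chr1", 7950, 9950, sz, label = "shore"))
  got2 <- assignBins(makeBinIndex(sz, 100), regions2)
  expect_setequal(got2[[binAt(9900)]], c("CpGI", "shore"))
})

test_that("region BED and gene model files round-trip", {
  sz <- c(chr1 = 100000L)
  dir <- withr::local_tempdir()
  regions <- c(gr0("chr1", 1000, 2000, sz, label = "CpGI"),
               gr0("chr1", 5000, 5200, sz, label = "shore"))
  bed <- file.path(dir, "r.bed")
  writeRegionsBed(regions, bed)
  back <- readRegionsBed(bed, sz)
  expect_equal(start(back), start(regions))
  expect_equal(end(back), end(regions))
  expect_equal(mcols(back)$label, mcols(regions)$label)

  gm <- file.path(dir, "g.tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tgene_id\texon_starts\texon_ends",
               "chr1\t100\t3100\t+\tg1\t100,1300\t400,1600"), gm)
  models <- readGeneModels(gm, sz)
  expect_equal(start(models$genes) - 1L, 100L)
  expect_equal(length(models$exons), 2L)
  expect_equal(end(models$exons), c(400L, 1600L))
})
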