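subty <- factor(rep(c("basalA", "basalB"), each = 10),
                levels = c("luminal", "basalA", "basalB"))

test_that("per-bin Welch test agrees with t.test and flags planted bins", {
  set.seed(71)
  n <- 60
  m <- matrix(rnorm(n * 20, mean = 0.5, sd = 0.1), nrow = n)
  m[1:10, 11:20] <- m[1:10, 11:20] - 0.3        # planted hypo in basal B
  m <- pmin(pmax(m, 0), 1)
  meth <- tinyMeth(m, subty)
  res <- pairwiseBinTest(meth, c("basalA", "basalB"), alpha = 0.05)

  ## row-by-row agreement with stats::t.test (Welch)
  for (i in c(1, 5, 30, 60)) {
    tt <- t.test(m[i, 1:10], m[i, 11:20])
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
  }
  expect_equal(res$pAdj, pmin(1, res$p * attr(res, "mTested")))
  expect_true(all(res$significant[1:10]))
  expect_true(all(res$hypoIn[1:10] == "basalB"))
  expect_false(any(res$significant[11:60]))
})

test_that("equal group means are never significant; Bonferroni arithmetic", {
  set.seed(72)
  v <- matrix(0.8 + rnorm(50, sd = 0.05), nrow = 5)
  m <- cbind(v, v)                               # group B mirrors group A
  meth <- tinyMeth(m, subty)
  res <- pairwiseBinTest(meth, c("basalA", "basalB"))
  expect_true(all(res$p > 0.999))
  expect_true(all(res$hypoIn == "tie"))
  ## m = 1000 tested bins, raw p = 1e-4 -> p_adj = 0.1, not significant
  expect_equal(min(1, 1e-4 * 1000), 0.1)
  set.seed(8)
  m2 <- matrix(runif(1000 * 20), nrow = 1000)
  res2 <- pairwiseBinTest(tinyMeth(m2, subty), c("basalA", "basalB"))
  expect_equal(attr(res2, "mTested"), 1000L)
  expect_equal(res2$pAdj, pmin(1, res2$p * 1000))
})

test_that("degenerate inputs: NA cells skipped, tiny groups rejected", {
  m <- matrix(runif(80), nrow = 4)
  m[2, 3] <- NA
  m[3, ] <- 0.4                                  # zero variance in both groups
  meth <- tinyMeth(m, subty)
  res <- pairwiseBinTest(meth, c("basalA", "basalB"))
  expect_false(res$tested[2]); expect_false(res$tested[3])
  expect_equal(attr(res, "nSkippedNA"), 1L)
  expect_equal(attr(res, "nSkippedZeroVar"), 1L)
  expect_equal(attr(res, "mTested"), 2L)

  one <- tinyMeth(matrix(runif(4), 2), factor(c("basalA", "basalB")))
  expect_error(pairwiseBinTest(one, c("basalA", "basalB")), ">= 2 samples")
  expect_error(pairwiseBinTest(meth, c("luminal", "basalB")),
               "not found")
})

test_that("bin merging obeys gap and direction semantics", {
  mk <- function(sig, dir) {
    n <- length(sig)
    data.frame(bin = 1:n, chrom = "chr1", start = (0:(n - 1)) * 100,
               end = (1:n) * 100, pAdj = ifelse(sig, 1e-4, 0.5),
               significant = sig, hypoIn = dir, stringsAsFactors = FALSE)
  }
  r <- mk(c(TRUE, TRUE, TRUE), rep("basalB", 3))
  d <- mergeBinsToDmrs(r, 0)
  expect_equal(nrow(d), 1L); expect_equal(d$nBins, 3L)
  expect_equal(c(d$start, d$end), c(0L, 300L))

  r <- mk(c(TRUE, FALSE, TRUE), rep("basalB", 3))
  expect_equal(nrow(mergeBinsToDmrs(r, 0)), 2L)
  expect_equal(nrow(mergeBinsToDmrs(r, 1)), 1L)

  r <- mk(c(TRUE, TRUE), c("basalA", "basalB"))
  expect_equal(nrow(mergeBinsToDmrs(r, 0)), 2L)

  ## chromosome break splits a run even with adjacent indices
  r <- mk(c(TRUE, TRUE), c("basalB", "basalB"))
  r$chrom <- c("chr1", "chr2")
  expect_equal(nrow(mergeBinsToDmrs(r, 0)), 2L)
})

test_that("bin merging matches a run-length oracle on random vectors", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    sig <- runif(n) < 0.4
    dir <- sample(c("basalA", "basalB", "tie"), n, replace = TRUE,
                  prob = c(0.45, 0.45, 0.1))
    gap <- sample(0:2, 1)
    r <- data.frame(bin = 1:n, chrom = "chr1", start = (0:(n - 1)) * 100,
                    end = (1:n) * 100, pAdj = runif(n),
                    significant = sig, hypoIn = dir,
                    stringsAsFactors = FALSE)
    got <- mergeBinsToDmrs(r, gap)
    want <- dmrOracle(sig, dir, gap)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$binFrom, vapply(want, `[[`, 1L, "from"))
      expect_equal(got$binTo, vapply(want, `[[`, 1L, "to"))
      expect_equal(got$hypoIn, vapply(want, `[[`, "x", "dir"))
    }
  }
})

test_that("region counting multi-counts labels and ratios partition", {
  m <- matrix(runif(120), nrow = 6)
  meth <- tinyMeth(m, subty)
  labels <- as(list(c("intron", "gene"), "shore", c("shore", "promoter"),
                    "intergenic", "shore", "CpGI"), "CharacterList")
  res <- pairwiseBinTest(meth, c("basalA", "basalB"))
  res$significant <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res$hypoIn <- c("basalB", "basalB", "basalA", "basalA", "basalA", "tie")
  counts <- countByRegion(res, labels)
  expect_equal(counts[["intron"]], 1L)
  expect_equal(counts[["gene"]], 1L)
  expect_equal(counts[["shore"]], 2L)
  expect_equal(counts[["intergenic"]], 0L)

  rat <- hypomethylationRatio(res, labels, "shore")
  expect_equal(as.vector(rat), c(0.5, 0.5))
  expect_equal(sum(rat), 1)
  ## 8 of 10 hypo in basal B -> 0.8
  res$significant <- rep(TRUE, 6)
  res$hypoIn <- c(rep("basalB", 4), "basalA", "basalB")
  lab10 <- as(as.list(rep("shore", 6)), "CharacterList")
  r2 <- hypomethylationRatio(res, lab10, "shore")
  expect_equal(unname(r2[["basalB"]]), 5 / 6)
  ## empty region -> NA
  rNA <- hypomethylationRatio(res, lab10, "shelf")
  expect_true(all(is.na(rNA)))
  expect_equal(attr(rNA, "nBins"), 0L)
})

test_that("all-zero table when nothing is significant", {
  m <- matrix(0.5 + rnorm(80, sd = 0.01), nrow = 4)
  meth <- tinyMeth(m, subty)
  res <- pairwiseBinTest(meth, c("basalA", "basalB"))
  labels <- as(as.list(rep("shore", 4)), "CharacterList")
  expect_true(all(countByRegion(res, labels) == 0))
})

test_that("family-wise error is controlled under the null", {
  ## pure-noise generator runs, 50 quick replicates at 500 bins
  cfg <- simConfig(seed = 100, nChroms = 1L, chromLen = 5e4, nIslands = 1L,
                   nGenes = 1L, nCoupledGenes = 1L, nPlantedShoreBins = 10L,
                   shoreHypoEffect = 0, boundaryPeakEffect = 0)
  genome <- simulateGenome(cfg)
  fam <- logical(50)
  for (i in seq_len(50)) {
    cfg$seed <- 100 + i
    meth <- simulateMethylation(genome, cfg)
    res <- pairwiseBinTest(meth, c("basalA", "basalB"), alpha = 0.05)
    fam[i] <- any(res$significant)
  }
  expect_lte(mean(fam), 0.05 + 3 * sqrt(0.05 * 0.95 / 50))
})
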