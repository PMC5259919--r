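obsRow <- function(cov, mm, sample = "s1", pos = 1L, rms = 0.5)
  data.frame(chrom = "chr1", pos = pos, sample = sample, coverage = cov,
             mismatches = mm, rms = rms, stringsAsFactors = FALSE)

test_that("binomial caller: worked examples and filters", {
  calls <- callMutations(rbind(obsRow(30, 0), obsRow(30, 15),
                               obsRow(5, 5, pos = 3L)))
  expect_equal(calls$pError[1], 1)
  expect_false(calls$isMutated[1])
  expect_lt(calls$pError[2], 1e-6)
  expect_true(calls$isMutated[2])
  ## low coverage excluded regardless of mismatches
  expect_false(calls$eligible[3])
  expect_false(calls$isMutated[3])
  ## malformed records rejected
  expect_error(callMutations(obsRow(10, 11)), "mismatches > coverage")
  ## coverage above the cap is subsampled proportionally
  capped <- callMutations(obsRow(500, 250))
  expect_equal(capped$pError,
               pbinom(124, 250, 0.002, lower.tail = FALSE))
})

test_that("caller tail probabilities match an exact summation oracle", {
  set.seed(61)
  cov <- sample(10:250, 100, replace = TRUE)
  mm <- vapply(cov, function(n) sample(0:min(n, 20), 1), integer(1))
  calls <- callMutations(do.call(rbind, Map(obsRow, cov, mm,
                                            pos = seq_along(cov))))
  want <- mapply(binomTailOracle, mm, cov, MoreArgs = list(p = 0.002))
  expect_equal(calls$pError, want, tolerance = 1e-12)
})

test_that("caller false-positive rate under the null is below its level", {
  set.seed(62)
  n <- 20000
  cov <- pmin(rpois(n, 30), 250)
  mm <- rbinom(n, cov, 0.002)
  calls <- callMutations(do.call(rbind, list(data.frame(
    chrom = "chr1", pos = seq_len(n), sample = "s1", coverage = cov,
    mismatches = mm, rms = 0.5, stringsAsFactors = FALSE))))
  fpr <- mean(calls$isMutated[calls$eligible])
  alpha <- attr(calls, "callAlpha")
  expect_lte(fpr, alpha + 3 * sqrt(alpha * (1 - alpha) / n))
})

test_that("stratified mutation rates: definitions and conservation", {
  subtype <- setNames(factor(c("luminal", "luminal", "basalA", "basalA",
                               "basalB", "basalB")),
                      sprintf("s%d", 1:6))
  set.seed(63)
  ## 100 eligible observations for luminal in one stratum, 5 mutated
  d <- data.frame(chrom = "chr1", pos = rep(1:50, 2),
                  sample = rep(c("s1", "s2"), each = 50),
                  coverage = 30L, mismatches = 0L, rms = 0.32,
                  stringsAsFactors = FALSE)
  d$mismatches[1:5] <- 15L
  calls <- callMutations(d)
  rt <- mutationRateByMethylation(calls, subtype, stratumWidth = 0.05)
  row <- rt[rt$subtype == "luminal" & abs(rt$lo - 0.30) < 1e-9, ]
  expect_equal(row$nSites, 100L)
  expect_equal(row$nMutated, 5L)
  expect_equal(row$rate, 0.05)
  ## empty strata are NA, not zero
  expect_true(all(is.na(rt$rate[rt$nSites == 0])))
  expect_true(all(rt$nSites[rt$subtype %in% c("basalA", "basalB")] == 0))
  ## conservation: mutated counts across strata equal total calls
  expect_equal(sum(rt$nMutated), sum(calls$isMutated))
  ## strata partition [0,1]
  strata <- unique(rt[, c("lo", "hi")])
  strata <- strata[order(strata$lo), ]
  expect_equal(strata$lo[-1], strata$hi[-nrow(strata)], tolerance = 1e-9)
  expect_equal(c(strata$lo[1], strata$hi[nrow(strata)]), c(0, 1))
})

test_that("stratum ANOVA: m=1 Bonferroni, null control and planted power", {
  subtype <- setNames(rep(factor(c("luminal", "basalA", "basalB")),
                          each = 10),
                      sprintf("s%02d", 1:30))
  set.seed(64)
  ## single tested stratum: pAdj equals p
  rates <- matrix(NA_real_, 20, 30,
                  dimnames = list(sprintf("st%02d", 1:20), names(subtype)))
  rates[5, ] <- runif(30, 0, 0.1)
  sa <- stratumAnova(rates, subtype)
  expect_equal(sum(!is.na(sa$p)), 1L)
  expect_equal(sa$pAdj[5], sa$p[5])
  ## identical subtype distributions: few false flags over replicates
  flagged <- vapply(1:40, function(i) {
    r <- matrix(rbinom(20 * 30, 100, 0.03) / 100, 20, 30,
                dimnames = list(sprintf("st%02d", 1:20), names(subtype)))
    any(stratumAnova(r, subtype)$significant)
  }, logical(1))
  expect_lte(mean(flagged), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
  ## 3x rate difference in chosen strata is detected there and only there
  r <- matrix(rbinom(20 * 30, 200, 0.01) / 200, 20, 30,
              dimnames = list(sprintf("st%02d", 1:20), names(subtype)))
  r[1:5, subtype == "basalA"] <-
    rbinom(5 * 10, 200, 0.03) / 200
  sa <- stratumAnova(r, subtype)
  expect_true(all(sa$significant[1:5]))
  expect_false(any(sa$significant[11:20]))
})

test_that("subtype-specific classification: worked examples", {
  nPer <- c(luminal = 10L, basalA = 10L, basalB = 10L)
  cc <- callsFromCarriers(rbind(
    c(luminal = 0L, basalA = 4L, basalB = 0L),   # basalA-specific (0.4,0,0)
    c(luminal = 0L, basalA = 4L, basalB = 2L),   # not specific (0.2 >= 0.1)
    c(luminal = 1L, basalA = 10L, basalB = 0L),  # 0.1 not < 0.1 -> excluded
    c(luminal = 0L, basalA = 3L, basalB = 0L)),  # exactly 0.30 qualifies
    nPer)
  spec <- classifySubtypeSpecific(cc$calls, cc$subtype)
  expect_equal(spec$pos, c(1L, 4L))
  expect_equal(spec$assigned, c("basalA", "basalA"))
  expect_equal(spec$freq_basalA, c(0.4, 0.3))
  expect_error(classifySubtypeSpecific(cc$calls, cc$subtype,
                                       minIn = 0.1, maxOut = 0.1),
               "minIn must exceed maxOut")
})

test_that("classification matches brute force over all carrier grids", {
  nPer <- c(luminal = 10L, basalA = 10L, basalB = 10L)
  grid <- expand.grid(luminal = 0:10, basalA = 0:10, basalB = 0:10)
  counts <- as.matrix(grid)
  ## drop the all-zero row: no calls at that site at all
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  cc <- callsFromCarriers(counts, nPer)
  spec <- classifySubtypeSpecific(cc$calls, cc$subtype)
  want <- apply(counts / 10, 1L, function(f)
    specificOracle(as.list(f)))
  wantIdx <- which(!is.na(want))
  expect_equal(spec$pos, wantIdx)
  expect_equal(spec$assigned, unname(want[wantIdx]))
})

test_that("classification is equivariant under subtype relabelling", {
  nPer <- c(luminal = 10L, basalA = 10L, basalB = 10L)
  set.seed(65)
  counts <- matrix(sample(0:10, 60, replace = TRUE), ncol = 3,
                   dimnames = list(NULL, names(nPer)))
  cc <- callsFromCarriers(counts, nPer)
  spec <- classifySubtypeSpecific(cc$calls, cc$subtype)
  ## relabel: swap basalA and basalB everywhere
  swap <- c(luminal = "luminal", basalA = "basalB", basalB = "basalA")
  subtype2 <- setNames(factor(swap[as.character(cc$subtype)],
                              levels = levels(cc$subtype)),
                       names(cc$subtype))
  spec2 <- classifySubtypeSpecific(cc$calls, subtype2)
  expect_equal(spec2$pos, spec$pos)
  expect_equal(spec2$assigned, unname(swap[spec$assigned]))
})

test_that("regional counts recover the planted regional bias", {
  cfg <- simConfig(seed = 29, nSites = 1500L, specificFraction = 0.1)
  sim <- simulateStudy(cfg)
  calls <- callMutations(sim$mut$sites)
  spec <- classifySubtypeSpecific(calls, subtypes(sim$meth))
  reg <- regionalMutationCounts(spec, calls, sim$meth)
  cpgRelated <- colSums(reg$counts[c("CpGI", "shore", "shelf"), ])
  expect_equal(names(which.max(cpgRelated)), "basalA")
  expect_equal(names(which.max(reg$counts["intron", ])), "basalB")
  ## empty input gives a zero table
  reg0 <- regionalMutationCounts(spec[0, ], calls, sim$meth)
  expect_true(all(reg0$counts == 0))
  expect_true(all(is.na(reg0$anova$p)))
})
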