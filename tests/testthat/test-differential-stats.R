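test_that("size factors follow the median-of-ratios formula", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
  expect_equal(unname(countSizeFactors(m)), c(1, 1))
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- countSizeFactors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  ## direct-formula oracle on a random 51 x 4 matrix (odd feature count, so
  ## the median ratio is a single element and no averaging convention enters)
  withr::with_seed(5, {
    m3 <- matrix(rpois(204, 50) + 1, 51, 4)
    ref <- exp(rowMeans(log(m3)))
    oracle <- apply(m3, 2, function(cnt) median(cnt / ref))
    expect_equal(unname(countSizeFactors(m3)), unname(oracle),
                 tolerance = 1e-12)
    ## feature-order invariance
    expect_equal(countSizeFactors(m3[sample(51), ]), countSizeFactors(m3))
  })
  ## agreement with the reference implementation
  expect_equal(unname(countSizeFactors(m3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-10)
  expect_warning(countSizeFactors(cbind(c(0, 5), c(5, 0))), "falling back")
})

test_that("nbTest: exact zero l2fc on symmetric layouts, flags all-zero features", {
  withr::with_seed(7, {
    base <- matrix(rnbinom(100 * 2, mu = 50, size = 10), 100, 2)
    counts <- cbind(base, base)  # groups contain identical sample pairs
    res <- nbTest(counts, rep(c("a", "b"), each = 2))
    expect_equal(res$l2fc, rep(0, 100))
    counts[3, ] <- 0
    res2 <- nbTest(counts, rep(c("a", "b"), each = 2))
    expect_identical(res2$flag[3], "all_zero")
    expect_equal(res2$pvalue[3], 1)
    expect_equal(res2$l2fc[3], 0)
  })
})

test_that("nbTest p-values are calibrated under the null", {
  withr::with_seed(8, {
    mu <- exp(rnorm(1000, log(200), 0.7))
    counts <- matrix(rnbinom(1000 * 6, mu = rep(mu, 6), size = 1 / 0.05), 1000)
    res <- nbTest(counts, rep(c("a", "b"), each = 3))
    expect_lt(mean(res$pvalue < 0.05), 0.07)
    ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
  })
})

test_that("nbTest approaches a z-test on log counts in the large-count Poisson limit", {
  withr::with_seed(9, {
    n <- 300; mu <- 1e4
    counts <- matrix(rpois(n * 6, mu), n, 6)
    res <- nbTest(counts, rep(c("a", "b"), each = 3),
                  dispersion = "fixed", dispFixed = 1e-8,
                  sizeFactors = rep(1, 6))
    lg <- log(counts)
    z <- (rowMeans(lg[, 4:6]) - rowMeans(lg[, 1:3])) / sqrt(2 / (3 * mu))
    pOracle <- 2 * pnorm(-abs(z))
    relDev <- abs(res$pvalue - pOracle) / pOracle
    expect_lt(median(relDev), 0.1)
    expect_gt(mean(relDev < 0.1), 0.9)
  })
})

test_that("BH adjustment reproduces the hand-computed step-up and its properties", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(10, {
    p <- runif(50)
    expect_true(all(bhAdjust(p) >= p))
    ord <- sample(50)
    expect_equal(bhAdjust(p)[ord], bhAdjust(p[ord]))
  })
  expect_identical(bhAdjust(numeric()), numeric())
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("volcano classification uses strict boundaries and matches a filter oracle", {
  empty <- data.frame(feature_id = character(), l2fc = numeric(),
                      pvalue = numeric(), padj = numeric())
  cls0 <- classifyVolcano(empty)
  expect_identical(attr(cls0, "n_up") + attr(cls0, "n_down") +
                     attr(cls0, "n_nonsig"), 0L)
  ## exact boundary: l2fc == cut is nonsig, p == cut is nonsig
  rec <- data.frame(feature_id = c("a", "b", "c"),
                    l2fc = c(0.5, 0.51, -0.6),
                    pvalue = c(0.001, 0.01, 0.002),
                    padj = c(0.01, 0.05, 0.01))
  cls <- classifyVolcano(rec, p_cut = 0.01, l2fc_cut = 0.5)
  expect_identical(as.character(cls$class), c("nonsig", "nonsig", "down"))
  withr::with_seed(11, {
    rnd <- data.frame(feature_id = paste0("f", 1:500),
                      l2fc = rnorm(500), pvalue = runif(500))
    rnd$padj <- bhAdjust(rnd$pvalue)
    got <- classifyVolcano(rnd, p_cut = 0.05, l2fc_cut = 1)
    oracle <- ifelse(rnd$pvalue < 0.05 & rnd$l2fc > 1, "up",
                     ifelse(rnd$pvalue < 0.05 & rnd$l2fc < -1, "down",
                            "nonsig"))
    expect_identical(as.character(got$class), oracle)
    ## partitions disjoint and exhaustive by construction of the oracle
    adj <- classifyVolcano(rnd, p_cut = 0.05, l2fc_cut = 1,
                           use_adjusted = TRUE)
    expect_true(all(as.character(adj$class)[adj$padj >= 0.05] == "nonsig"))
  })
})

test_that("direction fractions reproduce the printed percentage styles", {
  expect_identical(directionFractions(3071, 3462), 88.7)
  expect_identical(directionFractions(155, 3462), 4.48)
  expect_identical(directionFractions(1602, 3071), 52.2)
  expect_identical(directionFractions(44425, 308630), 14.4)
  expect_identical(directionFractions(0, 100), 0)
  expect_lte(sum(directionFractions(c(3071, 155), 3462)), 100)
  expect_error(directionFractions(5, 0), "positive")
  expect_error(directionFractions(c(60, 50), 100), "exceed")
})

test_that("delta-delta-Ct fold changes follow the closed form", {
  expect_equal(ddctFoldChange(20, 15, 22, 17), 1)     # ddCt = 0
  expect_equal(ddctFoldChange(20, 15, 22, 16), 2)     # ddCt = -1
  expect_equal(ddctFoldChange(24, 15, 22, 15), 0.25)  # ddCt = +2
  expect_error(ddctFoldChange(NA, 1, 1, 1))
})

licGridOracle <- function(assay) {
  ll <- function(f) {
    pNeg <- exp(-f * assay$dose)
    nPos <- assay$n_tested - assay$n_negative
    sum(assay$n_negative * (-f * assay$dose) +
          ifelse(nPos > 0, nPos * log1p(-pNeg), 0))
  }
  lo <- -9; hi <- -1
  for (round in 1:5) {
    grid <- 10^seq(lo, hi, length.out = 401)
    lls <- vapply(grid, ll, numeric(1))
    i <- which.max(lls)
    lo <- log10(grid[max(1, i - 1)]); hi <- log10(grid[min(401, i + 1)])
  }
  grid[i]
}

test_that("limiting-dilution frequency: closed form, grid oracle, scale consistency", {
  ## single dose closed form: f = -ln(5/10)/1000
  fit <- licFrequency(data.frame(dose = 1000, n_tested = 10, n_negative = 5))
  expect_equal(fit$frequency, -log(0.5) / 1000, tolerance = 1e-6)
  expect_true(fit$ci[1] < fit$frequency && fit$frequency < fit$ci[2])
  ## boundary: all negative
  fit0 <- licFrequency(data.frame(dose = c(500, 5000), n_tested = c(5, 5),
                                  n_negative = c(5, 5)))
  expect_equal(fit0$frequency, 0)
  expect_identical(fit0$flag, "all_negative")
  expect_gt(fit0$ci[2], 0)
  ## boundary: all engrafted
  fitI <- licFrequency(data.frame(dose = 500, n_tested = 5, n_negative = 0))
  expect_identical(fitI$flag, "all_positive")
  expect_true(is.infinite(fitI$frequency) && is.finite(fitI$ci[1]))
  ## random three-dose tables vs zooming log-grid search
  withr::with_seed(12, {
    for (k in 1:5) {
      f_true <- 10^runif(1, -5, -3)
      dose <- c(1e3, 1e4, 1e5)
      nneg <- rbinom(3, 10, exp(-f_true * dose))
      if (all(nneg == 10) || all(nneg == 0)) next
      assay <- data.frame(dose = dose, n_tested = 10, n_negative = nneg)
      fit <- licFrequency(assay)
      expect_equal(fit$frequency, licGridOracle(assay), tolerance = 1e-6)
      ## scale consistency: doses x 100 -> frequency / 100
      assay2 <- assay; assay2$dose <- assay2$dose * 100
      expect_equal(licFrequency(assay2)$frequency, fit$frequency / 100,
                   tolerance = 1e-12)
    }
  })
})

test_that("likelihood-ratio comparison separates distinct engraftment frequencies", {
  withr::with_seed(13, {
    dose <- c(1e3, 1e4, 1e5)
    mk <- function(f) data.frame(dose = dose, n_tested = 20,
                                 n_negative = rbinom(3, 20, exp(-f * dose)))
    aHi <- mk(1e-3); aLo <- mk(1e-5)
    expect_lt(licCompare(aHi, aLo)$pvalue, 0.01)
    same1 <- mk(1e-4); same2 <- mk(1e-4)
    expect_gt(licCompare(same1, same2)$pvalue, 0.01)
  })
})

test_that("resampled single-cell DE: null behaviour, planted recovery, determinism", {
  withr::with_seed(14, {
    nGenes <- 80; nCells <- 1200
    mu <- exp(rnorm(nGenes, log(5), 0.6))
    counts <- matrix(rpois(nGenes * nCells, mu), nGenes,
                     dimnames = list(paste0("g", 1:nGenes), NULL))
    nullLabels <- sample(rep(c(TRUE, FALSE), each = nCells / 2))
    resNull <- resampledScDE(counts, nullLabels, n_cells = 300, seed = 42)
    expect_lt(mean(abs(resNull$mean_logfc)), 0.05)
    expect_lt(mean(resNull$mean_padj < 0.05), 0.10)
    ## planted 4-fold genes in the positive group
    planted <- 1:20
    countsP <- counts
    pos <- nullLabels
    countsP[planted, pos] <- matrix(
      rpois(length(planted) * sum(pos), 4 * mu[planted]), length(planted))
    resP <- resampledScDE(countsP, pos, n_cells = 300, seed = 42)
    expect_gte(mean(resP$mean_padj[planted] < 0.05), 0.9)
    expect_true(all(resP$mean_logfc[planted] > 0))
    ## determinism
    expect_identical(resP, resampledScDE(countsP, pos, n_cells = 300, seed = 42))
    expect_false(identical(resP$mean_padj,
                           resampledScDE(countsP, pos, n_cells = 300,
                                         seed = 43)$mean_padj))
  })
})

test_that("one full-size iteration of resampledScDE equals a plain test run", {
  withr::with_seed(15, {
    nGenes <- 40
    counts <- matrix(rpois(nGenes * 200, 8), nGenes,
                     dimnames = list(paste0("g", 1:nGenes), NULL))
    grp <- rep(c(TRUE, FALSE), each = 100)
    res <- resampledScDE(counts, grp, n_iter = 1, n_cells = 100, seed = 1)
    ## oracle: single Wilcoxon rank-sum per gene on log2 CP10K, BH-adjusted
    libs <- colSums(counts)
    logm <- log2(1 + sweep(counts, 2, libs / 1e4, "/"))
    pOracle <- vapply(seq_len(nGenes), function(i)
      suppressWarnings(wilcox.test(logm[i, grp], logm[i, !grp])$p.value),
      numeric(1))
    expect_equal(res$mean_padj, bhAdjust(pOracle), tolerance = 1e-10)
    cp <- function(ix) rowMeans(sweep(counts[, ix], 2, libs[ix] / 1e4, "/"))
    expect_equal(res$mean_logfc,
                 unname(log2((cp(which(grp)) + 1) / (cp(which(!grp)) + 1))),
                 tolerance = 1e-10)
  })
})
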