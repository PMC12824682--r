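test_that("lineage scores follow the other-lineage normalization formula", {
  sets <- list(myeloid = c("p1", "p2"), erythroid = c("p3", "p4"),
               lymphoid = c("p5", "p6"))
  m <- matrix(0, 6, 3, dimnames = list(paste0("p", 1:6), paste0("c", 1:3)))
  m[c("p1", "p2"), 1] <- c(4, 6)      # only myeloid insertions
  m[, 2] <- 2                          # equal insertions everywhere
  sc <- lineageScores(m, sets)
  expect_equal(unname(sc[1, ]), c(10 / 1, 0, 0))
  expect_equal(unname(sc[2, ]), rep(4 / 5, 3))  # c=4 vs mean(4,4)+1
  expect_equal(unname(sc[3, ]), c(0, 0, 0))     # zero-insertion cell
  expect_equal(attr(sc, "zero_cells"), 3L, ignore_attr = TRUE)
  ## random matrix vs direct summation oracle
  withr::with_seed(81, {
    big <- matrix(rpois(6 * 50, 3), 6, 50, dimnames = list(paste0("p", 1:6), NULL))
    got <- lineageScores(big, sets, pseudocount = 1)
    for (i in 1:3) {
      own <- colSums(big[sets[[i]], ])
      oth <- sapply(setdiff(1:3, i), function(j) colSums(big[sets[[j]], ]))
      expect_equal(unname(got[, i]), unname(own / (rowMeans(oth) + 1)))
    }
  })
  expect_error(lineageScores(m, sets[1:2]), "three")
  expect_error(lineageScores(m, list(a = c("p1", "p2"), b = c("p2", "p3"),
                                     c = c("p5", "p6"))), "disjoint")
})

test_that("cisRE scores: bounded, quantile-capped, monotone in a cell's own counts", {
  withr::with_seed(82, {
    nP <- 40; nC <- 500
    counts <- matrix(rpois(nP * nC, 2), nP, nC,
                     dimnames = list(paste0("p", 1:nP), NULL))
    tss <- rpois(nC, 50) + 1
    ids <- paste0("p", 1:10)
    sc <- cisreScores(counts, ids, tssCounts = tss)
    expect_true(all(sc >= 0 & sc <= 1))
    ## zero network counts -> score 0
    c0 <- counts; c0[1:10, 7] <- 0
    expect_equal(cisreScores(c0, ids, tssCounts = tss)[7], 0)
    ## at most ~1% of cells strictly above the cap pre-clipping
    raw <- attr(sc, "raw")
    q <- quantile(raw, 0.99, names = FALSE)
    expect_lte(sum(raw > q), ceiling(0.01 * nC) + sum(raw == q))
    expect_equal(max(sc), 1)
    ## monotone: raising one cell's network counts never lowers its score
    for (k in 1:20) {
      i <- sample(nC, 1)
      j <- sample(10, 1)
      c2 <- counts
      c2[j, i] <- c2[j, i] + sample(5, 1)
      s2 <- cisreScores(c2, ids, tssCounts = tss)
      expect_gte(s2[i] + 1e-12, sc[i])
    }
    ## degenerate: all-zero network
    cz <- counts; cz[1:10, ] <- 0
    sz <- cisreScores(cz, ids, tssCounts = tss)
    expect_true(all(sz == 0))
    expect_identical(attr(sz, "flag"), "zero_cap")
  })
})

test_that("Tn5 weights invert the global insertion rate and average to one", {
  withr::with_seed(83, {
    m <- matrix(rpois(200, rep(c(1, 4), each = 50)), 100, 2,
                dimnames = list(paste0("p", 1:100), NULL))
    w <- computeTn5Weights(m)
    expect_equal(mean(w), 1)
    rate <- rowMeans(m)
    nz <- rate > 0
    expect_equal(unname(w[nz] / w[which(nz)[1]]),
                 unname(rate[which(nz)[1]] / rate[nz]))
  })
})

test_that("Spearman correlation matches the exhaustive rank formula at n = 8", {
  expect_equal(scoreCorrelation(1:10, (1:10)^2)$rho, 1)
  expect_equal(scoreCorrelation(1:10, -(1:10))$rho, -1)
  expect_identical(scoreCorrelation(rep(1, 5), 1:5)$flag, "constant_input")
  withr::with_seed(84, {
    for (k in 1:20) {
      a <- rnorm(8); b <- rnorm(8)
      got <- scoreCorrelation(a, b)
      d <- rank(a) - rank(b)
      rhoOracle <- 1 - 6 * sum(d^2) / (8 * (8^2 - 1))  # no ties a.s.
      expect_equal(got$rho, rhoOracle, tolerance = 1e-12)
      tOracle <- rhoOracle * sqrt(6 / (1 - rhoOracle^2))
      expect_equal(got$p, 2 * pt(-abs(tOracle), df = 6), tolerance = 1e-12)
      ## agreement with the reference implementation
      ct <- suppressWarnings(cor.test(a, b, method = "spearman",
                                      exact = FALSE))
      expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
    }
  })
})

test_that("RNA signature scores are mean log-normalized expression over the set", {
  m <- matrix(c(0, 0, 10, 30, 5, 5), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  m[, 1] <- 0  # all-zero cell scores 0
  sc <- signatureScoresRna(m, c("g1", "g2", "g3"))
  expect_equal(sc[1], 0)
  logm <- log2(1 + sweep(m, 2, pmax(colSums(m), 1) / 1e4, "/"))
  expect_equal(sc, unname(colMeans(logm)))
  expect_error(signatureScoresRna(m, c("nope1", "nope2")), "missing")
})

test_that("resampled group comparison: null rate, planted shift, determinism", {
  withr::with_seed(85, {
    nC <- 800
    grp <- rep(c(TRUE, FALSE), each = nC / 2)
    nullScores <- matrix(rnorm(nC * 30), nC, 30,
                         dimnames = list(NULL, paste0("s", 1:30)))
    resNull <- compareGroupsResampled(nullScores, grp, n_cells = 200,
                                      seed = 5)
    expect_lt(mean(resNull$mean_p < 0.05), 0.10)
    ## planted one-sd shift
    shifted <- nullScores[, 1] + ifelse(grp, 1, 0)
    resS <- compareGroupsResampled(cbind(shift = shifted), grp,
                                   n_cells = 200, seed = 5)
    expect_lt(resS$mean_p, 1e-3)
    expect_gt(resS$mean_diff, 0.8)
    expect_identical(resS,
                     compareGroupsResampled(cbind(shift = shifted), grp,
                                            n_cells = 200, seed = 5))
    ## small groups are flagged as resampled with replacement
    resR <- compareGroupsResampled(rnorm(50), rep(c(TRUE, FALSE), 25),
                                   n_cells = 200, seed = 1)
    expect_true(resR$resampled_with_replacement)
    expect_error(compareGroupsResampled(rnorm(10), rep(TRUE, 10)),
                 "both groups")
  })
})

test_that("pseudotime minibulks: binning, normalization and the group-by oracle", {
  ## 100 cells at pseudotime k/100 -> exactly one cell per bin
  m <- matrix(rpois(500, 5), 5, 100, dimnames = list(paste0("g", 1:5), NULL))
  mb <- pseudotimeMinibulks(m, (1:100) / 100, n_bins = 100, modality = "rna")
  expect_true(all(mb$cellCounts == 1))
  expect_equal(sum(mb$cellCounts), 100)
  ## all cells in one bin: that column is the total-sum normalization
  mb1 <- pseudotimeMinibulks(m, rep(0.5, 100), n_bins = 10, modality = "rna")
  expect_equal(sum(mb1$cellCounts > 0), 1)
  filled <- which(mb1$cellCounts > 0)
  expect_equal(mb1$matrix[, filled],
               rowSums(m) / sum(m) * 1e4, ignore_attr = TRUE)
  expect_true(all(is.na(mb1$matrix[, -filled])))
  ## atac normalization and brute-force group-by agreement
  withr::with_seed(86, {
    pt <- runif(100)
    tss <- rpois(100, 30) + 1
    w <- setNames(runif(5, 0.5, 2), rownames(m))
    mba <- pseudotimeMinibulks(m, pt, n_bins = 7, modality = "atac",
                               tssCounts = tss, tn5Weights = w)
    bin <- pmin(floor((pt - min(pt)) / (max(pt) - min(pt)) * 7) + 1, 7)
    for (b in 1:7) {
      ix <- which(bin == b)
      expect_equal(mba$cellCounts[b], length(ix))
      if (length(ix))
        expect_equal(mba$matrix[, b],
                     rowSums(m[, ix, drop = FALSE]) * w / sum(tss[ix]),
                     ignore_attr = TRUE)
    }
    expect_equal(sum(mba$cellCounts), 100)
  })
  expect_error(pseudotimeMinibulks(m, (1:100) / 100, n_bins = 1), "at least 2")
  expect_error(pseudotimeMinibulks(m, c(NA, runif(99))), "present for all")
})
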