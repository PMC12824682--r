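networkFixture <- function() {
  if (is.null(.fixtureCache$net)) {
    cfg <- smallConfig(1)
    ann <- cachedSmallAnn()
    atac <- simulateBulkCounts(cfg, ann, "atac", "6h")
    diff <- nbTest(atac$counts, atac$groups)
    bound <- boundDifferentialPeaks(diff, ann$peaks, ann$chip)
    .fixtureCache$net <- list(cfg = cfg, ann = ann, diff = diff,
                              bound = bound,
                              network = selectDirectNetwork(bound))
  }
  .fixtureCache$net
}

test_that("bound differential peaks: overlap flags match the oracle and show planted enrichment", {
  fx <- networkFixture()
  ann <- fx$ann
  ## no ChIP peaks -> nothing bound
  none <- boundDifferentialPeaks(fx$diff, ann$peaks, GRanges())
  expect_false(any(mcols(none)$bound))
  ## chromosome mismatch
  badChip <- GRanges("chrX", IRanges(1, 100))
  mcols(badChip)$score <- 10
  expect_error(boundDifferentialPeaks(fx$diff, ann$peaks, badChip),
               "chromosome mismatch")
  ## bound flags and max scores agree with the quadratic oracle
  bound <- fx$bound
  ov <- overlapOracle(ann$peaks, ann$chip)
  boundIdx <- mcols(ann$peaks)$name[unique(ov[, 1])]
  expect_setequal(mcols(bound)$name[mcols(bound)$bound],
                  intersect(mcols(bound)$name, boundIdx))
  for (nm in sample(mcols(bound)$name[mcols(bound)$bound], 10)) {
    i <- match(nm, mcols(ann$peaks)$name)
    expect_equal(mcols(bound)$chip_score[match(nm, mcols(bound)$name)],
                 max(mcols(ann$chip)$score[ov[ov[, 1] == i, 2]]))
  }
  ## planted design: up peaks are enriched for binding over the background
  expect_gt(attr(bound, "bound_fraction_up"), attr(bound, "bound_fraction_all"))
})

test_that("network selection: strict score cutoff, monotonicity, planted recovery", {
  fx <- networkFixture()
  net <- fx$network
  ids <- mcols(cisElements(net))$name
  truth <- fx$ann$truth$directCisreIds
  rec <- length(intersect(ids, truth)) / length(truth)
  prec <- length(intersect(ids, truth)) / length(ids)
  expect_gte(rec, 0.9)
  expect_gte(prec, 0.85)
  ## subset chain: network <= bound-and-differential <= differential
  expect_true(all(ids %in% mcols(fx$bound)$name[mcols(fx$bound)$bound]))
  ## raising the cutoff never grows the network
  sizes <- vapply(c(0, 25, 50, 100, 200), function(ct)
    length(cisElements(selectDirectNetwork(fx$bound, score_cut = ct))),
    numeric(1))
  expect_false(is.unsorted(rev(sizes)))
  ## scores exactly at the cutoff are excluded; all <= cut gives empty
  toy <- fx$bound
  mcols(toy)$chip_score <- rep(50, length(toy))
  expect_length(cisElements(selectDirectNetwork(toy, score_cut = 50)), 0)
})

test_that("eRNA comparison: identical tracks are null, planted induction is detected, profile composes", {
  fx <- networkFixture()
  cfg <- fx$cfg
  trT <- simulateTracks(cfg, fx$ann, "treated")
  trC <- simulateTracks(cfg, fx$ann, "control")
  same <- ernaCompare(fx$network, trT, trT)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  res <- ernaCompare(fx$network, trT, trC)
  expect_gt(mean(res$perCisre$mean_treated), mean(res$perCisre$mean_control))
  expect_lt(res$p, 0.01)
  ## aggregate profile equals the mean of per-anchor profiles
  prof <- windowDensity(trT, cisElements(fx$network), 2000, mode = "profile")
  expect_equal(res$profileTreated, colMeans(prof, na.rm = TRUE))
  expect_length(res$profileTreated, 4001)
})

test_that("motif enrichment: exchangeable sets are null, planted motifs rank first, tail is exact", {
  pwms <- readPfm(system.file("extdata", "motifs.pfm", package = "degronet"))
  withr::with_seed(61, {
    seqs <- vapply(1:200, function(i)
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
            collapse = ""), "")
    nullRes <- motifEnrichment(seqs[1:100], seqs[101:200], pwms)
    expect_true(all(nullRes$pvalue >= 0.05))
    ## plant the first motif in 90% of foreground, 5% of background
    fg <- degronet:::plantMotif(seqs[1:100], pwms$ETS_like, 0.9)
    bg <- degronet:::plantMotif(seqs[101:200], pwms$ETS_like, 0.05)
    res <- motifEnrichment(fg, bg, pwms)
    expect_identical(res$motif[1], "ETS_like")
    expect_lt(res$padj[1], 1e-3)
    expect_gt(res$enrichment[1], 1.5)
  })
  ## hypergeometric tail equals exhaustive enumeration at universe <= 30
  enumTail <- function(k, K, N, n) {
    js <- max(0, k):min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
  }
  for (cs in list(c(3, 10, 25, 8), c(0, 5, 20, 10), c(6, 6, 12, 6))) {
    expect_equal(phyper(cs[1] - 1, cs[2], cs[3] - cs[2], cs[4],
                        lower.tail = FALSE),
                 enumTail(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-12)
  }
  ## degenerate PWMs are rejected
  zero <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0), 4,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(motifEnrichment("ACGT", "ACGT", list(bad = zero)),
               "pseudocount")
})

test_that("peak-to-gene links: inclusive 1 Mb boundary and all-pairs oracle agreement", {
  ## hand-built layout around the boundary
  el <- GRanges("chr1", IRanges(c(5e6, 5e6), width = 200))
  mcols(el) <- DataFrame(name = c("e1", "e2"), summit = c(5e6, 5e6),
                         atac_l2fc = c(1, 1), atac_p = c(1e-6, 1e-6),
                         chip_score = c(60, 60),
                         direction = c("up", "up"))
  net <- new("CisRENetwork", elements = el[1], links = data.frame(),
             proximalGenes = character(), consensusGenes = character())
  tss <- GRanges("chr1", IRanges(c(5e6, 6e6, 6e6 + 1, 4e6), width = 1))
  mcols(tss)$name <- c("g_at_summit", "g_at_1mb", "g_beyond", "g_left_in")
  got <- linkPeaksToGenes(net, tss, max_distance = 1e6)
  lk <- geneLinks(got)
  expect_setequal(lk$gene_id, c("g_at_summit", "g_at_1mb", "g_left_in"))
  expect_equal(lk$distance[lk$gene_id == "g_at_summit"], 0)
  expect_equal(lk$distance[lk$gene_id == "g_at_1mb"], 1e6)
  ## random layout vs brute force
  fx <- networkFixture()
  net2 <- linkPeaksToGenes(fx$network, fx$ann$genes, max_distance = 3e5)
  lk2 <- geneLinks(net2)
  el2 <- cisElements(fx$network)
  oracle <- do.call(rbind, lapply(seq_along(el2), function(i) {
    d <- abs(mcols(el2)$summit[i] - start(fx$ann$genes))
    same <- as.character(seqnames(fx$ann$genes)) ==
      as.character(seqnames(el2)[i])
    hit <- which(same & d <= 3e5)
    if (!length(hit)) return(NULL)
    data.frame(cisre_id = mcols(el2)$name[i],
               gene_id = mcols(fx$ann$genes)$name[hit], distance = d[hit])
  }))
  keyOf <- function(df) sort(paste(df$cisre_id, df$gene_id, df$distance))
  expect_identical(keyOf(lk2), keyOf(oracle))
  expect_setequal(proximalGenes(net2), unique(oracle$gene_id))
})

test_that("consensus rule: default set algebra, custom rules, unknown names", {
  fx <- networkFixture()
  net <- fx$network
  net@proximalGenes <- c("a", "b", "c")
  d1 <- list(rna_deg_6h = "b", proseq_deg_4h = c("c", "d"))
  got <- buildConsensus(net, d1)
  expect_setequal(consensusGenes(got), c("b", "c"))
  ## all DEG sets empty -> empty consensus under the default rule
  gotE <- buildConsensus(net, list(rna_deg_6h = character(),
                                   rna_deg_24h = character()))
  expect_length(consensusGenes(gotE), 0)
  ## custom rule and venn counts
  gotU <- buildConsensus(net, d1, rule = "rna_deg_6h | proseq_deg_4h")
  expect_setequal(consensusGenes(gotU), c("b", "c", "d"))
  expect_error(buildConsensus(net, d1, rule = "proximal & nonexistent"),
               "unknown set name")
  v <- attr(got, "venn")
  expect_equal(v$n_consensus, 2)
  expect_equal(v$n_proximal, 3)
  ## consensus under the default rule is contained in the proximal set
  expect_true(all(consensusGenes(got) %in% proximalGenes(net)))
})

test_that("signature trends: row scaling, degenerate bins, planted decrease", {
  fx <- networkFixture()
  ids <- mcols(cisElements(fx$network))$name
  ## single bin: everything scales to zero
  m1 <- matrix(5, length(ids), 1, dimnames = list(ids, "bin_1"))
  tr1 <- signatureTrend(fx$network, m1, m1[0, , drop = FALSE])
  expect_true(all(tr1$atac == 0))
  ## planted decreasing accessibility -> negative trend of the scaled mean
  withr::with_seed(71, {
    bins <- 50
    base <- outer(runif(length(ids), 1, 3), seq(2, 0.5, length.out = bins))
    noisy <- base * matrix(exp(rnorm(length(base), 0, 0.1)), nrow(base))
    rownames(noisy) <- ids; colnames(noisy) <- paste0("bin_", 1:bins)
    tr <- signatureTrend(fx$network, noisy, noisy[0, , drop = FALSE])
    rho <- cor(seq_len(bins), colMeans(tr$atac), method = "spearman")
    expect_lt(rho, -0.5)
    ## scaling is idempotent
    expect_equal(degronet:::rowScale(tr$atac), tr$atac, tolerance = 1e-12)
    ## rows have zero mean / unit variance
    expect_equal(unname(rowMeans(tr$atac)), rep(0, nrow(tr$atac)),
                 tolerance = 1e-12)
    expect_equal(unname(apply(tr$atac, 1, sd)), rep(1, nrow(tr$atac)),
                 tolerance = 1e-12)
  })
})
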