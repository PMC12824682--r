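# Shared fixtures: a desk-scale config and a cached annotation so the many
# tests that only need *an* annotation do not regenerate it.

smallConfig <- function(seed = 1, ...) {
  syntheticConfig(seed = seed, nGenes = 60, nPeaks = 300, nChipPeaks = 120,
                  nDirectCisres = 30, genomeLength = 2e6, nCells = 400,
                  lineageSetSize = 40, scDepth = 800, scRnaDepth = 800,
                  trackBackgroundRate = 0.002, trackReadsPerCisre = 120,
                  screenDepth = 2e5, nElementsScreen = 12, ...)
}

.fixtureCache <- new.env(parent = emptyenv())

cachedSmallAnn <- function() {
  if (is.null(.fixtureCache$ann))
    .fixtureCache$ann <- simulateAnnotation(smallConfig(1))
  .fixtureCache$ann
}

# random peak set on a small genome, for interval-arithmetic oracles
randomPeakSet <- function(n, seed, chroms = c("chrA", "chrB"), L = 1e5) {
  withr::with_seed(seed, {
    st <- sample(L - 1000, n, replace = TRUE)
    w <- sample(50:500, n, replace = TRUE)
    gr <- GenomicRanges::GRanges(
      sample(chroms, n, replace = TRUE),
      IRanges::IRanges(st, width = w),
      strand = sample(c("+", "-", "*"), n, replace = TRUE))
    S4Vectors::mcols(gr)$name <- sprintf("p%04d", seq_len(n))
    S4Vectors::mcols(gr)$score <- round(runif(n, 0, 100), 3)
    S4Vectors::mcols(gr)$signalValue <- round(runif(n), 4)
    S4Vectors::mcols(gr)$pValue <- round(runif(n, 0, 50), 4)
    S4Vectors::mcols(gr)$qValue <- round(runif(n, 0, 50), 4)
    S4Vectors::mcols(gr)$summit <- GenomicRanges::start(gr) +
      sample(0:49, n, replace = TRUE)
    names(gr) <- S4Vectors::mcols(gr)$name
    gr
  })
}

# quadratic all-pairs overlap oracle (half-open semantics, 0-based irrelevant:
# closed 1-based GRanges [s, e] equals half-open [s, e+1))
overlapOracle <- function(a, b) {
  ca <- as.character(GenomicRanges::seqnames(a))
  cb <- as.character(GenomicRanges::seqnames(b))
  sa <- GenomicRanges::start(a); ea <- GenomicRanges::end(a)
  sb <- GenomicRanges::start(b); eb <- GenomicRanges::end(b)
  out <- vector("list", length(a))
  for (i in seq_along(a)) {
    j <- which(cb == ca[i] & sa[i] <= eb & sb <= ea[i])
    if (length(j)) out[[i]] <- cbind(i, j)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}
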