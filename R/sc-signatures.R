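## Per-cell scoring of lineage differentiation and cisRE-network
## accessibility, resampled group comparisons, pseudotime minibulks.

getCounts <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else x
}

#' Per-cell lineage differentiation scores
#'
#' For each lineage `L` with peak set `S_L`, the score of a cell is its total
#' insertions in `S_L` divided by the mean of its totals in the other two
#' lineages' sets plus a pseudocount:
#' `score_L = c_L / (mean(c_L', c_L'') + pseudocount)`.
#'
#' @param cells peak x cell count matrix or `SingleCellExperiment`.
#' @param sets named list of exactly three disjoint, equal-sized peak-id
#'   vectors (rows of `cells`).
#' @param pseudocount denominator pseudocount (default 1).
#' @return cells x 3 matrix of scores, one column per lineage; cells with
#'   zero total insertions score 0 everywhere and are listed in the
#'   `zero_cells` attribute.
#' @export
lineageScores <- function(cells, sets, pseudocount = 1) {
  counts <- getCounts(cells)
  if (length(sets) != 3L) stop("exactly three lineage sets required")
  if (length(unique(lengths(sets))) != 1L) stop("lineage sets must be equal-sized")
  if (any(duplicated(unlist(sets)))) stop("lineage sets must be disjoint")
  missing <- setdiff(unlist(sets), rownames(counts))
  if (length(missing)) stop("set features absent from matrix: ",
                            paste(head(missing, 5), collapse = ", "))
  tot <- vapply(sets, function(s)
    Matrix::colSums(counts[s, , drop = FALSE]), numeric(ncol(counts)))
  sc <- vapply(seq_len(3), function(i) {
    others <- rowMeans(tot[, -i, drop = FALSE])
    tot[, i] / (others + pseudocount)
  }, numeric(nrow(tot)))
  colnames(sc) <- names(sets)
  zero <- Matrix::colSums(counts) == 0
  sc[zero, ] <- 0
  attr(sc, "zero_cells") <- which(zero)
  sc
}

#' Tn5 insertion-bias weights
#'
#' Per-feature weight computed as the inverse of the global mean insertion
#' density per bp at the feature across all cells, normalized to mean 1.
#' Features with zero counts everywhere receive the maximum finite weight
#' before normalization.
#'
#' @param cells peak x cell counts or `SingleCellExperiment`.
#' @param widths per-feature widths in bp (default 1, i.e. per-feature
#'   rather than per-bp rates).
#' @return named numeric vector of weights with mean 1.
#' @export
computeTn5Weights <- function(cells, widths = NULL) {
  counts <- getCounts(cells)
  if (is.null(widths)) widths <- rep(1, nrow(counts))
  rate <- Matrix::rowMeans(counts) / widths
  w <- ifelse(rate > 0, 1 / rate, NA)
  w[is.na(w)] <- max(w, na.rm = TRUE)
  w <- w / mean(w)
  setNames(w, rownames(counts))
}

#' Per-cell cisRE-network accessibility scores
#'
#' Raw score = (sum of Tn5-weighted insertions over the network elements) /
#' (insertions in TSS regions); final score = raw capped at its
#' `quantile_cap` quantile across cells and rescaled to `[0, 1]`
#' (`min(raw / q, 1)`), which damps outlier cells.
#'
#' @param cells peak x cell counts or `SingleCellExperiment` whose `colData`
#'   carries `tss_count` (else supply `tssCounts`).
#' @param network a [CisRENetwork-class] or character vector of element ids.
#' @param tn5Weights per-feature weights (default: all 1).
#' @param quantile_cap quantile used as the cap (default 0.99).
#' @param tssCounts per-cell TSS insertion counts (> 0 for scored cells).
#' @return numeric per-cell scores in `[0, 1]`; attribute `flag` notes a
#'   degenerate all-zero cap.
#' @export
cisreScores <- function(cells, network, tn5Weights = NULL,
                        quantile_cap = 0.99, tssCounts = NULL) {
  counts <- getCounts(cells)
  ids <- if (is(network, "CisRENetwork"))
    mcols(cisElements(network))$name else network
  ids <- intersect(ids, rownames(counts))
  if (!length(ids)) stop("no network element present in the matrix")
  if (is.null(tssCounts) && is(cells, "SummarizedExperiment"))
    tssCounts <- SummarizedExperiment::colData(cells)$tss_count
  if (is.null(tssCounts)) stop("tssCounts required")
  if (any(tssCounts <= 0)) stop("tss_count must be positive for scored cells")
  stopifnot(quantile_cap > 0, quantile_cap <= 1)
  w <- if (is.null(tn5Weights)) setNames(rep(1, length(ids)), ids)
  else tn5Weights[ids]
  raw <- as.numeric(w %*% counts[ids, , drop = FALSE]) / tssCounts
  q <- quantile(raw, quantile_cap, names = FALSE)
  if (q == 0) {
    out <- rep(0, length(raw))
    attr(out, "flag") <- "zero_cap"
    return(out)
  }
  out <- pmin(raw / q, 1)
  attr(out, "raw") <- raw
  out
}

#' Spearman correlation with t-approximation p-value
#'
#' Rank correlation on average-ranked data; the two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param a,b equal-length numeric vectors (n >= 3).
#' @return list with `rho`, `p`, `n`, `flag` (`"constant_input"` when either
#'   vector is constant, rho/p then `NA`).
#' @export
scoreCorrelation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  n <- length(a)
  if (sd(a) == 0 || sd(b) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, flag = "constant_input"))
  rho <- cor(rank(a), rank(b))
  p <- if (abs(rho) == 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, flag = "")
}

#' Per-cell RNA signature scores
#'
#' Mean log2(counts-per-10k + 1) over a gene set, per cell.
#'
#' @param cells gene x cell counts or `SingleCellExperiment`.
#' @param geneSet character vector of gene ids; an empty intersection with
#'   the matrix features is an error listing the missing genes.
#' @return numeric per-cell scores.
#' @export
signatureScoresRna <- function(cells, geneSet) {
  counts <- getCounts(cells)
  present <- intersect(geneSet, rownames(counts))
  if (!length(present))
    stop("no signature gene present in the matrix; missing: ",
         paste(head(geneSet, 10), collapse = ", "))
  logm <- logNormalizeCp10k(counts)
  as.numeric(Matrix::colMeans(logm[present, , drop = FALSE]))
}

#' Resampled two-group comparison of per-cell scores
#'
#' Per iteration, subsamples `n_cells` cells from each group and applies a
#' rank-based two-sided test; reports the mean group difference and the mean
#' p across iterations. When `scores` is a matrix (cells x signatures) each
#' signature is compared and the averaged p-values are BH-adjusted across
#' signatures.
#'
#' The default test is the rank-sum (Mann-Whitney) test: the groups are
#' unpaired cell populations. A signed-rank option pairs the equal-sized
#' subsamples in drawing order.
#'
#' @param scores numeric vector or cells x signatures matrix.
#' @param groups logical or two-level vector; `TRUE`/second level is the
#'   "positive" group.
#' @param n_iter iterations (default 10).
#' @param n_cells cells per group per iteration (default 1000); smaller
#'   groups are sampled with replacement and flagged.
#' @param test `"ranksum"` (default) or `"signedrank"`.
#' @param seed integer seed.
#' @return `data.frame` with one row per signature: `signature`,
#'   `mean_diff` (positive minus negative group means, averaged),
#'   `mean_p`, `padj` (BH across signatures),
#'   `resampled_with_replacement`.
#' @export
compareGroupsResampled <- function(scores, groups, n_iter = 10,
                                   n_cells = 1000,
                                   test = c("ranksum", "signedrank"),
                                   seed = 1) {
  test <- match.arg(test)
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1,
                                          dimnames = list(NULL, "score"))
  grp <- if (is.logical(groups)) groups else {
    f <- factor(groups)
    if (nlevels(f) != 2L) stop("groups must have exactly two levels")
    f == levels(f)[2]
  }
  idxPos <- which(grp); idxNeg <- which(!grp)
  if (!length(idxPos) || !length(idxNeg)) stop("both groups must be present")
  withRepl <- length(idxPos) < n_cells || length(idxNeg) < n_cells
  nSig <- ncol(scores)
  sumDiff <- numeric(nSig); sumP <- numeric(nSig)
  withSeed(seed, {
    for (it in seq_len(n_iter)) {
      sPos <- sample(idxPos, n_cells, replace = withRepl)
      sNeg <- sample(idxNeg, n_cells, replace = withRepl)
      for (j in seq_len(nSig)) {
        xa <- scores[sPos, j]; xb <- scores[sNeg, j]
        p <- if (test == "ranksum") {
          suppressWarnings(wilcox.test(xa, xb)$p.value)
        } else {
          suppressWarnings(wilcox.test(xa, xb, paired = TRUE)$p.value)
        }
        sumP[j] <- sumP[j] + min(max(p, .Machine$double.xmin), 1)
        sumDiff[j] <- sumDiff[j] + (mean(xa) - mean(xb))
      }
    }
  })
  meanP <- sumP / n_iter
  data.frame(signature = colnames(scores) %||% paste0("sig", seq_len(nSig)),
             mean_diff = sumDiff / n_iter, mean_p = meanP,
             padj = bhAdjust(meanP),
             resampled_with_replacement = withRepl,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate cells into pseudotime minibulks
#'
#' Rescales pseudotime to `[0, 1]` (min-max) and assigns cells to `n_bins`
#' equal-width bins (or equal-count quantile bins). Per-bin feature sums are
#' normalized per modality: `"rna"` to counts per 10k; `"atac"` by the bin's
#' summed TSS insertions with per-feature Tn5 weights. Empty bins are
#' emitted as all-`NA` (masked) columns.
#'
#' @param cells feature x cell counts or `SingleCellExperiment`.
#' @param pseudotime per-cell pseudotime (no `NA`).
#' @param n_bins number of bins (>= 2, default 100).
#' @param modality `"rna"` or `"atac"`.
#' @param tssCounts per-cell TSS insertions (required for atac; taken from
#'   `colData` if available).
#' @param tn5Weights per-feature weights for atac (default all 1).
#' @param binning `"width"` (default) or `"quantile"` (equal-count).
#' @return list with `matrix` (feature x bin, normalized) and `cellCounts`
#'   (per-bin cell numbers; sums to `ncol(cells)`).
#' @export
pseudotimeMinibulks <- function(cells, pseudotime, n_bins = 100,
                                modality = c("rna", "atac"),
                                tssCounts = NULL, tn5Weights = NULL,
                                binning = c("width", "quantile")) {
  modality <- match.arg(modality)
  binning <- match.arg(binning)
  counts <- getCounts(cells)
  if (n_bins < 2) stop("n_bins must be at least 2")
  if (anyNA(pseudotime) || length(pseudotime) != ncol(counts))
    stop("pseudotime must be present for all cells")
  rng <- range(pseudotime)
  pt <- if (rng[1] == rng[2]) rep(0, length(pseudotime))
  else (pseudotime - rng[1]) / (rng[2] - rng[1])
  bin <- if (binning == "width") pmin(floor(pt * n_bins) + 1L, n_bins)
  else {
    qs <- quantile(pt, probs = seq(0, 1, length.out = n_bins + 1))
    as.integer(cut(pt, breaks = unique(qs), include.lowest = TRUE))
  }
  if (modality == "atac") {
    if (is.null(tssCounts) && is(cells, "SummarizedExperiment"))
      tssCounts <- SummarizedExperiment::colData(cells)$tss_count
    if (is.null(tssCounts)) stop("tssCounts required for atac minibulks")
  }
  nF <- nrow(counts)
  out <- matrix(NA_real_, nF, n_bins,
                dimnames = list(rownames(counts), paste0("bin_", seq_len(n_bins))))
  cellCounts <- integer(n_bins)
  w <- if (is.null(tn5Weights)) rep(1, nF) else tn5Weights[rownames(counts)]
  for (b in seq_len(n_bins)) {
    ix <- which(bin == b)
    cellCounts[b] <- length(ix)
    if (!length(ix)) next
    s <- Matrix::rowSums(counts[, ix, drop = FALSE])
    out[, b] <- if (modality == "rna") {
      tot <- sum(s)
      if (tot == 0) s else s / tot * 1e4
    } else {
      s * w / sum(tssCounts[ix])
    }
  }
  list(matrix = out, cellCounts = cellCounts)
}
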