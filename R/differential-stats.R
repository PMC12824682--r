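## Count-based differential testing, threshold/classification logic, and the
## small estimators (BH, delta-delta-Ct, limiting-dilution frequency).

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median ratio of each sample's
#' counts to the geometric-mean pseudo-reference, restricted to features with
#' nonzero counts in every sample. When no such feature exists the function
#' falls back to total-count ratios with a warning.
#'
#' @param counts features x samples count matrix.
#' @return positive numeric vector, one factor per sample.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' countSizeFactors(m)  # ~ (1, 2) up to normalization
#' @export
countSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allPos)) {
    warning("no feature with nonzero counts in all samples; ",
            "falling back to total-count ratios")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  logGeo <- rowMeans(log(counts[allPos, , drop = FALSE]))
  apply(counts[allPos, , drop = FALSE], 2, function(cnt) {
    exp(median(log(cnt) - logGeo))
  })
}

#' Negative-binomial Wald test for two-group differential counts
#'
#' Tests each feature for a treated-vs-control difference in mean normalized
#' counts under an NB(mean, dispersion) model with variance
#' `mu + dispersion * mu^2`. The log2 fold change uses a pseudocount of 0.5;
#' the Wald statistic divides the l2fc by its delta-method standard error,
#' `SE^2 = (1/ln(2)^2) * sum_g (1/mu_g + alpha) / n_g`. With the default
#' globally moderated dispersion (or a fixed one) the reference is standard
#' normal; with a per-feature moment estimate it is t with `n - 2` degrees
#' of freedom, since the dispersion then comes from the same few samples.
#'
#' @param counts features x samples matrix of raw counts.
#' @param groups length-`ncol(counts)` factor or vector with exactly two
#'   levels; the first level is the control/reference.
#' @param dispersion `"global-moment"` (default: one dispersion per assay,
#'   the mean of the per-feature moment estimates over well-expressed
#'   features - stable at 3-vs-3 designs and matched to a
#'   constant-per-assay dispersion model), `"feature-moment"` (per-feature
#'   method of moments, floored at 1e-8, no pooling across features) or
#'   `"fixed"`.
#' @param dispFixed dispersion value when `dispersion = "fixed"`.
#' @param sizeFactors optional per-sample factors; computed by
#'   [countSizeFactors()] when missing.
#' @return `data.frame` with columns `feature_id`, `base_mean`, `l2fc`,
#'   `pvalue`, `padj` (BH), `flag` (`"all_zero"` for features with no counts,
#'   which get `l2fc = 0`, `p = 1`).
#' @export
nbTest <- function(counts, groups,
                   dispersion = c("global-moment", "feature-moment", "fixed"),
                   dispFixed = 0.05, sizeFactors = NULL) {
  dispersion <- match.arg(dispersion)
  counts <- as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group")
  if (is.null(sizeFactors)) sizeFactors <- countSizeFactors(counts)
  norm <- sweep(counts, 2, sizeFactors, "/")
  ctl <- norm[, groups == levels(groups)[1], drop = FALSE]
  trt <- norm[, groups == levels(groups)[2], drop = FALSE]
  n1 <- ncol(ctl); n2 <- ncol(trt)
  m1 <- rowMeans(ctl); m2 <- rowMeans(trt)
  pc <- 0.5
  l2fc <- log2((m2 + pc) / (m1 + pc))
  baseMean <- rowMeans(norm)
  if (dispersion != "fixed") {
    v1 <- apply(ctl, 1, var); v2 <- apply(trt, 1, var)
    pooledVar <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
    alphaFeat <- pmax((pooledVar - mu) / pmax(mu, 1e-8)^2, 1e-8)
    alpha <- if (dispersion == "feature-moment") alphaFeat else {
      expressed <- mu >= 5
      rep(if (any(expressed)) mean(alphaFeat[expressed])
          else mean(alphaFeat), nrow(counts))
    }
  } else alpha <- rep(dispFixed, nrow(counts))
  se2 <- ((1 / (m1 + pc) + alpha) / n1 + (1 / (m2 + pc) + alpha) / n2) /
    log(2)^2
  z <- l2fc / sqrt(se2)
  p <- if (dispersion == "feature-moment") {
    2 * pt(-abs(z), df = n1 + n2 - 2)
  } else 2 * pnorm(-abs(z))
  allZero <- rowSums(counts) == 0
  l2fc[allZero] <- 0
  p[allZero] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(feature_id = rownames(counts) %||%
               paste0("f", seq_len(nrow(counts))),
             base_mean = baseMean, l2fc = l2fc, pvalue = p,
             padj = bhAdjust(p),
             flag = ifelse(allZero, "all_zero", ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values, order-invariant, elementwise `>=` the input.
#' @export
bhAdjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Volcano classification at effect/significance thresholds
#'
#' A record is `up` iff `p < p_cut` and `l2fc > l2fc_cut`, `down` iff
#' `p < p_cut` and `l2fc < -l2fc_cut`, else `nonsig`. All inequalities are
#' strict, matching the printed thresholds (e.g. "L2FC > 0.5"); records
#' sitting exactly on a boundary are `nonsig`.
#'
#' @param records `data.frame` with `l2fc`, `pvalue` and (if
#'   `use_adjusted`) `padj` columns, as from [nbTest()].
#' @param p_cut significance level in `(0, 1)`.
#' @param l2fc_cut absolute effect cutoff `>= 0`.
#' @param use_adjusted compare `padj` instead of raw `pvalue` (default FALSE;
#'   the thresholds in this workflow are printed as raw p cutoffs).
#' @return `records` with an added `class` factor plus attributes
#'   `n_up`, `n_down`, `n_nonsig`.
#' @export
classifyVolcano <- function(records, p_cut = 0.01, l2fc_cut = 0.5,
                            use_adjusted = FALSE) {
  stopifnot(p_cut > 0, p_cut < 1, l2fc_cut >= 0)
  p <- if (use_adjusted) records$padj else records$pvalue
  cls <- rep("nonsig", nrow(records))
  cls[p < p_cut & records$l2fc > l2fc_cut] <- "up"
  cls[p < p_cut & records$l2fc < -l2fc_cut] <- "down"
  records$class <- factor(cls, levels = c("up", "down", "nonsig"))
  attr(records, "n_up") <- sum(cls == "up")
  attr(records, "n_down") <- sum(cls == "down")
  attr(records, "n_nonsig") <- sum(cls == "nonsig")
  records
}

#' Percentages of classified features, printed-style rounding
#'
#' Returns `100 * n / n_total` rounded to 1 decimal at or above 10% and to 2
#' decimals below 10% (the two styles in which such fractions are customarily
#' printed, e.g. 88.7% vs 4.48%).
#'
#' @param n count (vectorised) of features in a class.
#' @param n_total total features (> 0); `sum(n)` must not exceed it.
#' @return numeric percentage(s).
#' @examples
#' directionFractions(c(up = 3071, down = 155), 3462)
#' @export
directionFractions <- function(n, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (sum(n) > n_total) stop("class counts exceed total")
  pct <- 100 * n / n_total
  ifelse(pct >= 10, round(pct, 1), round(pct, 2))
}

#' Relative qPCR fold change from delta-delta-Ct
#'
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#'         (Ct_target,control - Ct_ref,control)`; fold change `= 2^(-ddCt)`.
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl cycle
#'   threshold values (finite, vectorised).
#' @return fold change(s).
#' @examples
#' ddctFoldChange(20, 15, 22, 16)  # ddCt = -1 -> fold change 2
#' @export
ddctFoldChange <- function(ctTargetTreated, ctRefTreated,
                           ctTargetControl, ctRefControl) {
  stopifnot(is.finite(ctTargetTreated), is.finite(ctRefTreated),
            is.finite(ctTargetControl), is.finite(ctRefControl))
  ddct <- (ctTargetTreated - ctRefTreated) - (ctTargetControl - ctRefControl)
  2^(-ddct)
}

## Binomial log-likelihood of the single-hit model at frequency f
licLogLik <- function(f, dose, nTested, nNegative) {
  pNeg <- exp(-f * dose)
  nPos <- nTested - nNegative
  ll <- nNegative * (-f * dose)
  pos <- nPos > 0
  ll[pos] <- ll[pos] + nPos[pos] * log1p(-pNeg[pos])
  sum(ll)
}

#' Limiting-dilution initiating-cell frequency
#'
#' Single-hit Poisson model: a graft fails iff zero initiating cells were
#' injected, so `P(negative | dose d) = exp(-f * d)`. The frequency `f` is the
#' binomial MLE over all dose rows; the 95% CI comes from the profile
#' likelihood (deviance drop of `qchisq(.95, 1)`). `assay` rows are
#' `(dose, n_tested, n_negative)`.
#'
#' At the boundaries: all mice negative gives `f = 0` with an upper bound
#' only; all mice engrafted at all doses gives an infinite MLE, reported as
#' the lower bound only, flagged.
#'
#' @param assay `data.frame` with columns `dose`, `n_tested`, `n_negative`.
#' @return list with `frequency` (the MLE of `f`, per cell), `ci` (95%
#'   profile-likelihood interval), `logLik`, `flag`.
#' @examples
#' licFrequency(data.frame(dose = 1000, n_tested = 10, n_negative = 5))
#' @export
licFrequency <- function(assay) {
  stopifnot(all(c("dose", "n_tested", "n_negative") %in% colnames(assay)),
            nrow(assay) >= 1, all(assay$dose > 0),
            all(assay$n_negative >= 0),
            all(assay$n_negative <= assay$n_tested))
  d <- assay$dose; nT <- assay$n_tested; nN <- assay$n_negative
  dbar <- mean(d)
  ## work in u = f * mean(dose) on mean-normalized doses: rescaling all doses
  ## by a constant leaves the objective bit-identical, so the fitted
  ## frequency is exactly scale-consistent
  dn <- d / dbar
  llU <- function(logu) licLogLik(exp(logu), dn, nT, nN)
  lo <- log(1e-12); hi <- log(1e7)
  crit <- qchisq(0.95, 1) / 2
  if (all(nN == nT)) {                       # nothing engrafted: MLE f = 0
    llMax <- licLogLik(0, d, nT, nN)
    up <- uniroot(function(x) llU(x) - (llMax - crit), c(lo, hi),
                  tol = 1e-12)$root
    return(list(frequency = 0, ci = c(0, exp(up) / dbar), logLik = llMax,
                flag = "all_negative"))
  }
  if (all(nN == 0)) {                        # everything engrafted: f -> Inf
    llMax <- 0
    lowr <- uniroot(function(x) llU(x) - (llMax - crit), c(lo, hi),
                    tol = 1e-12)$root
    return(list(frequency = Inf, ci = c(exp(lowr) / dbar, Inf),
                logLik = llMax, flag = "all_positive"))
  }
  opt <- optimize(llU, c(lo, hi), maximum = TRUE, tol = 1e-12)
  uHat <- opt$maximum; llMax <- opt$objective
  ciLo <- uniroot(function(x) llU(x) - (llMax - crit), c(lo, uHat),
                  tol = 1e-12)$root
  ciHi <- uniroot(function(x) llU(x) - (llMax - crit), c(uHat, hi),
                  tol = 1e-12)$root
  list(frequency = exp(uHat) / dbar,
       ci = exp(c(ciLo, ciHi)) / dbar,
       logLik = llMax, flag = "")
}

#' Likelihood-ratio comparison of two limiting-dilution assays
#'
#' Tests whether two dilution assays share one initiating-cell frequency
#' against separate frequencies (1 df likelihood-ratio test).
#'
#' @param assayA,assayB dilution tables as in [licFrequency()].
#' @return list with `pvalue`, `stat`, and the two separate fits.
#' @export
licCompare <- function(assayA, assayB) {
  fitA <- licFrequency(assayA)
  fitB <- licFrequency(assayB)
  pooled <- rbind(assayA[, c("dose", "n_tested", "n_negative")],
                  assayB[, c("dose", "n_tested", "n_negative")])
  fit0 <- licFrequency(pooled)
  stat <- 2 * (fitA$logLik + fitB$logLik - fit0$logLik)
  list(pvalue = pchisq(stat, df = 1, lower.tail = FALSE), stat = stat,
       fitA = fitA, fitB = fitB)
}

## log2 counts-per-10k with pseudocount 1 (dense or sparse input)
logNormalizeCp10k <- function(counts) {
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1
  cpk <- sweep_sparse(counts, libs / 1e4)
  if (is(cpk, "CsparseMatrix")) {       # log2(1 + 0) = 0 keeps sparsity
    cpk@x <- log2(1 + cpk@x)
    cpk
  } else log2(1 + cpk)
}

sweep_sparse <- function(m, divisor) {
  if (is(m, "sparseMatrix")) m %*% Matrix::Diagonal(x = 1 / divisor)
  else sweep(m, 2, divisor, "/")
}

## vectorised two-sided rank-sum (Mann-Whitney) p-values per row of a matrix,
## normal approximation with tie correction and continuity correction
rankSumRows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  m <- cbind(as.matrix(xa), as.matrix(xb))
  ps <- vapply(seq_len(nrow(m)), function(i) {
    r <- rank(m[i, ])
    W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    mu <- na * nb / 2
    tieTab <- table(r)
    tieAdj <- sum(tieTab^3 - tieTab)
    n <- na + nb
    sig2 <- na * nb / 12 * ((n + 1) - tieAdj / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    min(1, 2 * pnorm(-abs(z)))
  }, numeric(1))
  ps
}

#' Resampled single-cell differential expression
#'
#' Repeatedly subsamples an equal number of cells from each group, runs a
#' per-gene two-group test on each subsample, BH-adjusts within iteration,
#' and reports the elementwise mean of log fold changes and of adjusted
#' p-values across iterations. Subsampling avoids the uninformatively tiny
#' p-values produced by testing tens of thousands of cells at once.
#'
#' @param counts genes x cells count matrix (dense or `dgCMatrix`).
#' @param groupLabels length-`ncol(counts)` logical or two-level vector;
#'   `TRUE`/second level is the "positive" group whose excess expression
#'   yields positive logFC.
#' @param n_iter number of resampling iterations (default 10).
#' @param n_cells cells drawn per group per iteration (default 1000). Groups
#'   smaller than `n_cells` are sampled with replacement and flagged.
#' @param test per-gene test: function(matA, matB) returning a vector of
#'   p-values (rows = genes); default is a vectorised two-sided Wilcoxon
#'   rank-sum on log2 counts-per-10k.
#' @param seed integer seed; output is deterministic given the seed.
#' @return `data.frame` with `gene`, `mean_logfc` (log2, positive vs negative
#'   group, pseudocount 1 on mean CP10K), `mean_padj`, plus attribute
#'   `resampled_with_replacement`.
#' @export
resampledScDE <- function(counts, groupLabels, n_iter = 10, n_cells = 1000,
                          test = NULL, seed = 1) {
  grp <- if (is.logical(groupLabels)) groupLabels else {
    f <- factor(groupLabels)
    if (nlevels(f) != 2L) stop("groupLabels must have exactly two levels")
    f == levels(f)[2]
  }
  idxPos <- which(grp); idxNeg <- which(!grp)
  if (!length(idxPos) || !length(idxNeg)) stop("both groups must be present")
  withRepl <- length(idxPos) < n_cells || length(idxNeg) < n_cells
  if (is.null(test)) test <- function(a, b) rankSumRows(a, b)
  logm <- logNormalizeCp10k(counts)
  cp10kFromLog <- function(cols) {
    sub <- as.matrix(logm[, cols, drop = FALSE])
    rowMeans(2^sub - 1)
  }
  nGenes <- nrow(counts)
  sumLfc <- numeric(nGenes); sumPadj <- numeric(nGenes)
  withSeed(seed, {
    for (it in seq_len(n_iter)) {
      sPos <- sample(idxPos, n_cells, replace = withRepl)
      sNeg <- sample(idxNeg, n_cells, replace = withRepl)
      p <- test(as.matrix(logm[, sPos, drop = FALSE]),
                as.matrix(logm[, sNeg, drop = FALSE]))
      p <- pmin(pmax(p, .Machine$double.xmin), 1)
      lfc <- log2((cp10kFromLog(sPos) + 1) / (cp10kFromLog(sNeg) + 1))
      sumLfc <- sumLfc + lfc
      sumPadj <- sumPadj + bhAdjust(p)
    }
  })
  out <- data.frame(gene = rownames(counts) %||% paste0("g", seq_len(nGenes)),
                    mean_logfc = sumLfc / n_iter,
                    mean_padj = sumPadj / n_iter,
                    stringsAsFactors = FALSE)
  attr(out, "resampled_with_replacement") <- withRepl
  out
}
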