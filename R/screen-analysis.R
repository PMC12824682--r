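## Guide- and element-level statistics for the CRISPRi rescue and CRISPRa
## differentiation screens: normalization, guide log fold changes, and a
## permutation aggregation in place of heavier screen-analysis machinery.

#' Normalize a screen count table
#'
#' Median-of-ratios size factors (shared with the bulk differential module)
#' plus counts-per-million; downstream log fold changes use normalized
#' counts with a pseudocount of 1.
#'
#' @param table a [ScreenTable-class]; every sample must have nonzero total.
#' @return list with `norm` (size-factor-normalized counts), `cpm`,
#'   `sizeFactors`.
#' @export
normalizeScreen <- function(table) {
  counts <- screenCounts(table)
  if (any(colSums(counts) == 0)) stop("all-zero sample column")
  sf <- countSizeFactors(counts)
  list(norm = sweep(counts, 2, sf, "/"),
       cpm = sweep(counts, 2, colSums(counts), "/") * 1e6,
       sizeFactors = sf)
}

#' Per-guide log2 fold changes, sorted population vs plasmid library
#'
#' `log2((norm_sorted + 1) / (norm_library + 1))` per sorted replicate, plus
#' the replicate mean and sd. Guides absent from the library (zero count,
#' pseudocount only) are flagged.
#'
#' @param table a [ScreenTable-class].
#' @return `data.frame`: `guide_id`, `element_id`, `control_flag`, one
#'   `lfc_<rep>` column per sorted replicate, `mean_lfc`, `sd_lfc`, `flag`.
#' @export
guideLfc <- function(table) {
  nn <- normalizeScreen(table)
  lib <- nn$norm[, table@libraryCol]
  lfc <- vapply(table@sortedCols, function(sc)
    log2((nn$norm[, sc] + 1) / (lib + 1)),
    numeric(nrow(nn$norm)))
  colnames(lfc) <- paste0("lfc_", table@sortedCols)
  out <- cbind(guideData(table),
               as.data.frame(lfc),
               mean_lfc = rowMeans(lfc),
               sd_lfc = apply(lfc, 1, sd),
               flag = ifelse(screenCounts(table)[, table@libraryCol] == 0,
                             "absent_from_library", ""))
  rownames(out) <- NULL
  out
}

## null distribution of mean LFC for sets of size k drawn from pool values;
## exhaustive when the number of subsets is small enough, else sampled
nullScores <- function(poolLfc, k, n_perm) {
  nPool <- length(poolLfc)
  nComb <- choose(nPool, k)
  if (nComb <= n_perm) {
    combs <- utils::combn(nPool, k)
    list(scores = colMeans(matrix(poolLfc[combs], nrow = k)),
         exhaustive = TRUE)
  } else {
    list(scores = vapply(seq_len(n_perm), function(i)
      mean(poolLfc[sample.int(nPool, k)]), numeric(1)),
         exhaustive = FALSE)
  }
}

#' Element-level screen test by permutation aggregation
#'
#' Element score = mean of its guides' replicate-mean LFCs. The null is the
#' score of random same-size guide sets drawn from the pool of non-targeting
#' plus element guides (positive controls are excluded from the pool); p is
#' the two-sided tail around the pool mean, exhaustive over all subsets when
#' their number does not exceed `n_perm` (no smoothing needed - the observed
#' set is part of the enumeration) and sampled with +1 smoothing otherwise.
#' BH adjustment across the tested elements.
#'
#' @param lfcs guide-level table from [guideLfc()].
#' @param n_perm permutation budget per element-size (default 10000).
#' @param seed integer seed.
#' @param minGuides elements with fewer guides are still tested but flagged
#'   as singletons when they have one guide.
#' @return `data.frame`: `element_id`, `control_flag`, `score`, `n_guides`,
#'   `pvalue`, `padj`, `flag`; ordered by `pvalue`.
#' @export
elementTest <- function(lfcs, n_perm = 10000, seed = 1, minGuides = 2) {
  testable <- lfcs$control_flag %in% c("element", "positive_control")
  pool <- lfcs$mean_lfc[lfcs$control_flag %in% c("nontargeting", "element")]
  flagPool <- ""
  if (sum(lfcs$control_flag == "nontargeting") < 10) {
    pool <- lfcs$mean_lfc
    flagPool <- "all_guide_null"
  }
  center <- mean(pool)
  elems <- split(lfcs$mean_lfc[testable], lfcs$element_id[testable])
  flags <- vapply(split(as.character(lfcs$control_flag[testable]),
                        lfcs$element_id[testable]), `[`, "", 1)
  sizes <- sort(unique(lengths(elems)))
  withSeed(seed, {
    nulls <- lapply(sizes, function(k) nullScores(pool, k, n_perm))
  })
  names(nulls) <- as.character(sizes)
  rows <- lapply(names(elems), function(el) {
    g <- elems[[el]]
    k <- length(g)
    sc <- mean(g)
    nl <- nulls[[as.character(k)]]
    dev <- abs(sc - center)
    nGe <- sum(abs(nl$scores - center) >= dev - 1e-12)
    p <- if (nl$exhaustive) nGe / length(nl$scores)
    else (1 + nGe) / (length(nl$scores) + 1)
    flag <- paste0(flagPool, if (k < minGuides) "singleton" else "")
    data.frame(element_id = el, control_flag = flags[[el]], score = sc,
               n_guides = k, pvalue = max(p, .Machine$double.xmin),
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bhAdjust(out$pvalue)
  out <- out[order(out$pvalue, out$element_id),
             c("element_id", "control_flag", "score", "n_guides",
               "pvalue", "padj", "flag")]
  rownames(out) <- NULL
  out
}

#' Check degrader-resistance positive controls
#'
#' In rescue mode every designated positive-control element must have a
#' positive element score (cells carrying those guides resist the degrader
#' and are enriched in the sorted population); in differentiation mode the
#' controls carry no expectation and pass vacuously.
#'
#' @param results element-level table from [elementTest()].
#' @param controlIds character vector of control element ids (all must be
#'   present in `results`).
#' @param mode `"rescue"` or `"differentiation"`.
#' @return `data.frame`: `element_id`, `score`, `required`, `pass`.
#' @export
positiveControlCheck <- function(results, controlIds,
                                 mode = c("rescue", "differentiation")) {
  mode <- match.arg(mode)
  if (!length(controlIds))
    return(data.frame(element_id = character(), score = numeric(),
                      required = logical(), pass = logical()))
  missing <- setdiff(controlIds, results$element_id)
  if (length(missing))
    stop("missing control element(s): ", paste(missing, collapse = ", "))
  ix <- match(controlIds, results$element_id)
  required <- mode == "rescue"
  data.frame(element_id = controlIds, score = results$score[ix],
             required = required,
             pass = if (required) results$score[ix] > 0 else TRUE,
             stringsAsFactors = FALSE)
}
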