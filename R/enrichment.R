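## Pre-ranked set enrichment and simple overlap tests, used to check
## network conservation across models.

## running-sum enrichment score of `inSet` (logical, in ranked order) with
## hit increments proportional to |stat|^weight
runningES <- function(statSorted, inSet, weight) {
  nh <- sum(inSet)
  n <- length(statSorted)
  hitW <- abs(statSorted[inSet])^weight
  denom <- sum(hitW)
  if (denom == 0) hitW <- rep(1 / nh, nh) else hitW <- hitW / denom
  steps <- numeric(n)
  steps[inSet] <- hitW
  steps[!inSet] <- -1 / (n - nh)
  rs <- cumsum(steps)
  i <- which.max(abs(rs))
  rs[i]
}

#' Pre-ranked set enrichment (running-sum statistic with permutation null)
#'
#' Features are ordered by decreasing ranking statistic (ties broken by id).
#' Walking down the list, hits increment the running sum proportionally to
#' `|stat|^weight` (normalized over hits) and misses decrement it by
#' `1/(N - Nh)`; the enrichment score ES is the maximum deviation from zero.
#' The null is gene-label permutation: random same-size sets. NES divides ES
#' by the mean `|ES_perm|` of same-sign permutations; the p-value is the
#' same-sign permutation tail frequency with +1 smoothing.
#'
#' @param stats named numeric vector of ranking statistics (no duplicate
#'   ids), e.g. differential l2fc or signed -log10 p.
#' @param geneSet character vector; its intersection with `names(stats)`
#'   must have >= 2 members.
#' @param weight hit-weight exponent (default 1; 0 gives rank-only ES
#'   invariant to monotone transforms of the statistic).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return list with `es`, `nes`, `pvalue`, `n_hits`, `leadingEdge`
#'   (indices into the ranked order up to the ES extremum).
#' @export
gseaPreranked <- function(stats, geneSet, weight = 1, n_perm = 1000,
                          seed = 1) {
  if (anyDuplicated(names(stats))) stop("duplicate ids in ranked list")
  ord <- order(-stats, names(stats))
  statSorted <- stats[ord]
  ids <- names(statSorted)
  inSet <- ids %in% geneSet
  nh <- sum(inSet)
  if (nh < 2) stop("fewer than 2 set members present in the ranked list")
  es <- runningES(statSorted, inSet, weight)
  n <- length(ids)
  perm <- withSeed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pick <- logical(n)
      pick[sample.int(n, nh)] <- TRUE
      runningES(statSorted, pick, weight)
    }, numeric(1))
  })
  same <- perm[sign(perm) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  ## leading edge: hits at or before the ES extremum
  hitW <- abs(statSorted[inSet])^weight
  denom <- sum(hitW)
  steps <- numeric(n)
  steps[inSet] <- if (denom == 0) 1 / nh else hitW / denom
  steps[!inSet] <- -1 / (n - nh)
  rs <- cumsum(steps)
  iMax <- which.max(abs(rs))
  lead <- if (es >= 0) which(inSet[seq_len(iMax)])
  else which(inSet) [which(inSet) >= iMax]
  list(es = es, nes = nes, pvalue = p, n_hits = nh, leadingEdge = lead)
}

#' Hypergeometric overlap of two sets in a universe
#'
#' Upper-tail probability of observing at least the realised overlap, plus
#' fold enrichment (observed / expected overlap).
#'
#' @param set_a,set_b character vectors, both subsets of `universe`.
#' @param universe character vector (non-empty).
#' @return list with `overlap`, `expected`, `fold`, `pvalue`.
#' @export
setOverlapTest <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("universe must be non-empty")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop("both sets must be subsets of the universe")
  N <- length(universe)
  k <- length(intersect(set_a, set_b))
  expected <- length(set_a) * length(set_b) / N
  p <- phyper(k - 1, length(set_b), N - length(set_b), length(set_a),
              lower.tail = FALSE)
  list(overlap = k, expected = expected,
       fold = if (expected > 0) k / expected else NA_real_, pvalue = p)
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file (set name, description, then member ids, tab
#'   separated).
#' @return `readGmt`: named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  out
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @export
writeGmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}
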