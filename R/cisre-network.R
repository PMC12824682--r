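## Building the direct repressor cisRE network and the consensus gene network
## from differential accessibility, occupancy peaks, density tracks and the
## gene annotation.

#' Flag differential accessibility peaks that are occupancy-bound
#'
#' Joins a differential table onto its peak set, classifies peaks at the
#' volcano thresholds, and flags each differential peak as bound iff it
#' overlaps at least one ChIP peak (half-open semantics). A peak overlapped
#' by several ChIP peaks carries the maximum occupancy score ("strong
#' occupancy" semantics).
#'
#' @param atacDiff differential `data.frame` from [nbTest()]; `feature_id`
#'   must match `name`s in `peaks`.
#' @param peaks `GRanges` peak universe with `name` and `summit` columns.
#' @param chip `GRanges` occupancy peaks with a `score` column on the
#'   -log10(p)*10 scale.
#' @param p_cut,l2fc_cut,use_adjusted volcano thresholds
#'   (see [classifyVolcano()]); ATAC defaults follow the printed usage
#'   (p < 1e-4, |l2fc| > 0.5).
#' @return `GRanges` of the differential (up or down) peaks with metadata
#'   `atac_l2fc`, `atac_p`, `direction`, `bound`, `chip_score`; attributes
#'   `n_bound_up`, `n_bound_down`, `bound_fraction_up`,
#'   `bound_fraction_all` summarise the overlap enrichment.
#' @export
boundDifferentialPeaks <- function(atacDiff, peaks, chip, p_cut = 1e-4,
                                   l2fc_cut = 0.5, use_adjusted = FALSE) {
  if (length(chip) &&
      !any(unique(as.character(seqnames(chip))) %in%
           unique(as.character(seqnames(peaks)))))
    stop("chromosome mismatch between peak and ChIP sets")
  ix <- match(atacDiff$feature_id, mcols(peaks)$name)
  if (anyNA(ix)) stop("differential features missing from the peak set")
  cls <- classifyVolcano(atacDiff, p_cut = p_cut, l2fc_cut = l2fc_cut,
                         use_adjusted = use_adjusted)
  ## bound flag + max score over all peaks first (for the background rate)
  boundAll <- rep(FALSE, length(peaks))
  scoreAll <- rep(0, length(peaks))
  if (length(chip)) {
    ov <- overlapPairs(peaks, chip)
    if (nrow(ov)) {
      boundAll[unique(ov$a)] <- TRUE
      sc <- tapply(mcols(chip)$score[ov$b], ov$a, max)
      scoreAll[as.integer(names(sc))] <- sc
    }
  }
  keep <- cls$class != "nonsig"
  out <- peaks[ix[keep]]
  mcols(out)$atac_l2fc <- cls$l2fc[keep]
  mcols(out)$atac_p <- cls$pvalue[keep]
  mcols(out)$direction <- as.character(cls$class[keep])
  mcols(out)$bound <- boundAll[ix[keep]]
  mcols(out)$chip_score <- scoreAll[ix[keep]]
  up <- mcols(out)$direction == "up"
  attr(out, "n_bound_up") <- sum(mcols(out)$bound & up)
  attr(out, "n_bound_down") <- sum(mcols(out)$bound & !up)
  attr(out, "bound_fraction_up") <- if (any(up))
    mean(mcols(out)$bound[up]) else NA_real_
  attr(out, "bound_fraction_all") <- mean(boundAll)
  out
}

#' Select the direct cisRE network at the occupancy-score cutoff
#'
#' Retains bound differential peaks whose occupancy score strictly exceeds
#' `score_cut` (a score of exactly 50 is excluded), in stable
#' (chromosome, start) order.
#'
#' @param boundPeaks output of [boundDifferentialPeaks()].
#' @param score_cut occupancy cutoff on the -log10(p)*10 scale (default 50).
#' @return a [CisRENetwork-class] (links and consensus still empty).
#' @export
selectDirectNetwork <- function(boundPeaks, score_cut = 50) {
  keep <- mcols(boundPeaks)$bound & mcols(boundPeaks)$chip_score > score_cut
  el <- boundPeaks[keep]
  el <- el[order(as.character(seqnames(el)), start(el))]
  mc <- mcols(el)[, c("name", "summit", "atac_l2fc", "atac_p",
                      "chip_score", "direction")]
  mcols(el) <- mc
  new("CisRENetwork", elements = el, links = data.frame(),
      proximalGenes = character(), consensusGenes = character())
}

#' Compare enhancer-RNA density over the network between conditions
#'
#' Per-cisRE mean densities in summit-centered +/- `halfwidthMean` bp
#' windows for both conditions, the aggregate per-bp profile over
#' +/- `halfwidthProfile` bp, and a paired two-sided t test on the
#' per-cisRE (treated - control) differences.
#'
#' @param network a [CisRENetwork-class] (non-empty).
#' @param trackTreated,trackControl [DensityTrack-class] objects.
#' @param halfwidthMean,halfwidthProfile window half-widths in bp (defaults
#'   500 and 2000).
#' @return list with `perCisre` (data.frame: id, mean_treated, mean_control),
#'   `profileTreated`, `profileControl` (per-bp aggregate means), `t`, `p`,
#'   `flag`.
#' @export
ernaCompare <- function(network, trackTreated, trackControl,
                        halfwidthMean = 500, halfwidthProfile = 2000) {
  el <- cisElements(network)
  if (!length(el)) stop("network is empty")
  mT <- windowDensity(trackTreated, el, halfwidthMean, mode = "mean")
  mC <- windowDensity(trackControl, el, halfwidthMean, mode = "mean")
  pT <- windowDensity(trackTreated, el, halfwidthProfile, mode = "profile")
  pC <- windowDensity(trackControl, el, halfwidthProfile, mode = "profile")
  d <- mT - mC
  flag <- ""
  if (all(mT == 0) && all(mC == 0)) {
    tStat <- NA_real_; p <- NA_real_
    flag <- "all_zero_windows"
  } else if (sd(d) == 0) {
    tStat <- if (all(d == 0)) 0 else sign(mean(d)) * Inf
    p <- if (all(d == 0)) 1 else 0
  } else {
    tt <- stats::t.test(mT, mC, paired = TRUE)
    tStat <- unname(tt$statistic); p <- tt$p.value
  }
  list(perCisre = data.frame(id = mcols(el)$name, mean_treated = mT,
                             mean_control = mC, stringsAsFactors = FALSE),
       profileTreated = colMeans(pT, na.rm = TRUE),
       profileControl = colMeans(pC, na.rm = TRUE),
       t = tStat, p = p, flag = flag)
}

## max log-odds of a position weight matrix over all positions of a sequence
## (integer-encoded A=1,C=2,G=3,T=4), one strand
maxScoreOneStrand <- function(s, M) {
  w <- ncol(M); L <- length(s)
  if (L < w) return(-Inf)
  sc <- numeric(L - w + 1)
  for (i in seq_len(w)) sc <- sc + M[cbind(s[i:(L - w + i)], i)]
  max(sc)
}

encodeSeqs <- function(seqs) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    v <- match(ch, c("A", "C", "G", "T"))
    if (anyNA(v)) stop("sequences must contain only A/C/G/T")
    v
  })
}

#' Motif enrichment of network sequences against a background
#'
#' A sequence contains a motif iff the maximum log2-odds score of the motif's
#' position weight matrix over all positions and both strands reaches
#' `logoddsCut` (binary, ZOOPS-like containment). Enrichment is tested with a
#' hypergeometric tail of foreground containment against the pooled
#' foreground+background universe, BH-adjusted across motifs.
#'
#' @param fgSeqs,bgSeqs character vectors or
#'   [Biostrings::DNAStringSet] of A/C/G/T sequences.
#' @param pwms named list of position frequency matrices (4 x width, rows
#'   A,C,G,T, columns summing to 1, all entries > 0 - apply a pseudocount
#'   upstream; a zero column is an error).
#' @param logoddsCut containment threshold on the log2-odds scale (uniform
#'   0.25 background), default 7.
#' @return `data.frame` (one row per motif, ordered by p): `motif`,
#'   `n_fg`, `n_bg`, `enrichment` (foreground rate / universe rate), `pvalue`
#'   (hypergeometric upper tail), `padj`.
#' @export
motifEnrichment <- function(fgSeqs, bgSeqs, pwms, logoddsCut = 7) {
  fg <- encodeSeqs(fgSeqs); bg <- encodeSeqs(bgSeqs)
  nF <- length(fg); nB <- length(bg); N <- nF + nB
  res <- lapply(names(pwms), function(nm) {
    pfm <- pwms[[nm]]
    if (any(colSums(pfm) == 0) || any(pfm < 0))
      stop("PWM '", nm, "' has a zero column; apply a pseudocount upstream")
    if (any(pfm == 0))
      stop("PWM '", nm, "' contains zero entries; apply a pseudocount upstream")
    M <- log2(sweep(pfm, 2, colSums(pfm), "/") / 0.25)
    contains <- function(s) {
      if (maxScoreOneStrand(s, M) >= logoddsCut) return(TRUE)
      rc <- rev(5L - s)
      maxScoreOneStrand(rc, M) >= logoddsCut
    }
    kF <- sum(vapply(fg, contains, logical(1)))
    kB <- sum(vapply(bg, contains, logical(1)))
    K <- kF + kB
    p <- phyper(kF - 1, K, N - K, nF, lower.tail = FALSE)
    enr <- if (K > 0) (kF / nF) / (K / N) else NA_real_
    data.frame(motif = nm, n_fg = kF, n_bg = kB, enrichment = enr,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bhAdjust(out$pvalue)
  out[order(out$pvalue), , drop = FALSE]
}

#' Link network cisREs to genes by summit-to-TSS proximity
#'
#' Links element `c` to gene `g` iff they share a chromosome and the
#' unsigned distance from the element summit to the TSS is `<=`
#' `max_distance` (inclusive; 1,000,001 bp at the default 1 Mb is not
#' linked). All qualifying genes are linked, not only the nearest.
#'
#' @param network a [CisRENetwork-class].
#' @param tss width-1 `GRanges` TSS table with gene ids in `name`.
#' @param max_distance linking radius in bp (default 1 Mb).
#' @return the network with `links` and `proximalGenes` filled in.
#' @export
linkPeaksToGenes <- function(network, tss, max_distance = 1e6) {
  el <- cisElements(network)
  if (!length(el)) {
    network@links <- data.frame(cisre_id = character(),
                                gene_id = character(), distance = numeric())
    network@proximalGenes <- character()
    return(network)
  }
  summit <- mcols(el)$summit
  win <- GRanges(seqnames(el),
                 IRanges(pmax(1, summit - max_distance),
                         summit + max_distance))
  hits <- findOverlaps(win, tss, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  dist <- abs(summit[q] - start(tss)[s])
  keep <- dist <= max_distance
  links <- data.frame(cisre_id = mcols(el)$name[q][keep],
                      gene_id = mcols(tss)$name[s][keep],
                      distance = dist[keep], stringsAsFactors = FALSE)
  links <- links[order(links$cisre_id, links$distance, links$gene_id), ,
                 drop = FALSE]
  rownames(links) <- NULL
  network@links <- links
  network@proximalGenes <- sort(unique(links$gene_id))
  validObject(network)
  network
}

## evaluate a set-algebra expression over named character sets:
## `&` intersect, `|` union, `-` setdiff, parentheses allowed
evalSetRule <- function(expr, sets) {
  if (is.symbol(expr)) {
    nm <- as.character(expr)
    if (!nm %in% names(sets)) stop("unknown set name in rule: ", nm)
    return(sets[[nm]])
  }
  if (is.call(expr)) {
    op <- as.character(expr[[1]])
    if (op == "(") return(evalSetRule(expr[[2]], sets))
    a <- evalSetRule(expr[[2]], sets)
    b <- evalSetRule(expr[[3]], sets)
    return(switch(op,
                  "&" = intersect(a, b),
                  "|" = union(a, b),
                  "-" = setdiff(a, b),
                  stop("unsupported operator in rule: ", op)))
  }
  stop("malformed rule expression")
}

#' Build the consensus gene network
#'
#' Evaluates a set-algebra rule over the cisRE-proximal gene set and the
#' degradation-responsive gene sets. The default rule is
#' `proximal & (rna_deg_6h | rna_deg_24h | proseq_deg_4h)` (restricted to
#' set names present in `degSets`): genes both near a network element and
#' responsive in at least one expression readout.
#'
#' @param network a [CisRENetwork-class] with `proximalGenes` filled in.
#' @param degSets named list of character gene sets (e.g. `rna_deg_6h`).
#' @param rule optional character expression over `proximal` and the
#'   `degSets` names with `&` (intersect), `|` (union), `-` (setdiff).
#' @return the network with `consensusGenes` set; attribute `venn` holds the
#'   per-region counts (per-set sizes, the union of responsive sets, and the
#'   consensus size).
#' @export
buildConsensus <- function(network, degSets, rule = NULL) {
  sets <- c(list(proximal = proximalGenes(network)), degSets)
  if (is.null(rule))
    rule <- paste0("proximal & (",
                   paste(names(degSets), collapse = " | "), ")")
  cons <- sort(evalSetRule(parse(text = rule)[[1]], sets))
  network@consensusGenes <- cons
  degUnion <- Reduce(union, degSets, character())
  attr(network, "venn") <- c(
    setNames(lapply(sets, length), paste0("n_", names(sets))),
    list(n_deg_union = length(degUnion),
         n_proximal_and_deg = length(intersect(sets$proximal, degUnion)),
         n_consensus = length(cons)))
  network
}

#' Gene ids responsive at a raw-p cutoff
#'
#' Convenience extractor of a degradation-responsive gene set from a
#' differential table (default p < .05, the consensus-rule cutoff).
#'
#' @param records differential `data.frame` from [nbTest()].
#' @param p_cut raw p-value cutoff (default 0.05).
#' @return character vector of `feature_id`s.
#' @export
degSet <- function(records, p_cut = 0.05) {
  records$feature_id[records$pvalue < p_cut]
}

## scale rows to zero mean / unit variance across unmasked columns;
## constant rows become all zero
rowScale <- function(m) {
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    r <- m[i, ]
    ok <- is.finite(r)
    if (sum(ok) < 2 || sd(r[ok]) == 0) out[i, ok] <- 0
    else out[i, ok] <- (r[ok] - mean(r[ok])) / sd(r[ok])
  }
  out
}

#' Scaled signature matrices along pseudotime minibulks
#'
#' Subsets minibulk matrices to the network elements (accessibility) and the
#' consensus genes (expression) and scales each feature row to zero mean and
#' unit variance across pseudotime bins (masked/empty bins are ignored;
#' constant rows scale to zeros). Column order is the pseudotime bin order.
#'
#' @param network a [CisRENetwork-class].
#' @param minibulkAtac,minibulkRna feature x bin matrices from
#'   [pseudotimeMinibulks()].
#' @return list with scaled `atac` and `rna` matrices.
#' @export
signatureTrend <- function(network, minibulkAtac, minibulkRna) {
  elIds <- intersect(mcols(cisElements(network))$name, rownames(minibulkAtac))
  gIds <- intersect(consensusGenes(network), rownames(minibulkRna))
  list(atac = rowScale(minibulkAtac[elIds, , drop = FALSE]),
       rna = rowScale(minibulkRna[gIds, , drop = FALSE]))
}
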