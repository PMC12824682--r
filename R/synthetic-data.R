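## Synthetic-data generator. Plants a known repressor cisRE/gene network in a
## small 3-chromosome genome so that every downstream stage (differential
## calling, network building, single-cell scoring, screen statistics) has a
## recoverable ground truth. All stages draw their own sub-seed from
## config@seed via deriveSeed(), so partial reruns are reproducible.

#' Configuration for the synthetic multiomic generator
#'
#' Holds every tunable of the planted-network simulation. The defaults are
#' the study conditions the package is exercised under: a 3 x 10 Mb genome,
#' 200 genes, a 2000-peak accessibility universe, 800 occupancy (ChIP) peaks
#' of which 150 planted direct cisREs score above the occupancy cutoff, a
#' planted log2 effect of 2 with an 85% up-bias (degradation of a repressor
#' predominantly de-represses), NB dispersion 0.05, 5000 cells over three
#' lineages, and a screen of 40 elements with up to 5 guides each.
#'
#' @slot seed master integer seed.
#' @slot nGenes,nPeaks,nChipPeaks,nDirectCisres feature counts
#'   (`nDirectCisres <= nChipPeaks <= nPeaks`).
#' @slot genomeLength bp per synthetic chromosome.
#' @slot nChroms number of chromosomes.
#' @slot effectL2fcMean planted log2 effect size for de-repressed features.
#' @slot nbDispersion NB dispersion (variance `mu + disp * mu^2`).
#' @slot fracUpBias fraction of planted non-cisRE effects that are increases.
#' @slot nCells,nLineages single-cell scale; `nLineages` is fixed at 3.
#' @slot pseudotimeNoise sd of the noise on the pseudotime-linked
#'   accessibility trend.
#' @slot lineageSetSize lineage-specific accessible peaks per lineage.
#' @slot nElementsScreen,guidesPerElement screen scale (`guidesPerElement
#'   <= 5`).
#' @slot bulkBaseMean median base mean of bulk counts.
#' @slot trackBackgroundRate per-bp Poisson background of density tracks.
#' @slot trackReadsPerCisre expected nascent reads per cisRE (control).
#' @slot ernaL2fc planted log2 increase in cisRE nascent density (treated).
#' @slot scDepth,scRnaDepth mean per-cell insertions / RNA counts.
#' @slot screenDepth sequencing depth per screen sample.
#' @slot scEffect log2 repression of consensus genes in repressor-positive
#'   cells.
#' @export
setClass("SyntheticConfig", representation(
  seed = "integer", nGenes = "numeric", nPeaks = "numeric",
  nChipPeaks = "numeric", nDirectCisres = "numeric",
  genomeLength = "numeric", nChroms = "numeric",
  effectL2fcMean = "numeric", nbDispersion = "numeric",
  fracUpBias = "numeric", nCells = "numeric", nLineages = "numeric",
  pseudotimeNoise = "numeric", lineageSetSize = "numeric",
  nElementsScreen = "numeric", guidesPerElement = "numeric",
  bulkBaseMean = "numeric", trackBackgroundRate = "numeric",
  trackReadsPerCisre = "numeric", ernaL2fc = "numeric",
  scDepth = "numeric", scRnaDepth = "numeric", screenDepth = "numeric",
  scEffect = "numeric"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (!(object@nDirectCisres <= object@nChipPeaks &&
        object@nChipPeaks <= object@nPeaks))
    msg <- c(msg, "need nDirectCisres <= nChipPeaks <= nPeaks")
  if (object@fracUpBias < 0 || object@fracUpBias > 1)
    msg <- c(msg, "fracUpBias must lie in [0, 1]")
  if (object@guidesPerElement > 5)
    msg <- c(msg, "at most 5 guides per element")
  if (object@nLineages != 3)
    msg <- c(msg, "only the three-lineage design is supported")
  ## sizing: peaks need ~1 kb of room each
  if (object@nPeaks * 1000 > object@nChroms * object@genomeLength)
    msg <- c(msg, "genome too small to place requested features")
  if (object@bulkBaseMean <= 0 || object@scDepth <= 0 ||
      object@scRnaDepth <= 0 || object@screenDepth <= 0)
    msg <- c(msg, "depth parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticConfig-class
#' @param seed master seed.
#' @param ... any slot of `SyntheticConfig` to override.
#' @return a validated `SyntheticConfig`.
#' @examples
#' cfg <- syntheticConfig(seed = 1, nCells = 500)
#' @export
syntheticConfig <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed), nGenes = 200, nPeaks = 2000, nChipPeaks = 800,
    nDirectCisres = 150, genomeLength = 1e7, nChroms = 3,
    effectL2fcMean = 2, nbDispersion = 0.05, fracUpBias = 0.85,
    nCells = 5000, nLineages = 3, pseudotimeNoise = 0.1,
    lineageSetSize = 300, nElementsScreen = 40, guidesPerElement = 5,
    bulkBaseMean = 200, trackBackgroundRate = 0.005,
    trackReadsPerCisre = 200, ernaL2fc = 1.5,
    scDepth = 2000, scRnaDepth = 2000, screenDepth = 1e6, scEffect = 1)
  args <- list(...)
  bad <- setdiff(names(args), names(defaults))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  defaults[names(args)] <- args
  defaults$seed <- as.integer(defaults$seed)
  do.call(new, c(list(Class = "SyntheticConfig"), defaults))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig (seed", object@seed, "):",
      object@nChroms, "x", fmtNum(object@genomeLength), "bp genome,",
      object@nGenes, "genes,", object@nPeaks, "peaks,",
      object@nDirectCisres, "planted cisREs,",
      object@nCells, "cells\n")
})

chromNames <- function(config) paste0("chr", seq_len(config@nChroms))

chromLengthsOf <- function(config) {
  setNames(rep(config@genomeLength, config@nChroms), chromNames(config))
}

#' Simulate the genome annotation with a planted direct cisRE network
#'
#' Generates the gene TSS table, the accessibility peak universe and the
#' occupancy (ChIP) peak set, and plants the ground truth: a set of direct
#' cisREs that are both differentially accessible (all up, i.e. de-repressed)
#' and covered by a ChIP peak scoring above 50 on the -log10(p)*10 occupancy
#' scale; decoy ChIP peaks score at or below 50 (on differential peaks) or
#' above 50 on non-differential peaks, so the downstream score/differential
#' filters are both load-bearing. Every planted cisRE lies within 1 Mb of at
#' least one planted target gene TSS; the union of nearest target genes is
#' the planted consensus gene set, each member carrying a degradation
#' response in at least one bulk assay.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with elements `genes` (width-1 TSS `GRanges`, gene ids in
#'   `name`), `peaks` (`GRanges` with `name`, `summit`), `chip` (`GRanges`
#'   with `name`, `score`), `chromLengths`, and `truth` (list:
#'   `directCisreIds`, `consensusGeneIds`, `atacL2fc` named per-peak vector,
#'   `geneEffects` data.frame of per-assay true l2fc, `decoyLowIds`,
#'   `decoyHighIds`).
#' @export
simulateAnnotation <- function(config) {
  validObject(config)
  withSeed(deriveSeed(config@seed, "annotation"), {
    chroms <- chromNames(config)
    L <- config@genomeLength
    ## genes: spaced TSSs, random strand
    nPer <- diff(round(seq(0, config@nGenes, length.out = config@nChroms + 1)))
    genes <- do.call(c, lapply(seq_along(chroms), function(ci) {
      n <- nPer[ci]
      pos <- sort(sample(seq(5000, L - 5000, by = 2000), n))
      GRanges(factor(rep(chroms[ci], n), levels = chroms),
              IRanges(pos, width = 1),
              strand = sample(c("+", "-"), n, replace = TRUE))
    }))
    mcols(genes)$name <- sprintf("gene_%04d", seq_along(genes))
    mcols(genes)$score <- rep(0, length(genes))
    names(genes) <- mcols(genes)$name
    ## peaks: random intervals, jittered summits
    nPk <- diff(round(seq(0, config@nPeaks, length.out = config@nChroms + 1)))
    peaks <- do.call(c, lapply(seq_along(chroms), function(ci) {
      n <- nPk[ci]
      w <- round(runif(n, 300, 700))
      s <- sort(round(runif(n, 2500, L - 2500 - max(w))))
      GRanges(factor(rep(chroms[ci], n), levels = chroms),
              IRanges(s, width = w))
    }))
    mcols(peaks)$name <- sprintf("peak_%04d", seq_along(peaks))
    mcols(peaks)$score <- rep(0, length(peaks))
    mcols(peaks)$summit <- start(peaks) +
      round(width(peaks) * runif(length(peaks), 0.3, 0.7))
    names(peaks) <- mcols(peaks)$name
    ## planted direct cisREs: peaks with >= 1 gene TSS within 1 Mb
    d2g <- GenomicRanges::distanceToNearest(peaks, genes)
    eligible <- queryHits(d2g)[mcols(d2g)$distance <= 1e6 - 1]
    planted <- sort(sample(eligible, config@nDirectCisres))
    plantedIds <- mcols(peaks)$name[planted]
    ## other differential peaks (not bound at high score)
    nOther <- round(0.15 * config@nPeaks)
    others <- sort(sample(setdiff(seq_along(peaks), planted), nOther))
    atacL2fc <- setNames(numeric(length(peaks)), mcols(peaks)$name)
    atacL2fc[planted] <- config@effectL2fcMean +
      rnorm(length(planted), 0, 0.3)
    sgn <- ifelse(runif(nOther) < config@fracUpBias, 1, -1)
    atacL2fc[others] <- sgn * (config@effectL2fcMean + rnorm(nOther, 0, 0.3))
    ## ChIP peaks: planted (score > 50), low-score decoys on differential
    ## peaks, high-score decoys on non-differential peaks, background
    nDecoyLow <- min(length(others), round(0.2 * config@nDirectCisres))
    nDecoyHigh <- round(0.3 * config@nDirectCisres)
    quiet <- setdiff(seq_along(peaks), c(planted, others))
    decoyLow <- sample(others, nDecoyLow)
    decoyHigh <- sample(quiet, nDecoyHigh)
    nBg <- config@nChipPeaks - length(planted) - nDecoyLow - nDecoyHigh
    if (nBg < 0) stop("nChipPeaks too small for the planted design")
    onPeak <- function(idx, scores) {
      ctr <- mcols(peaks)$summit[idx]
      gr <- GRanges(seqnames(peaks)[idx], IRanges(pmax(1, ctr - 200),
                                                  ctr + 200))
      mcols(gr)$score <- scores
      gr
    }
    chip <- c(onPeak(planted, runif(length(planted), 60, 250)),
              onPeak(decoyLow, runif(nDecoyLow, 5, 50)),
              onPeak(decoyHigh, runif(nDecoyHigh, 60, 200)))
    bgPos <- round(runif(nBg, 2000, L - 2000))
    bgChrom <- sample(chroms, nBg, replace = TRUE)
    bg <- GRanges(factor(bgChrom, levels = chroms),
                  IRanges(bgPos, width = 400))
    mcols(bg)$score <- runif(nBg, 5, 150)
    chip <- c(chip, bg)
    chip <- chip[order(as.character(seqnames(chip)), start(chip))]
    mcols(chip)$name <- sprintf("chip_%04d", seq_along(chip))
    names(chip) <- mcols(chip)$name
    ## consensus target genes: nearest gene per planted cisRE (< 1 Mb)
    near <- GenomicRanges::distanceToNearest(peaks[planted], genes)
    targetGenes <- unique(mcols(genes)$name[subjectHits(near)])
    ## per-assay gene effects: each target responds in >= 1 assay
    assays <- c("rna_6h", "rna_24h", "proseq_4h")
    eff <- matrix(0, length(genes), 3,
                  dimnames = list(mcols(genes)$name, assays))
    for (g in targetGenes) {
      memb <- runif(3) < 0.6
      if (!any(memb)) memb[sample(3, 1)] <- TRUE
      s <- ifelse(runif(1) < config@fracUpBias, 1, -1)
      eff[g, memb] <- s * (config@effectL2fcMean + rnorm(sum(memb), 0, 0.3))
    }
    ## background responders far from the planted network
    nonTarget <- setdiff(mcols(genes)$name, targetGenes)
    bgDeg <- sample(nonTarget, round(0.15 * length(nonTarget)))
    for (g in bgDeg) {
      memb <- runif(3) < 0.4
      if (any(memb)) {
        s <- ifelse(runif(1) < config@fracUpBias, 1, -1)
        eff[g, memb] <- s * (config@effectL2fcMean + rnorm(sum(memb), 0, 0.3))
      }
    }
    list(genes = genes, peaks = peaks, chip = chip,
         chromLengths = chromLengthsOf(config),
         truth = list(directCisreIds = plantedIds,
                      consensusGeneIds = targetGenes,
                      atacL2fc = atacL2fc,
                      geneEffects = as.data.frame(eff),
                      decoyLowIds = mcols(peaks)$name[decoyLow],
                      decoyHighIds = mcols(peaks)$name[decoyHigh]))
  })
}

#' Simulate bulk counts (3 treated vs 3 control) for one assay/timepoint
#'
#' Negative-binomial counts with variance `mu + dispersion * mu^2`; treated
#' means are shifted by the planted true l2fc of each feature; per-sample
#' library sizes vary by +/- 30%.
#'
#' @param config a [SyntheticConfig-class].
#' @param annotation output of [simulateAnnotation()].
#' @param assay `"rna"`, `"proseq"` or `"atac"`.
#' @param timepoint label such as `"6h"`; for rna/proseq, the pair
#'   `<assay>_<timepoint>` selects the planted gene-effect column (zero
#'   effects if that column was not planted).
#' @return list with `counts` (features x 6 samples), `groups` (factor,
#'   levels control/treated) and `trueL2fc`.
#' @export
simulateBulkCounts <- function(config, annotation,
                               assay = c("rna", "proseq", "atac"),
                               timepoint = "6h") {
  assay <- match.arg(assay)
  if (assay == "atac") {
    ids <- mcols(annotation$peaks)$name
    l2fc <- annotation$truth$atacL2fc[ids]
  } else {
    ids <- mcols(annotation$genes)$name
    key <- paste(assay, timepoint, sep = "_")
    ge <- annotation$truth$geneEffects
    l2fc <- if (key %in% colnames(ge)) setNames(ge[[key]], rownames(ge))[ids]
    else setNames(numeric(length(ids)), ids)
  }
  withSeed(deriveSeed(config@seed, paste("bulk", assay, timepoint)), {
    n <- length(ids)
    baseMean <- exp(rnorm(n, log(config@bulkBaseMean), 0.7))
    lib <- runif(6, 0.7, 1.3)
    treated <- c(rep(0, 3), rep(1, 3))
    mu <- outer(baseMean, lib) * 2^(outer(l2fc, treated))
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config@nbDispersion),
                     nrow = n,
                     dimnames = list(ids, paste0(assay, "_", timepoint, "_",
                                                 rep(c("ctl", "trt"), each = 3),
                                                 "_", rep(1:3, 2))))
    list(counts = counts,
         groups = factor(rep(c("control", "treated"), each = 3),
                         levels = c("control", "treated")),
         trueL2fc = l2fc)
  })
}

#' Simulate a strand-resolved nascent-transcription density track
#'
#' Poisson background at `trackBackgroundRate` per bp plus Gaussian-shaped
#' read pileups (sd 150 bp) centered on planted cisRE summits. In the treated
#' condition the planted cisREs carry `2^ernaL2fc`-fold more signal,
#' emulating enhancer-RNA induction upon repressor degradation.
#'
#' @param config a [SyntheticConfig-class].
#' @param annotation output of [simulateAnnotation()].
#' @param condition `"control"` or `"treated"`.
#' @return a [DensityTrack-class].
#' @export
simulateTracks <- function(config, annotation,
                           condition = c("control", "treated")) {
  condition <- match.arg(condition)
  withSeed(deriveSeed(config@seed, paste("track", condition)), {
    chroms <- chromNames(config)
    L <- config@genomeLength
    planted <- annotation$peaks[annotation$truth$directCisreIds]
    mult <- if (condition == "treated") 2^config@ernaL2fc else 1
    posList <- list(`+` = vector("list", length(chroms)),
                    `-` = vector("list", length(chroms)))
    for (ci in seq_along(chroms)) {
      for (s in c("+", "-")) {
        nBg <- rpois(1, config@trackBackgroundRate * L)
        posList[[s]][[ci]] <- round(runif(nBg, 1, L))
      }
    }
    ## signal reads at planted cisREs (both strands, random split)
    for (i in seq_along(planted)) {
      ci <- match(as.character(seqnames(planted)[i]), chroms)
      nr <- rpois(1, config@trackReadsPerCisre * mult)
      if (nr == 0) next
      pos <- pmin(pmax(round(mcols(planted)$summit[i] +
                               rnorm(nr, 0, 150)), 1), L)
      onPlus <- runif(nr) < 0.5
      posList[["+"]][[ci]] <- c(posList[["+"]][[ci]], pos[onPlus])
      posList[["-"]][[ci]] <- c(posList[["-"]][[ci]], pos[!onPlus])
    }
    toRleList <- function(pl) {
      out <- lapply(seq_along(chroms), function(ci) {
        p <- pl[[ci]]
        if (!length(p)) return(Rle(0, L))
        cv <- coverage(IRanges(p, width = 1), width = L)
        as(cv, "Rle")
      })
      names(out) <- chroms
      as(out, "SimpleRleList")
    }
    DensityTrack(plus = toRleList(posList[["+"]]),
                 minus = toRleList(posList[["-"]]))
  })
}

#' Simulate three-lineage single-cell ATAC and RNA matrices
#'
#' Cells belong to myeloid/erythroid/lymphoid analogs (50/25/25%). Each
#' lineage has a dedicated accessible peak set; planted cisRE accessibility
#' rises linearly (in expectation) along the myeloid pseudotime, with
#' `pseudotimeNoise` jitter. Repressor-positive cells express the planted
#' consensus genes `2^-scEffect`-fold lower than repressor-negative cells.
#'
#' @param config a [SyntheticConfig-class] (`nCells >= 100`).
#' @param annotation output of [simulateAnnotation()].
#' @return list with `atac` (peak x cell [SingleCellExperiment]), `rna`
#'   (gene x cell `SingleCellExperiment`) - both carrying `colData` columns
#'   `lineage`, `pseudotime`, `repressor_pos`, `tss_count` - and
#'   `lineageSets` (named list of peak-id vectors, equal sized, disjoint).
#' @export
simulateSingleCells <- function(config, annotation) {
  if (config@nCells < 100) stop("need at least 100 cells")
  if (config@nLineages != 3) stop("only the three-lineage design is supported")
  withSeed(deriveSeed(config@seed, "single_cells"), {
    nC <- config@nCells
    peaks <- annotation$peaks
    nP <- length(peaks)
    pids <- mcols(peaks)$name
    planted <- match(annotation$truth$directCisreIds, pids)
    lineages <- c("myeloid", "erythroid", "lymphoid")
    lin <- sample(lineages, nC, replace = TRUE, prob = c(0.5, 0.25, 0.25))
    pt <- runif(nC)
    ptEff <- pmin(pmax(pt + rnorm(nC, 0, config@pseudotimeNoise), 0), 1)
    repressor <- runif(nC) < 0.5
    ## disjoint lineage-specific peak sets among non-planted peaks
    pool <- setdiff(seq_len(nP), planted)
    sets <- split(sample(pool, 3 * config@lineageSetSize),
                  rep(1:3, each = config@lineageSetSize))
    names(sets) <- lineages
    ## per-peak base weights
    w0 <- exp(rnorm(nP, 0, 0.5))
    W <- matrix(w0, nP, nC)
    for (l in lineages) W[sets[[l]], lin == l] <-
      W[sets[[l]], lin == l] * 4
    ## planted cisREs: myeloid cells gain accessibility along pseudotime
    cisBase <- 0.05 + 1.5 * ptEff
    cisBase[lin != "myeloid"] <- 0.05
    W[planted, ] <- outer(w0[planted], cisBase)
    P <- sweep(W, 2, colSums(W), "/")
    depth <- exp(rnorm(nC, log(config@scDepth), 0.3))
    lambda <- sweep(P, 2, depth, "*")
    atacCounts <- matrix(rpois(length(lambda), lambda), nP, nC)
    tssCount <- rpois(nC, 0.3 * depth) + 1L
    ## RNA: consensus genes repressed in repressor-positive cells
    genes <- annotation$genes
    nG <- length(genes)
    gw <- exp(rnorm(nG, 0, 0.5))
    GW <- matrix(gw, nG, nC)
    consensusIdx <- match(annotation$truth$consensusGeneIds,
                          mcols(genes)$name)
    GW[consensusIdx, repressor] <- GW[consensusIdx, repressor] *
      2^(-config@scEffect)
    GP <- sweep(GW, 2, colSums(GW), "/")
    rdepth <- exp(rnorm(nC, log(config@scRnaDepth), 0.3))
    rnaCounts <- matrix(rpois(length(GP), sweep(GP, 2, rdepth, "*")), nG, nC)
    cd <- DataFrame(lineage = lin, pseudotime = pt,
                    repressor_pos = repressor, tss_count = tssCount,
                    row.names = sprintf("cell_%05d", seq_len(nC)))
    atacSE <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = as(atacCounts, "CsparseMatrix")), colData = cd)
    rownames(atacSE) <- pids
    colnames(atacSE) <- rownames(cd)
    rnaSE <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = as(rnaCounts, "CsparseMatrix")), colData = cd)
    rownames(rnaSE) <- mcols(genes)$name
    colnames(rnaSE) <- rownames(cd)
    list(atac = atacSE, rna = rnaSE,
         lineageSets = lapply(sets, function(ix) pids[ix]))
  })
}

#' Simulate a CRISPR cisRE screen count table
#'
#' Builds a guide library over `nElementsScreen` cisRE elements (3-5 guides
#' each), three degrader-resistance positive-control elements, and 50
#' non-targeting guides, then draws a plasmid-library column and three
#' sorted-population replicates multinomially at `screenDepth`. Three planted
#' hit elements are 8-fold enriched in the sorted population; in rescue mode
#' the positive controls are likewise always enriched, in differentiation
#' mode they behave as null.
#'
#' @param config a [SyntheticConfig-class].
#' @param truth the `truth` element of [simulateAnnotation()] output (hit
#'   elements are drawn from its planted cisRE ids).
#' @param mode `"rescue"` or `"differentiation"`.
#' @param foldEnrichment enrichment of planted hits in the sorted population.
#' @return list with `table` (a [ScreenTable-class]), `hitElements`,
#'   `positiveControls`, `mode`.
#' @export
simulateScreen <- function(config, truth,
                           mode = c("rescue", "differentiation"),
                           foldEnrichment = 8) {
  mode <- match.arg(mode)
  withSeed(deriveSeed(config@seed, paste("screen", mode)), {
    elems <- truth$directCisreIds[seq_len(min(config@nElementsScreen,
                                              length(truth$directCisreIds)))]
    posCtl <- c("posctrl_1", "posctrl_2", "posctrl_3")
    hit <- sample(elems, 3)
    mkGuides <- function(el, flag) {
      ng <- sample(3:config@guidesPerElement, length(el), replace = TRUE)
      data.frame(guide_id = unlist(lapply(seq_along(el), function(i)
        paste0(el[i], "_g", seq_len(ng[i])))),
        element_id = rep(el, ng),
        control_flag = flag, stringsAsFactors = FALSE)
    }
    gd <- rbind(mkGuides(elems, "element"),
                mkGuides(posCtl, "positive_control"),
                data.frame(guide_id = sprintf("nt_%02d", 1:50),
                           element_id = "NT",
                           control_flag = "nontargeting",
                           stringsAsFactors = FALSE))
    nGuides <- nrow(gd)
    w <- exp(rnorm(nGuides, 0, 0.3))
    libProps <- w / sum(w)
    depth <- config@screenDepth
    lib <- as.integer(rmultinom(1, depth, libProps))
    enrich <- rep(1, nGuides)
    enrich[gd$element_id %in% hit] <- foldEnrichment
    if (mode == "rescue")
      enrich[gd$control_flag == "positive_control"] <- foldEnrichment
    sortedProps <- libProps * enrich
    sortedProps <- sortedProps / sum(sortedProps)
    sorted <- vapply(1:3, function(r)
      as.integer(rmultinom(1, depth, sortedProps)), integer(nGuides))
    counts <- cbind(library = lib, sorted)
    colnames(counts) <- c("library", paste0("sorted_", 1:3))
    rownames(counts) <- gd$guide_id
    list(table = ScreenTable(counts, gd, libraryCol = "library",
                             sortedCols = paste0("sorted_", 1:3)),
         hitElements = hit, positiveControls = posCtl, mode = mode)
  })
}

#' @importFrom stats rmultinom rlnorm
NULL
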