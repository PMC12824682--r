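## End-to-end workflows over the synthetic generator: degron multiomics ->
## network; single-cell scoring; screen analysis. Every stage draws its seed
## from the config, outputs are written as plain text, and the summary JSON
## records parameters, md5 hashes and recovery metrics so a rerun under the
## same config is byte-identical.

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

hashFiles <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.character(h), basename(names(h)))
}

#' Read a simple position-frequency-matrix text file
#'
#' One record per motif: a `>name` header line followed by four lines
#' `A|C|G|T v1 v2 ...` of per-position frequencies.
#'
#' @param path file path.
#' @return named list of 4 x width matrices (rows A,C,G,T), columns
#'   normalized to sum to 1.
#' @export
readPfm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  starts <- grep("^>", lines)
  out <- lapply(starts, function(s) {
    rows <- lines[(s + 1):(s + 4)]
    m <- t(vapply(rows, function(r) {
      f <- strsplit(r, "[ \t]+")[[1]]
      as.numeric(f[-1])
    }, numeric(length(strsplit(rows[1], "[ \t]+")[[1]]) - 1)))
    rownames(m) <- vapply(strsplit(rows, "[ \t]+"), `[`, "", 1)
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    sweep(m, 2, colSums(m), "/")
  })
  names(out) <- sub("^>", "", lines[starts])
  out
}

randomSeqs <- function(n, width) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), "")
}

plantMotif <- function(seqs, pfm, frac) {
  w <- ncol(pfm)
  plant <- runif(length(seqs)) < frac
  for (i in which(plant)) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sample(length(s) - w + 1, 1)
    ins <- vapply(seq_len(w), function(j)
      sample(c("A", "C", "G", "T"), 1, prob = pfm[, j]), "")
    s[pos:(pos + w - 1)] <- ins
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

## shared first half of the degron and single-cell workflows: differential
## accessibility -> bound peaks -> network -> links -> consensus
deriveNetwork <- function(config, ann,
                          atac_p_cut = 1e-4, atac_l2fc_cut = 0.5,
                          score_cut = 50, deg_p_cut = 0.05,
                          max_distance = 1e6) {
  atac <- simulateBulkCounts(config, ann, "atac", "6h")
  rna6 <- simulateBulkCounts(config, ann, "rna", "6h")
  rna24 <- simulateBulkCounts(config, ann, "rna", "24h")
  pro4 <- simulateBulkCounts(config, ann, "proseq", "4h")
  atacDiff <- nbTest(atac$counts, atac$groups)
  rna6Diff <- nbTest(rna6$counts, rna6$groups)
  rna24Diff <- nbTest(rna24$counts, rna24$groups)
  pro4Diff <- nbTest(pro4$counts, pro4$groups)
  bound <- boundDifferentialPeaks(atacDiff, ann$peaks, ann$chip,
                                  p_cut = atac_p_cut,
                                  l2fc_cut = atac_l2fc_cut)
  network <- selectDirectNetwork(bound, score_cut = score_cut)
  network <- linkPeaksToGenes(network, ann$genes,
                              max_distance = max_distance)
  degSets <- list(rna_deg_6h = degSet(rna6Diff, deg_p_cut),
                  rna_deg_24h = degSet(rna24Diff, deg_p_cut),
                  proseq_deg_4h = degSet(pro4Diff, deg_p_cut))
  network <- buildConsensus(network, degSets)
  list(network = network, bound = bound, atacDiff = atacDiff,
       rnaDiff = list(rna_6h = rna6Diff, rna_24h = rna24Diff,
                      proseq_4h = pro4Diff),
       degSets = degSets)
}

recallPrecision <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  list(recall = if (length(truth)) tp / length(truth) else NA_real_,
       precision = if (length(predicted)) tp / length(predicted) else NA_real_)
}

#' Run the degron multiomics workflow end to end
#'
#' Simulates annotation, bulk counts and density tracks under `config`,
#' derives the direct cisRE network and the consensus gene network, compares
#' enhancer-RNA density between conditions, runs motif enrichment on
#' network vs background sequences (an ETS-like motif is planted in network
#' elements), checks network conservation with a pre-ranked enrichment of the
#' consensus genes on the 24h expression ranking, and writes all inputs,
#' outputs and a summary JSON (with md5 hashes of every output) to `outdir`.
#'
#' @param config a [SyntheticConfig-class].
#' @param outdir output directory (created if needed).
#' @return the summary list, invisibly; `summary.json` in `outdir` holds the
#'   same content.
#' @export
runDegronMultiomics <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  ann <- simulateAnnotation(config)
  writeNarrowPeak(ann$peaks, out("peaks.narrowPeak"))
  writeNarrowPeak(ann$chip, out("chip_peaks.bed"))
  writeTssBed(ann$genes, out("tss.bed"))
  der <- deriveNetwork(config, ann)
  network <- der$network
  ## volcano tables
  for (nm in names(der$rnaDiff))
    writeCountTable(as.matrix(der$rnaDiff[[nm]][, c("base_mean", "l2fc",
                                                    "pvalue", "padj")]) |>
                      `rownames<-`(der$rnaDiff[[nm]]$feature_id),
                    out(paste0("differential_", nm, ".tsv")))
  atacTab <- as.matrix(der$atacDiff[, c("base_mean", "l2fc", "pvalue", "padj")])
  rownames(atacTab) <- der$atacDiff$feature_id
  writeCountTable(atacTab, out("differential_atac_6h.tsv"))
  ## eRNA
  trackT <- simulateTracks(config, ann, "treated")
  trackC <- simulateTracks(config, ann, "control")
  writeDensityTrack(trackT, out("proseq_treated"))
  writeDensityTrack(trackC, out("proseq_control"))
  erna <- ernaCompare(network, trackT, trackC)
  write.table(erna$perCisre, out("erna_per_cisre.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ## motifs: sequences for network elements vs random background peaks
  pwms <- readPfm(system.file("extdata", "motifs.pfm", package = "degronet"))
  motifTab <- withSeed(deriveSeed(config@seed, "motif_seqs"), {
    fg <- plantMotif(randomSeqs(length(cisElements(network)), 300),
                     pwms[[1]], 0.6)
    bg <- plantMotif(randomSeqs(300, 300), pwms[[1]], 0.05)
    motifEnrichment(fg, bg, pwms)
  })
  write.table(motifTab, out("motif_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ## network BED (score column = occupancy score) + links + consensus
  el <- cisElements(network)
  bedEl <- el
  mcols(bedEl) <- DataFrame(name = mcols(el)$name,
                            score = mcols(el)$chip_score,
                            summit = mcols(el)$summit)
  writeNarrowPeak(bedEl, out("network.narrowPeak"))
  write.table(geneLinks(network), out("gene_links.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(consensusGenes(network), out("consensus_genes.txt"))
  writeJson(attr(network, "venn"), out("venn_counts.json"))
  ## conservation: consensus genes on the 24h expression ranking
  r24 <- der$rnaDiff$rna_24h
  ranked <- setNames(r24$l2fc, r24$feature_id)
  gsea <- gseaPreranked(ranked, consensusGenes(network),
                        n_perm = 500, seed = deriveSeed(config@seed, "gsea"))
  ## classification summary on the printed-style fractions
  atacCls <- classifyVolcano(der$atacDiff, p_cut = 1e-4, l2fc_cut = 0.5)
  nUp <- attr(atacCls, "n_up"); nDown <- attr(atacCls, "n_down")
  nDiff <- nUp + nDown
  rp <- recallPrecision(mcols(el)$name, ann$truth$directCisreIds)
  consRec <- recallPrecision(consensusGenes(network),
                             ann$truth$consensusGeneIds)
  summary <- list(
    workflow = "degron_multiomics", seed = config@seed,
    n_peaks = length(ann$peaks), n_genes = length(ann$genes),
    atac = list(n_up = nUp, n_down = nDown,
                pct_up = directionFractions(nUp, nDiff),
                pct_down = directionFractions(nDown, nDiff),
                bound_fraction_up = attr(der$bound, "bound_fraction_up"),
                bound_fraction_all = attr(der$bound, "bound_fraction_all")),
    network_size = length(el),
    consensus_size = length(consensusGenes(network)),
    network_recall = rp$recall, network_precision = rp$precision,
    consensus_recall = consRec$recall,
    erna = list(t = erna$t, p = erna$p),
    top_motif = motifTab$motif[1],
    gsea = list(es = gsea$es, nes = gsea$nes, p = gsea$pvalue))
  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "summary.json"]
  summary$file_hashes <- as.list(hashFiles(files))
  writeJson(summary, out("summary.json"))
  invisible(summary)
}

#' Run the single-cell scoring workflow end to end
#'
#' Simulates the three-lineage cell population, derives the cisRE network
#' from the bulk arm, computes per-cell lineage scores, Tn5-corrected
#' TSS-normalized cisRE scores and consensus-gene signature scores,
#' correlates cisRE and lineage scores (rank correlation), compares
#' signatures between repressor-positive and -negative cells with the
#' resampled rank test, runs resampled single-cell differential expression,
#' builds pseudotime minibulks on the myeloid trajectory and the scaled
#' signature-trend matrices, and writes outputs plus a hashed summary JSON.
#'
#' @inheritParams runDegronMultiomics
#' @param n_bins pseudotime bins for the minibulks (default 100).
#' @return the summary list, invisibly.
#' @export
runSingleCellScoring <- function(config, outdir, n_bins = 100) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  ann <- simulateAnnotation(config)
  der <- deriveNetwork(config, ann)
  network <- der$network
  sc <- simulateSingleCells(config, ann)
  cd <- SummarizedExperiment::colData(sc$atac)
  Matrix::writeMM(SummarizedExperiment::assay(sc$atac), out("atac_counts.mtx"))
  write.table(data.frame(cell = colnames(sc$atac), as.data.frame(cd)),
              out("cell_metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tn5 <- computeTn5Weights(sc$atac, widths = width(ann$peaks))
  lin <- lineageScores(sc$atac, sc$lineageSets)
  cis <- cisreScores(sc$atac, network, tn5Weights = tn5)
  corrs <- lapply(colnames(lin), function(l) scoreCorrelation(cis, lin[, l]))
  names(corrs) <- colnames(lin)
  sigConsensus <- signatureScoresRna(sc$rna, consensusGenes(network))
  scoresTab <- data.frame(cell = colnames(sc$atac),
                          lineage = cd$lineage, pseudotime = cd$pseudotime,
                          repressor_pos = cd$repressor_pos,
                          lin, cisre_score = cis,
                          consensus_signature = sigConsensus)
  write.table(scoresTab, out("cell_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cmp <- compareGroupsResampled(
    cbind(consensus_signature = sigConsensus, cisre_score = cis),
    cd$repressor_pos, n_iter = 10, n_cells = min(1000, config@nCells %/% 4),
    seed = deriveSeed(config@seed, "resample_scores"))
  write.table(cmp, out("group_comparison.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  de <- resampledScDE(SummarizedExperiment::assay(sc$rna), cd$repressor_pos,
                      n_cells = min(1000, config@nCells %/% 4),
                      seed = deriveSeed(config@seed, "resample_de"))
  write.table(de, out("resampled_de.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ## minibulks along the myeloid trajectory
  mye <- cd$lineage == "myeloid"
  mbAtac <- pseudotimeMinibulks(
    SummarizedExperiment::assay(sc$atac)[, mye, drop = FALSE],
    cd$pseudotime[mye], n_bins = n_bins, modality = "atac",
    tssCounts = cd$tss_count[mye], tn5Weights = tn5)
  mbRna <- pseudotimeMinibulks(
    SummarizedExperiment::assay(sc$rna)[, mye, drop = FALSE],
    cd$pseudotime[mye], n_bins = n_bins, modality = "rna")
  trend <- signatureTrend(network, mbAtac$matrix, mbRna$matrix)
  writeCountTable(round(trend$atac, 6), out("trend_atac.tsv"))
  writeCountTable(round(trend$rna, 6), out("trend_rna.tsv"))
  summary <- list(
    workflow = "single_cell_scoring", seed = config@seed,
    n_cells = config@nCells, n_bins = n_bins,
    network_size = length(cisElements(network)),
    spearman = lapply(corrs, function(x) list(rho = x$rho, p = x$p)),
    group_comparison = setNames(as.list(cmp$padj), cmp$signature),
    n_de_genes = sum(de$mean_padj < 0.05),
    minibulk_cells = sum(mbAtac$cellCounts))
  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "summary.json"]
  summary$file_hashes <- as.list(hashFiles(files))
  writeJson(summary, out("summary.json"))
  invisible(summary)
}

#' Run the screen workflow end to end
#'
#' Simulates the guide library and sorted replicates, computes guide log
#' fold changes and the element-level permutation test, checks the
#' degrader-resistance positive controls, and writes the volcano table,
#' control report and hashed summary JSON.
#'
#' @inheritParams runDegronMultiomics
#' @param mode `"rescue"` or `"differentiation"`.
#' @return the summary list, invisibly.
#' @export
runScreen <- function(config, outdir, mode = c("rescue", "differentiation")) {
  mode <- match.arg(mode)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(outdir, f)
  ann <- simulateAnnotation(config)
  sim <- simulateScreen(config, ann$truth, mode = mode)
  counts <- screenCounts(sim$table)
  writeCountTable(counts, out("screen_counts.tsv"))
  write.table(guideData(sim$table), out("guide_annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lfcs <- guideLfc(sim$table)
  res <- elementTest(lfcs, seed = deriveSeed(config@seed, "element_test"))
  write.table(res, out("element_volcano.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ctl <- positiveControlCheck(res, sim$positiveControls, mode = mode)
  write.table(ctl, out("control_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  hits <- res$element_id[res$padj < 0.05 & res$score > 0 &
                           res$control_flag == "element"]
  rp <- recallPrecision(hits, sim$hitElements)
  summary <- list(
    workflow = "screen", mode = mode, seed = config@seed,
    n_guides = nrow(counts), n_elements = length(unique(lfcs$element_id)),
    hit_recall = rp$recall, hit_precision = rp$precision,
    controls_pass = all(ctl$pass))
  files <- list.files(outdir, full.names = TRUE)
  files <- files[basename(files) != "summary.json"]
  summary$file_hashes <- as.list(hashFiles(files))
  writeJson(summary, out("summary.json"))
  invisible(summary)
}
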