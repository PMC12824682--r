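#' @importClassesFrom IRanges SimpleRleList
#' @importFrom IRanges IRanges RleList Views coverage
#' @importFrom S4Vectors Rle runValue runLength mcols mcols<- DataFrame
#'   queryHits subjectHits window
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#'   findOverlaps granges
#' @importFrom Biostrings DNAStringSet
NULL

## ---------------------------------------------------------------------------
## DensityTrack: strand-resolved per-base read density (e.g. PRO-seq)
## ---------------------------------------------------------------------------

#' Strand-resolved per-base read-density track
#'
#' Holds nascent-transcription (or any other) read density at single-base
#' resolution, one run-length-encoded vector per chromosome and strand.
#' Densities are non-negative; both strands must cover the same chromosomes.
#'
#' @slot plus,minus [IRanges::RleList] of per-base densities, one element per
#'   chromosome, plus and minus strand respectively.
#' @export
setClass("DensityTrack", representation(plus = "SimpleRleList",
                                        minus = "SimpleRleList"))

setValidity("DensityTrack", function(object) {
  msg <- character()
  if (!identical(names(object@plus), names(object@minus)))
    msg <- c(msg, "plus and minus strands must cover identical chromosomes")
  if (any(vapply(object@plus, function(r) any(runValue(r) < 0), logical(1))) ||
      any(vapply(object@minus, function(r) any(runValue(r) < 0), logical(1))))
    msg <- c(msg, "densities must be non-negative")
  ok <- vapply(names(object@plus), function(nm) {
    length(object@plus[[nm]]) == length(object@minus[[nm]])
  }, logical(1))
  if (!all(ok)) msg <- c(msg, "strand tracks must have equal lengths per chromosome")
  if (length(msg)) msg else TRUE
})

#' Construct a DensityTrack
#'
#' @param plus,minus named [IRanges::RleList] (or plain named lists of numeric
#'   vectors) of per-base densities. If `minus` is missing an all-zero minus
#'   strand is used.
#' @return a [DensityTrack-class] object.
#' @examples
#' tr <- DensityTrack(plus = list(chr1 = c(0, 1, 2, 1, 0)))
#' trackChroms(tr)
#' @export
DensityTrack <- function(plus, minus = NULL) {
  toRle <- function(x) {
    if (is(x, "SimpleRleList")) x
    else as(lapply(x, function(v) Rle(as.numeric(v))), "SimpleRleList")
  }
  plus <- toRle(plus)
  if (is.null(minus)) {
    minus <- as(lapply(plus, function(r) Rle(0, length(r))), "SimpleRleList")
    names(minus) <- names(plus)
  } else minus <- toRle(minus)
  new("DensityTrack", plus = plus, minus = minus)
}

#' @describeIn DensityTrack chromosomes covered by the track.
#' @param x,object a `DensityTrack`.
#' @export
trackChroms <- function(x) names(x@plus)

#' @describeIn DensityTrack per-chromosome lengths.
#' @export
trackLengths <- function(x) vapply(x@plus, length, numeric(1))

#' Strand-specific density accessor
#'
#' @param x a [DensityTrack-class].
#' @param strand `"+"` or `"-"`.
#' @return an `RleList` of per-base densities.
#' @export
strandDensity <- function(x, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (strand == "+") x@plus else x@minus
}

setMethod("show", "DensityTrack", function(object) {
  cat("DensityTrack with", length(object@plus), "chromosome(s):",
      paste(names(object@plus), collapse = ", "), "\n")
  tot <- sum(vapply(object@plus, sum, numeric(1))) +
    sum(vapply(object@minus, sum, numeric(1)))
  cat("  total density (both strands):", fmtNum(tot), "\n")
})

## ---------------------------------------------------------------------------
## CisRENetwork: the direct repressor cisRE network plus its gene links
## ---------------------------------------------------------------------------

#' Direct repressor cisRE network
#'
#' Bound, differentially accessible cis-regulatory elements retained at the
#' occupancy-score cutoff, together with their proximity-based gene links and
#' the consensus gene set obtained by intersecting cisRE-proximal genes with
#' degradation-responsive gene sets.
#'
#' @slot elements [GenomicRanges::GRanges] with metadata columns
#'   `summit` (absolute bp), `atac_l2fc`, `atac_p`, `chip_score`
#'   (occupancy on the -log10(p)*10 scale) and `direction` (`"up"`/`"down"`).
#' @slot links `data.frame` with columns `cisre_id`, `gene_id`,
#'   `distance` (unsigned bp from summit to TSS).
#' @slot proximalGenes character vector of genes within the linking distance
#'   of at least one element.
#' @slot consensusGenes character vector, the consensus gene network.
#' @export
setClass("CisRENetwork", representation(elements = "GRanges",
                                        links = "data.frame",
                                        proximalGenes = "character",
                                        consensusGenes = "character"))

setValidity("CisRENetwork", function(object) {
  msg <- character()
  need <- c("summit", "atac_l2fc", "atac_p", "chip_score", "direction")
  if (!all(need %in% colnames(mcols(object@elements))))
    msg <- c(msg, paste("elements must carry metadata columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(mcols(object@elements)$chip_score < 0))
      msg <- c(msg, "chip_score must be non-negative")
    dir <- mcols(object@elements)$direction
    lfc <- mcols(object@elements)$atac_l2fc
    if (any(dir == "up" & lfc < 0) || any(dir == "down" & lfc > 0))
      msg <- c(msg, "direction must be consistent with the sign of atac_l2fc")
  }
  if (nrow(object@links) &&
      !all(c("cisre_id", "gene_id", "distance") %in% colnames(object@links)))
    msg <- c(msg, "links must have columns cisre_id, gene_id, distance")
  if (length(msg)) msg else TRUE
})

#' @describeIn CisRENetwork the element `GRanges`.
#' @param x,object a `CisRENetwork`.
#' @export
cisElements <- function(x) x@elements

#' @describeIn CisRENetwork the cisRE-to-gene link table.
#' @export
geneLinks <- function(x) x@links

#' @describeIn CisRENetwork genes within linking distance of >= 1 element.
#' @export
proximalGenes <- function(x) x@proximalGenes

#' @describeIn CisRENetwork the consensus gene network.
#' @export
consensusGenes <- function(x) x@consensusGenes

setMethod("show", "CisRENetwork", function(object) {
  cat("CisRENetwork with", length(object@elements), "elements\n")
  if (length(object@elements)) {
    dir <- table(mcols(object@elements)$direction)
    cat("  direction:", paste(names(dir), dir, sep = "=", collapse = ", "), "\n")
  }
  cat("  gene links:", nrow(object@links),
      "| proximal genes:", length(object@proximalGenes),
      "| consensus genes:", length(object@consensusGenes), "\n")
})

## ---------------------------------------------------------------------------
## ScreenTable: guide-level CRISPR screen counts
## ---------------------------------------------------------------------------

#' Guide-level CRISPR screen count table
#'
#' Raw sgRNA counts for a plasmid library column and one or more sorted
#' population replicates, with each guide mapped to exactly one element.
#'
#' @slot counts integer matrix, guides x samples; rownames are guide ids.
#' @slot guideData `data.frame` with columns `guide_id`, `element_id` and
#'   `control_flag` in `{"element", "positive_control", "nontargeting"}`.
#' @slot libraryCol name of the plasmid-library column.
#' @slot sortedCols names of the sorted-population columns.
#' @export
setClass("ScreenTable", representation(counts = "matrix",
                                       guideData = "data.frame",
                                       libraryCol = "character",
                                       sortedCols = "character"))

setValidity("ScreenTable", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!identical(rownames(object@counts), object@guideData$guide_id))
    msg <- c(msg, "counts rownames must equal guideData$guide_id")
  if (anyDuplicated(object@guideData$guide_id))
    msg <- c(msg, "each guide must appear exactly once")
  if (!all(object@guideData$control_flag %in%
           c("element", "positive_control", "nontargeting")))
    msg <- c(msg, "control_flag must be element/positive_control/nontargeting")
  if (!object@libraryCol %in% colnames(object@counts))
    msg <- c(msg, "libraryCol absent from counts")
  if (!all(object@sortedCols %in% colnames(object@counts)))
    msg <- c(msg, "sortedCols absent from counts")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenTable
#'
#' @param counts guides x samples count matrix with rownames.
#' @param guideData per-guide data.frame (`guide_id`, `element_id`,
#'   `control_flag`).
#' @param libraryCol,sortedCols column names of the plasmid library and the
#'   sorted replicates. Defaults: first column is the library, the rest are
#'   sorted replicates.
#' @return a [ScreenTable-class].
#' @export
ScreenTable <- function(counts, guideData,
                        libraryCol = colnames(counts)[1],
                        sortedCols = setdiff(colnames(counts), libraryCol)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- guideData$guide_id
  new("ScreenTable", counts = counts,
      guideData = as.data.frame(guideData, stringsAsFactors = FALSE),
      libraryCol = libraryCol, sortedCols = sortedCols)
}

#' @describeIn ScreenTable the raw count matrix.
#' @param x,object a `ScreenTable`.
#' @export
screenCounts <- function(x) x@counts

#' @describeIn ScreenTable the per-guide annotation.
#' @export
guideData <- function(x) x@guideData

setMethod("show", "ScreenTable", function(object) {
  cat("ScreenTable:", nrow(object@counts), "guides x",
      ncol(object@counts), "samples\n")
  cat("  elements:", length(unique(object@guideData$element_id)),
      "| library column:", object@libraryCol,
      "| sorted replicates:", length(object@sortedCols), "\n")
  fl <- table(object@guideData$control_flag)
  cat("  flags:", paste(names(fl), fl, sep = "=", collapse = ", "), "\n")
})
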