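## Readers/writers for the chromatin formats and the interval/window engine.
## External files follow BED conventions (0-based, half-open); in memory all
## intervals live in GRanges (1-based, closed) with absolute 1-based summits.

#' Read a narrowPeak or BED6 peak file
#'
#' Accepts 6-column BED or 10-column narrowPeak. For narrowPeak input the
#' summit is reconstructed as an absolute position from the column-10 offset.
#' Malformed lines raise an error carrying the offending line number.
#'
#' @param path file path.
#' @return a [GenomicRanges::GRanges] with metadata columns `name`, `score`
#'   and, for narrowPeak input, `signalValue`, `pValue`, `qValue`, `summit`
#'   (absolute 1-based position).
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t600\tpk1\t0\t.\t5.5\t10\t8\t250", f)
#' readNarrowPeak(f)
#' @export
readNarrowPeak <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(emptyPeaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!all(nf %in% c(6L, 10L)) || length(unique(nf)) != 1L) {
    bad <- which(!nf %in% c(6L, 10L))[1] %||% which(nf != nf[1])[1]
    stop("parse error at line ", bad, ": expected 6 or 10 tab-separated ",
         "columns, found ", nf[bad])
  }
  ncol <- nf[1]
  m <- matrix(unlist(fields), ncol = ncol, byrow = TRUE)
  start0 <- suppressWarnings(as.numeric(m[, 2]))
  end0 <- suppressWarnings(as.numeric(m[, 3]))
  badNum <- which(is.na(start0) | is.na(end0))
  if (length(badNum))
    stop("parse error at line ", badNum[1], ": non-numeric coordinates")
  badIv <- which(start0 < 0 | end0 <= start0)
  if (length(badIv))
    stop("parse error at line ", badIv[1],
         ": interval must satisfy 0 <= start < end")
  gr <- GRanges(m[, 1], IRanges(start0 + 1, end0),
                strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"))
  mcols(gr)$name <- m[, 4]
  mcols(gr)$score <- as.numeric(m[, 5])
  if (ncol == 10L) {
    off <- suppressWarnings(as.numeric(m[, 10]))
    badOff <- which(!is.na(off) & off >= 0 & off >= end0 - start0)
    if (length(badOff))
      stop("validation error at line ", badOff[1],
           ": summit offset must be < interval length")
    mcols(gr)$signalValue <- as.numeric(m[, 7])
    mcols(gr)$pValue <- as.numeric(m[, 8])
    mcols(gr)$qValue <- as.numeric(m[, 9])
    mcols(gr)$summit <- ifelse(off < 0, NA_real_, start0 + off + 1)
  }
  names(gr) <- mcols(gr)$name
  gr
}

emptyPeaks <- function() {
  gr <- GRanges()
  mcols(gr)$name <- character()
  mcols(gr)$score <- numeric()
  gr
}

#' Write peaks as narrowPeak (10 columns) or BED6
#'
#' Writes 10-column narrowPeak whenever a `summit` metadata column is present
#' (column 10 is the summit offset from interval start, or -1 when absent),
#' otherwise plain BED6. Round trips through [readNarrowPeak()] are exact.
#'
#' @param peaks `GRanges` as returned by [readNarrowPeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNarrowPeak <- function(peaks, path) {
  mc <- mcols(peaks)
  nm <- if ("name" %in% colnames(mc)) mc$name else
    if (!is.null(names(peaks))) names(peaks) else
      paste0("peak_", seq_along(peaks))
  sc <- if ("score" %in% colnames(mc)) mc$score else rep(0, length(peaks))
  str <- as.character(strand(peaks))
  str[str == "*"] <- "."
  base <- cbind(as.character(seqnames(peaks)),
                fmtNum(start(peaks) - 1, 15), fmtNum(end(peaks), 15),
                nm, fmtNum(sc, 10), str)
  if ("summit" %in% colnames(mc)) {
    off <- ifelse(is.na(mc$summit), -1, mc$summit - start(peaks))
    base <- cbind(base,
                  fmtNum(mc$signalValue %||% rep(0, length(peaks)), 10),
                  fmtNum(mc$pValue %||% rep(-1, length(peaks)), 10),
                  fmtNum(mc$qValue %||% rep(-1, length(peaks)), 10),
                  fmtNum(off, 15))
  }
  writeLines(apply(base, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read / write a TSS table as BED6
#'
#' The TSS table stores one 1-bp interval per gene (BED start = 0-based TSS),
#' gene id in the name column, strand in column 6.
#'
#' @param path file path.
#' @return `readTssBed`: `GRanges` of width-1 TSS positions named by gene id.
#' @export
readTssBed <- function(path) {
  gr <- readNarrowPeak(path)
  if (length(gr) && any(width(gr) != 1L))
    stop("TSS table must contain width-1 intervals")
  gr
}

#' @rdname readTssBed
#' @param tss width-1 `GRanges` with a `name` metadata column.
#' @export
writeTssBed <- function(tss, path) {
  mc <- mcols(tss)
  keep <- GRanges(seqnames(tss), IRanges(start(tss), end(tss)),
                  strand = strand(tss))
  mcols(keep)$name <- mc$name
  mcols(keep)$score <- mc$score %||% rep(0, length(tss))
  writeNarrowPeak(keep, path)
}

#' Read / write strand-resolved bedGraph density tracks
#'
#' One bedGraph file per strand; zero runs are omitted on disk. Reading uses
#' \pkg{rtracklayer} and reconstitutes full-length per-base [DensityTrack-class]
#' vectors from the supplied chromosome lengths.
#'
#' @param plusPath,minusPath bedGraph paths for the two strands.
#' @param chromLengths named numeric vector of chromosome lengths.
#' @return a [DensityTrack-class].
#' @export
readDensityTrack <- function(plusPath, minusPath, chromLengths) {
  readOne <- function(p) {
    gr <- rtracklayer::import(p, format = "bedGraph")
    cov <- coverage(gr, weight = "score")
    out <- lapply(names(chromLengths), function(nm) {
      L <- as.integer(chromLengths[[nm]])
      if (nm %in% names(cov)) {
        r <- cov[[nm]]
        if (length(r) < L) r <- c(r, Rle(0, L - length(r)))
        r[seq_len(L)]
      } else Rle(0, L)
    })
    names(out) <- names(chromLengths)
    as(out, "SimpleRleList")
  }
  DensityTrack(plus = readOne(plusPath), minus = readOne(minusPath))
}

#' @rdname readDensityTrack
#' @param track a [DensityTrack-class].
#' @param prefix output path prefix; files `<prefix>_plus.bedGraph` and
#'   `<prefix>_minus.bedGraph` are written.
#' @export
writeDensityTrack <- function(track, prefix) {
  writeOne <- function(rl, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(rl)) {
      r <- rl[[nm]]
      ends <- cumsum(S4Vectors::runLength(r))
      starts <- ends - S4Vectors::runLength(r) + 1
      vals <- runValue(r)
      keep <- vals != 0
      if (any(keep)) {
        writeLines(paste(nm, fmtNum(starts[keep] - 1, 15),
                         fmtNum(ends[keep], 15), fmtNum(vals[keep], 10),
                         sep = "\t"), con)
      }
    }
    invisible(path)
  }
  p <- paste0(prefix, "_plus.bedGraph")
  m <- paste0(prefix, "_minus.bedGraph")
  writeOne(strandDensity(track, "+"), p)
  writeOne(strandDensity(track, "-"), m)
  invisible(c(plus = p, minus = m))
}

#' Read / write a TSV count table
#'
#' Tab-separated with a mandatory header row; the first column holds feature
#' ids and becomes the rownames of the returned matrix.
#'
#' @param path file path.
#' @return `readCountTable`: numeric matrix, features x samples.
#' @export
readCountTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname readCountTable
#' @param mat numeric matrix with rownames and colnames.
#' @export
writeCountTable <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' All overlapping interval pairs between two peak sets
#'
#' Half-open overlap semantics on shared chromosomes: intervals `[s1,e1)` and
#' `[s2,e2)` overlap iff `s1 < e2` and `s2 < e1`. Output is sorted by
#' (chromosome, start of the first set's interval), ties by (start, end, id).
#'
#' @param a,b `GRanges` peak sets.
#' @return `data.frame` with columns `a` and `b` (integer indices into the
#'   inputs), `chrom`, `a_start`.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
#' nrow(overlapPairs(a, b))  # adjacency is not overlap
#' @export
overlapPairs <- function(a, b) {
  hits <- findOverlaps(a, b, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  ord <- order(as.character(seqnames(a))[q], start(a)[q], end(a)[q], q, s)
  data.frame(a = q[ord], b = s[ord],
             chrom = as.character(seqnames(a))[q][ord],
             a_start = start(a)[q][ord])
}

#' Summit-centered window densities
#'
#' Extracts per-base density in a window of `2 * halfwidth + 1` bases centered
#' on each anchor's summit. Plus- and minus-strand densities are summed unless
#' `strandSum = FALSE` (then only the anchor's own strand is used).
#' Minus-strand anchors are orientation-flipped so profiles read 5'->3'.
#' Positions falling outside the chromosome are masked (`NA`) and the anchor
#' is flagged in the `truncated` attribute.
#'
#' @param track a [DensityTrack-class].
#' @param anchors `GRanges` with an absolute `summit` metadata column.
#' @param halfwidth window half-width in bp (> 0).
#' @param mode `"profile"` (anchors x positions matrix) or `"mean"` (scalar
#'   mean over unmasked positions per anchor).
#' @param strandSum sum both strands (default) or use anchor strand only.
#' @return matrix or numeric vector, with attribute `truncated` (logical per
#'   anchor).
#' @export
windowDensity <- function(track, anchors, halfwidth,
                          mode = c("profile", "mean"), strandSum = TRUE) {
  mode <- match.arg(mode)
  stopifnot(halfwidth > 0)
  summit <- mcols(anchors)$summit
  if (is.null(summit) || any(is.na(summit)))
    stop("all anchors must carry a summit")
  n <- length(anchors)
  w <- 2 * halfwidth + 1
  prof <- matrix(NA_real_, n, w)
  truncated <- logical(n)
  lens <- trackLengths(track)
  chr <- as.character(seqnames(anchors))
  str <- as.character(strand(anchors))
  for (i in seq_len(n)) {
    nm <- chr[i]
    if (!nm %in% names(lens)) stop("anchor chromosome not in track: ", nm)
    L <- lens[[nm]]
    lo <- summit[i] - halfwidth
    hi <- summit[i] + halfwidth
    clo <- max(lo, 1); chi <- min(hi, L)
    if (clo > lo || chi < hi) truncated[i] <- TRUE
    if (clo > chi) next
    vals <- as.numeric(window(strandDensity(track, "+")[[nm]], clo, chi))
    if (strandSum) {
      vals <- vals + as.numeric(window(strandDensity(track, "-")[[nm]], clo, chi))
    } else if (str[i] == "-") {
      vals <- as.numeric(window(strandDensity(track, "-")[[nm]], clo, chi))
    }
    prof[i, (clo - lo + 1):(chi - lo + 1)] <- vals
    if (str[i] == "-") prof[i, ] <- rev(prof[i, ])
  }
  if (mode == "mean") {
    out <- rowMeans(prof, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
  } else out <- prof
  attr(out, "truncated") <- truncated
  out
}
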