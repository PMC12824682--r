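#' @import methods
#' @importFrom stats rnbinom rpois rnorm runif rbinom quantile median var
#'   pnorm pt phyper p.adjust optimize uniroot wilcox.test qchisq pchisq
#'   setNames complete.cases sd cor
#' @importFrom utils read.table write.table head tail
NULL

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Each randomised stage of the pipeline draws its own seed from the master
#' seed so that partial reruns (e.g. regenerating only the screen counts)
#' are reproducible without sharing a single global stream.
#'
#' @param seed master integer seed.
#' @param tag character stage label.
#' @return an integer in `[0, 2^31 - 1)`.
#' @examples
#' deriveSeed(1L, "bulk_rna")
#' @export
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- as.double(seed %% 2147483647)
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

## evaluate `expr` under a local RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## deterministic number formatting for text output (no scientific notation)
fmtNum <- function(x, digits = 6L) {
  formatC(x, digits = digits, format = "g", flag = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
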