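#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a top-level seed and a label
#'
#' A single user-supplied seed is fanned out to independent per-stage (or
#' per-population) seeds so that any stage can be re-run in isolation and
#' still reproduce its stream. The derivation is a fixed multiplicative hash
#' of the label folded into the parent seed, reduced modulo 2^31 - 1 so the
#' result is always a valid R integer seed.
#'
#' @param seed integer parent seed.
#' @param label character label naming the stage or unit.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h + 1) %% (m - 1) + 1)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state. All stochastic operations in the package go through this.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Write a data frame as tab-separated values
#'
#' All pipeline tables are written as plain TSV with `NA` markers and no
#' quoting or locale-dependent formatting.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path input file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
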