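#' @useDynLib psifinder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbinom rlnorm rnorm runif setNames p.adjust pnorm
#'   quantile rnbinom rpois var aggregate
#' @importFrom utils write.table read.table head
NULL

BASES <- c("A", "C", "G", "T")

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named substreams, so any stage can be re-run in isolation and reproduce
#' its draws exactly. The substream seed is a deterministic 31-bit hash of
#' the master seed and the stream name.
#'
#' @param master integer master seed.
#' @param name character scalar naming the stream (e.g. `"sim/cmc_plus/rep2"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Locale-independent character ordering (C collation via radix sort), so
# output tables are byte-identical across systems.
order_radix <- function(...) order(..., method = "radix")

revcomp <- function(x) {
  out <- vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
                function(b) paste(rev(b), collapse = ""), character(1))
  unname(out)
}

# DNA (T) to RNA (U) display conversion for report tables.
dna_to_rna <- function(x) chartr("T", "U", x)

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Write a deterministic TSV table
#'
#' Fixed quoting and NA conventions so repeated runs produce byte-identical
#' files.
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

log_msg <- function(stage, level, msg, verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf("[%s] %s: %s", level, stage, msg))
  invisible(NULL)
}
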