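#' Derive a child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their randomness from one
#' master seed; independent sub-streams (per field, per genotype, per CV
#' repeat) use child seeds derived deterministically by a counter so that
#' results are reproducible without relying on global RNG state ordering.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer identifying the sub-stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' childSeed(1L, 0:3)
childSeed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(counter))
  as.integer((as.double(seed) %% 2147483647 + 1000003 * (counter + 1)) %%
               2147483646 + 1)
}

# run expr under a local seed, restoring RNG state afterwards
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# md5 of a character vector (schema identity), via a temporary file since
# base R exposes md5 only for files
.charHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

.featureCols <- function(table) {
  grep("^f[0-9]{3}$", colnames(table), value = TRUE)
}

.assertFeatureTable <- function(table) {
  fc <- .featureCols(table)
  if (length(fc) == 0L)
    stop("not a feature table: no f### columns found")
  invisible(fc)
}
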