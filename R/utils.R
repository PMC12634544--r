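#' Derive a reproducible substream seed
#'
#' Expands one global seed into named, independent-looking substreams so that
#' each randomised component of the pipeline draws from its own stream.
#' Adding a new component (with a new name) therefore never perturbs the
#' random numbers consumed by an existing one.
#'
#' The rule is fixed and documented: the stream name is hashed by Horner's
#' method over its UTF-8 codes modulo 2147483647, and the substream seed is
#' `(seed + 1009 * hash) mod 2147483647`. All arithmetic stays below 2^31 so
#' the result is always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param name character scalar naming the stream (e.g. `"soil_table"`).
#' @return An integer seed in `[0, 2147483646]`.
#' @export
#' @examples
#' substream_seed(42, "soil_table")
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L, nzchar(name))
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  as.integer((abs(seed) %% m + 1009 * h) %% m)
}

## internal: stop() with a consistent header, sprintf-style
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## internal: check a square numeric matrix is symmetric within tolerance
check_symmetric <- function(m, what = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    abort("%s must be a square matrix", what)
  if (max(abs(m - t(m))) > tol)
    abort("%s must be symmetric", what)
  invisible(TRUE)
}

## internal: truncated-at-zero normal draws by resampling (no point mass at 0)
rnorm_truncated <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L)
      abort("truncated-normal resampling failed: mean %g, sd %g leaves almost no positive mass", mean, sd)
  }
  out
}

## internal: matrix upper-triangle pairs as a 2-column index matrix
upper_pairs <- function(d) {
  which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
}
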