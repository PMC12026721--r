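#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (for positive values), the
#' convention used for all reported percentages. Base [round()] rounds ties
#' to even, which would print 16.665 as 16.66.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' roundHalfUp(100 / 6, 2)  # 16.67
roundHalfUp <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# stop() with a condition class so callers can distinguish validation from
# I/O failures (used by the CLI for exit codes)
tgsStop <- function(msg, class = "tgs_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

# deterministic sub-stream seed so genotype draws are unaffected by how many
# continuous variables are generated afterwards
subSeed <- function(seed, stream) {
  (abs(as.integer(seed)) + 1299709L * as.integer(stream)) %% 2147483629L
}

# largest-remainder allocation of 100.00 across percentages (2 decimals)
reconcilePct <- function(raw) {
  cents <- floor(raw * 100 + 1e-9)
  short <- round(10000 - sum(cents))
  if (short > 0) {
    rem <- raw * 100 - cents
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    cents[idx] <- cents[idx] + 1
  }
  cents / 100
}
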