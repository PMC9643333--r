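#' @importFrom methods new validObject is slot
#' @importFrom stats cor lm pbinom pnorm p.adjust runif sd setNames
#' @importFrom utils combn head
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Presentation rounding: round-half-up to `digits` decimals (matches how the
## study tables print column averages, e.g. mean 88.85 -> 88.9).
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Counter-based seed fan-out: one global seed yields independent per-component
## seeds, so adding a component does not shift the streams of the others.
## Kept below 2^31 - 1 (R integers are 32-bit).
fanSeed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(as.numeric(seed)) + 97003 * component) %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Canonical string key for an unordered pair of ids.
pairKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
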