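#' @importFrom stats rbinom sd setNames
#' @importFrom utils read.delim write.table
NULL

.DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assertFraction <- function(x, name, lo = 0, hi = 1, lo.open = FALSE, hi.open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo.open) x > lo else x >= lo) && (if (hi.open) x < hi else x <= hi)
  if (!ok) stop(sprintf("'%s' must be a fraction in %s%g, %g%s", name,
                        if (lo.open) "(" else "[", lo, hi,
                        if (hi.open) ")" else "]"), call. = FALSE)
  as.numeric(x)
}

# commercial rounding (half away from zero), used for reported percentages
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.randomDNA <- function(len) {
  paste(sample(.DNA_BASES, len, replace = TRUE), collapse = "")
}

# substitute exactly nSub random positions with a different base
.substituteBases <- function(seq, nSub) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), nSub)
  for (p in pos) {
    v[p] <- sample(setdiff(.DNA_BASES, v[p]), 1L)
  }
  paste(v, collapse = "")
}

# per-base substitution noise at the given rate
.applySequencingErrors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- rbinom(1L, nchar(seq), rate)
  if (n == 0L) seq else .substituteBases(seq, n)
}

# deterministic per-stage seed split, kept inside 32-bit integer range
.splitSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}
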