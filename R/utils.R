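# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one documented stream per (seed, index)
# pair, so adding replicates or scenarios never perturbs earlier draws.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  x <- (abs(as.double(seed)) %% m)
  # two rounds of a Lehmer-style mix keep distinct (seed, index) pairs apart
  x <- (x * 48271 + as.double(index) * 16807 + 12345) %% m
  x <- (x * 69621 + 7) %% m
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Locale-independent (C collation) character sort: node and parent orderings
# must not depend on the session locale.
csort <- function(x) sort(x, method = "radix")

abort <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "svbn_error")))
}

popcount <- function(m) {
  n <- 0L
  while (m > 0L) {
    n <- n + bitwAnd(m, 1L)
    m <- bitwShiftR(m, 1L)
  }
  n
}

bits_of <- function(m, nmax) {
  which(bitwAnd(m, bitwShiftL(1L, seq_len(nmax) - 1L)) != 0L)
}

mask_of <- function(idx) {
  if (length(idx) == 0L) return(0L)
  sum(bitwShiftL(1L, idx - 1L))
}
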