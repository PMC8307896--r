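# Independent brute-force oracles used only by the tests; deliberately naive
# and kept free of the package's own code paths they check.

# Exhaustive-history LZ76 parsing by literal substring search over ABc:
# candidate B grows while it occurs in the concatenation minus its last
# symbol; a trailing reproducible B counts as one component. Symbols are
# mapped to single characters (alphabet <= 24) so grepl(fixed) does the
# substring test.
lz76_oracle <- function(sym) {
  stopifnot(length(sym) >= 1, max(sym) < 24)
  chars <- strsplit(intToUtf8(as.integer(sym) + 65L), "")[[1]]
  n <- length(chars)
  cnt <- 1L
  h <- 1L  # end of parsed history A
  while (h < n) {
    i <- 1L
    repeat {
      B <- paste0(chars[(h + 1L):(h + i)], collapse = "")
      ABc <- paste0(chars[1:(h + i - 1L)], collapse = "")
      if (!grepl(B, ABc, fixed = TRUE)) {   # B novel: component ends
        cnt <- cnt + 1L
        h <- h + i
        break
      }
      if (h + i == n) {                     # sequence ended mid-component
        cnt <- cnt + 1L
        h <- n
        break
      }
      i <- i + 1L
    }
  }
  cnt
}

# Lehmer rank of the stable ascending ordinal pattern of a raw window,
# computed with base R sorting only.
ordinal_oracle <- function(w) {
  p <- order(w) - 1L  # order() is stable: ties keep temporal order
  m <- length(p)
  idx <- 0L
  for (i in seq_len(m - 1L)) {
    idx <- idx + sum(p[(i + 1L):m] < p[i]) * factorial(m - i)
  }
  as.integer(idx)
}

# Two-sided Mann-Whitney p-value by exhaustive enumeration of all label
# arrangements (tie-free samples assumed).
mw_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n2 <- length(b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# All binary sequences of length n, as rows of a matrix.
all_binary_seqs <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}
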