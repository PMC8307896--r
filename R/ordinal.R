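#' Ordinal analysis configuration
#'
#' Bundles the motif order `m` (number of samples per ordinal pattern,
#' admissible range 3..7) and time delay `tau` (spacing between the samples
#' of a motif, in samples). The defaults `m = 4`, `tau = 1` suit series of
#' at least ~1000 samples.
#'
#' @param m integer motif order, between 3 and 7.
#' @param tau integer time delay, >= 1.
#' @return An object of class `ordinal_config`.
#' @export
#' @examples
#' ordinal_config()        # m = 4, tau = 1
#' ordinal_config(5, 2)
ordinal_config <- function(m = 4L, tau = 1L) {
  m <- as.integer(m); tau <- as.integer(tau)
  if (length(m) != 1L || is.na(m) || m < 3L || m > 7L) {
    stop("order m must be an integer between 3 and 7")
  }
  if (length(tau) != 1L || is.na(tau) || tau < 1L) {
    stop("time delay tau must be an integer >= 1")
  }
  structure(list(m = m, tau = tau), class = "ordinal_config")
}

#' @export
print.ordinal_config <- function(x, ...) {
  cat(sprintf("<ordinal_config> m = %d, tau = %d (alphabet %d)\n",
              x$m, x$tau, factorial(x$m)))
  invisible(x)
}

#' Index of an ordinal pattern (Lehmer rank)
#'
#' Bijection between the `m!` ordinal patterns of order `m` and the integers
#' `0:(m! - 1)`, by lexicographic (Lehmer-code) enumeration; the identity
#' permutation maps to 0. [index_pattern()] is the inverse.
#'
#' @param perm integer permutation of `0:(m-1)` (0-based).
#' @return Integer index in `[0, m! - 1]`.
#' @export
#' @examples
#' pattern_index(c(0, 1, 2))  # 0
#' pattern_index(c(2, 1, 0))  # 5
pattern_index <- function(perm) {
  perm <- as.integer(perm)
  m <- length(perm)
  if (m < 1L || anyNA(perm) || !setequal(perm, 0:(m - 1L))) {
    stop("perm must be a permutation of 0:(m-1)")
  }
  idx <- 0L
  for (i in seq_len(m - 1L)) {
    idx <- idx + sum(perm[(i + 1L):m] < perm[i]) * factorial(m - i)
  }
  as.integer(idx)
}

#' @rdname pattern_index
#' @param index integer in `[0, m! - 1]`.
#' @param m motif order.
#' @export
index_pattern <- function(index, m) {
  index <- as.integer(index); m <- as.integer(m)
  if (index < 0L || index >= factorial(m)) stop("index out of [0, m!-1]")
  avail <- 0:(m - 1L)
  perm <- integer(m)
  for (i in seq_len(m)) {
    f <- factorial(m - i)
    d <- index %/% f
    index <- index %% f
    perm[i] <- avail[d + 1L]
    avail <- avail[-(d + 1L)]
  }
  perm
}

#' Ordinal-pattern symbolization
#'
#' Maps each delay-embedded window `(x[N], x[N + tau], ..., x[N + tau*(m-1)])`
#' to the permutation that arranges its values in increasing order, encoded as
#' a Lehmer-rank symbol in `0:(m! - 1)`. Ties are broken by temporal index
#' (stable sort), so equal values keep their original order. The output has
#' exactly `length(x) - (m - 1) * tau` symbols.
#'
#' @param x numeric vector, length at least `(m - 1) * tau + 1`.
#' @param cfg an [ordinal_config()].
#' @return A [symbol_sequence] with alphabet size `factorial(m)`.
#' @export
#' @examples
#' ordinal_symbolize(c(3, 1, 2), ordinal_config(3))  # pattern (1,2,0) -> 3
ordinal_symbolize <- function(x, cfg = ordinal_config()) {
  stopifnot(inherits(cfg, "ordinal_config"))
  x <- as.numeric(x)
  if (anyNA(x)) stop("cannot symbolize a signal containing NA")
  m <- cfg$m; tau <- cfg$tau
  nmin <- (m - 1L) * tau + 1L
  if (length(x) < nmin) {
    stop(sprintf("signal too short: need at least %d samples for m = %d, tau = %d",
                 nmin, m, tau))
  }
  nsym <- length(x) - (m - 1L) * tau
  base <- seq_len(nsym)
  # Y[, i] holds the i-th delayed sample of every window
  Y <- vapply(0:(m - 1L), function(i) x[base + i * tau], numeric(nsym))
  if (nsym == 1L) Y <- matrix(Y, nrow = 1L)
  # stable ascending rank of each window position (earlier index wins ties)
  R <- matrix(1L, nsym, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j == i) next
      lt <- Y[, j] < Y[, i]
      if (j < i) lt <- lt | (Y[, j] == Y[, i])
      R[, i] <- R[, i] + lt
    }
  }
  # P[k, ] is the ordinal pattern: positions (0-based) sorted by value
  P <- matrix(0L, nsym, m)
  for (i in seq_len(m)) P[cbind(base, R[, i])] <- i - 1L
  # Lehmer rank, vectorized over windows
  sym <- numeric(nsym)
  for (i in seq_len(m - 1L)) {
    ci <- integer(nsym)
    for (j in (i + 1L):m) ci <- ci + (P[, j] < P[, i])
    sym <- sym + ci * factorial(m - i)
  }
  symbol_sequence(as.integer(sym), as.integer(factorial(m)))
}

#' Permutation Lempel-Ziv complexity
#'
#' Symbolizes `x` into ordinal patterns, parses the symbol stream with
#' [lz76_count()] and normalizes as
#' `PLZC = c(n) * log_{m!}(n) / n`, where `n` is the number of ordinal
#' symbols (`length(x) - (m - 1) * tau`). Emits a warning (not an error)
#' when `m! > n`, in which case not every pattern can occur.
#'
#' @inheritParams ordinal_symbolize
#' @return A `complexity_result` with fields `c`, `n`, `normalized`.
#' @export
#' @examples
#' plzc(sin(2 * pi * 5 * seq(0, 1, length.out = 500)))
plzc <- function(x, cfg = ordinal_config()) {
  seq <- ordinal_symbolize(x, cfg)
  n <- length(seq)
  A <- factorial(cfg$m)
  if (A > n) {
    warning(sprintf("m! = %d exceeds symbol count n = %d; not every ordinal pattern can occur",
                    A, n))
  }
  cc <- lz76_count(seq)
  new_complexity_result(cc, n, cc * (log(n) / log(A)) / n)
}
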