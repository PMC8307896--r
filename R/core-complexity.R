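#' Symbol sequences over a finite alphabet
#'
#' A `symbol_sequence` is an integer vector of symbols in `0:(alphabet_size - 1)`
#' with the alphabet size attached. Binarization produces alphabet size 2;
#' ordinal symbolization produces alphabet size `factorial(m)`.
#'
#' @param symbols integer vector of non-negative symbols.
#' @param alphabet_size integer alphabet size `A >= 2`; every symbol must lie
#'   in `[0, A - 1]`.
#' @return An object of class `symbol_sequence`.
#' @export
#' @examples
#' symbol_sequence(c(0L, 1L, 1L, 0L), 2L)
symbol_sequence <- function(symbols, alphabet_size) {
  symbols <- as.integer(symbols)
  alphabet_size <- as.integer(alphabet_size)
  if (length(symbols) < 1L) stop("symbol sequence must have length >= 1")
  if (anyNA(symbols)) stop("symbol sequence contains NA")
  if (length(alphabet_size) != 1L || is.na(alphabet_size) || alphabet_size < 2L) {
    stop("alphabet_size must be a single integer >= 2")
  }
  if (any(symbols < 0L) || any(symbols >= alphabet_size)) {
    stop("symbols must lie in [0, alphabet_size - 1]")
  }
  structure(symbols, alphabet_size = alphabet_size, class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol_sequence> n = %d, alphabet = %d\n",
              length(x), attr(x, "alphabet_size")))
  print(utils::head(as.integer(x), 25L))
  invisible(x)
}

#' Binarize a signal by mean or median threshold
#'
#' Converts a real-valued series into a 0/1 symbol sequence by comparing each
#' sample with a threshold `Td` computed over the whole vector passed in:
#' symbol 1 where `x > Td`, symbol 0 otherwise (samples exactly equal to the
#' threshold map to 0).
#'
#' @param x numeric vector (NAs not allowed).
#' @param method threshold rule, `"mean"` (default) or `"median"`.
#' @return A [symbol_sequence] with alphabet size 2, same length as `x`.
#' @export
#' @examples
#' binarize(c(1, 2, 3, 4))             # 0 0 1 1 (Td = 2.5)
#' binarize(c(1, 9, 2, 8, 3), "median")
binarize <- function(x, method = c("mean", "median")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (length(x) == 0L) stop("cannot binarize an empty signal")
  if (anyNA(x)) stop("cannot binarize a signal containing NA")
  td <- if (method == "mean") mean(x) else stats::median(x)
  symbol_sequence(as.integer(x > td), 2L)
}

#' Lempel-Ziv (1976) production count
#'
#' Counts the components of the greedy exhaustive-history parsing of a symbol
#' sequence: the first symbol is component 1; thereafter a candidate extension
#' `B` grows while it is a substring of the concatenation minus its last
#' symbol, and a new component is registered when `B` is novel. A trailing
#' `B` that is still reproducible when the sequence ends counts as one final
#' component.
#'
#' @param seq a [symbol_sequence], or a bare integer vector of symbols.
#' @return Integer count `c(n)`, with `1 <= c(n) <= n`.
#' @export
#' @examples
#' lz76_count(symbol_sequence(rep(0L, 16L), 2L))                  # 2
#' lz76_count(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L,
#'              0L, 0L, 0L, 1L, 0L, 1L))                          # 6
lz76_count <- function(seq) {
  if (!inherits(seq, "symbol_sequence")) {
    seq <- symbol_sequence(seq, max(2L, max(as.integer(seq)) + 1L))
  }
  .lz76_count_cpp(as.integer(seq))
}

new_complexity_result <- function(c, n, normalized) {
  structure(list(c = as.integer(c), n = as.integer(n),
                 normalized = as.numeric(normalized)),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("<complexity_result> n = %d, c = %d, normalized = %.6g\n",
              x$n, x$c, x$normalized))
  invisible(x)
}

#' @export
as.data.frame.complexity_result <- function(x, ...) {
  data.frame(n = x$n, c = x$c, normalized = x$normalized)
}

#' Normalized binary Lempel-Ziv complexity
#'
#' Binarizes `x` against its mean (or median), parses the 0/1 stream with
#' [lz76_count()] and normalizes the production count as
#' `C(n) = c(n) * log2(n) / n`, where `n` is the symbol-sequence length
#' (equal to `length(x)` for binarization). Values above 1 at small `n` are
#' returned as computed, without clipping. A [symbol_sequence] may be passed
#' directly to skip binarization.
#'
#' @param x numeric vector of length >= 2, or a [symbol_sequence].
#' @param method threshold rule passed to [binarize()].
#' @return A `complexity_result` with fields `c`, `n`, `normalized`.
#' @export
#' @examples
#' s <- symbol_sequence(c(0,0,0,1,1,0,1,0,0,1,0,0,0,1,0,1), 2)
#' lzc(s)$normalized   # 6 * log2(16) / 16 = 1.5
lzc <- function(x, method = c("mean", "median")) {
  seq <- if (inherits(x, "symbol_sequence")) x else binarize(x, method)
  n <- length(seq)
  if (n < 2L) stop("lzc needs at least 2 samples")
  cc <- lz76_count(seq)
  new_complexity_result(cc, n, cc * log2(n) / n)
}
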