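#' Coarse-grain a series by non-overlapping block means
#'
#' Replaces `x` by the means of consecutive non-overlapping blocks of `s`
#' samples; the output has length `floor(length(x) / s)` and trailing
#' remainder samples are dropped. Scale 1 returns the input unchanged.
#'
#' @param x numeric vector.
#' @param s integer scale factor, `1 <= s <= length(x)`.
#' @return Numeric vector of block means.
#' @export
#' @examples
#' coarse_grain(1:5, 2)  # 1.5 3.5
coarse_grain <- function(x, s) {
  x <- as.numeric(x); s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L) stop("scale s must be an integer >= 1")
  if (s > length(x)) stop("scale s exceeds the signal length")
  if (s == 1L) return(x)
  nb <- length(x) %/% s
  colMeans(matrix(x[seq_len(nb * s)], nrow = s))
}

#' Check the multiscale parameter condition
#'
#' For order `m` and scale `s` applied to a series of length `N`, the
#' coarse-grained length is `floor(N / s)`; the advisory condition
#' `(m + 1)! <= floor(N / s)` keeps the ordinal alphabet well sampled at that
#' scale. Violations are reported as a warning message, never an error, since
#' the profile remains computable (if less reliable) beyond the bound.
#'
#' @param N integer original series length.
#' @param m integer motif order.
#' @param s integer scale factor.
#' @return A list with `ok` (logical) and `message` (`NA` when ok).
#' @export
#' @examples
#' validate_params(1000, 4, 8)  # ok: 125 >= 120
#' validate_params(1000, 4, 9)  # warn: 111 < 120
validate_params <- function(N, m, s) {
  N <- as.integer(N); m <- as.integer(m); s <- as.integer(s)
  stopifnot(N > 0L, m > 0L, s > 0L)
  len <- N %/% s
  need <- factorial(m + 1L)
  if (need <= len) {
    list(ok = TRUE, message = NA_character_)
  } else {
    list(ok = FALSE,
         message = sprintf("scale %d: (m+1)! = %d > floor(N/s) = %d", s, need, len))
  }
}

#' Multiscale permutation Lempel-Ziv complexity profile
#'
#' Computes [plzc()] on the coarse-grained series at every scale factor
#' `s = 1..s_max` (so `values[1]` is the single-scale PLZC of the raw
#' signal). Scales violating the `(m+1)! <= floor(N/s)` condition are still
#' computed; the messages from [validate_params()] are attached to the
#' profile instead of aborting.
#'
#' @param x numeric vector (or a [signal()]; its samples are used).
#' @param cfg an [ordinal_config()].
#' @param s_max integer largest scale factor (default 20).
#' @return An object of class `mplzc_profile`: list with `scales`, `values`,
#'   `cfg`, `source_length` and `warnings` (character, possibly empty).
#' @export
#' @examples
#' p <- mplzc(rnorm(2000), ordinal_config(4), s_max = 5)
#' p$values
mplzc <- function(x, cfg = ordinal_config(), s_max = 20L) {
  if (inherits(x, "signal")) x <- x$samples
  x <- as.numeric(x)
  s_max <- as.integer(s_max)
  stopifnot(inherits(cfg, "ordinal_config"), s_max >= 1L)
  N <- length(x)
  nmin <- (cfg$m - 1L) * cfg$tau + 1L
  if (N < s_max * nmin) {
    stop(sprintf("signal too short for s_max = %d: need at least %d samples",
                 s_max, s_max * nmin))
  }
  msgs <- character(0)
  values <- vapply(seq_len(s_max), function(s) {
    chk <- validate_params(N, cfg$m, s)
    if (!chk$ok) msgs <<- c(msgs, chk$message)
    suppressWarnings(plzc(coarse_grain(x, s), cfg)$normalized)
  }, numeric(1))
  structure(list(scales = seq_len(s_max), values = values, cfg = cfg,
                 source_length = N, warnings = msgs),
            class = "mplzc_profile")
}

#' @export
print.mplzc_profile <- function(x, ...) {
  cat(sprintf("<mplzc_profile> N = %d, m = %d, tau = %d, scales 1..%d\n",
              x$source_length, x$cfg$m, x$cfg$tau, length(x$scales)))
  print(round(x$values, 4))
  if (length(x$warnings)) {
    cat("parameter-condition warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.mplzc_profile <- function(x, ...) {
  data.frame(scale = x$scales, plzc = x$values)
}
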