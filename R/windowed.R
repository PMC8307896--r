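#' Sliding-window index ranges
#'
#' Splits a signal into windows of `window_len_s` seconds with fractional
#' `overlap`; the hop is `round(W * (1 - overlap))` samples, windows start at
#' `0, hop, 2*hop, ...` and the count is `floor((N - W) / hop) + 1`. A
#' trailing partial window is dropped.
#'
#' @param x a [signal()], or a numeric vector together with `fs`.
#' @param window_len_s window length in seconds.
#' @param overlap fraction in `[0, 1)` (0.8 means consecutive windows share
#'   80% of their samples).
#' @param fs sampling rate, taken from `x` when it is a [signal()].
#' @return A data.frame with columns `start` and `end` (1-based sample
#'   indices, inclusive) and `time_s` (window start time in seconds).
#' @export
#' @examples
#' sliding_windows(signal(rnorm(10000), 100), 10, 0.8)  # 46 windows
sliding_windows <- function(x, window_len_s, overlap = 0.8, fs = NULL) {
  if (inherits(x, "signal")) {
    fs <- x$fs
    n <- length(x$samples)
  } else {
    if (is.null(fs)) stop("fs is required when x is a bare vector")
    n <- length(x)
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  W <- as.integer(round(window_len_s * fs))
  if (W < 1L || W > n) stop("window length must be positive and no longer than the signal")
  hop <- as.integer(round(W * (1 - overlap)))
  if (hop < 1L) stop("overlap too large: hop would be zero samples")
  k <- 0:((n - W) %/% hop)
  starts <- k * hop + 1L
  data.frame(start = starts, end = starts + W - 1L, time_s = (starts - 1L) / fs)
}

#' Sliding-window multiscale complexity profile
#'
#' Computes the [mplzc()] profile on every sliding window of a signal,
#' yielding a (window x scale) matrix that tracks how the complexity
#' profile evolves along a nonstationary signal. Parameter-condition
#' messages from the per-window profiles are pooled (deduplicated) in
#' `warnings`.
#'
#' @param x a [signal()].
#' @param cfg an [ordinal_config()].
#' @param s_max largest scale factor.
#' @param window_len_s window length in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return An object of class `windowed_profile`: list with `values`
#'   (matrix, rows = windows, cols = scales), `window_starts` (seconds),
#'   `scales`, `window_len_s`, `overlap`, `cfg`, `warnings`.
#' @export
windowed_mplzc <- function(x, cfg = ordinal_config(), s_max = 10L,
                           window_len_s = 10, overlap = 0.8) {
  stopifnot(inherits(x, "signal"))
  win <- sliding_windows(x, window_len_s, overlap)
  profs <- lapply(seq_len(nrow(win)), function(i) {
    mplzc(x$samples[win$start[i]:win$end[i]], cfg, s_max)
  })
  values <- do.call(rbind, lapply(profs, `[[`, "values"))
  dimnames(values) <- list(NULL, paste0("s", seq_len(s_max)))
  structure(list(values = values, window_starts = win$time_s,
                 scales = seq_len(s_max), window_len_s = window_len_s,
                 overlap = overlap, cfg = cfg,
                 warnings = unique(unlist(lapply(profs, `[[`, "warnings")))),
            class = "windowed_profile")
}

#' @export
print.windowed_profile <- function(x, ...) {
  cat(sprintf("<windowed_profile> %d windows of %g s (overlap %g), scales 1..%d\n",
              nrow(x$values), x$window_len_s, x$overlap, length(x$scales)))
  invisible(x)
}

#' @export
as.data.frame.windowed_profile <- function(x, ...) {
  data.frame(time_s = rep(x$window_starts, times = length(x$scales)),
             scale = rep(x$scales, each = length(x$window_starts)),
             plzc = as.vector(x$values))
}
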