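#' Sampled signal container
#'
#' A `signal` couples a numeric sample vector with its sampling rate in Hz.
#'
#' @param samples numeric vector, non-empty.
#' @param fs sampling rate in Hz, > 0.
#' @return An object of class `signal` with fields `samples` and `fs`.
#' @export
signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  fs <- as.numeric(fs)
  if (length(samples) == 0L) stop("signal must have at least one sample")
  if (length(fs) != 1L || is.na(fs) || fs <= 0) stop("fs must be a positive number")
  structure(list(samples = samples, fs = fs), class = "signal")
}

#' @export
print.signal <- function(x, ...) {
  cat(sprintf("<signal> %d samples at %g Hz (%.4g s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.signal <- function(x) length(x$samples)

#' Seeded white and pink noise
#'
#' White noise is iid Gaussian with zero mean and unit variance (flat power
#' spectrum). Pink (1/f) noise is synthesized in the frequency domain:
#' complex Gaussian spectrum shaped by `|f|^(-alpha/2)` with `alpha = 1`,
#' inverse-transformed and standardized to zero mean and unit variance.
#' Identical `(kind, n, seed)` reproduce the samples bit-exactly.
#'
#' @param kind `"white"` or `"pink"`.
#' @param n number of samples, >= 2.
#' @param seed integer RNG seed (`NULL` uses the current RNG stream).
#' @param fs sampling rate recorded on the result (default 100 Hz).
#' @return A [signal()].
#' @export
#' @examples
#' gen_noise("white", 1000, seed = 1)
gen_noise <- function(kind = c("white", "pink"), n, seed = NULL, fs = 100) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  x <- with_seed(seed, {
    if (kind == "white") {
      rnorm(n)
    } else {
      # one-sided spectral shaping, hermitian-symmetrized for a real series
      nf <- n %/% 2L
      f <- seq_len(nf)
      amp <- 1 / sqrt(f)
      half <- amp * complex(real = rnorm(nf), imaginary = rnorm(nf))
      spec <- complex(length.out = n)
      spec[2:(nf + 1L)] <- half
      if (n %% 2L == 0L) spec[nf + 1L] <- complex(real = Re(half[nf]))
      spec[n:(n - nf + 2L)] <- Conj(spec[2:nf])
      y <- Re(fft(spec, inverse = TRUE)) / n
      (y - mean(y)) / sd(y)
    }
  })
  signal(x, fs)
}

# Phase of a logarithmic chirp running f0 -> f1 Hz over `duration` seconds:
# instantaneous frequency f(t) = f0 * (f1/f0)^(t/T).
log_chirp_phase <- function(t, f0, f1, duration) {
  k <- (f1 / f0)^(1 / duration)
  2 * pi * f0 * (k^t - 1) / log(k)
}

#' Logarithmic chirp signal
#'
#' Sine with instantaneous frequency sweeping logarithmically from `f0` to
#' `f1` Hz over the signal duration; optionally amplitude-modulated by a
#' slow, strictly positive chirp envelope (`1 + 0.5 * sin` of a 0.05 to
#' 0.5 Hz logarithmic chirp).
#'
#' @param f0,f1 start and end frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param duration length in seconds.
#' @param am logical; apply the chirp amplitude modulation.
#' @return A [signal()].
#' @export
gen_chirp <- function(f0 = 0.1, f1 = 20, fs = 100, duration = 100, am = FALSE) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- sin(log_chirp_phase(t, f0, f1, duration))
  if (am) x <- (1 + 0.5 * sin(log_chirp_phase(t, 0.05, 0.5, duration))) * x
  signal(x, fs)
}

#' MIX process: seeded mixture of a sinusoid and uniform noise
#'
#' Per sample `k`, with probability `p` emit uniform noise on
#' `[-sqrt(3), sqrt(3)]`, otherwise the unit-variance sinusoid
#' `sqrt(2) * sin(2 * pi * k / 12)` (period 12 samples). `p = 0` is purely
#' periodic; `p = 1` is iid uniform.
#'
#' @param p mixing probability in `[0, 1]`.
#' @param n number of samples.
#' @param seed integer RNG seed.
#' @param fs sampling rate recorded on the result.
#' @return A [signal()].
#' @export
gen_mix <- function(p, n, seed = NULL, fs = 100) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  k <- seq_len(n)
  x <- sqrt(2) * sin(2 * pi * k / 12)
  samples <- with_seed(seed, {
    z <- runif(n) < p
    y <- runif(n, -sqrt(3), sqrt(3))
    ifelse(z, y, x)
  })
  signal(samples, fs)
}

standardize <- function(x) {
  s <- sd(x)
  if (s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Benchmark suite of synthetic signals
#'
#' Generates the six-family battery used to probe how the complexity
#' profile responds to frequency, amplitude modulation, noise power,
#' bandwidth, spectral colour and periodicity. All signals are
#' `fs * duration` samples long:
#'
#' * `chirp` — constant-amplitude sine, frequency sweeping logarithmically
#'   0.1 to 20 Hz.
#' * `amchirp` — logarithmic chirp 0.25 to 5 Hz with chirp amplitude
#'   modulation.
#' * `quasi` — quasi-periodic sum of 0.5 Hz and 1 Hz sinusoids; clean for
#'   the first 20 s, then additive white noise whose standard deviation
#'   steps up every 10 s through 0.25, 0.5, 1, 2, 4, 8, 16, 32.
#' * `banded` — five equal-length segments of Gaussian noise band-limited
#'   around `fs/4`, bandwidth stepping linearly from `fs/15` to `fs/3`.
#' * `ar1` — AR(1) process whose coefficient runs linearly from +0.9
#'   (low-pass) to -0.9 (high-pass), re-standardized per 10-s window.
#' * `mix` — MIX process whose mixing probability runs linearly from 0.99
#'   down to 0.01 along the signal, evolving from randomness to periodic
#'   oscillation, so per-window complexity decreases along the signal.
#'
#' @param fs sampling rate in Hz (default 100).
#' @param duration length in seconds (default 100).
#' @param seed integer RNG seed; deterministic families ignore it.
#' @return Named list of six [signal()] objects:
#'   `chirp`, `amchirp`, `quasi`, `banded`, `ar1`, `mix`.
#' @export
gen_benchmark_suite <- function(fs = 100, duration = 100, seed = NULL) {
  n <- as.integer(round(fs * duration))
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  out <- list()

  out$chirp <- gen_chirp(0.1, 20, fs, duration, am = FALSE)
  out$amchirp <- gen_chirp(0.25, 5, fs, duration, am = TRUE)

  out$quasi <- with_seed(seed, {
    base <- sin(2 * pi * 0.5 * t) + sin(2 * pi * 1 * t)
    seg_sd <- c(0, 0, 0.25, 0.5, 1, 2, 4, 8, 16, 32)  # ten 10-s segments
    seg <- pmin(floor(t / 10) + 1, length(seg_sd))
    signal(base + rnorm(n, sd = seg_sd[seg]), fs)
  })

  out$banded <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    nseg <- 5L
    seg_len <- n %/% nseg
    bw <- seq(fs / 15, fs / 3, length.out = nseg)
    centre <- fs / 4
    segs <- lapply(seq_len(nseg), function(i) {
      len <- if (i < nseg) seg_len else n - seg_len * (nseg - 1L)
      w <- rnorm(len)
      fr <- seq(0, fs, length.out = len + 1L)[seq_len(len)]
      fr <- pmin(fr, fs - fr)  # two-sided frequency axis
      keep <- fr >= centre - bw[i] / 2 & fr <= centre + bw[i] / 2
      y <- Re(fft(fft(w) * keep, inverse = TRUE)) / len
      standardize(y)
    })
    signal(unlist(segs), fs)
  })

  out$ar1 <- with_seed(if (is.null(seed)) NULL else seed + 2L, {
    a <- seq(0.9, -0.9, length.out = n)
    x <- numeric(n)
    e <- rnorm(n)
    x[1] <- e[1]
    for (k in 2:n) x[k] <- a[k] * x[k - 1] + e[k]
    win <- as.integer(10 * fs)
    for (w0 in seq(1L, n, by = win)) {
      idx <- w0:min(n, w0 + win - 1L)
      x[idx] <- standardize(x[idx])
    }
    signal(x, fs)
  })

  out$mix <- with_seed(if (is.null(seed)) NULL else seed + 3L, {
    p <- seq(0.99, 0.01, length.out = n)
    k <- seq_len(n)
    per <- sqrt(2) * sin(2 * pi * k / 12)
    z <- runif(n) < p
    y <- runif(n, -sqrt(3), sqrt(3))
    signal(ifelse(z, y, per), fs)
  })

  out
}
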