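# Synthetic two-channel records in the Bern-Barcelona file layout (two
# comma-separated columns, one sample per row). These are stand-ins built
# from the package's own generators, labelled synthetic throughout; they are
# NOT the database records. "Focal-like" channels are strongly autocorrelated
# (more regular), "non-focal-like" channels are white.
make_synthetic_record_dir <- function(dir, pairs_per_group = 4L,
                                      n = 10240L, fs = 512, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ar1 <- function(a, innov) {
    x <- numeric(length(innov))
    x[1] <- innov[1]
    for (k in 2:length(innov)) x[k] <- a * x[k - 1] + innov[k]
    x
  }
  k <- 0L
  for (grp in c("F", "N")) {
    for (p in seq_len(pairs_per_group)) {
      k <- k + 1L
      set.seed(seed * 1000L + k)
      if (grp == "F") {
        ch1 <- ar1(0.95, rnorm(n))
        ch2 <- ar1(0.95, rnorm(n))
      } else {
        ch1 <- rnorm(n)
        ch2 <- rnorm(n)
      }
      rec <- list(channel1 = mplzc::signal(ch1, fs),
                  channel2 = mplzc::signal(ch2, fs))
      mplzc::write_record(rec, file.path(dir, sprintf("%s%03dsynthetic.txt", grp, p)))
    }
  }
  invisible(dir)
}
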