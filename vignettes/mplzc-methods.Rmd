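---
title: "Methods: multiscale permutation Lempel-Ziv complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale permutation Lempel-Ziv complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mplzc)
```

## The measurement chain

`mplzc` quantifies the rate at which new patterns appear in a univariate
series. Three layers stack on top of each other:

1. **Symbolization.** The raw series is reduced to a stream over a finite
   alphabet. The binary route thresholds at the mean (or median) of the
   vector passed in; the ordinal route replaces each delay-embedded window
   of `m` samples with the permutation that sorts it ascending, one of `m!`
   motifs. Ordinal coding sees only the ranks, so the measure inherits
   invariance under any strictly increasing transform of the data — a
   property the binary route only has for affine maps.

2. **Exhaustive-history parsing.** The Lempel-Ziv (1976) production count
   `c(n)`: scanning left to right, a candidate block grows while it already
   occurs in the prefix ending one symbol short of the block's end, and a
   component closes when the block is novel. `c(n)` is the number of
   components. The counter starts at 1 for the first symbol, and a trailing
   block that is still reproducible when the sequence ends contributes one
   final component (the Kaspar-Schuster convention); both choices are fixed
   here because the parsing rule alone does not pin down initialization or
   termination, and they match the standard worked parsings
   (`0001101001000101` → `0|001|10|100|1000|101`, c = 6).

3. **Normalization.** `C(n) = c(n) log2(n)/n` for binary streams,
   `PLZC = c(n) log_{m!}(n)/n` for ordinal streams with `n` the *symbol*
   count `N − (m−1)τ`. For an iid uniform stream over alphabet `A` the
   count approaches `n / log_A(n)`, so the normalized value tends to 1;
   values above 1 at small `n` are returned as computed, not clipped.

The multiscale profile applies the ordinal measure to coarse-grained
versions of the series — non-overlapping block means of length
`s = 1..s_max` — so slow structure that is invisible at the sampling scale
shows up at higher `s`. Remainder samples beyond `s⌊N/s⌋` are dropped,
matching the floor bound in the block-mean definition.

### What PLZC of noise converges to

A point worth stating explicitly because it is easy to get wrong: the
ordinal stream of iid noise is *not* iid over the `m!` motifs. Consecutive
windows share `m − 1` samples, and given a window's pattern the next sample
can only fall in `m` distinct rank positions, so the stream's entropy rate
is `log(m)` per symbol, a fraction `log(m)/log(m!)` of the maximum
(`≈ 0.436` for `m = 4`). White noise therefore plateaus near 0.5 at
`N = 10,000` (approaching 0.436 from above as `N` grows), not near 1. The
value 1 *is* reached by streams that are genuinely iid over their alphabet,
e.g. coin flips fed directly to the binary normalization — both behaviours
are pinned by tests. This is also why the EEG feature values live in the
0.3–0.55 range rather than near 1.

## Parameters

* **`m` (motif order, default 4, admissible 3–7).** Below 3 there are too
  few patterns to discriminate; above 7 the `m!` alphabet is computationally
  heavy and needs very long series. `m = 4` is appropriate from roughly
  `N ≥ 1000`, `m = 5` from `N ≥ 2000`, following the `m! ≤ n` rule of thumb.
* **`tau` (delay, default 1, samples).** Held at 1 at every scale;
  coarse-graining already performs the slow-time-scale exploration, and
  per-scale delay optimization is deliberately out of scope.
* **`s_max` (default 20).** At each scale the advisory condition
  `(m+1)! ≤ ⌊N/s⌋` is checked; violations are attached to the profile as
  warnings rather than errors, because the profile remains computable and
  group comparisons at such scales can still be informative (the m = 5,
  N = 10,240, s = 20 configuration violates the bound yet is a standard
  analysis point; we compute it and warn).
* **Windows (10 s, 80 % overlap).** The sliding-window profiler uses
  `hop = round(W(1 − overlap))` samples and drops a trailing partial
  window; at fs = 100 Hz and N = 100 s this gives 46 windows of 1000
  samples, enough for `m = 4` per the rule above.

## The synthetic benchmark battery

The generators emulate the signal-processing concepts the profile should
respond to, all at fs = 100 Hz, 100 s, seeded and bit-reproducible:

* white Gaussian noise and 1/f (pink) noise — pink is synthesized by
  spectral shaping (`|f|^{-1/2}` amplitudes on complex Gaussian spectra),
  standardized to zero mean, unit variance; the periodogram slope over
  1–40 Hz fits at −1.
* a constant-amplitude logarithmic chirp, 0.1→20 Hz (closed-form phase, so
  the endpoint frequencies are exact), and an amplitude-modulated chirp,
  0.25→5 Hz, whose envelope is `1 + 0.5·sin` of a slow 0.05→0.5 Hz chirp —
  strictly positive and slow, so ordinal patterns are essentially
  unchanged; this is what makes the measure's amplitude-insensitivity
  testable.
* a quasi-periodic sum of 0.5 and 1 Hz sinusoids, clean for 20 s, then
  white noise whose standard deviation steps through
  0.25, 0.5, 1, 2, 4, 8, 16, 32 every 10 s. The ladder is geometric so
  that the single-scale value saturates while higher scales keep
  discriminating.
* five equal segments of band-limited Gaussian noise centred at fs/4 with
  bandwidth stepping linearly from fs/15 to fs/3 (frequency-domain masking;
  no particular filter shape is canonical here).
* an AR(1) process whose coefficient runs linearly from +0.9 to −0.9,
  re-standardized per 10-s window so amplitude drift does not confound the
  windowed profile.
* a MIX sweep: per sample, a Bernoulli switch between the unit-variance
  sinusoid `√2·sin(2πk/12)` and uniform noise on `[−√3, √3]`, with the
  mixing probability running 0.99→0.01 along the signal (randomness →
  periodicity).

What these fixtures do **not** emulate: measurement artifacts, line noise,
nonstationary variance unrelated to the designed steps, volume conduction,
or any physiological structure. Passing the battery shows the measure
responds correctly to frequency, noise power, bandwidth, spectral colour
and periodicity — it does not certify performance on real EEG.

### The AR(1) sweep and spectral width

Measured single-scale PLZC (m = 4) over fixed coefficients:
`+0.9 → 0.54`, `0 → 0.57`, `−0.9 → 0.42`. Complexity peaks where the
spectrum is widest (white, middle of the sweep) and falls at *both*
narrowband ends; the anti-persistent end is lowest because its ordinal
stream is a near-deterministic alternation. Both halves of the sweep
traverse the same `|a|` range, so the meaningful contrast — and the one the
tests assert — is wide-spectrum windows (`|a| < 0.3`) against narrowband
windows (`|a| > 0.6`), not first half against second half.

## The EEG pipeline

Records are two comma-separated channel columns, 10,240 samples at 512 Hz;
the group is inferred from the `F`/`N` file-name prefix. Both channels of a
pair are treated as independent signals (this is how 50 pairs become 100
signals per group), and channel pairing is *not* respected in the
cross-validation folds — no grouping rule is defined for these records, and
this is a known caveat: siblings of a training channel can appear in the
test fold, which can flatter accuracy slightly.

Per scale, groups are compared with the two-sided Mann-Whitney rank test:
the exact null when both groups have ≤ 8 observations, the normal
approximation with tie correction otherwise, significance at p < 0.05.
Classification is a soft-margin support-vector classifier with an RBF
kernel under seeded stratified 10-fold cross-validation; features are
standardized per column inside each training fit (RBF kernels need
comparable scales), and `cost = 1`, `gamma = 1/n_features` defaults are
used with flags exposed — reported accuracies should be read with the
tolerance that heuristic hyperparameters imply, not as bit-exact targets.
Sensitivity, specificity and accuracy are computed from confusion counts
pooled over the held-out folds.

The packaged tests exercise this pipeline end-to-end on synthetic records
written in the same file format (strongly autocorrelated "focal-like" AR(1)
channels vs white "non-focal-like" channels); they verify the mechanics and
the directional result (the regular group scores lower at every scale), not
the published clinical numbers, which require the original database.

## Numerical and degenerate-input choices

* Threshold ties binarize to 0 (strict `>`); ordinal ties break by temporal
  index (stable sort) — both deterministic, the ordinal rule being standard
  practice for rank-based symbolization.
* Ordinal patterns map to symbols by lexicographic Lehmer rank (identity
  → 0). Any bijection yields the same `c(n)`; fixing one makes symbol
  streams reproducible across runs and platforms.
* Constant (or monotone) signals are legal inputs: one motif, `c = 2`,
  PLZC ≈ `2 log_{m!}(n)/n` — near zero, as it should be.
* All generators draw from R's RNG under an isolated seed (the caller's
  RNG state is saved and restored), so `seed` arguments are reproducible
  without side effects.

## Problem sizes used by the test suite

Stochastic properties are checked at the sizes the measures are designed
for: 50 seeds × N = 10,000 for the noise-profile behaviour, 20 seeds for
the windowed trends, 500 random sequences (alphabets 2, 6, 24, n ≤ 300)
plus all 8,190 binary strings of length ≤ 12 for parser/oracle equivalence,
and 6 + 6 synthetic record pairs of 10,240 samples for the pipeline run.

## Known limitations

* Single-channel only; no montage handling, artifact rejection or
  re-filtering (database records arrive band-pass filtered).
* The coarse-graining is the plain block-mean; overlapping or composite
  variants and per-scale delay selection are out of scope.
* SVM hyperparameters are heuristic defaults, not tuned; accuracy on real
  data will move a few points with tuning.
* PLZC values depend on `m` and `N` through the finite-size normalization;
  compare values only at matched `(m, τ, N, s)`.
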