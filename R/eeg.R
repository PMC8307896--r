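#' Read a two-channel EEG record
#'
#' Parses an ASCII record in the Bern-Barcelona layout: two comma-separated
#' numeric columns, one sample per row (10,240 samples at 512 Hz by
#' default). The group label is inferred from the first letter of the file
#' name: `F` = focal, `N` = non-focal.
#'
#' @param path path to the record file.
#' @param fs sampling rate in Hz (default 512).
#' @param expected_length required number of samples per channel
#'   (default 10240); `NULL` disables the length check.
#' @return An object of class `eeg_record`: list with `channel1`, `channel2`
#'   ([signal()]s), `group` (factor level `"focal"` or `"non-focal"`, `NA`
#'   when the file name matches neither convention) and `pair_id` (integer
#'   parsed from the digits of the file name, `NA` if absent).
#' @export
read_record <- function(path, fs = 512, expected_length = 10240L) {
  if (!file.exists(path)) stop(sprintf("record file not found: %s", path))
  dat <- tryCatch(
    read.csv(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop(sprintf("cannot parse record %s: %s", path, conditionMessage(e)))
  )
  if (ncol(dat) != 2L) {
    stop(sprintf("record %s has %d columns; expected 2", path, ncol(dat)))
  }
  if (!is.null(expected_length) && nrow(dat) != expected_length) {
    stop(sprintf("record %s has %d samples; expected %d", path, nrow(dat),
                 expected_length))
  }
  base <- basename(path)
  lead <- toupper(substr(base, 1L, 1L))
  group <- if (lead == "F") "focal" else if (lead == "N") "non-focal" else NA_character_
  digits <- regmatches(base, regexpr("[0-9]+", base))
  pair_id <- if (length(digits)) as.integer(digits) else NA_integer_
  structure(list(channel1 = signal(dat[[1]], fs),
                 channel2 = signal(dat[[2]], fs),
                 group = group, pair_id = pair_id, path = path),
            class = "eeg_record")
}

#' @rdname read_record
#' @param record an `eeg_record` (or list with `channel1`/`channel2`
#'   [signal()]s) to serialize.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record$channel1, "signal"), inherits(record$channel2, "signal"))
  write.table(data.frame(record$channel1$samples, record$channel2$samples),
              path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> pair %s, group %s, 2 channels x %d samples at %g Hz\n",
              ifelse(is.na(x$pair_id), "?", x$pair_id),
              ifelse(is.na(x$group), "?", x$group),
              length(x$channel1$samples), x$channel1$fs))
  invisible(x)
}

#' Multiscale complexity feature matrix from EEG records
#'
#' Treats the two channels of every record as independent signals and
#' computes one [mplzc()] profile per channel, giving a feature matrix with
#' one row per signal and one column per scale factor, plus a group label
#' per row.
#'
#' @param records list of `eeg_record` objects (see [read_record()]).
#' @param cfg an [ordinal_config()].
#' @param s_max number of scale factors (default 20, i.e. 20 features).
#' @return An object of class `feature_matrix`: list with `features`
#'   (numeric matrix, columns `s1..s<s_max>`), `labels` (factor) and `cfg`.
#' @export
build_features <- function(records, cfg = ordinal_config(), s_max = 20L) {
  if (length(records) == 0L) stop("no records supplied")
  rows <- lapply(records, function(r) {
    rbind(mplzc(r$channel1$samples, cfg, s_max)$values,
          mplzc(r$channel2$samples, cfg, s_max)$values)
  })
  features <- do.call(rbind, rows)
  colnames(features) <- paste0("s", seq_len(s_max))
  labels <- factor(rep(vapply(records, `[[`, character(1), "group"), each = 2L))
  rownames(features) <- paste0(rep(vapply(records, function(r) {
    sprintf("%s%03d", ifelse(identical(r$group, "focal"), "F", "N"),
            ifelse(is.na(r$pair_id), 0L, r$pair_id))
  }, character(1)), each = 2L), c("_ch1", "_ch2"))
  structure(list(features = features, labels = labels, cfg = cfg),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d signals x %d scales (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Per-scale group comparison by Mann-Whitney rank test
#'
#' For every scale column, reports the mean and standard deviation per group
#' and the two-sided Mann-Whitney (Wilcoxon rank-sum) p-value: the exact
#' null distribution when both groups have at most 8 observations, the
#' normal approximation with tie correction otherwise. Differences are
#' flagged significant at p < 0.05.
#'
#' @param fm a `feature_matrix` from [build_features()], or a plain numeric
#'   matrix together with `labels`.
#' @param labels two-level factor, required when `fm` is a bare matrix.
#' @return A data.frame with one row per scale: per-group `mean_*`/`sd_*`
#'   columns, `p_value` and `significant`.
#' @export
compare_groups <- function(fm, labels = NULL) {
  if (inherits(fm, "feature_matrix")) {
    features <- fm$features; labels <- fm$labels
  } else {
    features <- as.matrix(fm); labels <- factor(labels)
  }
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) stop("compare_groups needs exactly two groups")
  g1 <- levels(labels)[1]; g2 <- levels(labels)[2]
  a <- features[labels == g1, , drop = FALSE]
  b <- features[labels == g2, , drop = FALSE]
  exact <- nrow(a) <= 8L && nrow(b) <= 8L
  p <- vapply(seq_len(ncol(features)), function(j) {
    suppressWarnings(wilcox.test(a[, j], b[, j], exact = exact,
                                 correct = !exact)$p.value)
  }, numeric(1))
  out <- data.frame(scale = seq_len(ncol(features)),
                    mean_1 = colMeans(a), sd_1 = apply(a, 2, sd),
                    mean_2 = colMeans(b), sd_2 = apply(b, 2, sd),
                    p_value = p, significant = p < 0.05)
  names(out)[2:5] <- c(paste0(c("mean_", "sd_"), make.names(g1)),
                       paste0(c("mean_", "sd_"), make.names(g2)))
  rownames(out) <- NULL
  out
}

#' Classification performance from confusion counts
#'
#' Sensitivity, specificity and accuracy (in percent) from the four
#' confusion counts:
#' `SEN = TP/(TP+FN) * 100`, `SPF = TN/(TN+FP) * 100`,
#' `ACC = (TP+TN)/(TP+TN+FP+FN) * 100`.
#'
#' @param TP,TN,FP,FN non-negative integer confusion counts.
#' @param folds number of cross-validation folds the counts were pooled
#'   over (bookkeeping only).
#' @return An object of class `classification_report`.
#' @export
#' @examples
#' classification_report(85, 84, 16, 15)  # SEN 85, SPF 84, ACC 84.5
classification_report <- function(TP, TN, FP, FN, folds = NA_integer_) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 SEN = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
                 SPF = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_,
                 ACC = 100 * (TP + TN) / (TP + TN + FP + FN),
                 folds = as.integer(folds)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> TP %d FN %d TN %d FP %d (%s folds)\n",
              x$TP, x$FN, x$TN, x$FP, ifelse(is.na(x$folds), "?", x$folds)))
  cat(sprintf("  SEN %.2f%%  SPF %.2f%%  ACC %.2f%%\n", x$SEN, x$SPF, x$ACC))
  invisible(x)
}

# Seeded stratified fold assignment: every sample held out exactly once,
# per-fold class ratio within one sample.
stratified_folds <- function(labels, folds, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

#' Cross-validated RBF support-vector classification
#'
#' Classifies the rows of a feature matrix with a soft-margin support-vector
#' classifier (C-SVC, radial-basis kernel, per-column standardization inside
#' each training fit) under seeded stratified k-fold cross-validation.
#' Confusion counts are pooled over the held-out folds; `"focal"` (or, when
#' absent, the first factor level) is the positive class.
#'
#' @param fm a `feature_matrix`, or a plain numeric matrix with `labels`.
#' @param labels two-level factor, required when `fm` is a bare matrix.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed driving the fold assignment.
#' @param cost,gamma C-SVC hyperparameters; `gamma = NULL` uses the
#'   `1/ncol` heuristic.
#' @return A [classification_report()] with an extra `fold_assignment`
#'   attribute recording which fold held out each sample.
#' @export
classify <- function(fm, labels = NULL, folds = 10L, seed = NULL,
                     cost = 1, gamma = NULL) {
  if (inherits(fm, "feature_matrix")) {
    features <- fm$features; labels <- fm$labels
  } else {
    features <- as.matrix(fm); labels <- factor(labels)
  }
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) stop("classify needs exactly two classes")
  if (any(table(labels) < folds)) {
    stop(sprintf("need at least %d samples per class for %d-fold CV", folds, folds))
  }
  positive <- if ("focal" %in% levels(labels)) "focal" else levels(labels)[1]
  fold <- stratified_folds(labels, folds, seed)
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  pred <- factor(rep(levels(labels)[1], length(labels)), levels = levels(labels))
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (nlevels(droplevels(labels[tr])) < 2L) {
      stop("degenerate fold: a training split contains a single class")
    }
    fit <- e1071::svm(features[tr, , drop = FALSE], labels[tr],
                      type = "C-classification", kernel = "radial",
                      cost = cost, gamma = gamma, scale = TRUE)
    pred[!tr] <- predict(fit, features[!tr, , drop = FALSE])
  }
  tp <- sum(pred == positive & labels == positive)
  tn <- sum(pred != positive & labels != positive)
  fp <- sum(pred == positive & labels != positive)
  fn <- sum(pred != positive & labels == positive)
  rep <- classification_report(tp, tn, fp, fn, folds = folds)
  attr(rep, "fold_assignment") <- fold
  rep
}
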