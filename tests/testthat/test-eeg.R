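test_that("record I/O round-trips bit-exactly and infers the group", {
  dir <- withr::local_tempdir()
  set.seed(30)
  rec <- list(channel1 = signal(rnorm(512), 512), channel2 = signal(rnorm(512), 512))
  path <- file.path(dir, "F007.txt")
  write_record(rec, path)
  back <- read_record(path, expected_length = 512)
  expect_equal(back$channel1$samples, rec$channel1$samples)
  expect_equal(back$channel2$samples, rec$channel2$samples)
  expect_equal(back$group, "focal")
  expect_equal(back$pair_id, 7L)
  expect_equal(back$channel1$fs, 512)

  write_record(rec, file.path(dir, "N012.txt"))
  expect_equal(read_record(file.path(dir, "N012.txt"), expected_length = 512)$group,
               "non-focal")
})

test_that("malformed records raise format errors naming the file", {
  dir <- withr::local_tempdir()
  short <- file.path(dir, "F001.txt")
  writeLines(rep("0.1,0.2", 10), short)
  expect_error(read_record(short), "10 samples.*expected 10240")
  wide <- file.path(dir, "F002.txt")
  writeLines(rep("1,2,3", 20), wide)
  expect_error(read_record(wide, expected_length = 20), "3 columns")
  expect_error(read_record(file.path(dir, "missing.txt")), "not found")
})

test_that("build_features yields one row per channel with scale columns", {
  dir <- withr::local_tempdir()
  make_synthetic_record_dir(dir, pairs_per_group = 2, n = 1024, fs = 512, seed = 2)
  files <- list.files(dir, full.names = TRUE)
  records <- lapply(files, read_record, expected_length = 1024)
  cfg <- ordinal_config(4)
  fm <- build_features(records, cfg, s_max = 5)
  expect_equal(dim(fm$features), c(8, 5))
  expect_equal(as.vector(table(fm$labels)), c(4, 4))
  expect_equal(colnames(fm$features), paste0("s", 1:5))
  # column 1 is the raw single-scale value of the corresponding channel
  expect_equal(unname(fm$features[1, 1]),
               plzc(records[[1]]$channel1$samples, cfg)$normalized)
  expect_equal(unname(fm$features[2, 1]),
               plzc(records[[1]]$channel2$samples, cfg)$normalized)
  expect_error(build_features(list()), "no records")
})

test_that("compare_groups reproduces the exact rank-test worked example", {
  # two groups of three, complete separation: U = 0, exact p = 2/20
  fm <- rbind(matrix(c(1, 2, 3), 3, 2), matrix(c(4, 5, 6), 3, 2))
  out <- compare_groups(fm, labels = rep(c("a", "b"), each = 3))
  expect_equal(out$p_value, rep(0.1, 2))
  expect_false(any(out$significant))
  expect_equal(out$mean_a, rep(2, 2))
  expect_equal(out$mean_b, rep(5, 2))
})

test_that("compare_groups matches the enumeration oracle for small groups", {
  set.seed(31)
  for (i in 1:15) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- matrix(rnorm(n1), ncol = 1)
    b <- matrix(rnorm(n2), ncol = 1)
    out <- compare_groups(rbind(a, b), labels = rep(c("x", "y"), c(n1, n2)))
    expect_equal(out$p_value, mw_exact_oracle(a[, 1], b[, 1]), tolerance = 1e-10)
  }
})

test_that("compare_groups separates well-separated groups and not identical ones", {
  set.seed(32)
  a <- matrix(rnorm(50 * 4, mean = 0), 50)
  b <- matrix(rnorm(50 * 4, mean = 3), 50)
  out <- compare_groups(rbind(a, b), labels = rep(c("g1", "g2"), each = 50))
  expect_true(all(out$p_value < 0.05))
  expect_true(all(out$significant))

  same <- compare_groups(rbind(a, a), labels = rep(c("g1", "g2"), each = 50))
  expect_true(all(same$p_value > 0.9))
  expect_error(compare_groups(a, labels = rep("g1", 50)), "two groups")
})

test_that("classification_report identities hold for all small confusion counts", {
  r <- classification_report(85, 84, 16, 15)
  expect_equal(r$SEN, 85)
  expect_equal(r$SPF, 84)
  expect_equal(r$ACC, 84.5)
  for (tp in 0:5) for (tn in 0:5) for (fp in 0:5) for (fn in 0:5) {
    if (tp + tn + fp + fn == 0) next
    r <- classification_report(tp, tn, fp, fn)
    expect_equal(r$ACC, 100 * (tp + tn) / (tp + tn + fp + fn))
    if (tp + fn > 0) expect_equal(r$SEN, 100 * tp / (tp + fn))
    if (tn + fp > 0) expect_equal(r$SPF, 100 * tn / (tn + fp))
    expect_true(r$ACC >= 0 && r$ACC <= 100)
  }
  expect_error(classification_report(-1, 1, 1, 1), "non-negative")
})

test_that("stratified folds hold every sample out once with balanced classes", {
  labels <- factor(rep(c("focal", "non-focal"), each = 30))
  fold <- mplzc:::stratified_folds(labels, 10, seed = 5)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(as.vector(table(fold)), rep(6, 10))
  for (k in 1:10) {
    tab <- table(labels[fold == k])
    expect_lte(abs(tab[1] - tab[2]), 1)
  }
  # seeded: reproducible
  expect_identical(fold, mplzc:::stratified_folds(labels, 10, seed = 5))
})

test_that("classify is perfect on separable features and guards degeneracy", {
  set.seed(33)
  feats <- rbind(matrix(rnorm(100 * 5, mean = 5, sd = 0.1), 100),
                 matrix(rnorm(100 * 5, mean = -5, sd = 0.1), 100))
  labels <- factor(rep(c("focal", "non-focal"), each = 100))
  rep <- classify(feats, labels, folds = 10, seed = 1)
  expect_equal(rep$ACC, 100)
  expect_equal(rep$SEN, 100)
  expect_equal(rep$SPF, 100)
  expect_equal(rep$TP + rep$TN + rep$FP + rep$FN, 200)
  expect_error(classify(feats, labels, folds = 101), "at least")
})
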