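mk_ref <- function(pos, strand = "+", end_type = "TSS_5p") {
  tibble::tibble(chrom = "chr1", pos = as.integer(pos), strand = strand,
                 end_type = end_type)
}

mk_peakset <- function(pos, strand = "+", end_type = "TSS_5p") {
  tibble::tibble(peak_id = paste0("p", seq_along(pos)), chrom = "chr1",
                 strand = strand, dominant_pos = as.integer(pos),
                 end_type = end_type)
}

test_that("peaks are labeled TRUE within tolerance of same-strand references", {
  lab <- label_peaks(mk_peakset(1000), mk_ref(1005), tolerance = 50)
  expect_true(lab$label)
  expect_equal(lab$nearest_ref_dist, 5)
  far <- label_peaks(mk_peakset(1000), mk_ref(2000), tolerance = 50)
  expect_false(far$label)
  other_strand <- label_peaks(mk_peakset(1000),
                              mk_ref(1005, strand = "-"), tolerance = 50)
  expect_false(other_strand$label)
})

test_that("labels equal an all-pairs distance oracle and are monotone in tolerance", {
  set.seed(51)
  for (i in 1:20) {
    peaks <- mk_peakset(sample(1:2000, 40),
                        strand = sample(c("+", "-"), 40, replace = TRUE))
    refs <- mk_ref(sample(1:2000, 15),
                   strand = sample(c("+", "-"), 15, replace = TRUE))
    tol <- sample(c(10, 50, 200), 1)
    lab <- label_peaks(peaks, refs, tol)
    oracle <- vapply(seq_len(nrow(peaks)), function(j) {
      d <- abs(refs$pos[refs$strand == peaks$strand[j]] - peaks$dominant_pos[j])
      length(d) > 0 && min(d) <= tol
    }, logical(1))
    expect_equal(lab$label, oracle)
    wider <- label_peaks(peaks, refs, tol * 2)
    expect_true(all(wider$label[lab$label]))
  }
})

test_that("accuracy equals its confusion-matrix definition", {
  expect_equal(classifier_metrics(c(TRUE, FALSE), c(TRUE, FALSE))$acc, 1)
  m <- classifier_metrics(
    truth = c(rep(TRUE, 4), rep(FALSE, 6)),
    predicted = c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 5))
  )
  expect_equal(unlist(m[, c("TP", "TN", "FP", "FN")]),
               c(TP = 3L, TN = 5L, FP = 1L, FN = 1L))
  expect_equal(m$acc, 0.8)
  expect_equal(classifier_metrics(c(TRUE, FALSE), c(FALSE, TRUE))$acc, 0)
  set.seed(52)
  for (i in 1:20) {
    truth <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    pred <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    m <- classifier_metrics(truth, pred)
    expect_equal(m$acc, (m$TP + m$TN) / 30)
    expect_equal(m$acc, mean(truth == pred))
  }
})

test_that("the protocol encodes a stratified 70/30 split with 5-fold CV", {
  p <- training_protocol()
  expect_equal(p$train_fraction, 0.7)
  expect_equal(p$cv_folds, 5L)
  expect_setequal(p$algorithms, c("LR", "RF", "SVM", "KNN"))
})

test_that("linearly separable data yield perfect logistic-regression accuracy", {
  set.seed(53)
  n <- 80L
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- tibble::tibble(
    peak_id = paste0("p", 1:n),
    f1 = ifelse(lab, 1, 0) + stats::rnorm(n, 0, 0.01),
    f2 = stats::runif(n)
  )
  feats <- fake_features(x, c("distribution", "distribution"))
  m <- train_end_classifiers(feats, lab,
                             training_protocol(algorithms = "LR", seed = 1))
  expect_equal(m$LR$metrics$acc, 1)
})

test_that("single-class training data are refused", {
  x <- tibble::tibble(peak_id = paste0("p", 1:10), f1 = stats::runif(10))
  feats <- fake_features(x, "distribution")
  expect_error(train_end_classifiers(feats, rep(TRUE, 10)), "single class")
})

test_that("training is deterministic given the seed", {
  set.seed(54)
  n <- 60L
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- tibble::tibble(peak_id = paste0("p", 1:n),
                      f1 = ifelse(lab, 0.8, 0.2) + stats::rnorm(n, 0, 0.3),
                      f2 = stats::rnorm(n), f3 = stats::rnorm(n))
  feats <- fake_features(x, rep("distribution", 3))
  proto <- training_protocol(algorithms = c("RF", "KNN"), seed = 99)
  m1 <- train_end_classifiers(feats, lab, proto)
  m2 <- train_end_classifiers(feats, lab, proto)
  expect_identical(m1$RF$hyperparameters, m2$RF$hyperparameters)
  expect_identical(m1$KNN$hyperparameters, m2$KNN$hyperparameters)
  expect_identical(predict(m1$RF, feats), predict(m2$RF, feats))
  expect_identical(m1$RF$metrics, m2$RF$metrics)
})

test_that("permuted labels give chance-level accuracy near the majority fraction", {
  set.seed(55)
  n <- 100L
  x <- tibble::tibble(peak_id = paste0("p", 1:n),
                      f1 = stats::rnorm(n), f2 = stats::rnorm(n),
                      f3 = stats::rnorm(n), f4 = stats::rnorm(n))
  feats <- fake_features(x, rep("distribution", 4))
  labels <- rep(c(TRUE, FALSE), c(60, 40))   # majority fraction 0.6
  accs <- vapply(1:20, function(s) {
    perm <- sample(labels)
    m <- train_end_classifiers(feats, perm,
                               training_protocol(algorithms = "LR", seed = s))
    m$LR$metrics$acc
  }, double(1))
  expect_lt(abs(mean(accs) - 0.6), 0.12)
})

test_that("ablation attributes accuracy to the planted feature group", {
  set.seed(56)
  n <- 120L
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- tibble::tibble(
    peak_id = paste0("p", 1:n),
    noise1 = stats::rnorm(n), noise2 = stats::rnorm(n),
    signal = ifelse(lab, 1, 0) + stats::rnorm(n, 0, 0.2),
    constant = 0
  )
  feats <- fake_features(x, c("distribution", "distribution",
                              "artifact", "dummy"))
  ab <- ablate_groups(feats, lab, training_protocol(seed = 7),
                      algorithm = "RF")
  expect_setequal(ab$group, c("distribution", "artifact", "dummy"))
  expect_equal(ab$group[which.max(ab$drop)], "artifact")
  expect_lt(abs(ab$drop[ab$group == "dummy"]), 0.1)
})

test_that("filtering retains predicted-TRUE peaks with a probability column", {
  set.seed(57)
  n <- 80L
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- tibble::tibble(peak_id = paste0("p", 1:n),
                      f1 = ifelse(lab, 1, 0) + stats::rnorm(n, 0, 0.05),
                      f2 = stats::rnorm(n))
  feats <- fake_features(x, rep("distribution", 2))
  m <- train_end_classifiers(feats, lab,
                             training_protocol(algorithms = "RF", seed = 2))$RF
  peaks <- tibble::tibble(peak_id = x$peak_id, chrom = "chr1", strand = "+",
                          dominant_pos = seq_len(n), end_type = "TSS_5p")
  kept <- filter_peaks(m, peaks, feats)
  pred <- predict(m, feats)
  expect_equal(kept$peak_id, peaks$peak_id[pred])
  expect_true(all(kept$prob_true >= 0.5))
})

test_that("transfer evaluation enforces the feature contract", {
  set.seed(58)
  n <- 60L
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- tibble::tibble(peak_id = paste0("p", 1:n),
                      f1 = ifelse(lab, 1, 0), f2 = stats::rnorm(n))
  feats <- fake_features(x, rep("distribution", 2))
  m <- train_end_classifiers(feats, lab,
                             training_protocol(algorithms = "LR", seed = 3))$LR
  res <- cross_dataset_transfer(m, feats, lab)
  expect_equal(res$acc, 1)
  wrong <- fake_features(dplyr::rename(x, g1 = "f1"), rep("distribution", 2))
  expect_error(cross_dataset_transfer(m, wrong, lab), "contract")
})

test_that("tidiers and autoplot summarise a classifier set", {
  set.seed(59)
  n <- 60L
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- tibble::tibble(peak_id = paste0("p", 1:n),
                      f1 = ifelse(lab, 1, 0) + stats::rnorm(n, 0, 0.2),
                      f2 = stats::rnorm(n))
  feats <- fake_features(x, rep("distribution", 2))
  ms <- train_end_classifiers(feats, lab,
                              training_protocol(algorithms = c("LR", "KNN"),
                                                seed = 4))
  g <- glance(ms)
  expect_equal(g$algorithm, c("LR", "KNN"))
  expect_true(all(c("cv_acc", "acc") %in% names(g)))
  td <- tidy(ms$LR)
  expect_true(all(c("round", "lambda", "cv_acc") %in% names(td)))
  expect_s3_class(autoplot(ms), "ggplot")
})
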