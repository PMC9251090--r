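# SMOTE, stratified folds, metrics, cross-validated CART, and the IFS sweep.

test_that("SMOTE interpolates strictly between minority parents", {
  two <- rbind(a = c(0, 0), b = c(1, 2))
  syn <- smote_oversample(two, 50, k = 1, seed = 1)
  expect_equal(nrow(syn), 50)
  # every synthetic point lies on the segment [a, b], coordinate-wise
  expect_true(all(syn[, 1] >= 0 & syn[, 1] <= 1))
  expect_true(all(syn[, 2] >= 0 & syn[, 2] <= 2))
  expect_equal(syn[, 2], 2 * syn[, 1])        # collinear with the segment

  empty <- smote_oversample(two, 0)
  expect_equal(nrow(empty), 0)
  expect_error(smote_oversample(two[1, , drop = FALSE], 5), "at least 2")
})

test_that("SMOTE provenance identifies the parents of every sample", {
  set.seed(4)
  cloud <- matrix(stats::runif(40 * 3), 40, 3)
  syn <- smote_oversample(cloud, 200, k = 5, seed = 9)
  par <- attr(syn, "parents")
  recon <- cloud[par$i, ] + par$u * (cloud[par$nn, ] - cloud[par$i, ])
  bare <- syn
  attr(bare, "parents") <- NULL
  expect_equal(unname(bare), unname(recon), tolerance = 1e-12)
  lo <- pmin(cloud[par$i, ], cloud[par$nn, ])
  hi <- pmax(cloud[par$i, ], cloud[par$nn, ])
  expect_true(all(syn >= lo - 1e-12 & syn <= hi + 1e-12))
})

test_that("stratified folds balance every class to within one sample", {
  y <- c(rep(1, 20), rep(0, 80))
  f <- stratified_folds(y, 10, seed = 1)
  expect_true(all(table(f[y == 1]) == 2))
  expect_true(all(table(f[y == 0]) == 8))
  expect_length(f, 100)

  y2 <- c(rep(1, 13), rep(0, 40))
  f2 <- stratified_folds(y2, 10, seed = 2)
  pos_counts <- as.vector(table(factor(f2[y2 == 1], levels = 1:10)))
  expect_true(all(pos_counts %in% 1:2))
  expect_equal(sum(pos_counts), 13)

  expect_error(stratified_folds(c(rep(1, 3), rep(0, 50)), 10), "at least 10")
})

test_that("metrics follow the confusion-count definitions", {
  sym <- evaluate_metrics(list(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_equal(unlist(sym),
               c(acc = 0.5, sn = 0.5, sp = 0.5, precision = 0.5,
                 f1 = 0.5, mcc = 0))
  perfect <- evaluate_metrics(list(tp = 10, tn = 90, fp = 0, fn = 0))
  expect_equal(unlist(perfect),
               c(acc = 1, sn = 1, sp = 1, precision = 1, f1 = 1, mcc = 1))
  # zero-denominator metrics are defined as 0
  silent <- evaluate_metrics(list(tp = 0, tn = 9, fp = 0, fn = 1))
  expect_equal(silent$precision, 0)
  expect_equal(silent$f1, 0)
  expect_error(evaluate_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "zero")
})

test_that("cross-validation is perfect on a separable feature and pools counts", {
  set.seed(3)
  y <- rep(c(0, 1), each = 30)
  X <- matrix(y + 0.0, ncol = 1)
  cfg <- ifs_config(folds = 5, seed = 1)
  m <- cv_evaluate(X, y, cfg)
  expect_equal(m$f1, 1)
  expect_equal(m$mcc, 1)
  counts <- attr(m, "counts")
  expect_equal(sum(counts), length(y))   # every sample predicted exactly once
})

test_that("cross-validated MCC concentrates near zero on pure noise", {
  mccs <- vapply(1:3, function(s) {
    nd <- noise_data(n = 200, p = 5, seed = s)
    cv_evaluate(nd$X, nd$y, ifs_config(folds = 10, seed = s))$mcc
  }, 0)
  expect_lt(mean(abs(mccs)), 0.15)
})

test_that("IFS sweeps prefixes by step, includes the ragged tail, ties go small", {
  set.seed(8)
  y <- rep(c(0, 1), each = 40)
  X <- cbind(matrix(y, ncol = 1)[, rep(1, 3)], matrix(stats::rnorm(80 * 4), 80, 4))
  colnames(X) <- paste0("V", 1:7)
  curve <- ifs_run(X, y, ifs_config(step = 5, folds = 5, seed = 2))
  expect_equal(curve$points$n_features, c(5, 7))
  # the label-copy columns make every prefix perfect; the tie resolves to 5
  expect_equal(curve$best$n_features, 5)
  expect_equal(curve$best$f1, 1)

  # tie-breaking rule, checked directly on a synthetic curve
  pts <- data.frame(n_features = c(10, 20), f1 = c(0.7, 0.7))
  expect_equal(enrichdt:::ifs_best(pts)$n_features, 10)
})

test_that("identical seeds reproduce the whole curve", {
  nd <- noise_data(n = 100, p = 8, seed = 12)
  c1 <- ifs_run(nd$X, nd$y, ifs_config(step = 3, folds = 5, seed = 4))
  c2 <- ifs_run(nd$X, nd$y, ifs_config(step = 3, folds = 5, seed = 4))
  expect_identical(c1, c2)
})
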