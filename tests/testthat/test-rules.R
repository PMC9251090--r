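# Final-tree fitting and IF-THEN rule extraction.

# separable one-dimensional data: negatives below 0, positives above 1
split_data <- function(n = 40, seed = 1) {
  set.seed(seed)
  x <- c(stats::runif(n / 2, -1, 0), stats::runif(n / 2, 1, 2))
  list(X = matrix(x, ncol = 1, dimnames = list(NULL, "f")),
       y = rep(c(0L, 1L), each = n / 2))
}

test_that("separable data yields a depth-1 tree with two complementary rules", {
  sd1 <- split_data()
  ft <- fit_final_tree(sd1$X, sd1$y, ifs_config(seed = 1))
  rs <- extract_rules(ft)
  expect_length(rs$rules, 2)
  rels <- sort(vapply(rs$rules, function(r) r$conditions$relation, ""))
  expect_identical(rels, c("<=", ">"))
  thr <- unique(vapply(rs$rules, function(r) r$conditions$threshold, 0))
  expect_length(thr, 1)
  expect_gt(thr, 0); expect_lt(thr, 1)
  classes <- vapply(rs$rules, `[[`, "", "predicted_class")
  expect_setequal(classes, c("positive", "negative"))
})

test_that("repeated conditions on one feature collapse to the tightest bound", {
  conds <- list(
    list(feature = "f", relation = "<=", threshold = 5),
    list(feature = "f", relation = "<=", threshold = 3),
    list(feature = "f", relation = ">", threshold = -2),
    list(feature = "g", relation = ">", threshold = 0.5)
  )
  simp <- enrichdt:::simplify_conditions(conds)
  expect_equal(nrow(simp), 3)
  expect_equal(simp$threshold[simp$feature == "f" & simp$relation == "<="], 3)
  expect_equal(simp$threshold[simp$feature == "f" & simp$relation == ">"], -2)
})

test_that("rule count equals leaf count and supports sum to the real sample size", {
  set.seed(6)
  n <- 150
  X <- matrix(stats::rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("V", 1:4)))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + stats::rnorm(n, sd = 0.4) > 0.4)
  ft <- fit_final_tree(X, y, ifs_config(seed = 3))
  rs <- extract_rules(ft)
  expect_equal(length(rs$rules), sum(ft$tree$frame$var == "<leaf>"))
  supports <- t(vapply(rs$rules, `[[`, c(n_positive = 0, n_negative = 0),
                       "support"))
  expect_equal(sum(supports), n)
  expect_equal(sum(supports[, "n_positive"]), sum(y == 1))
  # ordered by descending total real support
  expect_true(all(diff(rowSums(supports)) <= 0))
})

test_that("rules reproduce tree predictions and match exactly once per probe", {
  set.seed(11)
  n <- 200
  X <- matrix(stats::rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(X[, 1] > 0.3 | X[, 2] < -0.8)
  ft <- fit_final_tree(X, y, ifs_config(seed = 5))
  rs <- extract_rules(ft)

  tree_pred <- enrichdt:::predict_cart(ft$tree, X)
  for (i in seq_len(n)) {
    rp <- predict_with_rules(rs, X[i, ])
    expect_identical(rp, if (tree_pred[i] == 1) "positive" else "negative")
  }

  probes <- matrix(stats::runif(500 * 3, -4, 4), 500, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  probe_pred <- enrichdt:::predict_cart(ft$tree, probes)
  for (i in seq_len(nrow(probes))) {
    matches <- vapply(rs$rules, enrichdt:::rule_matches, TRUE, x = probes[i, ])
    expect_equal(sum(matches), 1)
    expect_identical(rs$rules[[which(matches)]]$predicted_class,
                     if (probe_pred[i] == 1) "positive" else "negative")
  }
})

test_that("determinism and the degenerate single-split training accuracy hold", {
  sd2 <- split_data(n = 60, seed = 2)
  ft1 <- fit_final_tree(sd2$X, sd2$y, ifs_config(seed = 9))
  ft2 <- fit_final_tree(sd2$X, sd2$y, ifs_config(seed = 9))
  expect_identical(ft1$tree$frame, ft2$tree$frame)
  expect_identical(ft1$tree$splits, ft2$tree$splits)

  # unrestricted CART separates distinct points perfectly on its training set
  set.seed(13)
  n <- 80
  X <- matrix(stats::rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- sample(c(0L, 1L), n, replace = TRUE)
  ft3 <- fit_final_tree(X, y, ifs_config(seed = 2))
  balanced_n <- nrow(X) + ft3$n_synthetic
  pred_real <- enrichdt:::predict_cart(ft3$tree, X)
  expect_equal(pred_real, y)
  expect_equal(length(ft3$tree$where), balanced_n)
})

test_that("feature vectors missing a rule feature are refused", {
  sd3 <- split_data()
  rs <- extract_rules(fit_final_tree(sd3$X, sd3$y, ifs_config(seed = 1)))
  expect_error(predict_with_rules(rs, c(zzz = 1)), "cover")
})

test_that("rule sets serialize to JSON and readable text", {
  sd4 <- split_data(n = 30, seed = 4)
  rs <- extract_rules(fit_final_tree(sd4$X, sd4$y, ifs_config(seed = 1)))
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "rules.json")
  tp <- file.path(dir, "rules.txt")
  write_rules(rs, jp, tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(length(back$rules$predicted_class), length(rs$rules))
  expect_true(any(grepl("THEN class = positive", readLines(tp))))
})
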