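# Splitting, tree training with balanced class weights, depth selection
# and the bias power curve.

test_that("stratified split follows the 20% / 90:10 arithmetic", {
  labels <- rep(c("train", "generated"), each = 500)
  sp <- split_data(labels, seed = 4)
  expect_equal(length(sp$test), 200)
  expect_equal(length(sp$validation), 80)
  expect_equal(length(sp$train), 720)
  # disjoint and exhaustive
  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_identical(all_idx, seq_along(labels))
  # stratified: both classes appear proportionally in the test set
  expect_equal(sum(labels[sp$test] == "train"), 100)
  # identical seed, identical partition
  expect_identical(sp, split_data(labels, seed = 4))
  expect_error(split_data(rep("train", 20)), "both classes")
  expect_error(split_data(rep(c("a", "b"), c(5, 50))), ">= 10")
})

test_that("a label-defining feature is learned perfectly", {
  set.seed(2)
  n <- 200
  X <- cbind(flag = rep(c(0, 1), each = n / 2),
             matrix(rnorm(n * 5), n, 5))
  colnames(X) <- c("flag", paste0("v", 1:5))
  y <- ifelse(X[, "flag"] == 1, "generated", "train")
  d <- fit_discriminator(X, y, seed = 11)
  expect_equal(d$test_balanced_accuracy, 1)
  expect_gte(d$chosen_depth, 1)
  expect_equal(names(which.max(d$importances)), "flag")
})

test_that("importances are a probability vector over features", {
  set.seed(3)
  X <- matrix(rnorm(300 * 8), 300, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- ifelse(X[, 1] + rnorm(300, 0, 0.5) > 0, "a", "b")
  d <- fit_discriminator(X, y, seed = 5)
  expect_true(all(d$importances >= 0))
  expect_equal(sum(d$importances), 1)
  expect_lte(length(d$top_features), 5)
  expect_true(d$chosen_depth %in% 3:17)
  expect_gte(d$test_balanced_accuracy, 0)
  expect_lte(d$test_balanced_accuracy, 1)
})

test_that("randomly permuted labels give chance-level accuracy", {
  set.seed(8)
  X <- matrix(rnorm(500 * 20), 500, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  y <- sample(rep(c("train", "generated"), each = 250))
  accs <- vapply(1:10, function(s) {
    fit_discriminator(X, y, seed = s)$test_balanced_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("re-running with a fixed seed reproduces the report exactly", {
  set.seed(13)
  X <- matrix(rnorm(300 * 10), 300, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- ifelse(X[, 2] > 0.2, "train", "generated")
  d1 <- fit_discriminator(X, y, seed = 21)
  d2 <- fit_discriminator(X, y, seed = 21)
  expect_identical(d1$chosen_depth, d2$chosen_depth)
  expect_identical(d1$test_balanced_accuracy, d2$test_balanced_accuracy)
  expect_identical(d1$validation, d2$validation)
  expect_identical(d1$importances, d2$importances)
})

test_that("constant features yield a flagged chance-level report", {
  X <- matrix(1, 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("train", "generated"), each = 50)
  d <- fit_discriminator(X, y, seed = 2)
  expect_true(d$degenerate)
  expect_equal(d$test_balanced_accuracy, 0.5, tolerance = 1e-9)
})

test_that("depth truncation yields a nested tree family", {
  set.seed(30)
  X <- matrix(rnorm(400 * 12), 400, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  y <- ifelse(X[, 1] + 0.8 * X[, 2] + rnorm(400, 0, 0.6) > 0,
              "train", "generated")
  df <- as.data.frame(X); df$.y <- factor(y)
  full <- rpart::rpart(.y ~ ., df, method = "class",
                       control = rpart::rpart.control(
                         maxdepth = 13, cp = 0, xval = 0,
                         minsplit = 4, minbucket = 2))
  depths <- function(f) floor(log2(as.integer(rownames(f$frame))))
  prev_nodes <- NULL
  for (d in c(2, 4, 6)) {
    tr <- molaudit:::.truncate_tree(full, d)
    # no internal node deeper than d - 1; no leaf deeper than d
    dep <- depths(tr)
    expect_lte(max(dep[tr$frame$var != "<leaf>"]), d - 1)
    expect_lte(max(dep), d)
    # nested: every node of the shallower tree persists in the deeper
    if (!is.null(prev_nodes)) {
      expect_true(all(prev_nodes %in% rownames(tr$frame)))
    }
    prev_nodes <- rownames(tr$frame)
  }
  # truncating at the grown depth returns the tree unchanged
  expect_identical(molaudit:::.truncate_tree(full, 30)$frame, full$frame)
})
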