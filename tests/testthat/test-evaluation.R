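ref <- voc_reference()

test_that("stratified 7:3 split reproduces 63/27 with 21/9 per origin", {
  cohort <- generate_cohort(ref, seed = 1)
  sp <- stratified_split(cohort, seed = 42)
  expect_equal(nrow(sp$train), 63L)
  expect_equal(nrow(sp$test), 27L)
  expect_equal(as.vector(table(sp$train$origin)), c(21L, 21L, 21L))
  expect_equal(as.vector(table(sp$test$origin)), c(9L, 9L, 9L))
})

test_that("splits are disjoint and exhaustive across seeds", {
  cohort <- generate_cohort(ref, seed = 2, n_per_origin = 10)
  for (seed in 1:100) {
    sp <- stratified_split(cohort, seed = seed)
    ids <- c(sp$train$sample_id, sp$test$sample_id)
    expect_setequal(ids, cohort$sample_id)
    expect_equal(length(intersect(sp$train$sample_id, sp$test$sample_id)), 0L)
  }
})

test_that("small unbalanced splits follow the floor + remainder rule", {
  toy <- tibble::tibble(
    sample_id = paste0("s", 1:4), origin = c(0L, 0L, 1L, 1L),
    A1 = rnorm(4)
  )
  sp <- stratified_split(toy, train_fraction = 0.5, seed = 1)
  expect_equal(nrow(sp$train), 2L)
  expect_equal(sort(sp$train$origin), c(0L, 1L))
  expect_error(stratified_split(toy, train_fraction = 1),
               class = "kelptrace_argument_error")
  toy_bad <- toy[c(1, 2, 3), ]
  expect_error(stratified_split(toy_bad, seed = 1),
               class = "kelptrace_argument_error")
})

test_that("scaler is fit on training rows only and standardizes exactly", {
  train <- tibble::tibble(sample_id = paste0("t", 1:3), origin = c(0L, 1L, 2L),
                          A1 = c(2, 4, 6), A2 = c(1, 1, 1))
  expect_warning(scaler <- fit_scaler(train), "constant")
  expect_equal(unname(scaler$mu[["A1"]]), 4)
  # population SD: sqrt(mean((x - mu)^2))
  expect_equal(unname(scaler$sigma[["A1"]]), sqrt(8 / 3))

  scaled <- apply_scaler(scaler, train)
  expect_equal(mean(scaled$A1), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(scaled$A1^2)), 1, tolerance = 1e-12)
  expect_equal(scaled$A2, c(0, 0, 0))  # zero-variance path

  test <- tibble::tibble(sample_id = "u1", origin = 0L, A1 = 4, A2 = 9)
  scaled_test <- apply_scaler(scaler, test)
  expect_equal(scaled_test$A1, 0)  # equals the training mean exactly
  expect_equal(scaled_test$A2, 0)

  # applying never mutates the parameters
  before <- unclass(scaler)
  invisible(apply_scaler(scaler, test))
  expect_identical(unclass(scaler), before)
  expect_error(fit_scaler(train[0, ]), class = "kelptrace_argument_error")
})

test_that("a perfect confusion matrix yields 100% everywhere", {
  y <- rep(0:2, each = 9)
  probs <- matrix(0.05, 27, 3)
  probs[cbind(1:27, y + 1)] <- 0.9
  ev <- evaluate_predictions(y, probs)
  expect_equal(unname(diag(ev$confusion)), c(9L, 9L, 9L))
  expect_equal(sum(ev$confusion), 27L)
  expect_equal(ev$accuracy, 1)
  expect_equal(unname(ev$macro), c(1, 1, 1))
  expect_equal(unname(ev$auc), c(1, 1, 1))
  expect_equal(ev$metrics$f1, c(1, 1, 1))
})

test_that("degenerate all-one-class predictions score as expected", {
  y <- rep(0:2, each = 5)
  probs <- cbind(rep(0.8, 15), 0.1, 0.1)
  ev <- evaluate_predictions(y, probs)
  expect_equal(ev$accuracy, 1 / 3)
  m0 <- ev$metrics[ev$metrics$class == "rongcheng", ]
  expect_equal(m0$recall, 1)
  expect_equal(m0$precision, 1 / 3)
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting", {
  # worked binary examples: separable ranking -> 1; one discordant pair
  # among 2 x 2 -> 3/4
  for (case in list(list(truth = c(TRUE, TRUE, FALSE, FALSE), auc = 1),
                    list(truth = c(TRUE, FALSE, TRUE, FALSE), auc = 0.75))) {
    scores <- c(0.9, 0.8, 0.7, 0.1)
    pts <- kelptrace:::roc_points(scores, case$truth)
    expect_equal(kelptrace:::trapezoid_auc(pts$fpr, pts$tpr),
                 pair_count_auc(scores, case$truth))
    expect_equal(pair_count_auc(scores, case$truth), case$auc)
  }

  # random instances with heavy ties, n <= 50: exact equality incl. ties
  set.seed(7)
  for (trial in 1:50) {
    n <- sample(5:50, 1)
    positive <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(positive)) < 2) positive[1:2] <- c(TRUE, FALSE)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    pts <- kelptrace:::roc_points(scores, positive)
    auc_trap <- kelptrace:::trapezoid_auc(pts$fpr, pts$tpr)
    expect_equal(auc_trap, pair_count_auc(scores, positive), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on random binary problems", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (trial in 1:10) {
    n <- 40
    positive <- rep(c(TRUE, FALSE), each = n / 2)
    scores <- rnorm(n, mean = positive * runif(1, 0, 2))
    pts <- kelptrace:::roc_points(scores, positive)
    mine <- kelptrace:::trapezoid_auc(pts$fpr, pts$tpr)
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = positive, predictor = scores, quiet = TRUE,
      direction = "<", levels = c(FALSE, TRUE)
    )))
    expect_equal(mine, theirs, tolerance = 1e-12)
  }
})

test_that("class permutation permutes per-class metrics consistently", {
  set.seed(13)
  y <- sample(0:2, 60, replace = TRUE)
  probs <- matrix(runif(180), 60, 3)
  probs <- probs / rowSums(probs)
  ev <- evaluate_predictions(y, probs)
  expect_true(all(ev$metrics$f1 >= 0 & ev$metrics$f1 <= 1))
  expect_gte(ev$macro[["f1"]], 0)
  expect_lte(ev$macro[["f1"]], 1)

  perm <- c(2L, 0L, 1L)  # new label = perm[old label + 1]
  y_p <- perm[y + 1L]
  probs_p <- probs[, order(perm)]
  ev_p <- evaluate_predictions(y_p, probs_p)
  for (old_class in 0:2) {
    a <- ev$metrics[old_class + 1L, c("precision", "recall", "f1")]
    b <- ev_p$metrics[perm[old_class + 1L] + 1L, c("precision", "recall", "f1")]
    expect_equal(unname(as.numeric(a)), unname(as.numeric(b)))
    expect_equal(unname(ev$auc[old_class + 1L]),
                 unname(ev_p$auc[perm[old_class + 1L] + 1L]))
  }
  expect_error(evaluate_predictions(c(0, 1), probs),
               class = "kelptrace_argument_error")
})
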